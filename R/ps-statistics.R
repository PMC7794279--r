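# Portilla-Simoncelli summary statistics pooled over a fixed circular window.
#
# The statistic set follows the texture-analysis parameterization used with
# complex steerable pyramids: pixel-histogram marginals; skew/kurtosis and
# central autocorrelation of the bandlimited lowpass reconstruction at each
# scale; means and central autocorrelations of oriented band magnitudes;
# within-scale and adjacent-scale covariances of band magnitudes; within-scale
# covariances of band real parts and cross-scale phase (real/imaginary)
# covariances against phase-doubled parents; and the highpass variance.
# Symmetric halves of all correlation matrices and centrally-symmetric halves
# of autocorrelation neighborhoods are kept once, which at the default
# parameters (4 scales, 4 orientations, 7-pixel neighborhood) yields exactly
# 782 statistics.

#' Parameters of the summary-statistics computation
#'
#' @param n_scales Number of pyramid scales. Default 4.
#' @param n_orientations Number of orientations. Default 4.
#' @param neighborhood Odd size (>= 3) of the square neighborhood over which
#'   spatial autocorrelations are computed, in pixels of the relevant scale.
#'   Default 7 (0.7 deg at 30 px/deg after downsampling, the model-observer
#'   setting; texture synthesis pipelines typically use 9).
#' @param pooling_diameter_px Diameter of the circular pooling window in
#'   pixels. Default 360, the Bouma-law diameter at 12 deg eccentricity
#'   ([bouma_pooling_diameter()]).
#' @return Object of class `ps_params`.
#' @export
ps_params <- function(n_scales = 4, n_orientations = 4, neighborhood = 7,
                      pooling_diameter_px = 360) {
  if (neighborhood < 3 || neighborhood %% 2 != 1)
    stop("neighborhood must be an odd integer >= 3")
  if (n_scales < 1 || n_orientations < 1)
    stop("n_scales and n_orientations must be >= 1")
  structure(list(n_scales = as.integer(n_scales),
                 n_orientations = as.integer(n_orientations),
                 neighborhood = as.integer(neighborhood),
                 pooling_diameter_px = as.integer(pooling_diameter_px)),
            class = "ps_params")
}

#' @export
print.ps_params <- function(x, ...) {
  cat(sprintf("<ps_params %d scales, %d orientations, Na = %d, pooling %d px; %d statistics>\n",
              x$n_scales, x$n_orientations, x$neighborhood,
              x$pooling_diameter_px, ps_stat_count(x)))
  invisible(x)
}

#' Number of retained summary statistics
#'
#' Closed-form count of the deduplicated statistic set as a function of the
#' parameters; 782 at the defaults.
#'
#' @param params A [ps_params()].
#' @return Integer count.
#' @export
ps_stat_count <- function(params = ps_params()) {
  nsc <- params$n_scales; nor <- params$n_orientations
  half_ac <- (params$neighborhood^2 + 1) / 2
  tri <- nor * (nor + 1) / 2
  as.integer(
    6 +                            # pixel marginals
    2 * (nsc + 1) +                # lowpass skew/kurtosis
    half_ac * (nsc + 1) +          # lowpass autocorrelations
    half_ac * nsc * nor +          # magnitude autocorrelations
    nsc * nor +                    # magnitude means
    tri * nsc +                    # within-scale magnitude covariances
    nor^2 * (nsc - 1) +            # adjacent-scale magnitude covariances
    tri * nsc +                    # within-scale real-part covariances
    2 * nor^2 * (nsc - 1) +        # cross-scale phase covariances
    1                              # highpass variance
  )
}

## ---- weighted moments ----------------------------------------------------

w_moments <- function(x, w) {
  mu <- sum(w * x)
  v <- sum(w * (x - mu)^2)
  if (v < 1e-12) {
    c(mean = mu, var = v, skew = 0, kurt = 0)
  } else {
    c(mean = mu, var = v,
      skew = sum(w * (x - mu)^3) / v^1.5,
      kurt = sum(w * (x - mu)^4) / v^2)
  }
}

#' Window-weighted marginal pixel statistics
#'
#' Weighted mean, variance, skewness, kurtosis plus min and max of the
#' pixels under the window support. For zero-variance input, skewness and
#' kurtosis are reported as 0 by convention (no missing values downstream).
#'
#' @param img A [gray_image()] or matrix.
#' @param window A [pooling_window()] matching the image dimensions.
#' @return Named numeric vector of length 6.
#' @export
marginal_stats <- function(img, window) {
  m <- if (is_gray_image(img)) img_mat(img) else as.matrix(img)
  if (!all(dim(m) == dim(window)))
    stop("window dimensions must match the image")
  w <- window_at_scale(window, dim(m))
  mom <- w_moments(m, w)
  supp <- m[unclass(window) > 0]
  c(mom, min = min(supp), max = max(supp))
}

# Half of the Na x Na lag neighborhood under central symmetry, center first.
half_neighborhood <- function(na) {
  la <- (na - 1) %/% 2
  lags <- expand.grid(dj = -la:la, di = -la:la)
  keep <- lags$di > 0 | (lags$di == 0 & lags$dj >= 0)
  lags[keep, c("di", "dj")][order(-keep[keep]), ]
}

# Central autocorrelation statistics of one map under window weights:
# zero-lag entry is the weighted variance; off-center lags are symmetrized
# covariances normalized by that variance (0 when variance is degenerate).
autocorr_stats <- function(x, w, na, prefix) {
  mu <- sum(w * x)
  xc <- x - mu
  v <- sum(w * xc^2)
  la <- (na - 1) %/% 2
  cc <- w_ccor_map(w * xc, xc)   # all lags at once
  vals <- c()
  nms <- c()
  for (di in 0:la) {
    djs <- if (di == 0) 0:la else -la:la
    for (dj in djs) {
      if (di == 0 && dj == 0) {
        vals <- c(vals, v)
      } else {
        cpos <- ccor_at(cc, di, dj)
        cneg <- ccor_at(cc, -di, -dj)
        vals <- c(vals, if (v < 1e-12) 0 else 0.5 * (cpos + cneg) / v)
      }
      nms <- c(nms, sprintf("%s_d%d_%d", prefix, di, dj))
    }
  }
  stats::setNames(vals, nms)
}

# Weighted covariance of two centered maps.
w_cov <- function(xc, yc, w) sum(w * xc * yc)

## ---- full statistic vector -----------------------------------------------

#' Compute the summary-statistics vector of an image
#'
#' Runs the steerable-pyramid decomposition and evaluates the full
#' Portilla-Simoncelli statistic set over a circular pooling window centered
#' on the target, every averaging operation weighted by the window resampled
#' (block-averaged) to the relevant pyramid resolution. See the package
#' vignette for the exact enumeration of the retained set.
#'
#' @param img A [gray_image()] whose dimensions accommodate `n_scales`
#'   levels and the pooling window.
#' @param params A [ps_params()].
#' @param window A [pooling_window()]; defaults to a centered window of
#'   `params$pooling_diameter_px`.
#' @return Object of class `ps_stat_vector`: a named numeric vector (length
#'   [ps_stat_count()]) with the parameters attached as an attribute.
#' @export
compute_ps_statistics <- function(img, params = ps_params(), window = NULL) {
  m <- if (is_gray_image(img)) img_mat(img) else as.matrix(img)
  d <- dim(m)
  if (is.null(window)) {
    if (params$pooling_diameter_px > min(d))
      stop("pooling window diameter exceeds image size")
    window <- pooling_window(d, params$pooling_diameter_px)
  }
  nsc <- params$n_scales; nor <- params$n_orientations; na <- params$neighborhood
  pyr <- build_pyramid(gray_image(m, px_per_deg = if (is_gray_image(img)) img_ppd(img) else 30),
                       n_scales = nsc, n_orientations = nor)

  ws <- lapply(seq_len(nsc), function(s) window_at_scale(window, dim(pyr$bands[[s]][[1]])))
  out <- c()

  # 1. pixel marginals
  mom <- marginal_stats(m, window)
  out <- c(out, stats::setNames(mom, paste0("pix_", names(mom))))

  # 2-3. lowpass reconstructions: skew/kurtosis and autocorrelation
  lp <- vector("list", nsc + 1)
  lp[[nsc + 1]] <- pyr$lowpass
  cur <- pyr$lowpass
  for (s in nsc:1) {
    if (!all(dim(cur) == dim(pyr$bands[[s]][[1]]))) cur <- upsample2_spectral(cur)
    cur <- cur + Reduce(`+`, lapply(pyr$bands[[s]], Re))
    lp[[s]] <- cur
  }
  for (s in seq_len(nsc + 1)) {
    wl <- if (s <= nsc) ws[[s]] else window_at_scale(window, dim(lp[[s]]))
    mo <- w_moments(lp[[s]], wl)
    out <- c(out, stats::setNames(mo[c("skew", "kurt")],
                                  sprintf("lp_%s_s%d", c("skew", "kurt"), s)))
    out <- c(out, autocorr_stats(lp[[s]], wl, na, sprintf("lp_ac_s%d", s)))
  }

  # 4-5. band magnitudes: means, autocorrelations
  mags <- lapply(seq_len(nsc), function(s) lapply(pyr$bands[[s]], Mod))
  magc <- vector("list", nsc)   # centered magnitudes
  for (s in seq_len(nsc)) {
    magc[[s]] <- vector("list", nor)
    for (k in seq_len(nor)) {
      mu <- sum(ws[[s]] * mags[[s]][[k]])
      out <- c(out, stats::setNames(mu, sprintf("mag_mean_s%d_o%d", s, k)))
      magc[[s]][[k]] <- mags[[s]][[k]] - mu
    }
  }
  for (s in seq_len(nsc))
    for (k in seq_len(nor))
      out <- c(out, autocorr_stats(mags[[s]][[k]], ws[[s]], na,
                                   sprintf("mag_ac_s%d_o%d", s, k)))

  # 6. within-scale magnitude covariances (upper triangle incl. diagonal)
  for (s in seq_len(nsc))
    for (j in seq_len(nor))
      for (k in j:nor)
        out <- c(out, stats::setNames(w_cov(magc[[s]][[j]], magc[[s]][[k]], ws[[s]]),
                                      sprintf("mag_ccov_s%d_o%d_o%d", s, j, k)))

  # 7. adjacent-scale magnitude covariances (child vs upsampled parent)
  for (s in seq_len(nsc - 1)) {
    pmag <- lapply(seq_len(nor), function(k) {
      up <- upsample2_spectral(mags[[s + 1]][[k]])
      up - sum(ws[[s]] * up)
    })
    for (j in seq_len(nor))
      for (k in seq_len(nor))
        out <- c(out, stats::setNames(w_cov(magc[[s]][[j]], pmag[[k]], ws[[s]]),
                                      sprintf("mag_pcov_s%d_o%d_po%d", s, j, k)))
  }

  # 8. within-scale real-part covariances
  reals <- lapply(seq_len(nsc), function(s) lapply(pyr$bands[[s]], function(b) {
    r <- Re(b); r - sum(ws[[s]] * r)
  }))
  for (s in seq_len(nsc))
    for (j in seq_len(nor))
      for (k in j:nor)
        out <- c(out, stats::setNames(w_cov(reals[[s]][[j]], reals[[s]][[k]], ws[[s]]),
                                      sprintf("real_ccov_s%d_o%d_o%d", s, j, k)))

  # 9. cross-scale phase covariances against phase-doubled upsampled parents
  for (s in seq_len(nsc - 1)) {
    pdbl <- lapply(seq_len(nor), function(k) {
      up <- upsample2_spectral(pyr$bands[[s + 1]][[k]])
      ph <- up * up / pmax(Mod(up), 1e-12)   # doubled phase, magnitude kept
      list(re = Re(ph) - sum(ws[[s]] * Re(ph)),
           im = Im(ph) - sum(ws[[s]] * Im(ph)))
    })
    for (j in seq_len(nor))
      for (k in seq_len(nor)) {
        out <- c(out, stats::setNames(w_cov(reals[[s]][[j]], pdbl[[k]]$re, ws[[s]]),
                                      sprintf("phase_pcov_s%d_o%d_pre%d", s, j, k)))
        out <- c(out, stats::setNames(w_cov(reals[[s]][[j]], pdbl[[k]]$im, ws[[s]]),
                                      sprintf("phase_pcov_s%d_o%d_pim%d", s, j, k)))
      }
  }

  # 10. highpass variance
  whp <- window_at_scale(window, dim(pyr$highpass))
  out <- c(out, stats::setNames(w_moments(pyr$highpass, whp)["var"], "hp_var"))

  stopifnot(length(out) == ps_stat_count(params))
  structure(out, params = params, class = "ps_stat_vector")
}

#' @export
print.ps_stat_vector <- function(x, ...) {
  cat(sprintf("<ps_stat_vector of %d statistics>\n", length(x)))
  utils::str(stats::setNames(as.numeric(x[1:6]), names(x)[1:6]))
  invisible(x)
}

#' Element-wise difference of two statistic vectors
#'
#' The predictor construction of the model observer: subtracts the
#' statistics of the second stimulus from those of the first, requiring an
#' identical name ordering.
#'
#' @param a,b `ps_stat_vector` objects (or named numerics) with identical
#'   names.
#' @return Named numeric vector `a - b`.
#' @export
statistic_difference <- function(a, b) {
  if (length(a) != length(b) || !identical(names(a), names(b)))
    stop("statistic vectors are not aligned (names differ)")
  out <- as.numeric(a) - as.numeric(b)
  names(out) <- names(a)
  out
}

#' Write a statistic vector as name,value CSV
#'
#' @param x A `ps_stat_vector`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ps_stats <- function(x, path) {
  utils::write.csv(data.frame(name = names(x), value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}
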
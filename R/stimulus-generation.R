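# Construction of experiment stimuli: phase-scrambled counterparts,
# spectrum/histogram-matched surround textures, and the target/surround
# geometries (disk, split target, ring, half ring, gap) used in the
# texture-discrimination experiments.

impose_fas <- function(m, amp) {
  ph <- Arg(fft2(m))
  Re(ifft2(amp * exp(1i * ph)))
}

#' Phase-scramble an image
#'
#' Destroys higher-order statistics while preserving the Fourier amplitude
#' spectrum exactly: a seeded i.i.d. uniform noise image provides the phases,
#' which are combined with the input's amplitude spectrum. Only the noise
#' phases are used, so the noise distribution is immaterial.
#'
#' @param img A [gray_image()].
#' @param rng_seed Integer seed for the noise image.
#' @return A [gray_image()] with identical amplitude spectrum and scrambled
#'   phase structure.
#' @export
phase_scramble <- function(img, rng_seed = 1) {
  m <- img_mat(img)
  amp <- Mod(fft2(m))
  nz <- with_seed(rng_seed,
                  matrix(stats::runif(length(m)), nrow(m), ncol(m)))
  out <- Re(ifft2(amp * exp(1i * Arg(fft2(nz)))))
  gray_image(out, px_per_deg = img_ppd(img))
}

# local save/restore of the global RNG state so seeded helpers do not
# disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Rank-order histogram matching
#'
#' Replaces the pixel values of an image by a reference set of sorted
#' values, preserving the spatial rank order (ties broken by a fixed scan
#' order, column-major).
#'
#' @param img A [gray_image()].
#' @param reference_sorted_values Numeric vector of target values, length
#'   equal to the pixel count (sorted internally).
#' @return A [gray_image()] whose sorted pixel values equal the reference.
#' @export
histogram_match <- function(img, reference_sorted_values) {
  m <- img_mat(img)
  if (length(reference_sorted_values) != length(m))
    stop("reference length (", length(reference_sorted_values),
         ") must equal the pixel count (", length(m), ")")
  out <- m
  out[order(m)] <- sort(reference_sorted_values)
  gray_image(out, px_per_deg = img_ppd(img))
}

#' Alternating spectrum and histogram matching
#'
#' Iteratively imposes a reference Fourier amplitude spectrum and a
#' reference pixel histogram, ending on the histogram step; used to build
#' surround textures dissimilar to the target only in higher-order
#' statistics. Convergence is reported, not enforced: the final relative
#' spectrum and histogram errors are attached as the `"convergence"`
#' attribute, and a warning is issued when either error fails to decrease
#' monotonically over the last five iterations.
#'
#' @param img A [gray_image()] to adjust.
#' @param fas_reference A [gray_image()] supplying the target amplitude
#'   spectrum (same dimensions).
#' @param hist_reference Numeric vector of target pixel values (length of
#'   the pixel count).
#' @param n_iter Number of rounds. Default 30.
#' @return A [gray_image()] with a `"convergence"` attribute (data frame of
#'   per-iteration relative errors).
#' @export
iterative_fas_hist_match <- function(img, fas_reference, hist_reference,
                                     n_iter = 30) {
  m <- img_mat(img)
  if (!all(dim(m) == dim(fas_reference)))
    stop("images must share dimensions")
  amp <- Mod(fft2(img_mat(fas_reference)))
  href <- sort(hist_reference)
  amp_norm <- sqrt(sum(amp^2))
  h_norm <- sqrt(sum(href^2))
  fas_err <- hist_err <- numeric(n_iter)
  x <- m
  for (i in seq_len(n_iter)) {
    x <- impose_fas(x, amp)
    xs <- x
    xs[order(x)] <- href
    x <- xs
    fas_err[i] <- sqrt(sum((Mod(fft2(x)) - amp)^2)) / amp_norm
    hist_err[i] <- sqrt(sum((sort(x) - href)^2)) / h_norm
  }
  if (n_iter >= 5) {
    tail5 <- seq(n_iter - 4, n_iter)
    if (!all(diff(fas_err[tail5]) <= 1e-9) || !all(diff(hist_err[tail5]) <= 1e-9))
      warning("spectrum/histogram matching not monotonically converging over the last 5 iterations")
  }
  out <- gray_image(x, px_per_deg = img_ppd(img))
  attr(out, "convergence") <- data.frame(iter = seq_len(n_iter),
                                         fas_err = fas_err,
                                         hist_err = hist_err)
  out
}

rot90k <- function(m, k) {
  k <- k %% 4
  if (k == 0) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

#' Sample a patch from a large source texture
#'
#' Emulates trial-by-trial stimulus sampling: the source is rotated by a
#' seeded multiple of 90 degrees, then a patch position is drawn uniformly
#' over all valid positions.
#'
#' @param source A [gray_image()].
#' @param size_px Integer pair (rows, cols), or a single size.
#' @param rng_seed Integer seed controlling rotation and position.
#' @param rotation Optional fixed rotation count (0-3) overriding the drawn
#'   one, so that all textures of one trial can share a rotation.
#' @return A [gray_image()] patch.
#' @export
sample_patch <- function(source, size_px, rng_seed = 1, rotation = NULL) {
  m <- img_mat(source)
  size_px <- rep(as.integer(size_px), length.out = 2)
  with_seed(rng_seed, {
    k <- if (is.null(rotation)) sample.int(4, 1) - 1 else as.integer(rotation)
    m <- rot90k(m, k)
    d <- dim(m)
    if (any(size_px > d))
      stop("patch size (", size_px[1], " x ", size_px[2],
           ") exceeds source size (", d[1], " x ", d[2], ")")
    r0 <- if (d[1] == size_px[1]) 0L else sample.int(d[1] - size_px[1] + 1, 1) - 1L
    c0 <- if (d[2] == size_px[2]) 0L else sample.int(d[2] - size_px[2] + 1, 1) - 1L
    gray_image(m[r0 + seq_len(size_px[1]), c0 + seq_len(size_px[2])],
               px_per_deg = img_ppd(source))
  })
}
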
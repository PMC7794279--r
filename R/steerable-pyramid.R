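# Complex steerable pyramid, built in the frequency domain with circular
# boundary handling. Oriented bands are analytic (single-lobe) so that the
# coefficient magnitude is a local oriented-energy envelope and the real part
# a band-pass filter output; this is the filter bank feeding the
# summary-statistics stage.

# Radial raised-cosine pair on a log2 frequency axis. `hp` rises from 0 at
# c/2 to 1 at c; `lp` is its complement, so lp^2 + hp^2 = 1 everywhere.
radial_highpass <- function(r, c) {
  out <- numeric(length(r))
  out[r >= c] <- 1
  mid <- r > c / 2 & r < c
  out[mid] <- cos((pi / 2) * log2(r[mid] / c))
  dim(out) <- dim(r)
  out
}

radial_lowpass <- function(r, c) {
  out <- sqrt(pmax(0, 1 - radial_highpass(r, c)^2))
  dim(out) <- dim(r)
  out
}

# Angular amplitude of orientation k (1-based) out of K: |cos(theta - theta_k)|^(K-1)
# normalized so the squared amplitudes of all K orientations sum to 1.
angular_amplitude <- function(theta, k, K) {
  cK <- K * choose(2 * K - 2, K - 1) / 4^(K - 1)
  a <- cos(theta - (k - 1) * pi / K)
  (abs(a)^(K - 1)) / sqrt(cK)
}

# Single-lobe (analytic) complex orientation mask. The sqrt(2) factor makes
# the summed symmetrized band energies tile the spectrum exactly (Parseval for
# real-valued inputs); the unit-modulus constant fixes the phase convention so
# the real part behaves as an even-symmetric oriented filter.
angular_mask <- function(theta, k, K) {
  lobe <- cos(theta - (k - 1) * pi / K) > 0
  sqrt(2) * angular_amplitude(theta, k, K) * lobe * (-1i)^(K - 1)
}

#' Complex steerable-pyramid decomposition
#'
#' Decomposes an image into multi-scale, multi-orientation complex bands plus
#' real high- and lowpass residuals, the V1-like filtering stage of the
#' summary-statistics model. Filters are polar-separable in the frequency
#' domain, with raised-cosine radial transitions spanning one octave and
#' `cos^(K-1)` orientation tuning; their squared amplitude responses tile the
#' spectrum (tight frame), and downsampling is by alias-free spectral
#' cropping. Oriented bands are analytic (one frequency half-plane), so band
#' magnitudes are smooth local energy envelopes.
#'
#' @param img A [gray_image()] (or plain matrix). Both dimensions must be
#'   divisible by `2^n_scales`.
#' @param n_scales Number of scales (octaves). Default 4.
#' @param n_orientations Number of orientation bands per scale (>= 1).
#'   Default 4.
#' @return An object of class `steerable_pyramid`: a list with `bands` (a
#'   list over scales, each a list of `n_orientations` complex matrices; the
#'   scale-s band has dimensions `dim(img) / 2^(s-1)`), `highpass` (real,
#'   full resolution), `lowpass` (real, coarsest resolution), and the
#'   decomposition parameters.
#' @export
build_pyramid <- function(img, n_scales = 4, n_orientations = 4) {
  if (n_orientations < 1) stop("n_orientations must be >= 1")
  if (n_scales < 1) stop("n_scales must be >= 1")
  m <- if (is_gray_image(img)) img_mat(img) else as.matrix(img)
  d <- dim(m)
  if (any(d %% 2^n_scales != 0))
    stop("image dimensions (", d[1], " x ", d[2],
         ") must be divisible by 2^n_scales = ", 2^n_scales)

  F0 <- fftshift2(fft2(m))
  pg <- polar_grid(d[1], d[2])
  hi0 <- radial_highpass(pg$r, pi)
  lo0 <- radial_lowpass(pg$r, pi)

  highpass <- Re(ifft2(ifftshift2(F0 * hi0)))
  G <- F0 * lo0

  bands <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    dg <- dim(G)
    pgs <- polar_grid(dg[1], dg[2])
    him <- radial_highpass(pgs$r, pi / 2)
    bands[[s]] <- lapply(seq_len(n_orientations), function(k) {
      ifft2(ifftshift2(G * him * angular_mask(pgs$theta, k, n_orientations)))
    })
    G <- G * radial_lowpass(pgs$r, pi / 2)
    # Alias-free decimation: the retained spectrum is scaled by the area
    # ratio so coefficients equal samples of the filtered full-res signal.
    if (all(dim(G) %% 4 == 0)) G <- crop_spectrum(G) / 4
  }
  lowpass <- Re(ifft2(ifftshift2(G)))

  structure(list(bands = bands, highpass = highpass, lowpass = lowpass,
                 n_scales = n_scales, n_orientations = n_orientations,
                 dims = d,
                 px_per_deg = if (is_gray_image(img)) img_ppd(img) else NA_real_),
            class = "steerable_pyramid")
}

#' @export
print.steerable_pyramid <- function(x, ...) {
  cat(sprintf("<steerable_pyramid %d scales x %d orientations, input %d x %d>\n",
              x$n_scales, x$n_orientations, x$dims[1], x$dims[2]))
  invisible(x)
}

#' Full-resolution equivalent filter amplitude masks
#'
#' Returns the frequency-domain amplitude responses of every pyramid filter
#' at full resolution (centered spectrum layout), used for verifying the
#' tight-frame/Parseval property of the decomposition.
#'
#' @param dims Integer pair: image dimensions.
#' @param n_scales,n_orientations As in [build_pyramid()].
#' @return List with `highpass`, `lowpass` (real masks) and `bands`
#'   (list over scales of lists of complex single-lobe masks).
#' @export
pyramid_filters <- function(dims, n_scales = 4, n_orientations = 4) {
  pg <- polar_grid(dims[1], dims[2])
  hi0 <- radial_highpass(pg$r, pi)
  lowcum <- radial_lowpass(pg$r, pi)
  bands <- vector("list", n_scales)
  for (s in seq_len(n_scales)) {
    c_s <- pi / 2^s
    him <- radial_highpass(pg$r, c_s)
    bands[[s]] <- lapply(seq_len(n_orientations), function(k) {
      lowcum * him * angular_mask(pg$theta, k, n_orientations)
    })
    lowcum <- lowcum * radial_lowpass(pg$r, c_s)
  }
  list(highpass = hi0, lowpass = lowcum, bands = bands)
}

#' Serialize pyramid coefficients for inspection
#'
#' Writes each band as plain CSV matrices (real and imaginary parts) into a
#' directory, for debugging and external comparison.
#'
#' @param pyr A `steerable_pyramid`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pyramid <- function(pyr, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, name)
    utils::write.table(m, file.path(dir, paste0(name, ".csv")), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  wr(pyr$highpass, "highpass")
  wr(pyr$lowpass, "lowpass")
  for (s in seq_along(pyr$bands))
    for (k in seq_along(pyr$bands[[s]])) {
      wr(Re(pyr$bands[[s]][[k]]), sprintf("band_s%d_o%d_re", s, k))
      wr(Im(pyr$bands[[s]][[k]]), sprintf("band_s%d_o%d_im", s, k))
    }
  invisible(dir)
}
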
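# Procedural structured textures. These are download-free stand-ins for
# synthesized naturalistic textures: large images with pronounced
# higher-order structure (sparse oriented ridges, blobs, or a regular grid)
# that is destroyed by phase scrambling while the amplitude spectrum is
# preserved. Element density and size are defined in degrees of visual
# field, so textures rendered at different resolutions carry the same
# content per degree. See the vignette for what they do and do not emulate.

#' Parameters of the procedural texture generator
#'
#' @param size_px Image side in pixels. Default 1024 (the size of the
#'   synthesized source textures in the experiments).
#' @param element_kind `"oriented_edge"` (sparse elongated ridges),
#'   `"blob"` (sparse isotropic blobs) or `"grid"` (jittered regular
#'   lattice of blobs).
#' @param density Expected number of elements per square degree (> 0).
#'   Default 1.5, which puts a dozen-plus elements in a 3.7-degree target.
#' @param element_width_deg Cross-section scale of one element in degrees.
#'   Default 0.08 (about 2.4 px at the display resolution); rendering
#'   clamps the pixel width at 0.8 px for very coarse resolutions.
#' @param orientation_bandwidth Circular SD (degrees) of element
#'   orientations around horizontal; large values give weakly oriented
#'   textures. Default 20.
#' @param contrast Output contrast in (0, 1]: the range occupied around
#'   mid gray. Default 0.9.
#' @param rng_seed Integer seed.
#' @return Object of class `procedural_texture_params`.
#' @export
procedural_texture_params <- function(size_px = 1024,
                                      element_kind = c("oriented_edge",
                                                       "blob", "grid"),
                                      density = 1.5,
                                      element_width_deg = 0.08,
                                      orientation_bandwidth = 20,
                                      contrast = 0.9,
                                      rng_seed = 1) {
  element_kind <- match.arg(element_kind)
  if (density <= 0) stop("density must be > 0")
  if (contrast <= 0 || contrast > 1) stop("contrast must be in (0, 1]")
  structure(list(size_px = as.integer(size_px), element_kind = element_kind,
                 density = density, element_width_deg = element_width_deg,
                 orientation_bandwidth = orientation_bandwidth,
                 contrast = contrast, rng_seed = as.integer(rng_seed)),
            class = "procedural_texture_params")
}

# Additively render one anisotropic Gaussian ridge (circular boundary).
render_ridge <- function(acc, cy, cx, phi, sig_l, sig_w, amp) {
  n <- nrow(acc)
  ext <- ceiling(2.5 * sig_l)
  ys <- (cy - ext):(cy + ext)
  xs <- (cx - ext):(cx + ext)
  yy <- matrix(rep(ys - cy, times = length(xs)), length(ys), length(xs))
  xx <- matrix(rep(xs - cx, each = length(ys)), length(ys), length(xs))
  u <- xx * cos(phi) + yy * sin(phi)
  v <- -xx * sin(phi) + yy * cos(phi)
  patch <- amp * exp(-u^2 / (2 * sig_l^2) - v^2 / (2 * sig_w^2))
  yi <- ((ys - 1) %% n) + 1
  xi <- ((xs - 1) %% n) + 1
  acc[yi, xi] <- acc[yi, xi] + patch
  acc
}

#' Generate a procedural structured texture
#'
#' Seeded and reproducible. Paired with [phase_scramble()] (and histogram
#' co-matching via [texture_pair()]) it yields a naturalistic/scrambled
#' pair with matched amplitude spectra and discriminably different
#' higher-order statistics.
#'
#' @param params A [procedural_texture_params()].
#' @param px_per_deg Rendering resolution (converts the degree-based
#'   element density and size to pixels). Default 30.
#' @return A [gray_image()] in \[0, 1\].
#' @export
generate_texture <- function(params = procedural_texture_params(),
                             px_per_deg = 30) {
  n <- params$size_px
  area_deg2 <- (n / px_per_deg)^2
  sig_w <- max(0.8, params$element_width_deg * px_per_deg)
  with_seed(params$rng_seed, {
    acc <- matrix(0, n, n)
    bw <- params$orientation_bandwidth * pi / 180
    if (params$element_kind == "grid") {
      pitch <- max(6, round(0.5 * px_per_deg))   # 0.5-degree lattice
      centers <- expand.grid(cy = seq(pitch %/% 2, n, by = pitch),
                             cx = seq(pitch %/% 2, n, by = pitch))
      jit <- pitch / 8
      for (i in seq_len(nrow(centers))) {
        acc <- render_ridge(acc,
                            centers$cy[i] + round(stats::rnorm(1, 0, jit)),
                            centers$cx[i] + round(stats::rnorm(1, 0, jit)),
                            phi = stats::rnorm(1, 0, bw),
                            sig_l = pitch / 5, sig_w = pitch / 5,
                            amp = stats::runif(1, 0.7, 1))
      }
    } else {
      n_elem <- stats::rpois(1, params$density * area_deg2)
      elong <- if (params$element_kind == "oriented_edge") 5 else 1
      for (i in seq_len(n_elem)) {
        acc <- render_ridge(acc,
                            sample.int(n, 1), sample.int(n, 1),
                            phi = stats::rnorm(1, 0, bw),
                            sig_l = sig_w * elong, sig_w = sig_w,
                            amp = stats::runif(1, 0.5, 1))
      }
    }
    # sparse positive elements on a dark ground: strong positive skew and
    # phase-aligned structure, both destroyed by scrambling
    acc <- acc / max(acc, 1e-12)
    lo <- 0.5 - params$contrast / 2
    gray_image(lo + params$contrast * acc, px_per_deg = px_per_deg)
  })
}

#' Naturalistic/scrambled texture pair with shared spectrum and histogram
#'
#' Generates a structured texture and its phase-scrambled counterpart, then
#' matches both pixel histograms to the average of the two and re-imposes
#' the original amplitude spectrum, iterating both steps and ending on the
#' spectrum step. The pair therefore shares the amplitude spectrum exactly
#' and the pixel histogram approximately, so only higher-order statistics
#' distinguish its members.
#'
#' @param params A [procedural_texture_params()].
#' @param n_iter Matching rounds. Default 30.
#' @param px_per_deg Rendering resolution for both images.
#' @return List of class `texture_pair` with elements `naturalistic` and
#'   `scrambled`.
#' @export
texture_pair <- function(params = procedural_texture_params(), n_iter = 30,
                         px_per_deg = 30) {
  nat <- generate_texture(params, px_per_deg = px_per_deg)
  scr <- phase_scramble(nat, rng_seed = params$rng_seed + 10000L)
  amp <- Mod(fft2(img_mat(nat)))
  xn <- img_mat(nat); xs <- img_mat(scr)
  for (i in seq_len(n_iter)) {
    avg <- (sort(xn) + sort(xs)) / 2
    tmp <- xn; tmp[order(xn)] <- avg; xn <- tmp
    tmp <- xs; tmp[order(xs)] <- avg; xs <- tmp
    xn <- impose_fas(xn, amp)
    xs <- impose_fas(xs, amp)
  }
  structure(list(naturalistic = gray_image(xn, px_per_deg = px_per_deg),
                 scrambled = gray_image(xs, px_per_deg = px_per_deg)),
            class = "texture_pair")
}

#' @export
print.texture_pair <- function(x, ...) {
  cat(sprintf("<texture_pair %d x %d>\n", nrow(x$naturalistic),
              ncol(x$naturalistic)))
  invisible(x)
}
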
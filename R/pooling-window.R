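#' Bouma-law pooling diameter
#'
#' Diameter in pixels of the circular integration area implied by Bouma's law
#' of crowding: surround elements interfere with a target when they lie
#' within `bouma_factor` times the eccentricity, so that distance is taken as
#' the radius of integration around the target center.
#'
#' @param eccentricity_deg Target eccentricity in degrees (> 0).
#' @param bouma_factor Bouma fraction (> 0). Default 0.5.
#' @param px_per_deg Pixels per degree (> 0). Default 30.
#' @return Integer diameter in pixels: `round(2 * bouma_factor *
#'   eccentricity_deg * px_per_deg)`. At the task geometry (12 deg
#'   eccentricity, factor 0.5, 30 px/deg) this is 360 px.
#' @export
bouma_pooling_diameter <- function(eccentricity_deg, bouma_factor = 0.5,
                                   px_per_deg = 30) {
  vals <- c(eccentricity_deg, bouma_factor, px_per_deg)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all arguments must be positive finite numbers")
  as.integer(round(2 * bouma_factor * eccentricity_deg * px_per_deg))
}

#' Circular pooling window
#'
#' Weight map of the fixed pooling area over which summary statistics are
#' computed. Weights are a binary disk by default; `edge = "raised_cosine"`
#' applies a half-cosine roll-off over the outer `soft_px` pixels instead.
#'
#' @param dims Integer pair: image dimensions (rows, cols).
#' @param diameter_px Window diameter in pixels (must fit inside `dims`).
#' @param center Numeric pair (row, col) of the window center; defaults to
#'   the image center.
#' @param edge `"hard"` (binary disk, the default) or `"raised_cosine"`.
#' @param soft_px Roll-off width in pixels for the raised-cosine edge.
#' @return Object of class `pooling_window`: a weight matrix in \[0, 1\]
#'   with `center` and `diameter_px` attributes.
#' @export
pooling_window <- function(dims, diameter_px, center = (dims + 1) / 2,
                           edge = c("hard", "raised_cosine"), soft_px = 8) {
  edge <- match.arg(edge)
  if (diameter_px <= 0) stop("diameter_px must be positive")
  if (diameter_px > min(dims))
    stop("pooling window diameter (", diameter_px,
         ") exceeds the smallest image dimension (", min(dims), ")")
  r <- diameter_px / 2
  dy <- seq_len(dims[1]) - center[1]
  dx <- seq_len(dims[2]) - center[2]
  dist <- sqrt(outer(dy^2, dx^2, `+`))
  w <- if (edge == "hard") {
    (dist <= r) * 1
  } else {
    0.5 * (1 + cos(pi * pmin(pmax((dist - (r - soft_px)) / soft_px, 0), 1)))
  }
  if (sum(w) <= 0) stop("pooling window has empty support")
  structure(w, center = center, diameter_px = diameter_px,
            class = c("pooling_window", "matrix"))
}

#' @export
print.pooling_window <- function(x, ...) {
  cat(sprintf("<pooling_window %d px diameter at (%.1f, %.1f) in %d x %d>\n",
              attr(x, "diameter_px"), attr(x, "center")[1],
              attr(x, "center")[2], nrow(x), ncol(x)))
  invisible(x)
}

# Window weights resampled (block-averaged) to a pyramid level and
# normalized to sum 1. Errors if the support vanishes at that resolution.
window_at_scale <- function(window, dims) {
  w <- unclass(window)
  attr(w, "center") <- attr(w, "diameter_px") <- NULL
  f <- nrow(w) / dims[1]
  stopifnot(f == ncol(w) / dims[2], f == as.integer(f))
  ws <- block_downsample(w, as.integer(f))
  s <- sum(ws)
  if (s <= 0) stop("pooling window support is empty at scale factor ", f)
  ws / s
}
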
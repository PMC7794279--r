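#' Grayscale image with a visual-field scale
#'
#' The universal image currency of the package: a 2-D luminance matrix with
#' values nominally in \[0, 1\] plus a pixels-per-degree factor relating pixel
#' coordinates to degrees of visual field. The default of 30 px/deg matches
#' a 40 cm viewing distance on the display used in the texture-discrimination
#' experiments the package models.
#'
#' @param pixels Numeric matrix of luminance values. Both dimensions must be
#'   even and at least 32.
#' @param px_per_deg Pixels per degree of visual field (> 0). Default 30.
#' @return An object of class `gray_image` (a matrix with a `px_per_deg`
#'   attribute).
#' @export
gray_image <- function(pixels, px_per_deg = 30) {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || !all(is.finite(pixels)))
    stop("gray_image pixels must be finite numeric values")
  d <- dim(pixels)
  if (any(d < 32) || any(d %% 2 != 0))
    stop("gray_image dimensions must be even and >= 32 (got ",
         d[1], " x ", d[2], ")")
  if (!is.numeric(px_per_deg) || length(px_per_deg) != 1 || px_per_deg <= 0)
    stop("px_per_deg must be a single positive number")
  structure(pixels, px_per_deg = px_per_deg, class = c("gray_image", "matrix"))
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<gray_image %d x %d, %.3g px/deg, range [%.3g, %.3g]>\n",
              d[1], d[2], attr(x, "px_per_deg"), min(x), max(x)))
  invisible(x)
}

#' @rdname gray_image
#' @param x Object to coerce or test.
#' @export
as_gray_image <- function(x, px_per_deg = 30) {
  if (is_gray_image(x)) return(x)
  gray_image(x, px_per_deg = px_per_deg)
}

#' @rdname gray_image
#' @export
is_gray_image <- function(x) inherits(x, "gray_image")

# strip class for plain matrix math
img_mat <- function(img) {
  m <- unclass(img)
  attr(m, "px_per_deg") <- NULL
  m
}

img_ppd <- function(img) {
  p <- attr(img, "px_per_deg")
  if (is.null(p)) 30 else p
}

#' Read or write a grayscale PNG
#'
#' 8- or 16-bit grayscale PNG files are mapped linearly to \[0, 1\]. Color
#' PNGs are converted by averaging channels on read.
#'
#' @param path File path.
#' @param px_per_deg Scale factor to attach on read.
#' @return `read_image_png` returns a [gray_image()]; `write_image_png`
#'   returns `path` invisibly.
#' @export
read_image_png <- function(path, px_per_deg = 30) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- apply(a[, , seq_len(min(3, dim(a)[3])), drop = FALSE], c(1, 2), mean)
  gray_image(a, px_per_deg = px_per_deg)
}

#' @rdname read_image_png
#' @param img A [gray_image()]. Values are clamped to \[0, 1\] on write.
#' @export
write_image_png <- function(img, path) {
  m <- pmin(pmax(img_mat(img), 0), 1)
  png::writePNG(m, path)
  invisible(path)
}
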
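# Stimulus geometry: target shapes (disk, split target), surround shapes
# (ring, half rings), gaps and edge gradients, rendered as alpha-composited
# texture patches over a uniform gray background.

#' Geometry and content description of one stimulus
#'
#' All sizes are in degrees of visual field and converted to pixels at
#' rendering time. The two gap modes reproduce the two ways the experiments
#' created a target-surround discontinuity: `shrink_target` keeps surround
#' geometry fixed and shrinks the target (the segmentation experiment),
#' `enlarge_surround` keeps target size fixed and pushes the surround
#' outward, preserving its width (the dissimilarity experiment). At
#' `gap_deg = 0` the two modes produce identical stimuli.
#'
#' @param eccentricity_deg Target eccentricity (metadata; fixation is
#'   assumed to lie toward the left edge of the rendered canvas). Default 12.
#' @param target_shape `"disk"` or `"split"` (two half-disks with their
#'   straight sides facing outward, flush with the surround's inner edge).
#' @param target_diameter_deg Nominal target diameter in degrees (> 0).
#' @param surround_kind `"none"`, `"ring"`, `"half_ring_inward"` or
#'   `"half_ring_outward"`.
#' @param surround_width_factor Ring width as a multiple of the nominal
#'   target diameter. Default 1 (the dissimilarity/naturalness experiments);
#'   1.4 reproduces the first experiment's geometry.
#' @param gap_deg Width of the background gap (>= 0; 0 = continuous).
#'   Default 0.5; 0.35 reproduces the first experiment.
#' @param gap_mode `"shrink_target"` or `"enlarge_surround"`.
#' @param surround_content `"same_texture"`, `"hos_dissimilar"`,
#'   `"fas_hos_dissimilar"` or `"phase_scrambled"` (consumed by the
#'   experiment drivers when choosing the surround source texture).
#' @param edge_gradient_px Length of the linear transparency gradient at
#'   every texture boundary, in pixels. Default 4.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(eccentricity_deg = 12,
                          target_shape = c("disk", "split"),
                          target_diameter_deg = 3.7,
                          surround_kind = c("ring", "none",
                                            "half_ring_inward",
                                            "half_ring_outward"),
                          surround_width_factor = 1,
                          gap_deg = 0.5,
                          gap_mode = c("shrink_target", "enlarge_surround"),
                          surround_content = c("same_texture",
                                               "hos_dissimilar",
                                               "fas_hos_dissimilar",
                                               "phase_scrambled"),
                          edge_gradient_px = 4) {
  target_shape <- match.arg(target_shape)
  surround_kind <- match.arg(surround_kind)
  gap_mode <- match.arg(gap_mode)
  surround_content <- match.arg(surround_content)
  if (target_diameter_deg <= 0) stop("target_diameter_deg must be > 0")
  if (gap_deg < 0) stop("gap_deg must be >= 0")
  structure(list(eccentricity_deg = eccentricity_deg,
                 target_shape = target_shape,
                 target_diameter_deg = target_diameter_deg,
                 surround_kind = surround_kind,
                 surround_width_factor = surround_width_factor,
                 gap_deg = gap_deg, gap_mode = gap_mode,
                 surround_content = surround_content,
                 edge_gradient_px = edge_gradient_px),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec %s target %.2f deg, surround %s (width x%.1f), gap %.2f deg (%s), content %s>\n",
              x$target_shape, x$target_diameter_deg, x$surround_kind,
              x$surround_width_factor, x$gap_deg, x$gap_mode,
              x$surround_content))
  invisible(x)
}

#' Read/write a stimulus spec as JSON
#' @param x A [stimulus_spec()].
#' @param path File path.
#' @return `write_stimulus_spec` returns `path` invisibly;
#'   `read_stimulus_spec` returns a [stimulus_spec()].
#' @export
write_stimulus_spec <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stimulus_spec
#' @export
read_stimulus_spec <- function(path) {
  do.call(stimulus_spec, jsonlite::read_json(path, simplifyVector = TRUE))
}

# Pixel-level geometry derived from a spec at a given resolution.
stimulus_geometry <- function(spec, px_per_deg) {
  r_nom <- spec$target_diameter_deg / 2 * px_per_deg
  gap_px <- spec$gap_deg * px_per_deg
  if (spec$gap_mode == "shrink_target") {
    r_target <- r_nom - gap_px
    r1 <- r_nom
  } else {
    r_target <- r_nom
    r1 <- r_nom + gap_px
  }
  if (r_target <= 0)
    stop("gap leaves no target: inner radius ", r_target, " <= 0")
  width <- spec$surround_width_factor * 2 * r_nom
  list(r_nom = r_nom, r_target = r_target, gap_px = gap_px,
       r1 = r1, r2 = r1 + width, width = width)
}

# argument order matters: pmin/pmax keep the first argument's attributes
clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Render a stimulus
#'
#' Composites a textured target (disk or split target) and an uninformative
#' textured surround (ring or half ring) over a uniform background, with
#' linear transparency gradients of `edge_gradient_px` pixels at every
#' texture boundary. Target and surround patches are sampled independently
#' from their source textures; both share one seeded 90-degree rotation, as
#' in the trial-sampling procedure. The target is composited on top of the
#' surround, which underlaps by one gradient length at continuous borders so
#' that adjoining textures cross-fade without exposing the background.
#'
#' @param spec A [stimulus_spec()].
#' @param target_src,surround_src Source textures ([gray_image()]), at least
#'   as large as the canvas.
#' @param background Background gray level. Default 0.5.
#' @param rng_seed Integer seed for rotation and patch positions.
#' @param canvas_px Canvas size (single even integer); defaults to the
#'   smallest multiple of 16 accommodating the surround plus gradients.
#' @return A [gray_image()] of the rendered stimulus, with the alpha masks
#'   attached as attribute `"masks"` (target, surround alphas).
#' @export
compose_stimulus <- function(spec, target_src, surround_src = NULL,
                             background = 0.5, rng_seed = 1,
                             canvas_px = NULL) {
  ppd <- img_ppd(target_src)
  geo <- stimulus_geometry(spec, ppd)
  g <- spec$edge_gradient_px
  if (is.null(canvas_px)) {
    need <- 2 * (geo$r2 + 2 * g)
    canvas_px <- 16 * ceiling(need / 16)
  }
  n <- as.integer(canvas_px)
  ctr <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n) - ctr, each = n), n, n)   # column offset
  yg <- matrix(rep(seq_len(n) - ctr, times = n), n, n)  # row offset
  dist <- sqrt(xg^2 + yg^2)

  ## target alpha
  if (spec$target_shape == "disk") {
    a_t <- clamp01((geo$r_target - dist) / g)
  } else {
    # two half-disks, straight sides flush with the surround inner edge
    t_off <- geo$r1
    r_piece <- geo$r_target
    d_r <- sqrt((xg - t_off)^2 + yg^2) - r_piece
    d_l <- sqrt((xg + t_off)^2 + yg^2) - r_piece
    a_r <- clamp01(-d_r / g) * clamp01((t_off + g - xg) / g)
    a_l <- clamp01(-d_l / g) * clamp01((t_off + g + xg) / g)
    a_t <- pmax(a_r, a_l)
  }

  ## surround alpha
  if (spec$surround_kind == "none") {
    a_s <- matrix(0, n, n)
  } else {
    outer_ramp <- clamp01((geo$r2 - dist) / g)
    if (spec$target_shape == "disk") {
      inner_edge <- if (geo$gap_px > 0) geo$r1 else geo$r_target - 2 * g
      inner_ramp <- clamp01((dist - inner_edge) / g)
      a_s <- inner_ramp * outer_ramp
    } else {
      # full disk under the target, minus a gap band around the curved sides
      d_min <- pmin(d_r, d_l)
      gap_clear <- clamp01((d_min - geo$gap_px) / g)
      strip <- clamp01((t_off - abs(xg)) / g + 1)       # where the gap applies
      a_s <- outer_ramp * (1 - strip * (1 - gap_clear))
    }
    if (spec$surround_kind == "half_ring_inward")
      a_s <- a_s * clamp01(0.5 - xg / g)                # fixation side (left)
    if (spec$surround_kind == "half_ring_outward")
      a_s <- a_s * clamp01(0.5 + xg / g)
  }

  ## textures: one shared rotation, independent positions
  rot <- with_seed(rng_seed, sample.int(4, 1) - 1)
  tex_t <- img_mat(sample_patch(target_src, n, rng_seed = rng_seed + 1,
                                rotation = rot))
  out <- matrix(background, n, n)
  if (!is.null(surround_src) && spec$surround_kind != "none") {
    tex_s <- img_mat(sample_patch(surround_src, n, rng_seed = rng_seed + 2,
                                  rotation = rot))
    out <- a_s * tex_s + (1 - a_s) * out
  }
  out <- a_t * tex_t + (1 - a_t) * out
  res <- gray_image(out, px_per_deg = ppd)
  attr(res, "masks") <- list(target = a_t, surround = a_s)
  res
}
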
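# Drivers that tie stimuli, statistics and the classifier into simulated
# experiments: one model observer corresponds to one human participant, and
# the emitted trial records feed the same log-odds analysis as behavioral
# data.

mix_seed <- function(...) {
  s <- 0
  for (v in c(...)) s <- (s * 131 + as.numeric(v)) %% (.Machine$integer.max - 1)
  as.integer(s) + 1L
}

#' Condition tables of the simulated experiments
#'
#' Experiment ids index the contextual-modulation manipulation studied:
#' 1 = surround presence (uninformative continuous ring, width 1.4 x target
#' diameter); 2 = target-surround discontinuity (gap created by shrinking
#' the target, 0.35 deg); 3 = target-surround dissimilarity (same texture,
#' higher-order dissimilar, spectrum-and-higher-order dissimilar; continuous
#' ring of width 1 x target diameter); 4 = surround naturalness
#' (naturalistic vs phase-scrambled surround). The half-ring position
#' manipulation has no model simulation.
#'
#' @param experiment_id Integer 1-4.
#' @return List of conditions; each holds `label`, a named `factors`
#'   character vector (the trial-record coding), and a [stimulus_spec()].
#' @export
experiment_conditions <- function(experiment_id) {
  d <- 3.7  # target diameter, deg (110 px at 30 px/deg)
  switch(as.character(experiment_id),
    "1" = list(
      list(label = "no_surround", factors = c(surround = "absent"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "none",
                                surround_width_factor = 1.4, gap_deg = 0)),
      list(label = "surround", factors = c(surround = "present"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                surround_width_factor = 1.4, gap_deg = 0))),
    "2" = list(
      list(label = "continuous", factors = c(discontinuity = "cont"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                surround_width_factor = 1.4, gap_deg = 0,
                                gap_mode = "shrink_target")),
      list(label = "discontinuous", factors = c(discontinuity = "discont"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                surround_width_factor = 1.4, gap_deg = 0.35,
                                gap_mode = "shrink_target"))),
    "3" = list(
      list(label = "same_texture", factors = c(dissimilarity = "none"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                gap_deg = 0, gap_mode = "enlarge_surround",
                                surround_content = "same_texture")),
      list(label = "hos_dissimilar", factors = c(dissimilarity = "hos"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                gap_deg = 0, gap_mode = "enlarge_surround",
                                surround_content = "hos_dissimilar")),
      list(label = "fas_hos_dissimilar", factors = c(dissimilarity = "fas_hos"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                gap_deg = 0, gap_mode = "enlarge_surround",
                                surround_content = "fas_hos_dissimilar"))),
    "4" = list(
      list(label = "naturalistic", factors = c(naturalness = "nat"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                gap_deg = 0, surround_content = "same_texture")),
      list(label = "phase_scrambled", factors = c(naturalness = "scr"),
           spec = stimulus_spec(target_diameter_deg = d, surround_kind = "ring",
                                gap_deg = 0, surround_content = "phase_scrambled"))),
    stop("unknown experiment_id: ", experiment_id)
  )
}

# Surround source image for a condition, given the target pair and a
# generator for dissimilar textures.
surround_source <- function(content, tex, other, n_match_iter = 30) {
  switch(content,
    same_texture = tex$naturalistic,
    phase_scrambled = tex$scrambled,
    hos_dissimilar = suppressWarnings(
      iterative_fas_hist_match(other, tex$naturalistic,
                               sort(img_mat(tex$naturalistic)),
                               n_iter = n_match_iter)),
    fas_hos_dissimilar = histogram_match(other, sort(img_mat(tex$naturalistic)))
  )
}

#' Simulate a full experiment with model observers
#'
#' For each observer replicate: builds a seeded texture pair, renders pools
#' of single-stimulus images per condition (naturalistic or phase-scrambled
#' target, plus the condition's surround), computes summary statistics over
#' the Bouma pooling window, assembles the three classes of ordered
#' stimulus pairs, trains the noisy penalized classifier, and evaluates it
#' on a held-out test pool. Observers assigned to the same texture share its
#' stimulus ensemble but differ in training-pair composition, training
#' noise and test noise; multi-texture experiments spread observers over
#' several texture ensembles, as the reference designs pooled several
#' textures.
#'
#' At `scale_factor = 1` the design matches the reference protocol: 750
#' training pairs (250 per class) and 1500 test pairs (500 per class) per
#' surround condition, with 8 observers. Smaller factors shrink the pair
#' counts and image pools proportionally for desk-scale runs.
#'
#' @param experiment_id Integer 1-4 (see [experiment_conditions()]).
#' @param n_observers Number of model observers. Default 8.
#' @param scale_factor Proportional reduction of train/test sizes.
#'   Default 0.2 (desk scale).
#' @param master_seed Integer seed from which every random draw derives.
#' @param px_per_deg Rendering resolution. Default 30 (the experimental
#'   display); reduced resolutions shrink all geometry proportionally.
#' @param texture_kind Element kind for the procedural source texture.
#' @param n_textures Number of texture ensembles; observers are assigned
#'   round-robin. Defaults per experiment to the reference designs: one
#'   texture for the surround-presence and discontinuity experiments, four
#'   for the dissimilarity and naturalness experiments.
#' @param n_match_iter Iterations for surround spectrum/histogram matching.
#' @param noise_multiplier Scales the observer's calibrated internal noise.
#' @return Object of class `experiment_simulation`: list with `accuracy`
#'   (data frame observer x condition), `trials` (trial records as in
#'   behavioral data), and `meta` (sizes, seeds, per-observer penalties).
#' @export
simulate_experiment <- function(experiment_id, n_observers = 8,
                                scale_factor = 0.2, master_seed = 1,
                                px_per_deg = 30,
                                texture_kind = "oriented_edge",
                                n_textures = NULL,
                                n_match_iter = 30,
                                noise_multiplier = 1) {
  # single-texture experiments vs multi-texture experiments (the
  # dissimilarity and naturalness studies pooled several textures)
  if (is.null(n_textures))
    n_textures <- c(1L, 1L, 4L, 4L)[experiment_id]
  conds <- experiment_conditions(experiment_id)
  # edge gradients are defined in display pixels (4 px at 30 px/deg);
  # keep them proportional at reduced rendering resolutions
  for (i in seq_along(conds))
    conds[[i]]$spec$edge_gradient_px <-
      max(1, round(conds[[i]]$spec$edge_gradient_px * px_per_deg / 30))
  params <- ps_params(pooling_diameter_px =
                        bouma_pooling_diameter(12, 0.5, px_per_deg))

  # canvas: largest surround extent plus gradients, at least the window
  g <- conds[[1]]$spec$edge_gradient_px
  r2max <- max(vapply(conds, function(cn)
    stimulus_geometry(cn$spec, px_per_deg)$r2, numeric(1)))
  need <- max(2 * (r2max + 2 * g) + 8, params$pooling_diameter_px + 8)
  canvas <- as.integer(16 * ceiling(need / 16))
  window <- pooling_window(c(canvas, canvas), params$pooling_diameter_px)

  tex_size <- as.integer(2 * ceiling(canvas * 1.25 / 2))
  # one texture ensemble per texture id; observers are spread round-robin
  # over textures, emulating the multi-texture designs
  other_kind <- if (texture_kind == "blob") "grid" else "blob"
  textures <- lapply(seq_len(n_textures), function(t) {
    tex_seed <- mix_seed(master_seed, experiment_id, 11, t)
    list(pair = texture_pair(procedural_texture_params(
           size_px = tex_size, element_kind = texture_kind,
           rng_seed = tex_seed), px_per_deg = px_per_deg),
         # dissimilar surrounds come from a different texture family, as
         # the dissimilar source textures did in the experiments
         other = generate_texture(procedural_texture_params(
           size_px = tex_size, element_kind = other_kind,
           rng_seed = tex_seed + 7L), px_per_deg = px_per_deg))
  })

  # pair counts per class per condition; the test-pair count is floored so
  # that per-observer accuracy estimates stay usable at small scales (pairs
  # are resampled from the image pools with fresh noise per trial)
  n_train_pair <- max(10L, round(250 * scale_factor))
  n_test_pair <- max(150L, round(500 * scale_factor))
  pool_train <- max(16L, round(250 * scale_factor))     # images per target class
  pool_test <- max(24L, round(500 * scale_factor))

  stat_pool <- function(cond_i, target_img, surr_img, n_img, seed_tag, t) {
    spec <- conds[[cond_i]]$spec
    t(vapply(seq_len(n_img), function(i) {
      st <- compose_stimulus(spec, target_img, surr_img,
                             rng_seed = mix_seed(master_seed, experiment_id,
                                                 cond_i, seed_tag, t, i),
                             canvas_px = canvas)
      as.numeric(compute_ps_statistics(st, params, window))
    }, numeric(ps_stat_count(params))))
  }

  # per texture and condition: a train pool (observer-specific pair subsets
  # are drawn from it) and a test pool
  pools <- lapply(seq_len(n_textures), function(t) {
    tex <- textures[[t]]$pair
    lapply(seq_along(conds), function(ci) {
      surr <- surround_source(conds[[ci]]$spec$surround_content, tex,
                              textures[[t]]$other, n_match_iter)
      list(train_nat = stat_pool(ci, tex$naturalistic, surr, pool_train, 1, t),
           train_scr = stat_pool(ci, tex$scrambled, surr, pool_train, 2, t),
           test_nat = stat_pool(ci, tex$naturalistic, surr, pool_test, 3, t),
           test_scr = stat_pool(ci, tex$scrambled, surr, pool_test, 4, t))
    })
  })

  make_pairs <- function(nat, scr, n_per_class, seed) {
    with_seed(seed, {
      idx <- function(pool, n) sample.int(nrow(pool), n, replace = TRUE)
      X <- rbind(scr[idx(scr, n_per_class), , drop = FALSE] -
                   nat[idx(nat, n_per_class), , drop = FALSE],
                 nat[idx(nat, n_per_class), , drop = FALSE] -
                   scr[idx(scr, n_per_class), , drop = FALSE],
                 nat[idx(nat, n_per_class), , drop = FALSE] -
                   nat[idx(nat, n_per_class), , drop = FALSE])
      list(X = X, y = rep(OBSERVER_CLASSES, each = n_per_class))
    })
  }

  # fixed test-pair composition per texture, shared by its observers
  test_sets <- lapply(seq_len(n_textures), function(t)
    lapply(seq_along(conds), function(ci)
      make_pairs(pools[[t]][[ci]]$test_nat, pools[[t]][[ci]]$test_scr,
                 n_test_pair, mix_seed(master_seed, experiment_id, ci, 99, t))))

  acc <- NULL
  trials <- NULL
  lambdas <- numeric(n_observers)
  for (o in seq_len(n_observers)) {
    t <- ((o - 1) %% n_textures) + 1
    tr <- lapply(seq_along(conds), function(ci)
      make_pairs(pools[[t]][[ci]]$train_nat, pools[[t]][[ci]]$train_scr,
                 n_train_pair,
                 mix_seed(master_seed, experiment_id, ci, 200, o)))
    Xtr <- do.call(rbind, lapply(tr, `[[`, "X"))
    ytr <- unlist(lapply(tr, `[[`, "y"))
    model <- fit_observer_classifier(Xtr, ytr,
                                     rng_seed = mix_seed(master_seed,
                                                         experiment_id, 300, o),
                                     noise_multiplier = noise_multiplier)
    lambdas[o] <- model$lambda
    for (ci in seq_along(conds)) {
      ts <- test_sets[[t]][[ci]]
      # common random numbers: the test-noise draw is shared across
      # conditions within an observer (test sets have equal sizes), so
      # between-condition contrasts are not inflated by independent noise
      pred <- predict_observer(model, ts$X,
                               rng_seed = mix_seed(master_seed, experiment_id,
                                                   400, o))
      correct <- as.numeric(pred == ts$y)
      acc <- rbind(acc, data.frame(observer = o, texture = t,
                                   condition = conds[[ci]]$label,
                                   n = length(correct),
                                   accuracy = mean(correct)))
      fac <- conds[[ci]]$factors
      tr_df <- data.frame(participant_id = sprintf("model_%02d", o),
                          session_id = sprintf("exp%d_model_%02d",
                                               experiment_id, o),
                          texture_id = sprintf("synthetic_T%d", t),
                          true_class = ts$y,
                          response = c(scr_left = "left", scr_right = "right",
                                       none = "none")[pred],
                          correct = correct == 1,
                          stringsAsFactors = FALSE)
      for (f in names(fac)) tr_df[[f]] <- fac[[f]]
      trials <- rbind(trials, tr_df)
    }
  }
  structure(list(accuracy = acc, trials = trials,
                 meta = list(experiment_id = experiment_id,
                             n_textures = n_textures,
                             n_observers = n_observers,
                             scale_factor = scale_factor,
                             master_seed = master_seed,
                             px_per_deg = px_per_deg, canvas_px = canvas,
                             pooling_diameter_px = params$pooling_diameter_px,
                             n_train_pair = n_train_pair,
                             n_test_pair = n_test_pair,
                             pool_train = pool_train, pool_test = pool_test,
                             lambda = lambdas,
                             conditions = vapply(conds, `[[`, "",  "label"))),
            class = "experiment_simulation")
}

#' @export
print.experiment_simulation <- function(x, ...) {
  cat(sprintf("<experiment_simulation %d: %d observers, conditions: %s>\n",
              x$meta$experiment_id, x$meta$n_observers,
              paste(x$meta$conditions, collapse = ", ")))
  m <- stats::aggregate(accuracy ~ condition, data = x$accuracy, FUN = mean)
  print(m)
  invisible(x)
}

#' Mean accuracy per condition of a simulation
#'
#' @param sim An `experiment_simulation`.
#' @return Named numeric vector of mean accuracies across observers.
#' @export
condition_means <- function(sim) {
  m <- stats::aggregate(accuracy ~ condition, data = sim$accuracy, FUN = mean)
  stats::setNames(m$accuracy, m$condition)
}
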
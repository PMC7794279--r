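# The model observer on controlled predictor ensembles: noise calibration
# closed forms, chance floor under destroyed information, near-perfect
# performance on separable clouds, determinism, and pair antisymmetry.

make_clouds <- function(n_per_class, p = 40, sep = 10, seed = 1) {
  # three Gaussian class clouds separated along two orthogonal directions
  with_seed_test(seed, {
    centers <- rbind(c(sep, 0), c(-sep, 0), c(0, sep))
    X <- do.call(rbind, lapply(1:3, function(k) {
      base <- matrix(stats::rnorm(n_per_class * p), n_per_class, p)
      base[, 1] <- base[, 1] + centers[k, 1]
      base[, 2] <- base[, 2] + centers[k, 2]
      base
    }))
    list(X = X, y = rep(c("scr_left", "scr_right", "none"), each = n_per_class))
  })
}

test_that("noise calibration returns pooled per-predictor SDs", {
  X <- cbind(rep(c(-1, 1), 10), rep(2, 20), rep(c(-2, 2), 10))
  sds <- calibrate_noise(X)
  expect_equal(sds[2], 0)                       # constant column: no noise
  expect_equal(sds[3] / sds[1], 2)              # homogeneity
  expect_equal(sds[1], stats::sd(rep(c(-1, 1), 10)))
  expect_error(calibrate_noise(X[1, , drop = FALSE]), "2 training rows")
})

test_that("observer reaches near-perfect accuracy on separable clouds without noise", {
  tr <- make_clouds(60, sep = 10, seed = 2)
  te <- make_clouds(100, sep = 10, seed = 3)
  m <- peritex:::fit_observer_classifier(tr$X, tr$y, rng_seed = 1,
                                         noise_multiplier = 0)
  pred <- peritex:::predict_observer(m, te$X, rng_seed = 4)
  expect_gt(mean(pred == te$y), 0.98)
})

test_that("massive noise drives accuracy to the three-class chance floor", {
  tr <- make_clouds(60, sep = 10, seed = 5)
  te <- make_clouds(500, sep = 10, seed = 6)
  m <- peritex:::fit_observer_classifier(tr$X, tr$y, rng_seed = 1,
                                         noise_multiplier = 1000)
  pred <- peritex:::predict_observer(m, te$X, rng_seed = 7)
  acc <- mean(pred == te$y)
  expect_gt(acc, 0.30)
  expect_lt(acc, 0.37)
})

test_that("evaluation is deterministic under a fixed seed and class-swap symmetric", {
  tr <- make_clouds(50, sep = 3, seed = 8)
  te <- make_clouds(200, sep = 3, seed = 9)
  m <- peritex:::fit_observer_classifier(tr$X, tr$y, rng_seed = 2)
  p1 <- peritex:::predict_observer(m, te$X, rng_seed = 11)
  p2 <- peritex:::predict_observer(m, te$X, rng_seed = 11)
  expect_identical(p1, p2)

  # swapping left/right stimuli negates predictors and swaps the two
  # scrambled-class labels; accuracy is unchanged in expectation
  swap <- c(scr_left = "scr_right", scr_right = "scr_left", none = "none")
  tr_sw <- list(X = -tr$X, y = unname(swap[tr$y]))
  m_sw <- peritex:::fit_observer_classifier(tr_sw$X, tr_sw$y, rng_seed = 2)
  p_sw <- peritex:::predict_observer(m_sw, -te$X, rng_seed = 11)
  acc <- mean(p1 == te$y)
  acc_sw <- mean(p_sw == unname(swap[te$y]))
  expect_lt(abs(acc - acc_sw), 0.06)   # Monte-Carlo tolerance
})

test_that("training requires all three classes", {
  tr <- make_clouds(30, seed = 10)
  keep <- tr$y != "none"
  expect_error(peritex:::fit_observer_classifier(tr$X[keep, ], tr$y[keep]),
               "three classes")
})

test_that("observer trains and evaluates on rendered stimulus pairs", {
  src <- fix_texture()
  scr <- phase_scramble(src, 4)
  spec <- stimulus_spec(surround_kind = "none", gap_deg = 0,
                        target_diameter_deg = 3.7)
  params <- ps_params(pooling_diameter_px = 56)
  mk <- function(cls, i) {
    nat <- compose_stimulus(spec, src, rng_seed = 100 + i, canvas_px = 64)
    oth <- compose_stimulus(spec, if (cls == "none") src else scr,
                            rng_seed = 200 + i, canvas_px = 64)
    if (cls == "scr_left") trial_stimulus_pair(oth, nat, cls)
    else trial_stimulus_pair(nat, oth, cls)
  }
  pairs <- unlist(lapply(c("scr_left", "scr_right", "none"), function(cl)
    lapply(1:8, function(i) mk(cl, i))), recursive = FALSE)
  m <- suppressWarnings(train_observer(pairs, params, rng_seed = 1,
                                       nfolds = 4))
  expect_s3_class(m, "observer_model")
  expect_length(m$noise_sd, 782)
  tab <- evaluate_observer(m, pairs, params, rng_seed = 2)
  expect_equal(sum(tab$n), length(pairs))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})

test_that("image-level pair pipeline: identical stimuli give zero predictors, swaps negate", {
  src <- fix_texture()
  spec <- stimulus_spec(surround_kind = "none", gap_deg = 0)
  a <- compose_stimulus(spec, src, rng_seed = 1, canvas_px = 96)
  b <- compose_stimulus(spec, src, rng_seed = 2, canvas_px = 96)
  params <- ps_params(pooling_diameter_px = 80)
  pr_same <- build_predictors(trial_stimulus_pair(a, a, "none"), params)
  expect_equal(max(abs(pr_same)), 0)
  pr_ab <- build_predictors(trial_stimulus_pair(a, b, "scr_left"), params)
  pr_ba <- build_predictors(trial_stimulus_pair(b, a, "scr_right"), params)
  expect_equal(pr_ab, -pr_ba)
  expect_length(pr_ab, 782)
})
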
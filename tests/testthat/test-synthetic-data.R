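# The synthetic generators: reproducibility, oriented structure, the
# HOS-vs-spectrum dissociation the task depends on, and the behavioral
# simulator's closed-form accuracy targets.

test_that("texture generation is seeded and reproducible", {
  p <- procedural_texture_params(size_px = 128, rng_seed = 9)
  t1 <- generate_texture(p)
  t2 <- generate_texture(p)
  expect_identical(unclass(t1)[, ], unclass(t2)[, ])
  t3 <- generate_texture(procedural_texture_params(size_px = 128, rng_seed = 10))
  expect_false(identical(unclass(t1)[, ], unclass(t3)[, ]))
})

test_that("oriented textures concentrate energy in the aligned band", {
  tx <- generate_texture(procedural_texture_params(size_px = 256,
                                                   element_kind = "oriented_edge",
                                                   orientation_bandwidth = 8,
                                                   rng_seed = 3))
  pyr <- build_pyramid(tx)
  # horizontal ridges: energy in the vertical-frequency band (o3) exceeds
  # the orthogonal band (o1) at matched scale
  e <- vapply(pyr$bands[[3]], function(b) sum(Mod(b)^2), numeric(1))
  expect_gt(e[3] / e[1], 2)
})

test_that("a texture pair dissociates higher-order statistics from the spectrum", {
  tp <- texture_pair(procedural_texture_params(size_px = 256, rng_seed = 12),
                     n_iter = 15, px_per_deg = 6)
  # spectra identical, histograms nearly shared
  expect_lt(rel_fas_err(tp$naturalistic, tp$scrambled), 1e-10)
  sn <- sort(as.vector(unclass(tp$naturalistic)))
  ss <- sort(as.vector(unclass(tp$scrambled)))
  expect_lt(sqrt(mean((sn - ss)^2)) / stats::sd(sn), 0.1)

  # statistic-space dissociation under a uniform pooling window: band
  # powers (variance + squared mean of each magnitude map) are determined
  # by the shared spectrum alone and agree to machine precision, while the
  # full statistic vector differs substantially (higher-order structure)
  params <- ps_params(pooling_diameter_px = 200)
  w <- pooling_window(c(256, 256), 256)
  w[] <- 1
  vn <- compute_ps_statistics(tp$naturalistic, params, w)
  vs <- compute_ps_statistics(tp$scrambled, params, w)
  pow <- function(v) unlist(lapply(1:4, function(s) vapply(1:4, function(o)
    v[[sprintf("mag_ac_s%d_o%d_d0_0", s, o)]] +
      v[[sprintf("mag_mean_s%d_o%d", s, o)]]^2, numeric(1))))
  pn <- pow(vn); psc <- pow(vs)
  d_pow <- sqrt(sum((pn - psc)^2)) / sqrt(sum(pn^2))
  d_all <- sqrt(sum((as.numeric(vn) - as.numeric(vs))^2)) /
    sqrt(sum(as.numeric(vn)^2))
  expect_lt(d_pow, 1e-8)
  expect_gt(d_all, 0.05)
  # the highpass variance is likewise spectrum-bound
  expect_equal(unname(vn["hp_var"]), unname(vs["hp_var"]), tolerance = 1e-10)
})

test_that("behavioral simulation hits its closed-form accuracy targets", {
  # no effects, baseline 0.9, no random variation
  p0 <- behavioral_sim_params(n_participants = 6, trials_per_condition = 200,
                              fixed_lors = c(surround = 0),
                              baseline_logit = stats::qlogis(0.9),
                              random_sd = c(participant = 0, texture = 0),
                              rng_seed = 2)
  r0 <- simulate_behavior(p0)
  expect_lt(abs(mean(r0$correct) - 0.9), 0.02)

  # surround LOR -1.07 from a 0.74 baseline: predicted 0.512
  p1 <- behavioral_sim_params(n_participants = 10, trials_per_condition = 300,
                              fixed_lors = c(surround = -1.07),
                              baseline_logit = stats::qlogis(0.74),
                              random_sd = c(participant = 0, texture = 0),
                              rng_seed = 3)
  r1 <- simulate_behavior(p1)
  pred <- lor_to_probability(0.74, -1.07)
  expect_equal(pred, 0.494, tolerance = 1e-3)
  expect_lt(abs(mean(r1$correct[r1$surround == "present"]) - pred), 0.03)
  expect_lt(abs(mean(r1$correct[r1$surround == "absent"]) - 0.74), 0.03)

  # responses are consistent with the outcome column
  ok <- r1$correct == (r1$response == c(scr_left = "left", scr_right = "right",
                                        none = "none")[r1$true_class])
  expect_true(all(ok))
})

test_that("generating LOR is recovered by the mixed model", {
  p <- behavioral_sim_params(n_participants = 12, n_textures = 2,
                             trials_per_condition = 80,
                             fixed_lors = c(surround = -1.0),
                             random_sd = c(participant = 0.4, texture = 0.2),
                             rng_seed = 17)
  rec <- simulate_behavior(p)
  fg <- suppressMessages(fit_glmm(rec, ci_method = "wald"))
  expect_lt(abs(fg$fixed_effects$estimate - (-1.0)), 0.45)
  expect_lt(fg$fixed_effects$p_lrt, 0.01)
  expect_true(any(grepl("texture", names(fg$random_sd))))
})
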
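# Generative twin of the behavioral analysis: binomial trial data from a
# logistic model with known condition log-odds ratios and participant and
# texture random effects, used for parameter-recovery testing and as a
# stand-in for human participants.

#' Parameters of the behavioral simulator
#'
#' Defaults emulate the scale of one experiment: a handful of participants
#' per texture, 70-120 trials per condition, a strong negative surround
#' effect, and moderate between-participant variability.
#'
#' @param n_participants Participants per texture. Default 8.
#' @param n_textures Number of textures (sessions are participant x
#'   texture). Default 1.
#' @param trials_per_condition Trials per condition per session. Default 90.
#' @param fixed_lors Named numeric vector of condition log-odds ratios,
#'   e.g. `c(surround = -1.07)`; names must be known condition factors.
#' @param baseline_logit Logit of the reference-condition success
#'   probability. Default `qlogis(0.74)`.
#' @param random_sd Named vector with elements `participant` and `texture`:
#'   SDs of the random intercepts and slopes for each grouping.
#' @param rng_seed Integer seed.
#' @return Object of class `behavioral_sim_params`.
#' @export
behavioral_sim_params <- function(n_participants = 8, n_textures = 1,
                                  trials_per_condition = 90,
                                  fixed_lors = c(surround = -1.07),
                                  baseline_logit = stats::qlogis(0.74),
                                  random_sd = c(participant = 0.5,
                                                texture = 0.3),
                                  rng_seed = 1) {
  if (trials_per_condition < 1) stop("trials_per_condition must be >= 1")
  if (any(random_sd < 0)) stop("random-effect SDs must be >= 0")
  if (is.null(names(fixed_lors)) || any(!nzchar(names(fixed_lors))))
    stop("fixed_lors must be a named vector")
  structure(list(n_participants = as.integer(n_participants),
                 n_textures = as.integer(n_textures),
                 trials_per_condition = as.integer(trials_per_condition),
                 fixed_lors = fixed_lors,
                 baseline_logit = baseline_logit,
                 random_sd = random_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "behavioral_sim_params")
}

#' Simulate trial records from a logistic model
#'
#' Draws, per texture and per participant-in-texture, independent Gaussian
#' random intercepts and per-factor random slopes with the stated SDs
#' (correlations zero), computes each condition's success probability via
#' the inverse logit of baseline + fixed LORs + random effects, and draws
#' Bernoulli outcomes. The 3-AFC structure is retained: each trial carries
#' a true configuration and a response consistent with the outcome.
#'
#' @param params A [behavioral_sim_params()].
#' @return Trial data frame compatible with [exclusion_filter()],
#'   [fit_participant_glm()] and [fit_glmm()].
#' @export
simulate_behavior <- function(params = behavioral_sim_params()) {
  with_seed(params$rng_seed, {
    lors <- params$fixed_lors
    facs <- names(lors)
    levs <- lapply(facs, function(f) {
      lev <- factor_level_order[[f]]
      if (is.null(lev)) lev <- c("ref", "alt")
      if (f == "dissimilarity") stop("use 2-level factors for simulation")
      lev
    })
    names(levs) <- facs
    grid <- expand.grid(levs, stringsAsFactors = FALSE)

    sd_p <- params$random_sd[["participant"]]
    sd_t <- if ("texture" %in% names(params$random_sd))
      params$random_sd[["texture"]] else 0

    out <- vector("list", 0)
    classes <- OBSERVER_CLASSES
    resp_ok <- c(scr_left = "left", scr_right = "right", none = "none")
    for (tx in seq_len(params$n_textures)) {
      b_t <- stats::rnorm(1 + length(facs), 0, sd_t)  # intercept + slopes
      for (pp in seq_len(params$n_participants)) {
        b_p <- stats::rnorm(1 + length(facs), 0, sd_p)
        for (ci in seq_len(nrow(grid))) {
          x <- vapply(facs, function(f) as.numeric(grid[ci, f] == levs[[f]][2]),
                      numeric(1))
          eta <- params$baseline_logit + b_t[1] + b_p[1] +
            sum(x * (lors + b_t[-1] + b_p[-1]))
          n <- params$trials_per_condition
          correct <- stats::runif(n) < stats::plogis(eta)
          true_class <- sample(classes, n, replace = TRUE)
          response <- ifelse(correct, resp_ok[true_class],
                             vapply(true_class, function(tc)
                               sample(setdiff(unname(resp_ok), resp_ok[tc]), 1),
                               character(1)))
          df <- data.frame(
            participant_id = sprintf("P%02d", pp),
            session_id = sprintf("T%02d_P%02d", tx, pp),
            texture_id = sprintf("T%02d", tx),
            true_class = true_class,
            response = unname(response),
            correct = correct,
            stringsAsFactors = FALSE)
          for (f in facs) df[[f]] <- grid[ci, f]
          out[[length(out) + 1]] <- df
        }
      }
    }
    do.call(rbind, out)
  })
}
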
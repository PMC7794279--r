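# The summary-statistics model observer: noisy PS-statistic differencing
# plus a cross-validated L2-penalized multinomial classifier simulating the
# three-alternative forced-choice texture discrimination task.

OBSERVER_CLASSES <- c("scr_left", "scr_right", "none")

#' One ordered stimulus pair of the 3-AFC task
#'
#' @param left,right Single-stimulus images ([gray_image()]); both members
#'   of a pair share the same surround condition.
#' @param true_class `"scr_left"`, `"scr_right"` or `"none"` (no scrambled
#'   target).
#' @param condition_label Text label of the surround condition.
#' @return Object of class `trial_stimulus_pair`.
#' @export
trial_stimulus_pair <- function(left, right, true_class, condition_label = "default") {
  true_class <- match.arg(true_class, OBSERVER_CLASSES)
  structure(list(left = left, right = right, true_class = true_class,
                 condition_label = condition_label),
            class = "trial_stimulus_pair")
}

#' Predictors of one stimulus pair
#'
#' The statistic-difference code of the model observer: the summary
#' statistics of the second (right) stimulus subtracted from those of the
#' first (left), giving one predictor per retained statistic (782 at the
#' default parameters).
#'
#' @param pair A [trial_stimulus_pair()].
#' @param params A [ps_params()].
#' @param window A [pooling_window()] shared by both stimuli (centered on
#'   the target).
#' @return Named numeric vector of statistic differences.
#' @export
build_predictors <- function(pair, params = ps_params(), window = NULL) {
  a <- compute_ps_statistics(pair$left, params, window)
  b <- compute_ps_statistics(pair$right, params, window)
  statistic_difference(a, b)
}

#' Per-predictor noise standard deviations
#'
#' The model's internal noise is calibrated on the pooled training set of
#' all conditions: each predictor receives Gaussian noise with standard
#' deviation equal to its standard deviation across that set. Constant
#' predictors receive no noise.
#'
#' @param training_predictors Numeric matrix, one row per training pair.
#' @return Numeric vector of column standard deviations.
#' @export
calibrate_noise <- function(training_predictors) {
  X <- as.matrix(training_predictors)
  if (nrow(X) < 2) stop("need at least 2 training rows to calibrate noise")
  apply(X, 2, stats::sd)
}

# Core fit on a ready predictor matrix: add seeded noise, scale to unit
# variance, fit a 3-class logistic regression with L2 penalty, lambda by
# 10-fold cross-validation over a logarithmic grid.
fit_observer_classifier <- function(X, y, rng_seed = 1, nfolds = 10,
                                    lambda = 10^seq(3, -3, length.out = 50),
                                    noise_multiplier = 1) {
  X <- as.matrix(X)
  y <- factor(y, levels = OBSERVER_CLASSES)
  if (nlevels(droplevels(y)) < 3) stop("all three classes must be present for training")
  noise_sd <- calibrate_noise(X) * noise_multiplier
  Xn <- with_seed(rng_seed, X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) *
                    rep(noise_sd, each = nrow(X)))
  scale_div <- apply(Xn, 2, stats::sd)
  scale_div[scale_div < 1e-12] <- 1
  Xs <- sweep(Xn, 2, scale_div, "/")
  foldid <- with_seed(rng_seed + 1, sample(rep_len(seq_len(nfolds), nrow(Xs))))
  cv <- glmnet::cv.glmnet(Xs, y, family = "multinomial", alpha = 0,
                          lambda = lambda, foldid = foldid,
                          standardize = FALSE)
  structure(list(fit = cv$glmnet.fit, lambda = cv$lambda.min,
                 noise_sd = noise_sd, scale = scale_div,
                 noise_multiplier = noise_multiplier,
                 classes = OBSERVER_CLASSES, rng_seed = rng_seed,
                 n_train = nrow(X), cv_error = min(cv$cvm)),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  cat(sprintf("<observer_model: %d predictors, n_train = %d, lambda = %.4g>\n",
              length(x$noise_sd), x$n_train, x$lambda))
  invisible(x)
}

#' Train the model observer on stimulus pairs
#'
#' Full training pipeline in the task's order: compute the statistic
#' differences of every pair, add seeded Gaussian noise (standard deviations
#' from [calibrate_noise()] over the pooled set), normalize each predictor
#' to unit variance, and fit the penalized 3-class logistic regression with
#' the penalty weight chosen by 10-fold cross-validation.
#'
#' @param train_pairs List of [trial_stimulus_pair()]; all three classes
#'   must be present.
#' @param params A [ps_params()].
#' @param window A [pooling_window()].
#' @param rng_seed Seed for the noise and fold assignment.
#' @param noise_multiplier Scales the calibrated noise (1 = the standard
#'   setting).
#' @param nfolds Cross-validation folds for the penalty search. Default 10;
#'   reduce for very small training sets.
#' @return An `observer_model`.
#' @export
train_observer <- function(train_pairs, params = ps_params(), window = NULL,
                           rng_seed = 1, noise_multiplier = 1, nfolds = 10) {
  X <- t(vapply(train_pairs, build_predictors, numeric(ps_stat_count(params)),
                params = params, window = window))
  y <- vapply(train_pairs, function(p) p$true_class, character(1))
  fit_observer_classifier(X, y, rng_seed = rng_seed, nfolds = nfolds,
                          noise_multiplier = noise_multiplier)
}

# Classify a predictor matrix with fresh noise (test stage).
predict_observer <- function(model, X, rng_seed = 1) {
  X <- as.matrix(X)
  Xn <- with_seed(rng_seed, X + matrix(stats::rnorm(length(X)), nrow(X), ncol(X)) *
                    rep(model$noise_sd, each = nrow(X)))
  Xs <- sweep(Xn, 2, model$scale, "/")
  pr <- predict(model$fit, newx = Xs, s = model$lambda, type = "response")
  pr <- pr[, , 1]
  # argmax with ties broken by the fixed class order
  model$classes[max.col(pr[, model$classes, drop = FALSE], ties.method = "first")]
}

#' Evaluate a trained observer
#'
#' Applies the model to labeled test pairs with fresh noise (noise is
#' applied at both training and testing stages; the test noise uses the
#' standard deviations frozen at training) and reports accuracy per
#' condition.
#'
#' @param model An `observer_model`.
#' @param test_pairs List of [trial_stimulus_pair()].
#' @param params,window As in [train_observer()].
#' @param rng_seed Seed for the test noise.
#' @return Data frame with columns `condition`, `n`, `accuracy`.
#' @export
evaluate_observer <- function(model, test_pairs, params = ps_params(),
                              window = NULL, rng_seed = 1) {
  X <- t(vapply(test_pairs, build_predictors, numeric(ps_stat_count(params)),
                params = params, window = window))
  y <- vapply(test_pairs, function(p) p$true_class, character(1))
  cond <- vapply(test_pairs, function(p) p$condition_label, character(1))
  evaluate_observer_matrix(model, X, y, cond, rng_seed)
}

evaluate_observer_matrix <- function(model, X, y, cond, rng_seed = 1) {
  pred <- predict_observer(model, X, rng_seed = rng_seed)
  agg <- stats::aggregate(correct ~ condition,
                          data = data.frame(condition = cond,
                                            correct = as.numeric(pred == y)),
                          FUN = function(z) c(n = length(z), acc = mean(z)))
  data.frame(condition = agg$condition,
             n = agg$correct[, "n"],
             accuracy = agg$correct[, "acc"],
             stringsAsFactors = FALSE)
}
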
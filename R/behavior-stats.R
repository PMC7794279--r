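# Log-odds-ratio analysis of trial data: session exclusion, per-participant
# binomial GLMs with Wald intervals, and hierarchical binomial GLMMs with
# nested, zero-correlation random effects, LRT p-values and profile CIs.

TRIAL_ID_COLS <- c("participant_id", "session_id", "texture_id",
                   "true_class", "response", "correct")

# condition factor columns = everything that is not identification/outcome
trial_factor_cols <- function(records) {
  setdiff(names(records), TRIAL_ID_COLS)
}

#' Session exclusion filter
#'
#' Excludes experimental sessions in which performance stayed below the
#' threshold in every condition of the session (floor performance; chance
#' in the 3-AFC task is 1/3).
#'
#' @param records Trial data frame (one row per trial) with at least
#'   `session_id`, `correct`, and condition factor columns.
#' @param threshold Accuracy threshold. Default 0.45.
#' @return List with `kept` and `excluded` (subsets of `records`) and
#'   `excluded_sessions` (character vector).
#' @export
exclusion_filter <- function(records, threshold = 0.45) {
  stopifnot(is.data.frame(records), "session_id" %in% names(records))
  fac <- trial_factor_cols(records)
  if (length(fac) == 0) {
    records$.cond <- "all"
    fac <- ".cond"
  }
  cond <- interaction(records[fac], drop = TRUE)
  acc <- stats::aggregate(correct ~ session + cond,
                          data = data.frame(correct = as.numeric(records$correct),
                                            session = records$session_id,
                                            cond = cond),
                          FUN = mean)
  worst <- stats::aggregate(correct ~ session, data = acc, FUN = max)
  excluded <- worst$session[worst$correct < threshold]
  empty <- setdiff(unique(records$session_id), acc$session)
  if (length(empty)) warning("sessions without trials ignored: ",
                             paste(empty, collapse = ", "))
  list(kept = records[!records$session_id %in% excluded, , drop = FALSE],
       excluded = records[records$session_id %in% excluded, , drop = FALSE],
       excluded_sessions = as.character(excluded))
}

# Numeric 0/1 coding of condition factors. Two-level factors are coded by
# level order (first observed sorted level = reference). A three-level
# dissimilarity factor (none/hos/fas_hos) is coded by two nested dummies:
# `hos` = any dissimilarity, `fas` = spectrum dissimilarity on top, so the
# spectrum effect is the change from the higher-order-dissimilar condition.
factor_level_order <- list(
  surround = c("absent", "present"),
  discontinuity = c("cont", "discont"),
  naturalness = c("scr", "nat"),
  position = c("out", "in"),
  split = c("disk", "split"),
  gap = c("absent", "present"),
  dissimilarity = c("none", "hos", "fas_hos")
)

code_factors <- function(records, factors) {
  X <- list()
  for (f in factors) {
    v <- as.character(records[[f]])
    lev <- factor_level_order[[f]]
    if (is.null(lev)) lev <- sort(unique(v))
    if (!all(v %in% lev)) stop("unexpected levels in factor ", f)
    if (f == "dissimilarity") {
      X[["dissim_hos"]] <- as.numeric(v %in% c("hos", "fas_hos"))
      X[["dissim_fas"]] <- as.numeric(v == "fas_hos")
    } else {
      if (length(lev) != 2) stop("factor ", f, " must have 2 levels")
      X[[f]] <- as.numeric(v == lev[2])
    }
  }
  as.data.frame(X)
}

#' Per-participant binomial GLM
#'
#' Fits `correct ~ factors` with a logit link to the trials of a single
#' participant (typically one session), returning the log-odds ratio of
#' each factor with Wald confidence interval and Wald p-value. Perfect
#' separation is flagged and reported with an infinite-interval marker
#' rather than an error.
#'
#' @param records Trial data frame of one participant/session.
#' @param factors Character vector of condition factor columns; defaults to
#'   all condition columns present.
#' @param conf_level Confidence level. Default 0.95.
#' @return Data frame with columns `term`, `estimate`, `ci_low`, `ci_high`,
#'   `p_wald`, `separation`.
#' @export
fit_participant_glm <- function(records, factors = trial_factor_cols(records),
                                conf_level = 0.95) {
  X <- code_factors(records, factors)
  dat <- cbind(data.frame(correct = as.numeric(records$correct)), X)
  for (v in names(X))
    if (length(unique(X[[v]])) < 2)
      stop("both levels of each factor must be present (", v, ")")
  fit <- stats::glm(stats::reformulate(names(X), response = "correct"),
                    family = stats::binomial(), data = dat)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- names(X)
  est <- sm[terms, "Estimate"]
  se <- sm[terms, "Std. Error"]
  sep <- abs(est) > 10 | se > 100   # separation heuristic
  data.frame(term = terms,
             estimate = est,
             ci_low = ifelse(sep, -Inf, est - z * se),
             ci_high = ifelse(sep, Inf, est + z * se),
             p_wald = sm[terms, "Pr(>|z|)"],
             separation = sep,
             row.names = NULL)
}

#' Hierarchical binomial GLMM with nested diagonal random effects
#'
#' The population-level analysis: a binomial (logit) mixed model of the
#' binary trial outcome on the condition factors, with, for each fixed
#' effect (and the intercept), a random effect for texture and one for
#' participants nested within texture; correlations between random effects
#' are fixed at zero. With a single texture (or
#' `random_structure = "participant_only"`) only participant effects are
#' used. Estimation is by maximum likelihood with the Laplace approximation
#' ( `nAGQ` can select adaptive quadrature for single-term models).
#' P-values come from likelihood-ratio tests of the full model against the
#' model with that fixed effect deleted; confidence intervals from profile
#' likelihood, falling back to Wald (flagged) if profiling fails.
#'
#' @param records Trial data frame.
#' @param factors Condition factor columns; defaults to all present.
#' @param random_structure `"texture_participant"` (default) or
#'   `"participant_only"`.
#' @param ci_method `"profile"` (default) or `"wald"`.
#' @param nAGQ Integration points for the random-effect integrals (1 =
#'   Laplace, the default; higher values allowed only by lme4 for a single
#'   scalar random effect).
#' @return Object of class `glmm_fit`: list with `fixed_effects` (term,
#'   estimate, ci_low, ci_high, p_lrt, ci_method), `random_sd`, `loglik`,
#'   `converged`, and the fitted lme4 model.
#' @export
fit_glmm <- function(records, factors = trial_factor_cols(records),
                     random_structure = c("texture_participant",
                                          "participant_only"),
                     ci_method = c("profile", "wald"), nAGQ = 1,
                     lrt = TRUE) {
  random_structure <- match.arg(random_structure)
  ci_method <- match.arg(ci_method)
  X <- code_factors(records, factors)
  dat <- cbind(data.frame(correct = as.numeric(records$correct),
                          participant_id = records$participant_id,
                          texture_id = if ("texture_id" %in% names(records))
                            records$texture_id else "T1"),
               X)
  terms <- names(X)
  n_tex <- length(unique(dat$texture_id))
  use_texture <- random_structure == "texture_participant" && n_tex >= 2
  if (random_structure == "texture_participant" && !use_texture)
    message("single texture: texture random effects dropped")
  grp <- if (use_texture)
    c("texture_id", "texture_id:participant_id") else "participant_id"
  n_grp <- length(unique(dat$participant_id))
  re <- paste0("(1 + ", paste(terms, collapse = " + "), " || ", grp, ")")

  build <- function(tm) {
    fe <- if (length(tm)) paste(tm, collapse = " + ") else "1"
    stats::as.formula(paste("correct ~", fe, "+", paste(re, collapse = " + ")))
  }

  if (n_grp < 2 && !use_texture) {
    warning("fewer than 2 grouping units: falling back to a plain GLM")
    gl <- fit_participant_glm(records, factors)
    return(structure(list(fixed_effects = data.frame(
      term = gl$term, estimate = gl$estimate, ci_low = gl$ci_low,
      ci_high = gl$ci_high, p_lrt = gl$p_wald, ci_method = "wald"),
      random_sd = numeric(0), loglik = NA_real_, converged = TRUE,
      model = NULL), class = "glmm_fit"))
  }

  ctrl <- lme4::glmerControl(optimizer = "bobyqa",
                             calc.derivs = FALSE,
                             check.conv.singular = "ignore")
  fit <- suppressMessages(lme4::glmer(build(terms), data = dat,
                                      family = stats::binomial(),
                                      control = ctrl, nAGQ = nAGQ))
  conv <- length(fit@optinfo$conv$lme4$messages) == 0

  # LRT per fixed effect (random structure kept)
  p_lrt <- if (lrt) vapply(terms, function(tm) {
    red <- suppressMessages(lme4::glmer(build(setdiff(terms, tm)), data = dat,
                                        family = stats::binomial(),
                                        control = ctrl, nAGQ = nAGQ))
    an <- suppressMessages(stats::anova(fit, red))
    an[["Pr(>Chisq)"]][2]
  }, numeric(1)) else rep(NA_real_, length(terms))

  est <- lme4::fixef(fit)[terms]
  used_method <- ci_method
  ci <- NULL
  if (ci_method == "profile") {
    ci <- tryCatch({
      pr <- suppressMessages(suppressWarnings(
        stats::profile(fit, which = terms, alphamax = 0.045, maxpts = 12,
                       signames = FALSE)))
      as.matrix(suppressMessages(stats::confint(pr, level = 0.95))[terms, ,
                                                                   drop = FALSE])
    }, error = function(e) NULL)
    if (is.null(ci) || any(!is.finite(ci))) {
      used_method <- "wald"
      ci <- NULL
    }
  }
  if (is.null(ci)) {
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))[paste0(terms)]
    ci <- cbind(est - 1.96 * se, est + 1.96 * se)
    rownames(ci) <- terms
  }

  vc <- lme4::VarCorr(fit)
  rsd <- unlist(lapply(names(vc), function(g)
    stats::setNames(attr(vc[[g]], "stddev"),
                    paste0(g, ".", names(attr(vc[[g]], "stddev"))))))

  structure(list(fixed_effects = data.frame(
    term = terms, estimate = as.numeric(est),
    ci_low = ci[terms, 1], ci_high = ci[terms, 2],
    p_lrt = as.numeric(p_lrt), ci_method = used_method, row.names = NULL),
    random_sd = rsd, loglik = as.numeric(stats::logLik(fit)),
    converged = conv, model = fit), class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("<glmm_fit> fixed effects (log-odds ratios):\n")
  print(x$fixed_effects, digits = 3)
  if (length(x$random_sd)) {
    cat("random-effect SDs:\n")
    print(round(x$random_sd, 3))
  }
  invisible(x)
}

#' Convert a log-odds ratio to a success probability
#'
#' @param baseline_p Baseline success probability, strictly inside (0, 1).
#' @param lor Log-odds ratio to add.
#' @return `plogis(qlogis(baseline_p) + lor)`.
#' @export
lor_to_probability <- function(baseline_p, lor) {
  if (any(baseline_p <= 0 | baseline_p >= 1))
    stop("baseline_p must be strictly between 0 and 1")
  stats::plogis(stats::qlogis(baseline_p) + lor)
}

#' Read a trial CSV, optionally renaming deposit columns
#'
#' @param path CSV file with one row per trial.
#' @param column_map Optional named character vector `c(ours = "theirs")`
#'   translating external column names (e.g. of a downloaded deposit) to
#'   the trial-record schema.
#' @return Trial data frame.
#' @export
read_trial_csv <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(d)) stop("column not found: ", theirs)
      names(d)[names(d) == theirs] <- ours
    }
  }
  if ("correct" %in% names(d)) d$correct <- as.logical(d$correct)
  d
}
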
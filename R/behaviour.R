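#' Behavioural preprocessing
#'
#' Splits a trial table into the accuracy analysis table (timeouts
#' excluded; spatial stream confusions and random errors jointly coded as
#' incorrect) and the response-speed table (correct trials only, speed =
#' 1/RT). Trials without a response within the 4-s window count as
#' timeouts.
#'
#' @param trials Data frame with columns `accuracy` (correct /
#'   spatial_confusion / random_error / timeout) and `reaction_time` (s);
#'   other columns are carried through.
#' @param response_window_s Response deadline in seconds.
#' @return List with `accuracy` (adds logical `correct`) and `speed`
#'   (adds `speed`) data frames.
#' @export
preprocess_behaviour <- function(trials, response_window_s = 4) {
  timeout <- trials$accuracy == "timeout" |
    (!is.na(trials$reaction_time) & trials$reaction_time >= response_window_s)
  acc <- trials[!timeout, , drop = FALSE]
  acc$correct <- acc$accuracy == "correct"
  spd <- acc[acc$correct & !is.na(acc$reaction_time), , drop = FALSE]
  spd$speed <- 1 / spd$reaction_time
  if (nrow(spd) == 0) warning("no correct trials: speed table is empty")
  list(accuracy = acc, speed = spd)
}

#' Breakdown of error types with a paired test
#'
#' Computes per-subject proportions of spatial stream confusions and random
#' errors (relative to answered trials), logit-transforms them with a
#' small-sample adjustment (numerator + 0.5, denominator + 1, so zero
#' counts stay finite), and compares the two error types with a paired t
#' test.
#'
#' @param trials Trial table as in [preprocess_behaviour()].
#' @return List with `by_subject` (subject, prop_confusion, prop_random,
#'   logit_confusion, logit_random), `t`, `df`, `p`.
#' @export
error_breakdown <- function(trials) {
  answered <- trials[trials$accuracy != "timeout", , drop = FALSE]
  adj_logit <- function(k, n) stats::qlogis((k + 0.5) / (n + 1))
  by_subject <- do.call(rbind, lapply(split(answered, answered$subject),
    function(d) {
      n <- nrow(d)
      kc <- sum(d$accuracy == "spatial_confusion")
      kr <- sum(d$accuracy == "random_error")
      data.frame(subject = d$subject[1],
                 prop_confusion = kc / n, prop_random = kr / n,
                 logit_confusion = adj_logit(kc, n),
                 logit_random = adj_logit(kr, n))
    }))
  rownames(by_subject) <- NULL
  d <- by_subject$logit_confusion - by_subject$logit_random
  if (stats::sd(d) == 0) {
    tt <- list(statistic = 0, parameter = length(d) - 1, p.value = 1)
  } else {
    tt <- stats::t.test(by_subject$logit_confusion,
                        by_subject$logit_random, paired = TRUE)
  }
  list(by_subject = by_subject, t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Within/between-subject (state/trait) decomposition of a neural measure
#'
#' Splits a per-trial neural measure into a between-subject (trait)
#' regressor, the subject mean z-scored across subjects, and a
#' within-subject (state) regressor, the trial-by-trial deviation from the
#' subject mean, z-scored globally. By construction the two are orthogonal
#' and the within regressor sums to zero within every subject.
#'
#' @param x Per-trial neural measure.
#' @param subject Subject id per trial.
#' @return Data frame with `between` and `within` regressors (one row per
#'   trial).
#' @export
decompose_within_between <- function(x, subject) {
  sub_mean <- tapply(x, subject, mean, na.rm = TRUE)
  zs <- function(v) {
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }
  between_z <- zs(as.numeric(sub_mean))
  names(between_z) <- names(sub_mean)
  within <- x - sub_mean[as.character(subject)]
  data.frame(between = as.numeric(between_z[as.character(subject)]),
             within = zs(as.numeric(within)))
}

# deviation-coded (+/- 0.5) numeric regressors for the standard factors
code_predictors <- function(d) {
  if (!is.null(d$spatial_cue)) {
    d$spatial <- ifelse(d$spatial_cue == "informative", 0.5, -0.5)
  }
  if (!is.null(d$semantic_cue)) {
    d$semantic <- ifelse(d$semantic_cue == "specific", 0.5, -0.5)
  }
  if (!is.null(d$probed_ear)) {
    d$ear <- ifelse(d$probed_ear == "right", 0.5, -0.5)
  }
  if (!is.null(d$probed_first)) {
    d$onset_lead <- ifelse(d$probed_first, 0.5, -0.5)
  }
  zsub <- function(v, subject) {
    m <- tapply(v, subject, mean)
    z <- as.numeric(scale(as.numeric(m)))
    if (all(is.na(z))) z <- rep(0, length(m))
    names(z) <- names(m)
    as.numeric(z[as.character(subject)])
  }
  if (!is.null(d$age)) d$age_z <- zsub(d$age, d$subject)
  if (!is.null(d$pta)) d$pta_z <- zsub(d$pta, d$subject)
  d
}

tidy_fit <- function(model, family = c("binomial", "gaussian")) {
  family <- match.arg(family)
  cf <- stats::coef(summary(model))
  stat_col <- if (family == "binomial") "z value" else "t value"
  est <- cf[, "Estimate"]
  se <- cf[, "Std. Error"]
  stat <- cf[, stat_col]
  p <- 2 * stats::pnorm(-abs(stat))    # Wald, t-as-z for linear models
  tab <- data.frame(term = rownames(cf), estimate = est, se = se,
                    statistic = stat, p = p, row.names = NULL)
  keep <- tab$term != "(Intercept)"
  tab$p_fdr <- NA_real_
  tab$p_fdr[keep] <- fdr_correct(tab$p[keep])
  if (family == "binomial") {
    tab$or <- exp(tab$estimate)
    tab$or_lo <- exp(tab$estimate - 1.96 * tab$se)
    tab$or_hi <- exp(tab$estimate + 1.96 * tab$se)
  } else {
    tab$ci_lo <- tab$estimate - 1.96 * tab$se
    tab$ci_hi <- tab$estimate + 1.96 * tab$se
  }
  tab
}

#' Mixed-effects model of single-trial accuracy
#'
#' Binomial (logit link) generalized linear mixed model with random
#' intercepts for subject and item, Wald z tests, odds ratios, and BH-FDR
#' corrected p values. The fixed-effect roster is configurable through
#' `formula_rhs`, so cue-only, brain-behaviour, and control models are all
#' expressible.
#'
#' @param data Accuracy table from [preprocess_behaviour()]; passed through
#'   [code_predictors()] if the coded columns are absent.
#' @param formula_rhs Right-hand side of the fixed-effects formula (a
#'   string); random intercepts `(1 | subject) + (1 | item)` are appended
#'   unless `random` overrides them.
#' @param random Random-effects specification (string).
#' @return A `fit_result`: list with `table` (tidy coefficients with OR and
#'   95% CI), `model`, `converged`, `separation` flag, `logLik`.
#' @export
fit_accuracy_model <- function(data,
                               formula_rhs = "spatial * semantic + ear + age_z + pta_z",
                               random = "(1 | subject) + (1 | item)") {
  if (!("spatial" %in% names(data)) && "spatial_cue" %in% names(data)) {
    data <- code_predictors(data)
  }
  f <- stats::as.formula(paste("correct ~", formula_rhs, "+", random))
  model <- lme4::glmer(f, data = data, family = stats::binomial())
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged) {
    warning("accuracy model convergence issues: ",
            paste(unlist(msgs), collapse = "; "),
            " (max |gradient| = ",
            signif(max(abs(model@optinfo$derivs$gradient)), 3), ")")
  }
  tab <- tidy_fit(model, "binomial")
  separation <- any(abs(tab$estimate) > 10)
  if (separation) warning("possible separation: |log-odds| > 10")
  structure(list(table = tab, model = model, converged = converged,
                 separation = separation, logLik = stats::logLik(model)),
            class = "fit_result")
}

#' Mixed-effects model of response speed
#'
#' Gaussian linear mixed model on z-scored speed (1/RT) with random
#' intercepts for subject and item; coefficients are standardized slopes
#' with Wald t-as-z p values and BH-FDR correction.
#'
#' @param data Speed table from [preprocess_behaviour()].
#' @param formula_rhs,random As in [fit_accuracy_model()].
#' @param z_outcome Whether to z-score the speed outcome (the reporting
#'   convention for standardized slopes).
#' @return A `fit_result` with standardized coefficients and 95% CI.
#' @export
fit_speed_model <- function(data,
                            formula_rhs = "spatial * semantic + ear + age_z + pta_z",
                            random = "(1 | subject) + (1 | item)",
                            z_outcome = TRUE) {
  if (!("spatial" %in% names(data)) && "spatial_cue" %in% names(data)) {
    data <- code_predictors(data)
  }
  data$speed_y <- if (z_outcome) as.numeric(scale(data$speed)) else data$speed
  f <- stats::as.formula(paste("speed_y ~", formula_rhs, "+", random))
  model <- lme4::lmer(f, data = data, REML = FALSE)
  msgs <- model@optinfo$conv$lme4$messages
  converged <- is.null(msgs)
  if (!converged) {
    warning("speed model convergence issues: ",
            paste(unlist(msgs), collapse = "; "))
  }
  structure(list(table = tidy_fit(model, "gaussian"), model = model,
                 converged = converged, separation = FALSE,
                 logLik = stats::logLik(model)),
            class = "fit_result")
}

#' Likelihood-ratio test for random-slope extensions
#'
#' Compares a base mixed model to an extension with additional random
#' slopes via a chi-square likelihood-ratio test on nested ML fits; the
#' extension is adopted only on significant improvement.
#'
#' @param base,extended `fit_result` objects or merMod models fitted to the
#'   same data.
#' @param alpha Significance level for adopting the extension.
#' @return List with `statistic`, `df`, `p`, `adopt_extension`.
#' @export
lrt_random_slopes <- function(base, extended, alpha = 0.05) {
  get_model <- function(x) if (inherits(x, "fit_result")) x$model else x
  m0 <- get_model(base)
  m1 <- get_model(extended)
  if (stats::nobs(m0) != stats::nobs(m1)) {
    stop("models are not nested: different numbers of observations")
  }
  ll0 <- stats::logLik(m0)
  ll1 <- stats::logLik(m1)
  df <- attr(ll1, "df") - attr(ll0, "df")
  if (df < 0) stop("models are not nested: extension has fewer parameters")
  stat <- max(0, 2 * (as.numeric(ll1) - as.numeric(ll0)))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p, adopt_extension = p < alpha)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p values controlling the false discovery rate at the
#' chosen level; a wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p Raw p values.
#' @param q Target FDR level (recorded, not used by the adjustment itself).
#' @return Adjusted p values.
#' @export
fdr_correct <- function(p, q = 0.05) {
  stats::p.adjust(p, method = "BH")
}
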
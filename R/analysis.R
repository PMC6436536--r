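#' Standardize to z-scores
#'
#' Centers to mean 0 and scales to sample SD 1 (n-1 denominator), the
#' `scale(Age)` convention of the regression tables.
#'
#' @param values Numeric vector with at least two distinct values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(values) {
  if (!is.numeric(values) || length(values) < 2L)
    stop("need a numeric vector of length >= 2", call. = FALSE)
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a constant vector", call. = FALSE)
  (values - mean(values)) / s
}

#' Sum-code a two-level factor as +/-1
#'
#' @param x Vector (factor or character) with exactly two distinct values.
#' @param positive_level The level mapped to +1; the other gets -1.
#' @return Numeric vector of +1/-1.
#' @export
sum_code <- function(x, positive_level) {
  levs <- unique(as.character(x))
  if (length(levs) != 2L)
    stop("`x` must have exactly 2 levels, found ", length(levs), call. = FALSE)
  if (!positive_level %in% levs)
    stop("`positive_level` not present in `x`", call. = FALSE)
  ifelse(as.character(x) == positive_level, 1, -1)
}

#' Ordinary least squares with a regression-table summary
#'
#' Thin wrapper over [stats::lm()] returning the coefficient table
#' (estimate, SE, t, two-sided p on residual df) together with the residual
#' five-number summary, in the layout of the study's printed tables.
#'
#' @param formula Model formula.
#' @param data Data frame.
#' @return List of class `regression_result`: `coefficients` (data frame
#'   `term`, `estimate`, `se`, `t`, `p`), `residual_summary`, `sigma`, `n`,
#'   `df_residual`, and the underlying `model`.
#' @export
fit_ols <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(fit)))
    stop("singular design: ", paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                                    collapse = ", "), call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  structure(list(
    coefficients = data.frame(term = rownames(ct), estimate = ct[, 1],
                              se = ct[, 2], t = ct[, 3], p = ct[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    residual_summary = stats::quantile(stats::residuals(fit),
                                       c(0, .25, .5, .75, 1)),
    sigma = sm$sigma, n = length(stats::residuals(fit)),
    df_residual = fit$df.residual, model = fit
  ), class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS fit, n = %d\n", x$n))
  print(format_coef_table(x$coefficients), row.names = FALSE)
  invisible(x)
}

format_coef_table <- function(ct) {
  data.frame(term = ct$term,
             Estimate = signif(ct$estimate, 6), SE = signif(ct$se, 4),
             t = round(ct$t, 3), p = signif(ct$p, 4),
             sig = stars(ct$p), stringsAsFactors = FALSE)
}

stars <- function(p) {
  cut(p, c(-Inf, .001, .01, .05, .1, Inf),
      labels = c("***", "**", "*", ".", ""))
}

#' Random-intercept linear mixed model, fit by maximum likelihood
#'
#' Fits `response ~ fixed effects + (1 | group)` by ML (`REML = FALSE`) via
#' `lme4`, returning the fixed-effect table with the subject-intercept and
#' residual variance components and the fit statistics.  The t statistics are
#' Wald; two-sided p-values use a t reference with `n_obs - n_fixed` degrees
#' of freedom (the reference tables print no p-values for this model; see the
#' methods vignette).
#'
#' @param formula Fixed-effects formula (e.g. `log_w ~ education * s_task`).
#' @param data Data frame in long (one row per observation) form.
#' @param group Name of the grouping column (default `"participant_id"`).
#' @return List of class `mixed_model_result`: `fixed` (term/estimate/se/t/p),
#'   `varcomp` (named vector `subject_intercept`, `residual`), `logLik`,
#'   `AIC`, `BIC`, `deviance`, `df_resid`, `n_obs`, `n_groups`, `converged`,
#'   and the underlying `model`.
#' @export
fit_lmm_random_intercept <- function(formula, data, group = "participant_id") {
  if (!group %in% names(data))
    stop("grouping column `", group, "` not in data", call. = FALSE)
  f <- stats::as.formula(paste(deparse(formula),
                               sprintf("+ (1 | %s)", group)))
  # boundary (sigma2_subject = 0) fits are legitimate ML solutions here
  fit <- lme4::lmer(f, data = data, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  ct <- stats::coef(summary(fit))
  n_obs <- stats::nobs(fit)
  df <- n_obs - nrow(ct)
  vc <- as.data.frame(lme4::VarCorr(fit))
  conv <- length(fit@optinfo$conv$lme4) == 0L
  ll <- stats::logLik(fit)
  structure(list(
    fixed = data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
                       t = ct[, 3], p = 2 * stats::pt(-abs(ct[, 3]), df),
                       row.names = NULL, stringsAsFactors = FALSE),
    varcomp = c(subject_intercept = vc$vcov[vc$grp == group],
                residual = vc$vcov[vc$grp == "Residual"]),
    logLik = as.numeric(ll), AIC = stats::AIC(fit), BIC = stats::BIC(fit),
    deviance = -2 * as.numeric(ll), df_resid = df, n_obs = n_obs,
    n_groups = lme4::ngrps(fit)[[1]], converged = conv, model = fit
  ), class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("Linear mixed model (ML): %d obs, %d groups\n", x$n_obs, x$n_groups))
  cat(sprintf("Random effects: subject intercept var %.5f, residual var %.5f\n",
              x$varcomp[["subject_intercept"]], x$varcomp[["residual"]]))
  cat(sprintf("AIC %.1f  BIC %.1f  logLik %.1f  deviance %.1f\n",
              x$AIC, x$BIC, x$logLik, x$deviance))
  print(format_coef_table(x$fixed), row.names = FALSE)
  invisible(x)
}

#' Recombine per-task OLS fits into sum-coded mixed-model fixed effects
#'
#' On a balanced complete-pairs design with a +/-1 task sum code, the mixed
#' model's fixed effects are exact linear combinations of the two per-task
#' OLS fits: intercept = mean of intercepts, task = half-difference
#' (positive minus negative level), slope = mean of slopes, interaction =
#' half-difference of slopes.
#'
#' @param positive Named or plain numeric `c(intercept, slope)` for the task
#'   coded +1 (cards).
#' @param negative Same for the task coded -1 (computer).
#' @return Named vector `intercept`, `slope`, `task`, `slope_task`.
#' @export
sum_code_combine <- function(positive, negative) {
  stopifnot(length(positive) == 2L, length(negative) == 2L)
  c(intercept  = (positive[[1]] + negative[[1]]) / 2,
    slope      = (positive[[2]] + negative[[2]]) / 2,
    task       = (positive[[1]] - negative[[1]]) / 2,
    slope_task = (positive[[2]] - negative[[2]]) / 2)
}

#' Per-subject difference scores (cards minus computer)
#'
#' Negative scores mean better (lower-W) performance on the cards task.
#' Subjects missing either task are excluded; their count is attached as
#' attribute `n_excluded`.
#'
#' @param cohort Wide cohort data frame with `logw_cards` and
#'   `logw_computer` (plus demographics), as in an `ans_cohort$cohort`.
#' @return Data frame with a `diff_logw` column and the demographic
#'   covariates, one row per complete subject.
#' @export
difference_scores <- function(cohort) {
  need <- c("logw_cards", "logw_computer")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  complete <- !is.na(cohort$logw_cards) & !is.na(cohort$logw_computer)
  out <- cohort[complete, , drop = FALSE]
  out$diff_logw <- out$logw_cards - out$logw_computer
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!complete)
  out
}

#' Education level at which the task difference vanishes
#'
#' For a difference-score model `diff = intercept + slope * education + ...`,
#' the tasks stop differing at `-intercept / slope` years of education.
#'
#' @param intercept Difference-score model intercept.
#' @param edu_slope Education slope (must be nonzero).
#' @return Crossover education in years.
#' @export
crossover_education <- function(intercept, edu_slope) {
  if (!is.numeric(edu_slope) || edu_slope == 0)
    stop("crossover undefined for zero education slope", call. = FALSE)
  -intercept / edu_slope
}
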
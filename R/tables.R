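#' Fit the full set of study-style regression tables on a cohort
#'
#' Drives the four models of the analysis stage in sequence:
#' \enumerate{
#'   \item the sum-coded random-intercept mixed model
#'     `Log W ~ education * task + (1 | subject)` (ML);
#'   \item the two per-task OLS regressions `Log W ~ education`, plus their
#'     W-scale variants (`W ~ education`);
#'   \item the difference-score model
#'     `cards - computer ~ education + order + scale(age) + gender`
#'     (order and gender sum-coded, female = +1, computer-first = +1);
#'   \item the demographics model `education ~ scale(age) * gender`;
#' }
#' and the crossover-education statistic derived from model 3.
#'
#' @param x An `ans_cohort` (from [generate_cohort()]) or a wide cohort data
#'   frame with `logw_cards`, `logw_computer`, `education_years`,
#'   `age_years`, `gender`, `computer_first`.
#' @param include_order_interaction Add an education x order term to the
#'   difference-score model (a probe variant, off by default).
#' @return List of class `ans_tables`: `mixed`, `per_task`
#'   (`$computer`, `$cards`), `per_task_w`, `difference`, `education`,
#'   `crossover_years`, `n_excluded`.
#' @export
reproduce_tables <- function(x, include_order_interaction = FALSE) {
  cohort <- if (inherits(x, "ans_cohort")) x$cohort else x
  need <- c("logw_cards", "logw_computer", "education_years", "age_years",
            "gender", "computer_first")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)

  long <- rbind(
    data.frame(participant_id = cohort$participant_id,
               education_years = cohort$education_years,
               s_task = 1, log_w = cohort$logw_cards,
               stringsAsFactors = FALSE),
    data.frame(participant_id = cohort$participant_id,
               education_years = cohort$education_years,
               s_task = -1, log_w = cohort$logw_computer,
               stringsAsFactors = FALSE)
  )
  long <- long[!is.na(long$log_w), ]
  mixed <- fit_lmm_random_intercept(log_w ~ education_years * s_task, long)

  per_task <- list(
    computer = fit_ols(logw_computer ~ education_years, cohort),
    cards    = fit_ols(logw_cards ~ education_years, cohort)
  )
  wdat <- transform(cohort, w_computer = exp(logw_computer),
                    w_cards = exp(logw_cards))
  per_task_w <- list(
    computer = fit_ols(w_computer ~ education_years, wdat),
    cards    = fit_ols(w_cards ~ education_years, wdat)
  )

  d <- difference_scores(cohort)
  d$order_sum <- ifelse(d$computer_first, 1, -1)
  d$z_age <- standardize(d$age_years)
  d$gender_sum <- sum_code(d$gender, "female")
  f <- if (include_order_interaction)
    diff_logw ~ education_years * order_sum + z_age + gender_sum
  else
    diff_logw ~ education_years + order_sum + z_age + gender_sum
  difference <- fit_ols(f, d)

  edu_dat <- cohort
  edu_dat$z_age <- standardize(edu_dat$age_years)
  edu_dat$gender_sum <- sum_code(edu_dat$gender, "female")
  education <- fit_ols(education_years ~ z_age * gender_sum, edu_dat)

  cf <- difference$coefficients
  crossover <- crossover_education(
    cf$estimate[cf$term == "(Intercept)"],
    cf$estimate[cf$term == "education_years"]
  )

  structure(list(mixed = mixed, per_task = per_task, per_task_w = per_task_w,
                 difference = difference, education = education,
                 crossover_years = crossover,
                 n_excluded = attr(d, "n_excluded")),
            class = "ans_tables")
}

#' @export
print.ans_tables <- function(x, ...) {
  cat("== Mixed model: Log W ~ education * task + (1 | subject) ==\n")
  print(x$mixed)
  cat("\n== Per-task OLS: Log W ~ education ==\n")
  cat("-- computer --\n"); print(x$per_task$computer)
  cat("-- cards --\n"); print(x$per_task$cards)
  cat("\n== Difference score (cards - computer) ~ education + order + scale(age) + gender ==\n")
  print(x$difference)
  cat("\n== Education ~ scale(age) * gender ==\n")
  print(x$education)
  cat(sprintf("\nCrossover education (tasks stop differing): %.1f years\n",
              x$crossover_years))
  invisible(x)
}

#' Export the table report as TSV files plus a JSON bundle
#'
#' @param tables An `ans_tables` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(inherits(tables, "ans_tables"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    tsv(tables$mixed$fixed, "mixed_fixed_effects.tsv"),
    tsv(tables$per_task$computer$coefficients, "ols_computer.tsv"),
    tsv(tables$per_task$cards$coefficients, "ols_cards.tsv"),
    tsv(tables$difference$coefficients, "difference_model.tsv"),
    tsv(tables$education$coefficients, "education_model.tsv")
  )
  bundle <- list(
    mixed = list(fixed = tables$mixed$fixed,
                 varcomp = as.list(tables$mixed$varcomp),
                 logLik = tables$mixed$logLik, AIC = tables$mixed$AIC,
                 BIC = tables$mixed$BIC, deviance = tables$mixed$deviance,
                 n_obs = tables$mixed$n_obs, n_groups = tables$mixed$n_groups),
    ols_computer = tables$per_task$computer$coefficients,
    ols_cards = tables$per_task$cards$coefficients,
    ols_w_scale_computer = tables$per_task_w$computer$coefficients,
    ols_w_scale_cards = tables$per_task_w$cards$coefficients,
    difference_model = tables$difference$coefficients,
    education_model = tables$education$coefficients,
    crossover_years = tables$crossover_years,
    n_excluded = tables$n_excluded
  )
  jp <- file.path(dir, "results.json")
  jsonlite::write_json(bundle, jp, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(paths, jp))
}

#' Export a difference-score scatter table for plotting
#'
#' A plain difference-vs-education export (one row per subject with age and
#' gender); no smoother is applied.
#'
#' @param cohort Wide cohort data frame or `ans_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_difference_scatter <- function(cohort, path) {
  if (inherits(cohort, "ans_cohort")) cohort <- cohort$cohort
  d <- difference_scores(cohort)
  utils::write.csv(
    d[, c("participant_id", "education_years", "age_years", "gender",
          "diff_logw")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
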
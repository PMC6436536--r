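#' Weber-fraction parameter recovery from simulated staircase sessions
#'
#' Simulates `n_sessions` independent 30-trial staircase sessions at a known
#' Weber fraction and refits each by maximum likelihood and by MAP,
#' quantifying estimator bias, spread and recovery error.  The weak prior is
#' expected to shrink estimator variance with negligible effect on the mean.
#'
#' @param true_w True Weber fraction of the simulated responder.
#' @param n_sessions Number of replicate sessions.
#' @param seed Integer seed.
#' @param prior,bounds Passed to the fitters.
#' @param n_trials Trials per session (default 30).
#' @return List: `estimates` (data frame `w_ml`, `w_map` per session) and
#'   `summary` (named vector: `true_w`, `median_est_map`, `median_est_ml`,
#'   `median_abs_err_map`, `median_abs_err_ml`, `bias_map`, `bias_ml`,
#'   `var_map`, `var_ml`).
#' @export
recover_w_estimates <- function(true_w, n_sessions = 500L, seed = 1L,
                                prior = prior_spec("exponential", 1.0),
                                bounds = c(0.01, 3.0), n_trials = 30L) {
  set.seed(seed)
  session_seeds <- sample.int(.Machine$integer.max, n_sessions)
  w_ml <- w_map <- numeric(n_sessions)
  for (i in seq_len(n_sessions)) {
    s <- simulate_session(true_w, task = "cards", participant_id = "rec",
                          seed = session_seeds[i], n_trials = n_trials)
    w_ml[i] <- fit_w_ml(s$trials, bounds = bounds)$w_hat
    w_map[i] <- fit_w_map(s$trials, prior = prior, bounds = bounds)$w_hat
  }
  list(
    estimates = data.frame(w_ml = w_ml, w_map = w_map),
    summary = c(true_w = true_w,
                median_est_map = stats::median(w_map),
                median_est_ml = stats::median(w_ml),
                median_abs_err_map = stats::median(abs(w_map - true_w)),
                median_abs_err_ml = stats::median(abs(w_ml - true_w)),
                bias_map = mean(w_map) - true_w,
                bias_ml = mean(w_ml) - true_w,
                var_map = stats::var(w_map),
                var_ml = stats::var(w_ml))
  )
}

#' End-to-end recovery of the mixed-model fixed effects
#'
#' Generates `n_reps` parametric cohorts at the given generative parameters,
#' fits the sum-coded random-intercept mixed model to each, and reports (a)
#' the coverage of nominal Wald 95% intervals for each fixed effect and (b)
#' the largest deviation, across replicates, of the mixed-model fixed
#' effects from the sum-coded recombination of the two per-task OLS fits
#' (an exact algebraic identity on complete-pairs data).
#'
#' The coverage target for the task effect is the implied marginal
#' coefficient `beta_task + (delta_order / 2) * mean(order sum code)`: the
#' generator's task-order effect is not a term of the fitted model and, with
#' complete pairs, its omission shifts only the task coefficient (see the
#' methods vignette).
#'
#' @param n_reps Number of replicate cohorts.
#' @param params A [generative_params()] object (its `seed` is ignored;
#'   per-replicate seeds derive from `seed`).
#' @param seed Integer seed.
#' @param level Interval coverage level (default 0.95).
#' @return List: `coverage` (named fractions for `intercept`, `education`,
#'   `task`, `education_task`), `identity_max_abs_err`, `n_reps`, and
#'   `estimates` (per-replicate fixed-effect draws).
#' @export
recover_fixed_effects <- function(n_reps = 500L, params = generative_params(),
                                  seed = 1L, level = 0.95) {
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  z <- stats::qnorm(1 - (1 - level) / 2)
  terms_lmm <- c("(Intercept)", "education_years", "s_task",
                 "education_years:s_task")
  cover <- matrix(FALSE, n_reps, 4,
                  dimnames = list(NULL, c("intercept", "education", "task",
                                          "education_task")))
  est <- matrix(NA_real_, n_reps, 4, dimnames = dimnames(cover))
  identity_err <- numeric(n_reps)

  for (r in seq_len(n_reps)) {
    p <- params
    p$seed <- rep_seeds[r]
    cohort <- generate_cohort(p, mode = "parametric")$cohort
    long_fit <- fit_lmm_random_intercept(
      log_w ~ education_years * s_task,
      rbind(
        data.frame(participant_id = cohort$participant_id,
                   education_years = cohort$education_years, s_task = 1,
                   log_w = cohort$logw_cards),
        data.frame(participant_id = cohort$participant_id,
                   education_years = cohort$education_years, s_task = -1,
                   log_w = cohort$logw_computer)
      ))
    fx <- long_fit$fixed
    fx <- fx[match(terms_lmm, fx$term), ]

    mean_order <- mean(ifelse(cohort$computer_first, 1, -1))
    targets <- c(params$beta0, params$beta_edu,
                 params$beta_task + params$delta_order / 2 * mean_order,
                 params$beta_edu_task)
    cover[r, ] <- abs(fx$estimate - targets) <= z * fx$se
    est[r, ] <- fx$estimate

    ols_cards <- fit_ols(logw_cards ~ education_years, cohort)
    ols_comp <- fit_ols(logw_computer ~ education_years, cohort)
    combo <- sum_code_combine(ols_cards$coefficients$estimate,
                              ols_comp$coefficients$estimate)
    identity_err[r] <- max(abs(
      fx$estimate - combo[c("intercept", "slope", "task", "slope_task")]))
  }
  list(coverage = colMeans(cover),
       identity_max_abs_err = max(identity_err),
       n_reps = n_reps,
       estimates = as.data.frame(est))
}

#' Practice-phase pass rate of a simulated responder
#'
#' Monte-Carlo estimate of the probability of clearing the practice gate
#' (zero errors on some attempt out of three eight-trial attempts at the
#' 1:3 ratio).  For a chance responder the closed form is
#' `1 - (1 - 0.5^8)^3`.
#'
#' @param w True Weber fraction.
#' @param n_seeds Number of simulated responders.
#' @param seed Integer seed.
#' @return Proportion passing.
#' @export
practice_pass_rate <- function(w, n_seeds = 1e5, seed = 1L) {
  set.seed(seed)
  passed <- logical(n_seeds)
  for (i in seq_len(n_seeds)) passed[i] <- run_practice(w)$passed
  mean(passed)
}
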
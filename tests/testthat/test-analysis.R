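test_that("standardize matches the scale() convention", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  x <- rnorm(50, 10, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_equal(sd(z), 1)
  expect_equal(standardize(z), z)
  expect_error(standardize(rep(2, 5)), "constant")
})

test_that("sum_code maps the positive level to +1 and flips signs on recode", {
  x <- c("cards", "computer", "cards", "computer")
  expect_equal(sum_code(x, "cards"), c(1, -1, 1, -1))
  expect_equal(sum(sum_code(x, "cards")), 0)
  expect_error(sum_code(c("a", "b", "c"), "a"), "2 levels")
  expect_error(sum_code(c("a", "a"), "a"), "2 levels")

  set.seed(8)
  d <- data.frame(task = rep(c("cards", "computer"), each = 30),
                  edu = rep(rnorm(30), 2))
  d$y <- 1 + 0.5 * d$edu + rnorm(60, 0, 0.3)
  d$s1 <- sum_code(d$task, "cards")
  d$s2 <- sum_code(d$task, "computer")
  f1 <- fit_ols(y ~ edu * s1, d)$coefficients
  f2 <- fit_ols(y ~ edu * s2, d)$coefficients
  expect_equal(f1$estimate[f1$term == "s1"], -f2$estimate[f2$term == "s2"])
  expect_equal(f1$estimate[f1$term == "edu:s1"],
               -f2$estimate[f2$term == "edu:s2"])
  expect_equal(f1$estimate[f1$term == "(Intercept)"],
               f2$estimate[f2$term == "(Intercept)"])
})

test_that("fit_ols solves least squares exactly and matches the normal equations", {
  d <- data.frame(x = 1:10, y = 2 * (1:10))
  f <- suppressWarnings(fit_ols(y ~ x, d))  # exact fit: summary.lm warns
  expect_equal(f$coefficients$estimate, c(0, 2))
  expect_equal(unname(f$residual_summary), rep(0, 5))

  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    d <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
    d$y <- rnorm(n)
    f <- fit_ols(y ~ x1 + x2, d)
    X <- cbind(1, d$x1, d$x2)
    beta <- solve(t(X) %*% X, t(X) %*% d$y)  # independent oracle
    expect_equal(f$coefficients$estimate, as.numeric(beta), tolerance = 1e-8)
    # SEs from the unbiased residual variance
    res <- d$y - X %*% beta
    s2 <- sum(res^2) / (n - 3)
    expect_equal(f$coefficients$se,
                 sqrt(diag(s2 * solve(t(X) %*% X))), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # two-sided t p-values
    expect_equal(f$coefficients$p,
                 2 * pt(-abs(f$coefficients$t), n - 3))
  }
  d$x3 <- d$x1 + d$x2
  expect_error(fit_ols(y ~ x1 + x2 + x3, d), "singular")
})

test_that("the mixed model collapses to OLS when the group variance is zero", {
  set.seed(20)
  n <- 80
  d <- data.frame(participant_id = rep(sprintf("s%02d", 1:(n / 2)), each = 2),
                  x = rnorm(n))
  d$y <- 1 + 0.4 * d$x + rnorm(n, 0, 0.5)  # no subject effect at all
  m <- fit_lmm_random_intercept(y ~ x, d)
  o <- fit_ols(y ~ x, d)
  expect_lt(m$varcomp[["subject_intercept"]], 1e-6)
  expect_equal(m$fixed$estimate, o$coefficients$estimate, tolerance = 1e-6)
  expect_equal(m$n_obs, n)
  expect_equal(m$n_groups, n / 2)
  expect_true(m$converged)
})

test_that("balanced complete pairs: mixed fixed effects equal per-task OLS combinations", {
  co <- generate_cohort(generative_params(seed = 41), "parametric")$cohort
  long <- rbind(
    data.frame(participant_id = co$participant_id,
               education_years = co$education_years, s_task = 1,
               log_w = co$logw_cards),
    data.frame(participant_id = co$participant_id,
               education_years = co$education_years, s_task = -1,
               log_w = co$logw_computer))
  m <- fit_lmm_random_intercept(log_w ~ education_years * s_task, long)
  cards <- fit_ols(logw_cards ~ education_years, co)$coefficients$estimate
  comp <- fit_ols(logw_computer ~ education_years, co)$coefficients$estimate
  combo <- sum_code_combine(cards, comp)
  expect_equal(m$fixed$estimate,
               unname(combo[c("intercept", "slope", "task", "slope_task")]),
               tolerance = 1e-8)
  # fit statistics are mutually consistent
  expect_equal(m$deviance, -2 * m$logLik)
  expect_equal(m$AIC, m$deviance + 2 * 6)
})

test_that("difference scores subtract computer from cards with exclusions counted", {
  co <- data.frame(participant_id = c("a", "b", "c"),
                   logw_cards = c(-1.2, -1.0, NA),
                   logw_computer = c(-1.2, -1.4, -1.1))
  d <- difference_scores(co)
  expect_equal(nrow(d), 2)
  expect_equal(attr(d, "n_excluded"), 1)
  expect_equal(d$diff_logw, c(0, 0.4))
  # lower (better) W on cards gives a negative score
  expect_lt(difference_scores(
    data.frame(participant_id = "x", logw_cards = -1.5,
               logw_computer = -1.0))$diff_logw, 0)
  expect_error(difference_scores(data.frame(logw_cards = 1)), "lacks")
})

test_that("crossover education is -intercept/slope", {
  expect_equal(crossover_education(-0.287, 0.051), 5.627, tolerance = 1e-3)
  expect_equal(crossover_education(0, 0.05), 0)
  expect_equal(crossover_education(-0.1, 0.05), 2)
  expect_error(crossover_education(-0.3, 0), "zero")
})

test_that("reproduce_tables recovers generating betas exactly when noise-free", {
  p <- generative_params(n_participants = 50, seed = 2, sigma2_subject = 0,
                         sigma2_resid = 0, delta_order = 0)
  tab <- suppressWarnings(reproduce_tables(generate_cohort(p, "parametric")))
  expect_equal(tab$mixed$fixed$estimate,
               c(p$beta0, p$beta_edu, p$beta_task, p$beta_edu_task),
               tolerance = 1e-6)
  # identity: mixed-model education effect = mean of the per-task OLS slopes
  slopes <- c(tab$per_task$cards$coefficients$estimate[2],
              tab$per_task$computer$coefficients$estimate[2])
  expect_equal(tab$mixed$fixed$estimate[2], mean(slopes), tolerance = 1e-8)
  # crossover consistent with the difference-model coefficients
  cf <- tab$difference$coefficients
  expect_equal(tab$crossover_years,
               -cf$estimate[cf$term == "(Intercept)"] /
                 cf$estimate[cf$term == "education_years"])
})

test_that("the education x order probe variant adds exactly one term", {
  co <- generate_cohort(generative_params(seed = 43), "parametric")
  base <- reproduce_tables(co)
  probe <- reproduce_tables(co, include_order_interaction = TRUE)
  expect_equal(nrow(probe$difference$coefficients),
               nrow(base$difference$coefficients) + 1)
  expect_true("education_years:order_sum" %in% probe$difference$coefficients$term)
})
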
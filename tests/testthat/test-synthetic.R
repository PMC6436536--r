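test_that("demographics respect bounds and the education model's structure", {
  set.seed(1)
  demo <- sample_demographics(generative_params(n_participants = 2000))
  expect_true(all(demo$education_years >= 0 & demo$education_years <= 16))
  expect_true(all(demo$education_years %% 1 == 0))
  expect_true(all(demo$age_years >= 17 & demo$age_years <= 77))
  expect_true(all(demo$gender %in% c("female", "male")))
  # order split close to the 63:141 default
  expect_lt(abs(mean(demo$computer_first) - 63 / 141), 0.05)

  # noise-free latent education: a female at the sample mean age rounds
  # 3.5706 - 1.2057 to 2 years
  p0 <- generative_params(n_participants = 500,
                          edu_model = c(intercept = 3.5706, b_age = -1.2454,
                                        b_gender = -1.2057,
                                        b_age_gender = -0.4277, sd_resid = 0))
  set.seed(2)
  d0 <- sample_demographics(p0)
  z <- standardize(d0$age_years)
  near_mean_f <- which(abs(z) < 0.02 & d0$gender == "female")
  expect_true(length(near_mean_f) > 0)
  expect_true(all(d0$education_years[near_mean_f] == 2))
})

test_that("education generator coefficients are recovered by refitting", {
  # interior regime (no clamping) so the linear structure is identifiable
  em <- c(intercept = 8, b_age = -1.2454, b_gender = -1.2057,
          b_age_gender = -0.4277, sd_resid = 1.5)
  set.seed(31)
  demo <- sample_demographics(
    generative_params(n_participants = 10000, edu_model = em))
  demo$z_age <- standardize(demo$age_years)
  demo$g <- sum_code(demo$gender, "female")
  fit <- fit_ols(education_years ~ z_age * g, demo)$coefficients
  truth <- c(8, -1.2454, -1.2057, -0.4277)
  expect_true(all(abs(fit$estimate - truth) <= 2 * fit$se))
})

test_that("the Log W generator reproduces the per-task intercepts exactly", {
  p <- generative_params(n_participants = 10, sigma2_subject = 0,
                         sigma2_resid = 0, delta_order = 0,
                         edu_model = c(intercept = -99, b_age = 0, b_gender = 0,
                                       b_age_gender = 0, sd_resid = 0))
  set.seed(5)
  demo <- sample_demographics(p)        # education clamps to 0 for everyone
  expect_true(all(demo$education_years == 0))
  lw <- sample_true_logw(demo, p)
  expect_equal(unique(lw$true_log_w[lw$task == "cards"]), -1.417944,
               tolerance = 1e-6)
  expect_equal(unique(lw$true_log_w[lw$task == "computer"]), -1.086634,
               tolerance = 1e-6)
  expect_equal(lw$true_w, exp(lw$true_log_w))
})

test_that("difference scores regress on education at twice the interaction", {
  p <- generative_params(seed = 17)
  tab <- reproduce_tables(generate_cohort(p, "parametric"))
  cf <- tab$difference$coefficients
  est <- cf$estimate[cf$term == "education_years"]
  se <- cf$se[cf$term == "education_years"]
  expect_lt(abs(est - 2 * p$beta_edu_task), 2 * se)
  # and the order coefficient recovers the generating delta
  est_o <- cf$estimate[cf$term == "order_sum"]
  se_o <- cf$se[cf$term == "order_sum"]
  expect_lt(abs(est_o - p$delta_order), 2 * se_o)
})

test_that("parametric cohorts are reproducible and respect the schema", {
  p <- generative_params(n_participants = 60, seed = 23)
  a <- generate_cohort(p, "parametric")
  b <- generate_cohort(p, "parametric")
  expect_identical(a$cohort, b$cohort)
  expect_equal(nrow(a$cohort), 60)
  expect_true(all(c("logw_cards", "logw_computer") %in% names(a$cohort)))
  expect_equal(a$n_practice_failed, 0L)
})

test_that("full-mode cohorts add estimation noise and drop practice failers", {
  p <- generative_params(n_participants = 141, seed = 29)
  param <- generate_cohort(p, "parametric")
  full <- generate_cohort(p, "full")
  # practice failures are a small minority under the default W distribution
  # (simulation across seeds puts the rate near 6-12%; see the vignette)
  expect_gte(full$n_practice_failed, 0)
  expect_lte(full$n_practice_failed / 141, 0.15)
  expect_equal(nrow(full$cohort), 141 - full$n_practice_failed)
  # estimated Log W has strictly larger spread than the generating truth
  v_full <- var(c(full$cohort$logw_cards, full$cohort$logw_computer))
  v_param <- var(c(param$cohort$logw_cards, param$cohort$logw_computer))
  expect_gt(v_full, v_param)
  # every simulated session is replay-valid and 30 trials long
  counts <- table(paste(full$trials$participant_id, full$trials$task))
  expect_true(all(counts == 30))
})
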
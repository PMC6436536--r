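test_that("the level table is exactly the study's 12 fixed pairs", {
  lt <- level_table()
  expect_equal(lt$index, 0:11)
  expect_equal(lt$n_small, c(5, 7, 8, 9, 8, 10, 12, 7, 8, 9, 10, 11))
  expect_equal(lt$n_large, c(15, 14, 12, 12, 10, 12, 14, 8, 9, 10, 11, 12))
  expect_equal(lt$ratio_label,
               c("1:3", "1:2", "2:3", "3:4", "4:5", "5:6", "6:7", "7:8",
                 "8:9", "9:10", "10:11", "11:12"))
  # counts reduce to the label's ratio
  lab <- strsplit(lt$ratio_label, ":")
  expect_true(all(mapply(function(l, ns, nl)
    ns * as.integer(l[2]) == nl * as.integer(l[1]),
    lab, lt$n_small, lt$n_large)))
  # totals as close to 20 as the ratios allow (6:7 needs 12 + 14 = 26)
  expect_true(all(abs(lt$n_small + lt$n_large - 20) <= 6))
})

test_that("two-up/one-down transitions respect floor, ceiling and streak", {
  expect_equal(next_level(1, "wrong"), 1)                       # 1:2 floor
  expect_equal(next_level(2, "correct", 1), 3)                  # 2:3 -> 3:4
  expect_equal(next_level(2, "correct", 0), 2)                  # first correct
  expect_equal(next_level(11, "correct", 1), 11)                # ceiling clamp
  expect_equal(next_level(5, "wrong", 1), 4)
  expect_error(next_level(0, "correct"), "1..11")
  expect_error(next_level(12, "wrong"), "1..11")
})

test_that("trial decks hold 4 red-correct and 4 black-correct in seeded order", {
  lt <- level_table()
  d <- build_trial_deck(lt[3, ], rng_seed = 5)
  expect_equal(nrow(d), 8)
  expect_equal(sort(d$version), 1:8)
  expect_equal(sum(d$correct_color == "red"), 4)
  expect_identical(d, build_trial_deck(lt[3, ], rng_seed = 5))
  # seeded shuffle is uniform: first slot red-correct about half the time
  firsts <- vapply(1:2000,
                   function(s) build_trial_deck(lt[3, ], s)$correct_color[1],
                   character(1))
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(firsts == "red") - 0.5), 3 * se)
})

test_that("simulated sessions are deterministic and replay-valid", {
  s1 <- simulate_session(0.25, "cards", "p1", seed = 7)
  s2 <- simulate_session(0.25, "cards", "p1", seed = 7)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$trials), 30)
  expect_true(validate_session(s1))

  set.seed(55)
  for (w in runif(15, 0.05, 2)) {
    s <- simulate_session(w, seed = sample.int(1e6, 1))
    expect_true(validate_session(s))
  }
})

test_that("a noiseless responder climbs two-per-level to the ceiling", {
  s <- simulate_session(1e-9, seed = 3)
  expect_true(all(s$trials$is_correct))
  expect_equal(s$trials$level_index,
               c(rep(1:10, each = 2), rep(11, 10)))
  expect_equal(min(which(s$trials$level_index == 11)), 21)
})

test_that("a chance responder sits at the easiest test levels", {
  set.seed(77)
  n_sessions <- 300
  at_easy <- vapply(sample.int(1e6, n_sessions), function(seed) {
    s <- simulate_session(1e6, seed = seed)
    mean(s$trials$level_index <= 2)
  }, numeric(1))
  expect_gte(mean(at_easy), 0.80)
})

test_that("mean achieved level decreases with true W", {
  set.seed(88)
  mean_final <- vapply(c(0.1, 0.2, 0.4, 0.8), function(w) {
    mean(vapply(sample.int(1e6, 250), function(seed) {
      s <- simulate_session(w, seed = seed)
      mean(s$trials$level_index[21:30])
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_final) < 0))
})

test_that("deck templates only repeat after all eight are used", {
  # a floor-sitting chance responder exhausts the 1:2 deck several times
  s <- simulate_session(50, seed = 13, n_trials = 40)
  expect_true(validate_session(s))  # includes deck accounting
  v <- s$trials$deck_version[s$trials$level_index == 1]
  expect_gt(length(v), 8)  # reshuffle actually happened
  expect_equal(sort(v[1:8]), 1:8)
})

test_that("practice phase gates on a perfect attempt within three tries", {
  p <- run_practice(1e-9, seed = 1)
  expect_true(p$passed)
  expect_equal(p$attempts_used, 1)
  expect_equal(p$per_attempt_errors, 0L)
  expect_identical(run_practice(0.2, seed = 9), run_practice(0.2, seed = 9))
  p_bad <- run_practice(1e6, seed = 4)
  expect_lte(p_bad$attempts_used, 3)
  expect_equal(p_bad$passed, any(p_bad$per_attempt_errors == 0))
})
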
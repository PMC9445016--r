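# Functional-test scoring rules.

test_that("mean-over-trials scoring handles full and partial inputs", {
  expect_equal(score_bilateral_mean(c(10, 12)), 11)
  expect_equal(score_bilateral_mean(9), 9)
  expect_equal(score_bilateral_mean(c(10, 10, 11, 11, 12, 12)), 11)
  expect_true(is.na(score_bilateral_mean(numeric(0))))
  expect_true(is.na(score_bilateral_mean(c(NA, NA))))
})

test_that("CKCUES averages trials but scores 0 when not attempted", {
  expect_equal(score_ckcue(c(20, 22, 24)), 22)
  expect_equal(score_ckcue(15), 15)
  expect_identical(score_ckcue(numeric(0), attempted = FALSE), 0)
  expect_error(score_ckcue(c(1, 2, 3, 4)), class = "mvh_input_error")
})

test_that("plumb line is the sample variance of four landmark distances", {
  expect_equal(score_plumb_line(c(2, 2, 2, 2)), 0)
  expect_equal(score_plumb_line(c(1, 2, 3, 4)), 5 / 3)
  expect_equal(score_plumb_line(c(1, 2, 3, 4) + 1), 5 / 3)  # shift-invariant
  expect_error(score_plumb_line(c(1, 2, 3)), class = "mvh_input_error")
})

test_that("normalized reach composites are unit-invariant", {
  reaches <- rep(0.9, 8)
  expect_equal(score_star_excursion(reaches, reaches, 0.9), 1.0)
  expect_equal(score_star_excursion(rep(0.8, 8), rep(1.0, 8), 1.0), 0.9)
  # doubling distances and leg length leaves the score unchanged
  expect_equal(score_star_excursion(2 * rep(0.8, 8), 2 * rep(1.0, 8), 2.0),
               score_star_excursion(rep(0.8, 8), rep(1.0, 8), 1.0))
  expect_equal(score_y_balance_upper(rep(0.9, 3), rep(1.1, 3), 1.0), 1.0)
  # single tested leg is used alone
  expect_equal(score_star_excursion(rep(1, 8), NULL, 1), 1)
  expect_true(is.na(score_star_excursion(NULL, NULL, 1)))
  expect_error(score_star_excursion(rep(1, 5), NULL, 1),
               class = "mvh_input_error")
})

test_that("hurdle step takes the per-leg median then the leg mean", {
  expect_equal(score_hurdle_step(c(3, 3, 3), c(3, 3, 3)), 3)
  expect_equal(score_hurdle_step(c(2, 2, 3), c(3, 3, 3)), 2.5)
  # any pain grade (0) zeroes that leg
  expect_equal(score_hurdle_step(c(0, 3, 3), c(3, 3, 3)), 1.5)
  expect_equal(score_hurdle_step(c(0, 3, 3), c(3, 3, 3), pain_zero = FALSE), 3)
  expect_error(score_hurdle_step(c(2, 4, 3), c(3, 3, 3)),
               class = "mvh_input_error")
})

test_that("timed balance scores sum durations up to the caps", {
  expect_equal(score_timed_balance(c(30, 30), n_trials = 2), 60)
  expect_equal(score_timed_balance(c(12.5, 20), n_trials = 2), 32.5)
  expect_equal(score_timed_balance(rep(30, 6), n_trials = 6), 180)
  expect_equal(score_timed_balance(c(10, 20, 30), n_trials = 6), 60)
  expect_error(score_timed_balance(c(31, 20), n_trials = 2),
               class = "mvh_input_error")
  expect_error(score_timed_balance(c(10, 20), n_trials = 3),
               class = "mvh_input_error")
  # monotone non-decreasing in each trial duration
  expect_gte(score_timed_balance(c(20, 25), 2),
             score_timed_balance(c(15, 25), 2))
})

test_that("sway balance scores average per-trial ellipse areas", {
  same <- data.frame(x = rep(1, 10), y = rep(2, 10))
  expect_equal(score_balance_acc(list(same)), 0)
  withr::with_seed(71, {
    t1 <- data.frame(x = rnorm(200), y = rnorm(200))
    t2 <- data.frame(x = rnorm(200, 0, 2), y = rnorm(200, 0, 2))
    expect_equal(score_balance_acc(list(t1, t2)),
                 mean(c(ellipse_area_95(t1$x, t1$y),
                        ellipse_area_95(t2$x, t2$y))))
  })
  expect_true(is.na(score_balance_acc(list())))
})

test_that("assemble_test_scores populates all 15 fields and marks missing", {
  spec <- cohort_spec(n = 1, seed = 3)
  pr <- sample_profiles(spec)[1, ]
  tm <- simulate_test_measurements(pr, spec)
  scores <- assemble_test_scores(tm$trials, acc = tm$acc,
                                 leg_length = pr$leg_length,
                                 arm_length = pr$arm_length,
                                 participant_id = pr$participant_id)
  expect_named(scores, c("participant_id", functional_test_names()))
  expect_lte(scores$ctsib_t, 180)
  expect_lte(scores$romberg_t, 60)
  expect_true(scores$hurdle_step >= 0 && scores$hurdle_step <= 3)
  # determinism
  expect_identical(assemble_test_scores(tm$trials, acc = tm$acc,
                                        leg_length = pr$leg_length,
                                        arm_length = pr$arm_length,
                                        participant_id = pr$participant_id),
                   scores)
  # absent hop test propagates as missing, not zero
  trials2 <- tm$trials[tm$trials$test != "single_leg_hop", ]
  s2 <- assemble_test_scores(trials2, acc = tm$acc,
                             leg_length = pr$leg_length,
                             arm_length = pr$arm_length)
  expect_true(is.na(s2$single_leg_hop))
  expect_equal(s2$sit_reach, scores$sit_reach)
})

test_that("a not-attempted CKCUES row scores zero, an absent one NA", {
  trials <- data.frame(test = "ckcue", limb = "", trial = 1,
                       value = NA_real_, unit = "count")
  expect_identical(assemble_test_scores(trials)$ckcue, 0)
  none <- data.frame(test = character(), limb = character(),
                     trial = integer(), value = numeric(),
                     unit = character())
  expect_true(is.na(assemble_test_scores(none)$ckcue))
})
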
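# Synthetic cohort generator: reproducibility, class structure, noiseless
# templates, and impairment monotonicity.

test_that("profiles are reproducible and respect class proportions", {
  spec <- cohort_spec(n = 150, seed = 12)
  p1 <- sample_profiles(spec)
  p2 <- sample_profiles(spec)
  expect_identical(p1, p2)
  expect_true(all(abs(p1$theta - rowMeans(p1[, c("m", "s", "p")])) < 1e-8))
  # class-mean theta ordering athlete < healthy < impaired
  mu <- tapply(p1$theta, p1$class, mean)
  expect_lt(mu[["athlete"]], mu[["healthy"]])
  expect_lt(mu[["healthy"]], mu[["impaired"]])
  # degenerate proportions
  all_ath <- cohort_spec(n = 20, seed = 12,
                         proportions = c(healthy = 0, athlete = 1,
                                         impaired = 0))
  expect_true(all(sample_profiles(all_ath)$class == "athlete"))
  expect_error(cohort_spec(n = 5), class = "mvh_input_error")
})

test_that("an unimpaired noiseless participant matches the templates", {
  spec <- cohort_spec(n = 1, seed = 8, noise = FALSE)
  pr <- default_profile(0)
  slb <- extract_single_leg_balance(simulate_trace("single_leg_balance", pr, spec))
  expect_equal(slb$toe_taps, 0)
  expect_lt(slb$slb_trunk_var, 0.5)

  ohs <- extract_overhead_squat(simulate_trace("overhead_squat", pr, spec))
  expect_equal(ohs$ohs_pelvis_depth, (0.50 - 0.06) - (0.95 - 0.60),
               tolerance = 1e-9)
  fts <- extract_feet_together_squat(
    simulate_trace("feet_together_squat", pr, spec))
  expect_equal(fts$fts_pelvis_depth, (0.50 - 0.06) - (0.95 - 0.58),
               tolerance = 1e-9)
  expect_equal(fts$fts_knee_max, 135, tolerance = 1)

  # all timed balance trials at the cap
  tm <- simulate_test_measurements(impairment_profile(0, id_index = 1L), spec)
  expect_equal(tm$trials$value[tm$trials$test == "romberg_t"], c(30, 30))
  expect_equal(tm$trials$value[tm$trials$test == "ctsib_t"], rep(30, 6))
})

test_that("traces and scores are byte-identical across same-seed runs", {
  spec <- cohort_spec(n = 2, seed = 4242)
  pr <- sample_profiles(spec)[2, ]
  t1 <- simulate_trace("forward_lunge", pr, spec)
  t2 <- simulate_trace("forward_lunge", pr, spec)
  expect_identical(t1, t2)
  expect_identical(simulate_overall_scores(pr, spec),
                   simulate_overall_scores(pr, spec))
  tm1 <- simulate_test_measurements(pr, spec)
  tm2 <- simulate_test_measurements(pr, spec)
  expect_identical(tm1, tm2)
  # a different seed yields different data
  spec2 <- cohort_spec(n = 2, seed = 4243)
  expect_false(identical(simulate_trace("forward_lunge",
                                        sample_profiles(spec2)[2, ], spec2),
                         t1))
  expect_error(simulate_trace("forward_lunge",
                              list(theta = 1.2, m = 1.2, s = 0, p = 0,
                                   id_index = 1), spec),
               class = "mvh_input_error")
})

test_that("overall scores degrade with impairment and keep low trial CV", {
  spec <- cohort_spec(n = 1, seed = 9, noise = FALSE)
  expect_equal(simulate_overall_scores(default_profile(0), spec),
               rep(95, 3))
  expect_equal(simulate_overall_scores(default_profile(1), spec),
               rep(65, 3))
})

test_that("extracted metrics move monotonically with impairment", {
  # paired seeds: mean over seeds must order strictly with theta
  lo <- 0.1
  hi <- 0.8
  n_seeds <- 15
  vals <- function(theta, act, field, extractor) {
    vapply(seq_len(n_seeds), function(s) {
      spec <- cohort_spec(n = 1, seed = 3000 + s)
      extractor(simulate_trace(act, default_profile(theta), spec))[[field]]
    }, numeric(1))
  }
  inc <- list(  # increase with impairment
    c("single_leg_balance", "postural_sway"),
    c("single_leg_balance", "slb_trunk_var"),
    c("forward_lunge", "lunge_knee_ground"),
    c("overhead_squat", "ohs_elbow_var"))
  dec <- list(  # decrease with impairment
    c("overhead_squat", "ohs_knee_max"),
    c("overhead_squat", "ohs_pelvis_depth"),
    c("overhead_reach", "reach_shoulder_max"),
    c("feet_together_squat", "fts_pelvis_depth"))
  extr <- list(single_leg_balance = extract_single_leg_balance,
               forward_lunge = extract_forward_lunge,
               overhead_squat = extract_overhead_squat,
               overhead_reach = extract_overhead_reach,
               feet_together_squat = extract_feet_together_squat)
  for (spec_pair in inc) {
    act <- spec_pair[1]; field <- spec_pair[2]
    expect_gt(mean(vals(hi, act, field, extr[[act]])),
              mean(vals(lo, act, field, extr[[act]])),
              label = sprintf("mean %s at theta=%.1f", field, hi))
  }
  for (spec_pair in dec) {
    act <- spec_pair[1]; field <- spec_pair[2]
    expect_lt(mean(vals(hi, act, field, extr[[act]])),
              mean(vals(lo, act, field, extr[[act]])),
              label = sprintf("mean %s at theta=%.1f", field, hi))
  }
})

test_that("composite impairment proxies recover the latent parameter", {
  spec <- cohort_spec(n = 80, seed = 606)
  coh <- simulate_cohort(spec)
  metrics <- suppressWarnings(extract_cohort_metrics(coh$traces))
  df <- merge(coh$profiles, metrics, by = "participant_id")
  # a crude proxy: standardized fault metrics minus standardized ability ones
  zs <- function(v) (v - mean(v)) / sd(v)
  proxy <- zs(df$postural_sway) + zs(df$slb_trunk_var) +
    zs(df$lunge_knee_ground) - zs(df$ohs_knee_max) - zs(df$fts_pelvis_depth)
  fit <- lm(proxy ~ df$theta)
  expect_gt(coef(fit)[2], 0)
  expect_gt(cor(proxy, df$theta), 0.7)
})
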
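# Activity metric extraction: averaging contracts, sign conventions,
# bilateral symmetry, and generator ground truth.

test_that("single-leg-balance metrics average over the two stance phases", {
  withr::with_seed(61, {
    base <- data.frame(x = rnorm(600), y = rnorm(600))
    scaled <- base * sqrt(2)  # ellipse area exactly doubles
    tr <- make_slb_trace(base, scaled)
    m <- extract_single_leg_balance(tr)
    a_left <- ellipse_area_95(base$x, base$y)
    expect_equal(m$postural_sway, 1.5 * a_left, tolerance = 1e-12)
    expect_equal(m$toe_taps, 0)
  })
})

test_that("toe taps are attributed to the raised foot of each phase", {
  # two dips during left stance (raised right toe), one during right stance
  dip <- function(n_taps) {
    z <- rep(0.12, 600)
    for (k in seq_len(n_taps)) z[(k * 120):(k * 120 + 10)] <- -0.01
    z
  }
  tr <- make_slb_trace(data.frame(x = rnorm(600), y = rnorm(600)),
                       data.frame(x = rnorm(600), y = rnorm(600)),
                       toe_raised_left = dip(2), toe_raised_right = dip(1))
  m <- extract_single_leg_balance(tr)
  expect_equal(m$toe_taps, 1.5)  # mean of 2 and 1
})

test_that("missing balance phase annotations are an input error", {
  n <- 600
  ch <- list(trunk_lateral = rep(1, n), toe_z_L = rep(0.02, n),
             toe_z_R = rep(0.12, n), com_acc_x = rnorm(n),
             com_acc_y = rnorm(n))
  expect_error(
    motion_trace("single_leg_balance", 60, ch,
                 phases = data.frame(label = "balance_left", start = 1,
                                     end = 300)),
    class = "mvh_input_error")
})

test_that("lunge knee-ground distance averages per-repetition minima", {
  spec <- cohort_spec(n = 1, seed = 5)
  tr <- simulate_trace("forward_lunge", default_profile(0), spec)
  # overwrite knee channels with hand-placed per-rep minima {0.05 x3, 0.15 x3}
  w <- segment_repetitions(tr, expected = 6)
  kz <- rep(0.5, tr$n)
  mins <- c(0.05, 0.05, 0.05, 0.15, 0.15, 0.15)
  for (i in seq_len(6)) {
    mid <- (w$start[i] + w$end[i]) %/% 2
    idx <- (mid - 30):(mid + 30)
    u <- seq(0, 1, length.out = length(idx))
    kz[idx] <- 0.5 - (0.5 - mins[i]) * 0.5 * (1 - cos(2 * pi * u))
  }
  tr$channels$knee_z_L <- kz
  tr$channels$knee_z_R <- rep(0.5, tr$n)
  m <- extract_forward_lunge(tr)
  expect_equal(m$lunge_knee_ground, 0.10, tolerance = 1e-6)
})

test_that("squat depth keeps the min(knee) - min(pelvis) sign convention", {
  sq <- make_squat_trace(dips = 3, depth = 0.3)  # pelvis min 0.65, knee min 0.45
  m <- extract_feet_together_squat(sq$trace)
  expect_equal(m$fts_pelvis_depth, 0.45 - 0.65, tolerance = 1e-9)
  # pelvis below the knees: positive depth
  sq2 <- make_squat_trace(dips = 3, depth = 0.55)
  m2 <- extract_feet_together_squat(sq2$trace)
  expect_equal(m2$fts_pelvis_depth, 0.45 - 0.40, tolerance = 1e-9)
})

test_that("overhead squat extracts elbow variance over repetitions only", {
  sq <- make_squat_trace("overhead_squat", dips = 6, depth = 0.5)
  m <- extract_overhead_squat(sq$trace)
  expect_equal(m$ohs_elbow_var, 0)        # constant elbows
  expect_equal(m$ohs_trunk_max, 2)        # constant trunk deviation
  expect_gt(m$ohs_hip_max, 90)            # damped max of a 100-deg excursion
  expect_lte(m$ohs_hip_max, 100)
})

test_that("overhead reach averages bilaterally", {
  n <- 600
  tr <- motion_trace("overhead_reach", 60, list(
    shoulder_flexion_L = rep(160, n), shoulder_flexion_R = rep(170, n),
    elbow_flexion_L = rep(10, n), elbow_flexion_R = rep(20, n)))
  m <- extract_overhead_reach(tr)
  expect_equal(m$reach_shoulder_max, 165)
  expect_equal(m$reach_elbow_max, 15)
  expect_equal(m$reach_elbow_var, 0)
})

test_that("metrics are invariant under a left/right swap", {
  spec <- cohort_spec(n = 1, seed = 17)
  pr <- default_profile(0.5)
  for (act in assessment_activities()) {
    tr <- simulate_trace(act, pr, spec)
    sw <- tr
    nm <- names(sw$channels)
    swapped <- sub("_L$", "_TMP", nm)
    swapped <- sub("_R$", "_L", swapped)
    swapped <- sub("_TMP$", "_R", swapped)
    names(sw$channels) <- swapped
    if (nrow(sw$phases)) {
      sw$phases$label <- c(balance_left = "balance_right",
                           balance_right = "balance_left")[sw$phases$label]
    }
    f <- switch(act,
      single_leg_balance = extract_single_leg_balance,
      forward_lunge = extract_forward_lunge,
      overhead_squat = extract_overhead_squat,
      overhead_reach = extract_overhead_reach,
      feet_together_squat = extract_feet_together_squat)
    expect_equal(f(sw), f(tr), tolerance = 1e-12, info = act)
  }
})

test_that("extract_all fills missing activities with NA and is deterministic", {
  spec <- cohort_spec(n = 1, seed = 23)
  pr <- default_profile(0.3)
  traces <- setNames(
    lapply(assessment_activities(), simulate_trace, profile = pr, spec = spec),
    assessment_activities())
  full <- extract_all(traces, participant_id = "P001")
  expect_named(full, c("participant_id", activity_metric_names()))
  expect_true(all(!is.na(full[activity_metric_names()])))
  expect_identical(extract_all(traces, participant_id = "P001"), full)

  partial <- extract_all(traces[-1], participant_id = "P001")
  expect_true(all(is.na(partial[c("postural_sway", "toe_taps",
                                  "slb_trunk_max", "slb_trunk_var")])))
  expect_false(anyNA(partial[c("ohs_pelvis_depth", "fts_knee_max")]))
  expect_equal(attr(partial, "missing_activities"), "single_leg_balance")
})
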
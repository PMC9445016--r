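# Synthetic motion-capture cohort generator. Emulates the statistical
# structure the validation analysis assumes -- three ability classes, a
# latent impairment parameter degrading mobility/stability/posture features
# monotonically, trial-to-trial score noise -- so every pipeline stage is
# testable without human-subject data. It is a statistical stand-in, not a
# biomechanical simulation.

#' Cohort generation settings
#'
#' Defaults mirror the validation study's design: 150 participants split
#' 113 healthy / 17 athlete / 20 movement impaired, three assessment trials
#' per participant, 60 Hz motion capture.
#'
#' @param n Number of participants.
#' @param proportions Named class proportions (`healthy`, `athlete`,
#'   `impaired`), summing to 1.
#' @param seed Integer seed; mandatory, all generator randomness flows from
#'   it.
#' @param fs Motion-capture sampling rate (Hz).
#' @param n_trials Assessment trials per participant.
#' @param sigma_trial Trial-to-trial SD of the overall score (points).
#' @param noise Apply measurement noise (0.3 deg on angles, 3 mm on
#'   positions, 0.01 m/s^2 on accelerations) to generated channels?
#' @param beta_params Class-conditional Beta parameters for the latent
#'   impairment theta (illustrative defaults; athletes concentrate near 0,
#'   impaired participants near 0.67).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 150,
                        proportions = c(healthy = 113 / 150,
                                        athlete = 17 / 150,
                                        impaired = 20 / 150),
                        seed,
                        fs = 60,
                        n_trials = 3,
                        sigma_trial = 1.5,
                        noise = TRUE,
                        beta_params = list(athlete = c(2, 10),
                                           healthy = c(3, 6),
                                           impaired = c(8, 4))) {
  if (missing(seed) || is.null(seed)) {
    mvh_stop("cohort_spec requires an explicit seed; no unseeded generation")
  }
  if (abs(sum(proportions) - 1) > 1e-8) {
    mvh_stop("class proportions must sum to 1")
  }
  if (!all(sort(names(proportions)) == c("athlete", "healthy", "impaired"))) {
    mvh_stop("proportions must be named healthy, athlete, impaired")
  }
  structure(
    list(n = as.integer(n), proportions = proportions,
         seed = as.integer(seed), fs = fs, n_trials = as.integer(n_trials),
         sigma_trial = sigma_trial, noise = isTRUE(noise),
         beta_params = beta_params),
    class = "cohort_spec"
  )
}

#' Impairment profile for a single participant
#'
#' The latent impairment `theta` in \[0, 1\] (0 = unimpaired) with its
#' mobility/stability/posture subcomponents `m`, `s`, `p`, constrained to
#' `theta = mean(m, s, p)`.
#'
#' @param theta Latent impairment in \[0, 1\].
#' @param m,s,p Mobility, stability, posture deficits in \[0, 1\]; default to
#'   `theta`.
#' @param class_label Optional ability class.
#' @param id_index Participant index used for seed derivation.
#' @return One-row data frame.
#' @export
impairment_profile <- function(theta, m = theta, s = theta, p = theta,
                               class_label = NA_character_, id_index = 1L) {
  vals <- c(theta = theta, m = m, s = s, p = p)
  if (any(vals < 0) || any(vals > 1)) {
    mvh_stop("theta and its subcomponents must lie in [0, 1]")
  }
  if (abs(theta - mean(c(m, s, p))) > 1e-8) {
    mvh_stop("theta must equal the mean of m, s and p")
  }
  data.frame(participant_id = sprintf("P%03d", id_index),
             id_index = as.integer(id_index), class = class_label,
             theta = theta, m = m, s = s, p = p, stringsAsFactors = FALSE)
}

#' Sample impairment profiles for a cohort
#'
#' Classes are sampled from the spec's proportions; within class, theta
#' follows the class-conditional Beta distribution (athlete < healthy <
#' impaired stochastically). Subcomponents add a zero-sum perturbation
#' (SD 0.07) around theta so that `theta = mean(m, s, p)` holds exactly.
#' Limb lengths (leg ~ N(0.90, 0.04) m, arm ~ N(0.76, 0.04) m) are attached
#' for the normalised reach tests.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with one row per participant: `participant_id`,
#'   `id_index`, `class`, `theta`, `m`, `s`, `p`, `leg_length`,
#'   `arm_length`.
#' @export
sample_profiles <- function(spec) {
  withr::with_seed(derive_seed(spec$seed, 1), {
    classes <- sample(names(spec$proportions), spec$n, replace = TRUE,
                      prob = spec$proportions)
    rows <- lapply(seq_len(spec$n), function(i) {
      bp <- spec$beta_params[[classes[i]]]
      theta <- stats::rbeta(1, bp[1], bp[2])
      comp <- c(theta, theta, theta)
      for (try in 1:100) {
        d <- stats::rnorm(2, 0, 0.07)
        cand <- theta + c(d, -sum(d))
        if (all(cand >= 0 & cand <= 1)) {
          comp <- cand
          break
        }
      }
      impairment_profile(theta, comp[1], comp[2], comp[3],
                         class_label = classes[i], id_index = i)
    })
    profiles <- do.call(rbind, rows)
    profiles$leg_length <- stats::rnorm(spec$n, 0.90, 0.04)
    profiles$arm_length <- stats::rnorm(spec$n, 0.76, 0.04)
    profiles
  })
}

# half-cosine repetition dip with a flat hold at the bottom (the participant
# pauses at the deepest position); 0 at rest, 1 at the bottom plateau
rep_shape <- function(n, fs, centers_s, width_s, plateau = 0.85) {
  y <- numeric(n)
  for (c0 in centers_s) {
    i0 <- max(1L, as.integer(floor((c0 - width_s / 2) * fs)) + 1L)
    i1 <- min(n, as.integer(ceiling((c0 + width_s / 2) * fs)) + 1L)
    idx <- i0:i1
    u <- ((idx - 1) / fs - (c0 - width_s / 2)) / width_s
    raw <- 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))
    y[idx] <- pmax(y[idx], pmin(1, raw / plateau))
  }
  y
}

# mean-reverting (Ornstein-Uhlenbeck) noise; stationary SD `sd`,
# correlation time `tau` -- used for centre-of-mass acceleration so sway
# area is well defined and robust to the sampling rate
ou_series <- function(n, fs, sd, tau = 0.5) {
  a <- exp(-1 / (fs * tau))
  x <- stats::filter(stats::rnorm(n, 0, sd * sqrt(1 - a^2)), a,
                     method = "recursive", init = stats::rnorm(1, 0, sd))
  as.numeric(x)
}

add_noise <- function(x, sd, on) if (on && sd > 0) x + stats::rnorm(length(x), 0, sd) else x

# generator effect-size constants (study conditions; see the methods
# vignette for rationale)
GEN <- list(
  angle_sd = 0.3, pos_sd = 0.003, acc_sd = 0.01,
  acc_base = 0.3, acc_gain = 5,        # COM acceleration SD = base*(1+gain*s)
  trunk_base = 1.0, trunk_gain = 4,    # trunk amplitude = base*(1+gain*p)
  tap_rate = 3,                        # expected toe taps per phase = rate*s
  mob = function(m) 1 - 0.6 * m        # mobility scaling of depths/angles
)

sim_single_leg_balance <- function(profile, spec, noise) {
  fs <- spec$fs
  n_phase <- round(10 * fs)
  gap <- round(fs)
  n <- 2L * n_phase + gap
  t <- (seq_len(n) - 1) / fs
  A <- GEN$trunk_base * (1 + GEN$trunk_gain * profile$p)
  trunk <- A * (0.5 + 0.5 * sin(2 * pi * 0.3 * t))
  acc_sd <- GEN$acc_base * (1 + GEN$acc_gain * profile$s)
  left <- c(1L, n_phase)
  right <- c(n_phase + gap + 1L, n)

  toe <- function(other_phase) {
    z <- rep(0.02, n)
    idx <- other_phase[1]:other_phase[2]
    z[idx] <- 0.12
    k <- stats::rpois(1, GEN$tap_rate * profile$s)
    if (k > 0) {
      margin <- fs
      slots <- seq(other_phase[1] + margin, other_phase[2] - margin, by = fs)
      pick <- slots[sample.int(length(slots), min(k, length(slots)))]
      w <- round(0.4 * fs)
      for (c0 in pick) {
        j <- max(idx[1], c0 - w %/% 2):min(idx[length(idx)], c0 + w %/% 2)
        u <- (j - (c0 - w / 2)) / w
        z[j] <- 0.12 - 0.13 * 0.5 * (1 - cos(2 * pi * pmin(pmax(u, 0), 1)))
      }
    }
    z
  }
  # stance on the left foot raises the right toe, and vice versa
  toe_R <- toe(left)
  toe_L <- toe(right)

  motion_trace(
    activity = "single_leg_balance", fs = fs,
    channels = list(
      trunk_lateral = add_noise(trunk, GEN$angle_sd, noise),
      toe_z_L = add_noise(toe_L, GEN$pos_sd, noise),
      toe_z_R = add_noise(toe_R, GEN$pos_sd, noise),
      com_acc_x = add_noise(ou_series(n, fs, acc_sd), GEN$acc_sd, noise),
      com_acc_y = add_noise(ou_series(n, fs, acc_sd), GEN$acc_sd, noise)
    ),
    phases = data.frame(label = c("balance_left", "balance_right"),
                        start = c(left[1], right[1]),
                        end = c(left[2], right[2])),
    participant_id = profile$participant_id
  )
}

sim_forward_lunge <- function(profile, spec, noise) {
  fs <- spec$fs
  centers <- 2 + 3.5 * 0:5
  n <- round(22 * fs)
  min_z <- 0.01 + 0.15 * profile$m   # impaired knees stop short of the floor
  deep_R <- rep_shape(n, fs, centers[1:3], 2)
  deep_L <- rep_shape(n, fs, centers[4:6], 2)
  knee_R <- 0.50 - (0.50 - min_z) * deep_R - 0.15 * deep_L
  knee_L <- 0.50 - (0.50 - min_z) * deep_L - 0.15 * deep_R
  t <- (seq_len(n) - 1) / fs
  A <- GEN$trunk_base * (1 + GEN$trunk_gain * profile$p)
  trunk <- A * (0.5 + 0.5 * sin(2 * pi * 0.3 * t))
  motion_trace(
    activity = "forward_lunge", fs = fs,
    channels = list(
      trunk_lateral = add_noise(trunk, GEN$angle_sd, noise),
      knee_z_L = add_noise(knee_L, GEN$pos_sd, noise),
      knee_z_R = add_noise(knee_R, GEN$pos_sd, noise)
    ),
    participant_id = profile$participant_id
  )
}

sim_squat <- function(profile, spec, noise, activity) {
  fs <- spec$fs
  ohs <- activity == "overhead_squat"
  n_reps <- if (ohs) 6 else 3
  centers <- 2 + 3.5 * (0:(n_reps - 1))
  n <- round((max(centers) + 2.5) * fs)
  shape <- rep_shape(n, fs, centers, 2.5)
  mob <- GEN$mob(profile$m)
  pelvis <- 0.95 - (if (ohs) 0.60 else 0.58) * mob * shape
  hip <- (if (ohs) 120 else 115) * mob * shape
  kneef <- (if (ohs) 130 else 135) * mob * shape
  channels <- list(
    pelvis_z = add_noise(pelvis, GEN$pos_sd, noise),
    knee_z_L = add_noise(0.50 - 0.06 * shape, GEN$pos_sd, noise),
    knee_z_R = add_noise(0.50 - 0.06 * shape, GEN$pos_sd, noise),
    hip_flexion_L = add_noise(hip, GEN$angle_sd, noise),
    hip_flexion_R = add_noise(hip, GEN$angle_sd, noise),
    knee_flexion_L = add_noise(kneef, GEN$angle_sd, noise),
    knee_flexion_R = add_noise(kneef, GEN$angle_sd, noise)
  )
  if (ohs) {
    elbow <- 4 + 32 * profile$s * shape   # unsteady arms flex the elbows
    t <- (seq_len(n) - 1) / fs
    A <- GEN$trunk_base * (1 + GEN$trunk_gain * profile$p)
    channels$elbow_flexion_L <- add_noise(elbow, GEN$angle_sd, noise)
    channels$elbow_flexion_R <- add_noise(elbow, GEN$angle_sd, noise)
    channels$trunk_lateral <- add_noise(
      A * (0.5 + 0.5 * sin(2 * pi * 0.3 * t)), GEN$angle_sd, noise)
  }
  motion_trace(activity = activity, fs = fs, channels = channels,
               participant_id = profile$participant_id)
}

sim_overhead_reach <- function(profile, spec, noise) {
  fs <- spec$fs
  centers <- 2.5 + 4.5 * 0:2
  n <- round(14 * fs)
  shape <- rep_shape(n, fs, centers, 3)
  shoulder <- 172 * GEN$mob(profile$m) * shape
  elbow <- 4 + 32 * profile$s * shape
  motion_trace(
    activity = "overhead_reach", fs = fs,
    channels = list(
      shoulder_flexion_L = add_noise(shoulder, GEN$angle_sd, noise),
      shoulder_flexion_R = add_noise(shoulder, GEN$angle_sd, noise),
      elbow_flexion_L = add_noise(elbow, GEN$angle_sd, noise),
      elbow_flexion_R = add_noise(elbow, GEN$angle_sd, noise)
    ),
    participant_id = profile$participant_id
  )
}

#' Simulate one activity trace for a participant
#'
#' Deterministic given the cohort seed and the participant's index:
#' template kinematics for the activity with impairment effects layered on.
#' Squat/lunge depths and joint-angle amplitudes scale with `(1 - 0.6 m)`;
#' trunk deviation amplitude scales with `(1 + 4 p)`; centre-of-mass
#' acceleration is mean-reverting noise with SD scaled by `(1 + 5 s)`;
#' toe taps are injected as a Poisson count with rate `3 s` per balance
#' phase; Gaussian measurement noise (0.3 deg / 3 mm) is added to every
#' channel unless `spec$noise` is off. Phase and repetition structure
#' (10 s per balance side; 6, 6, 3, 3 repetitions for lunge, overhead
#' squat, reach and feet-together squat) is written into the annotations.
#'
#' @param activity One of [assessment_activities()].
#' @param profile One row of [sample_profiles()] (or
#'   [impairment_profile()]).
#' @param spec A [cohort_spec()].
#' @return A [motion_trace].
#' @export
simulate_trace <- function(activity, profile, spec) {
  profile <- as.list(profile)
  if (any(unlist(profile[c("theta", "m", "s", "p")]) < 0) ||
      any(unlist(profile[c("theta", "m", "s", "p")]) > 1)) {
    mvh_stop("impairment parameters must lie in [0, 1]")
  }
  act_index <- match(activity, assessment_activities())
  if (is.na(act_index)) {
    mvh_stop(sprintf("unknown activity '%s'", activity))
  }
  seed <- derive_seed(spec$seed, 131 * profile$id_index + 17 * act_index)
  withr::with_seed(seed, {
    switch(activity,
      single_leg_balance = sim_single_leg_balance(profile, spec, spec$noise),
      forward_lunge = sim_forward_lunge(profile, spec, spec$noise),
      overhead_squat = sim_squat(profile, spec, spec$noise, "overhead_squat"),
      overhead_reach = sim_overhead_reach(profile, spec, spec$noise),
      feet_together_squat = sim_squat(profile, spec, spec$noise,
                                      "feet_together_squat"))
  })
}

#' Simulate per-trial overall movement health scores
#'
#' Stands in for the proprietary 0-100 assessment score: each trial is
#' `clip(95 - 30 theta + e, 0, 100)` with `e ~ N(0, sigma_trial)`.
#' The default trial SD of 1.5 points puts the intrasubject coefficient of
#' variation in the low single-digit percent range typical of repeated
#' standardized assessments.
#'
#' @param profile One row of [sample_profiles()].
#' @param spec A [cohort_spec()].
#' @return Numeric vector of `spec$n_trials` scores.
#' @export
simulate_overall_scores <- function(profile, spec) {
  profile <- as.list(profile)
  seed <- derive_seed(spec$seed, 700000 + profile$id_index)
  withr::with_seed(seed, {
    base <- 95 - 30 * profile$theta
    e <- if (spec$noise) {
      stats::rnorm(spec$n_trials, 0, spec$sigma_trial)
    } else {
      numeric(spec$n_trials)
    }
    pmin(100, pmax(0, base + e))
  })
}

# per-test generative settings: latent mean as a linear function of the
# relevant subcomponent, Gaussian trial noise, and approximate completion
# rates (missing counts out of 150 participants)
TESTGEN <- list(
  sit_reach = list(miss = 1), rbb = list(miss = 2),
  single_leg_hop = list(miss = 17), functional_reach = list(miss = 1),
  romberg = list(miss = 1), star_excursion = list(miss = 1),
  y_balance = list(miss = 13), ckcue = list(miss = 20),
  plumb_line = list(miss = 0), ctsib = list(miss = 1),
  hurdle_step = list(miss = 3), uhbe = list(miss = 2)
)

#' Simulate raw functional-test trial measurements
#'
#' Each test's latent mean is a linear function of the relevant impairment
#' subcomponent with the hypothesised sign (e.g. sit-and-reach decreases
#' with the mobility deficit, plumb-line landmark scatter increases with the
#' posture deficit, timed balance decreases with the stability deficit and
#' is capped at 30 s per trial), plus Gaussian trial noise. Per-test
#' missingness approximates the study's completion counts and is more
#' likely at higher impairment; a skipped CKCUES test is recorded as
#' not attempted (scoring 0) rather than missing.
#'
#' @param profile One row of [sample_profiles()].
#' @param spec A [cohort_spec()].
#' @return List with `trials` (long data frame: `test`, `limb`, `trial`,
#'   `value`, `unit`) and `acc` (`ctsib`/`romberg` lists of per-trial
#'   planar acceleration samples).
#' @export
simulate_test_measurements <- function(profile, spec) {
  profile <- as.list(profile)
  m <- profile$m; s <- profile$s; p <- profile$p; th <- profile$theta
  leg_length <- profile$leg_length %||% 0.90
  arm_length <- profile$arm_length %||% 0.76
  noise <- spec$noise
  seed <- derive_seed(spec$seed, 800000 + profile$id_index)
  withr::with_seed(seed, {
    rows <- list()
    add <- function(test, limb, values, unit) {
      rows[[length(rows) + 1]] <<- data.frame(
        test = test, limb = limb, trial = seq_along(values), value = values,
        unit = unit, stringsAsFactors = FALSE)
    }
    ns <- function(k, sd) if (noise) stats::rnorm(k, 0, sd) else numeric(k)
    missing_test <- function(key) {
      stats::runif(1) < TESTGEN[[key]]$miss / 150 * (0.5 + 1.5 * th)
    }

    if (!missing_test("sit_reach")) {
      add("sit_reach", "", 16 - 11 * m + ns(3, 1.2), "in")
    }
    if (!missing_test("rbb")) {
      add("rbb_s", "L", 9 - 8 * m + ns(1, 0.8), "in")
      add("rbb_s", "R", 9 - 8 * m + ns(1, 0.8), "in")
      add("rbb_i", "L", 2.5 + 9 * m + ns(1, 0.8), "in")
      add("rbb_i", "R", 2.5 + 9 * m + ns(1, 0.8), "in")
    }
    if (!missing_test("single_leg_hop")) {
      add("single_leg_hop", "L", 62 - 38 * m + ns(1, 5), "in")
      add("single_leg_hop", "R", 62 - 38 * m + ns(1, 5), "in")
    }
    if (!missing_test("functional_reach")) {
      add("functional_reach", "", 12.5 - 5.5 * m + ns(6, 0.9), "in")
    }
    romberg_done <- !missing_test("romberg")
    if (romberg_done) {
      add("romberg_t", "", pmin(30, pmax(0, 33 - 21 * s + ns(2, 2.5))), "s")
    }
    if (!missing_test("star_excursion")) {
      leg_in <- leg_length / 0.0254
      add("star_excursion", "L", leg_in * (1.03 - 0.33 * m) + ns(8, 1.5), "in")
      add("star_excursion", "R", leg_in * (1.03 - 0.33 * m) + ns(8, 1.5), "in")
    }
    if (!missing_test("y_balance")) {
      arm_in <- arm_length / 0.0254
      add("y_balance", "L", arm_in * (0.97 - 0.30 * m) + ns(3, 1.2), "in")
      add("y_balance", "R", arm_in * (0.97 - 0.30 * m) + ns(3, 1.2), "in")
    }
    if (missing_test("ckcue")) {
      add("ckcue", "", rep(NA_real_, 1), "count")  # not attempted -> 0
    } else {
      add("ckcue", "", round(pmax(0, 25 - 14 * m + ns(3, 1.8))), "count")
    }
    add("plumb_line", "", abs(1.5 + ns(4, 0.4 + 2.2 * p)), "in")
    ctsib_done <- !missing_test("ctsib")
    if (ctsib_done) {
      add("ctsib_t", "", pmin(30, pmax(0, 34 - 23 * s + ns(6, 2.2))), "s")
    }
    if (!missing_test("hurdle_step")) {
      g <- function() pmin(3, pmax(0, round(3.3 - 2.6 * th + ns(3, 0.35))))
      add("hurdle_step", "L", g(), "grade")
      add("hurdle_step", "R", g(), "grade")
    }
    if (!missing_test("uhbe")) {
      add("uhbe", "", pmax(0, 46 - 33 * s + ns(2, 4)), "s")
    }

    sway_trials <- function(k) {
      sd <- 0.25 * (1 + 5 * s)
      lapply(seq_len(k), function(i) {
        data.frame(x = stats::rnorm(300, 0, sd), y = stats::rnorm(300, 0, sd))
      })
    }
    acc <- list(
      ctsib = if (ctsib_done) sway_trials(6) else list(),
      romberg = if (romberg_done) sway_trials(2) else list()
    )
    list(trials = do.call(rbind, rows), acc = acc)
  })
}

#' Simulate a full cohort in memory
#'
#' Profiles, five activity traces per participant, per-trial overall
#' scores, and raw functional-test measurements -- everything the pipeline
#' consumes -- all derived from the single cohort seed.
#'
#' @param spec A [cohort_spec()].
#' @return List of class `mvh_cohort`: `spec`, `profiles`, `traces` (list
#'   keyed by participant then activity), `scores` (long data frame), and
#'   `tests` (list keyed by participant: `trials`, `acc`).
#' @export
simulate_cohort <- function(spec) {
  profiles <- sample_profiles(spec)
  traces <- list()
  tests <- list()
  score_rows <- list()
  for (i in seq_len(nrow(profiles))) {
    pr <- profiles[i, ]
    id <- pr$participant_id
    traces[[id]] <- stats::setNames(
      lapply(assessment_activities(), simulate_trace, profile = pr,
             spec = spec),
      assessment_activities())
    tests[[id]] <- simulate_test_measurements(pr, spec)
    sc <- simulate_overall_scores(pr, spec)
    score_rows[[i]] <- data.frame(participant_id = id,
                                  trial = seq_along(sc), score = sc,
                                  stringsAsFactors = FALSE)
  }
  structure(
    list(spec = spec, profiles = profiles, traces = traces,
         scores = do.call(rbind, score_rows), tests = tests),
    class = "mvh_cohort"
  )
}
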
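# Scoring of the thirteen reference functional movement tests. Two balance
# tests (CTSIB and Sharpened Romberg) each yield a timed score and a
# sway-ellipse score, giving 15 scalar scores per participant.

#' Names of the functional-test scores
#'
#' The 15 reference-test scalars: plumb line (in^2), reach behind back
#' inferior/superior (in), CKCUES touch count, upper-extremity Y balance
#' (dimensionless), sit and reach (in), functional reach (in), star excursion
#' (dimensionless), hurdle step (0-3), unilateral hip bridge endurance (s),
#' single leg hop (in), CTSIB and Sharpened Romberg balance times (s) and
#' sway-ellipse areas ((m/s^2)^2).
#' @return Character vector of 15 score names.
#' @export
functional_test_names <- function() {
  c("plumb_line", "rbb_i", "rbb_s", "ckcue", "y_balance", "sit_reach",
    "functional_reach", "star_excursion", "hurdle_step", "uhbe",
    "single_leg_hop", "ctsib_t", "ctsib_acc", "romberg_t", "romberg_acc")
}

#' Hypothesised correlation directions for the functional tests
#'
#' Direction each reference test is expected to correlate with the overall
#' movement health score: reach distances, touch counts, grades and balance
#' times increase with better movement health (`"+"`); posture deviation
#' variance, the inferior reach-behind-back distance, and the sway-ellipse
#' scores increase with worse movement health (`"-"`).
#' @return Named character vector over [functional_test_names()].
#' @export
test_hypotheses <- function() {
  c(plumb_line = "-", rbb_i = "-", rbb_s = "+", ckcue = "+", y_balance = "+",
    sit_reach = "+", functional_reach = "+", star_excursion = "+",
    hurdle_step = "+", uhbe = "+", single_leg_hop = "+", ctsib_t = "+",
    ctsib_acc = "-", romberg_t = "+", romberg_acc = "-")
}

#' Mean-over-trials score
#'
#' The aggregation rule shared by most distance/time tests: the arithmetic
#' mean over all provided trial (or limb) values. An empty input is a
#' missing score (`NA`), never a zero: participants completed varying
#' subsets of the tests.
#'
#' @param values Numeric trial values (any unit); `NA`s are dropped.
#' @return Mean of the values, or `NA` if none were provided.
#' @export
score_bilateral_mean <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(NA_real_)
  }
  mvh_check_numeric(values, "values")
  mean(values)
}

#' Score the closed kinetic chain upper-extremity stability test
#'
#' Mean hand-touch count over up to three 15 s trials. A participant who was
#' not able to attempt the test scores 0 (the one test where non-completion
#' is an explicit zero rather than a missing value).
#'
#' @param counts Touch counts (0-3 trials).
#' @param attempted Was the test attempted?
#' @return Mean count, 0 if not attempted, `NA` if attempted but no counts
#'   recorded.
#' @export
score_ckcue <- function(counts, attempted = TRUE) {
  if (!attempted) {
    return(0)
  }
  if (length(counts) > 3) {
    mvh_stop("at most three CKCUES trials are scored")
  }
  score_bilateral_mean(counts)
}

#' Score the plumb-line posture test
#'
#' Sample variance (denominator n - 1) of the landmark-to-line distances
#' measured at the shoulder, hip, knee and ankle. Invariant to a common
#' shift of all four distances.
#'
#' @param distances Exactly four landmark distances (in).
#' @return Variance of the four distances (in^2).
#' @export
score_plumb_line <- function(distances) {
  distances <- distances[!is.na(distances)]
  if (length(distances) == 0) {
    return(NA_real_)
  }
  if (length(distances) != 4) {
    mvh_stop("plumb line requires distances at exactly 4 landmarks")
  }
  mvh_check_numeric(distances, "distances")
  stats::var(distances)
}

#' Score the star excursion balance test
#'
#' Per leg, the mean reach distance over the eight directions normalised by
#' leg length; the final score is the mean over the legs provided. The score
#' is dimensionless and invariant to a common unit change of reaches and leg
#' length.
#'
#' @param reaches_left,reaches_right Eight reach distances per leg (either
#'   may be `NULL` for a leg not tested).
#' @param leg_length Leg length in the same unit as the reaches (> 0).
#' @return Dimensionless composite, or `NA` if no leg was tested.
#' @export
score_star_excursion <- function(reaches_left, reaches_right, leg_length) {
  score_normalized_reach(list(reaches_left, reaches_right), leg_length,
                         n_directions = 8, what = "star excursion")
}

#' Score the upper-extremity Y balance test
#'
#' Per arm, the mean reach length over the three directions (medial,
#' inferolateral, superolateral) normalised by arm length; final score is
#' the mean over the arms provided.
#'
#' @param reaches_left,reaches_right Three reach lengths per arm.
#' @param arm_length Arm length in the same unit as the reaches (> 0).
#' @return Dimensionless composite, or `NA` if no arm was tested.
#' @export
score_y_balance_upper <- function(reaches_left, reaches_right, arm_length) {
  score_normalized_reach(list(reaches_left, reaches_right), arm_length,
                         n_directions = 3, what = "Y balance")
}

score_normalized_reach <- function(sides, limb_length, n_directions, what) {
  sides <- Filter(function(s) !is.null(s) && !all(is.na(s)), sides)
  if (length(sides) == 0) {
    return(NA_real_)
  }
  if (is.na(limb_length) || !is.numeric(limb_length) || limb_length <= 0) {
    mvh_stop(sprintf("%s requires a positive limb length", what))
  }
  per_side <- vapply(sides, function(s) {
    s <- s[!is.na(s)]
    if (length(s) != n_directions) {
      mvh_stop(sprintf("%s requires %d reach distances per limb",
                       what, n_directions))
    }
    mvh_check_numeric(s, what)
    mean(s) / limb_length
  }, numeric(1))
  mean(per_side)
}

#' Score the hurdle step test
#'
#' Each leg performs three steps graded 0-3 by a clinician (0 = pain,
#' 1 = failure, 2 = compromised, 3 = clean). The three grades are aggregated
#' into one 0-3 score per leg; the final score is the mean of the two leg
#' aggregates. The default per-leg rule is the median of the three grades,
#' with any grade of 0 (pain) forcing that leg's aggregate to 0.
#'
#' @param grades_left,grades_right Grades in `{0, 1, 2, 3}`, up to three per
#'   leg (`NULL` for an untested leg).
#' @param aggregate Per-leg aggregation function (default median).
#' @param pain_zero Should any grade 0 force the leg aggregate to 0?
#' @return Final score in `[0, 3]`, or `NA` if neither leg was tested.
#' @export
score_hurdle_step <- function(grades_left, grades_right,
                              aggregate = stats::median, pain_zero = TRUE) {
  per_leg <- function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    if (!all(g %in% 0:3)) {
      mvh_stop("hurdle step grades must be 0, 1, 2 or 3")
    }
    if (pain_zero && any(g == 0)) return(0)
    aggregate(g)
  }
  legs <- c(per_leg(grades_left), per_leg(grades_right))
  legs <- legs[!is.na(legs)]
  if (length(legs) == 0) {
    return(NA_real_)
  }
  mean(legs)
}

#' Score a timed balance test
#'
#' Sum of the per-trial stance durations, clipped to the test's total cap:
#' 60 s over the two Sharpened Romberg trials, 180 s over the six CTSIB
#' conditions. Each trial is itself capped at 30 s.
#'
#' @param durations Stance durations in seconds, each in `[0, cap_per_trial]`.
#' @param n_trials Number of trials defining the test (2 or 6).
#' @param cap_per_trial Per-trial cap (s), default 30.
#' @param total_cap Total cap (s), default `n_trials * cap_per_trial`.
#' @return Total balance time (s), or `NA` if no durations were recorded.
#' @export
score_timed_balance <- function(durations, n_trials,
                                cap_per_trial = 30,
                                total_cap = n_trials * cap_per_trial) {
  if (!n_trials %in% c(2, 6)) {
    mvh_stop("n_trials must be 2 (Sharpened Romberg) or 6 (CTSIB)")
  }
  durations <- durations[!is.na(durations)]
  if (length(durations) == 0) {
    return(NA_real_)
  }
  mvh_check_numeric(durations, "durations")
  if (length(durations) > n_trials) {
    mvh_stop(sprintf("more than %d trial durations supplied", n_trials))
  }
  if (any(durations < 0) || any(durations > cap_per_trial + 1e-9)) {
    mvh_stop(sprintf("trial durations must lie in [0, %g] s", cap_per_trial))
  }
  min(sum(durations), total_cap)
}

#' Score a sway-ellipse balance test
#'
#' Mean over trials of the 95% prediction-ellipse area of the
#' centre-of-mass acceleration recorded during each stance trial
#' (see [ellipse_area_95()]). Used for CTSIB (acc) and Sharpened
#' Romberg (acc).
#'
#' @param trials List of per-trial planar samples; each element a matrix or
#'   data frame with columns `x` and `y` (m/s^2), at least 3 rows.
#' @return Mean ellipse area ((m/s^2)^2), or `NA` for an empty list.
#' @export
score_balance_acc <- function(trials) {
  if (length(trials) == 0) {
    return(NA_real_)
  }
  areas <- vapply(trials, function(tr) {
    tr <- as.data.frame(tr)
    ellipse_area_95(tr$x, tr$y)
  }, numeric(1))
  mean(areas)
}

#' Assemble the 15 functional-test scores for one participant
#'
#' Applies each test's aggregation rule to the raw trial measurements of one
#' participant. `trials` is long-format: one row per trial with columns
#' `test`, `limb` (`"L"`, `"R"`, or `""`), `trial`, `value`. Tests with no
#' rows score `NA` (missing), except CKCUES, where a row with `NA` value
#' marks a not-attempted test and scores 0.
#'
#' @param trials Data frame of raw trial measurements for one participant.
#' @param acc Named list of sway-trial samples: `ctsib` and `romberg`, each
#'   a list of planar sample sets (see [score_balance_acc()]).
#' @param leg_length,arm_length Limb lengths in the same unit as the star
#'   excursion / Y balance reaches.
#' @param participant_id Optional identifier for the output row.
#' @return One-row data frame with `participant_id` plus the columns of
#'   [functional_test_names()].
#' @export
assemble_test_scores <- function(trials, acc = list(), leg_length = NA,
                                 arm_length = NA, participant_id = NULL) {
  trials <- as.data.frame(trials)
  val <- function(test, limb = NULL) {
    r <- trials[trials$test == test, , drop = FALSE]
    if (!is.null(limb)) r <- r[r$limb == limb, , drop = FALSE]
    r$value
  }
  has <- function(test) any(trials$test == test)

  ckcue_vals <- val("ckcue")
  ckcue <- if (!has("ckcue")) {
    NA_real_
  } else if (all(is.na(ckcue_vals))) {
    score_ckcue(numeric(0), attempted = FALSE)
  } else {
    score_ckcue(ckcue_vals[!is.na(ckcue_vals)])
  }

  side_or_null <- function(test, limb) {
    v <- val(test, limb)
    if (length(v) == 0) NULL else v
  }

  out <- data.frame(
    participant_id = participant_id %||% NA_character_,
    plumb_line = score_plumb_line(val("plumb_line")),
    rbb_i = score_bilateral_mean(val("rbb_i")),
    rbb_s = score_bilateral_mean(val("rbb_s")),
    ckcue = ckcue,
    y_balance = if (has("y_balance")) {
      score_y_balance_upper(side_or_null("y_balance", "L"),
                            side_or_null("y_balance", "R"), arm_length)
    } else NA_real_,
    sit_reach = score_bilateral_mean(val("sit_reach")),
    functional_reach = score_bilateral_mean(val("functional_reach")),
    star_excursion = if (has("star_excursion")) {
      score_star_excursion(side_or_null("star_excursion", "L"),
                           side_or_null("star_excursion", "R"), leg_length)
    } else NA_real_,
    hurdle_step = if (has("hurdle_step")) {
      score_hurdle_step(side_or_null("hurdle_step", "L"),
                        side_or_null("hurdle_step", "R"))
    } else NA_real_,
    uhbe = score_bilateral_mean(val("uhbe")),
    single_leg_hop = score_bilateral_mean(val("single_leg_hop")),
    ctsib_t = if (has("ctsib_t")) {
      score_timed_balance(val("ctsib_t"), n_trials = 6)
    } else NA_real_,
    ctsib_acc = score_balance_acc(acc$ctsib),
    romberg_t = if (has("romberg_t")) {
      score_timed_balance(val("romberg_t"), n_trials = 2)
    } else NA_real_,
    romberg_acc = score_balance_acc(acc$romberg),
    stringsAsFactors = FALSE
  )
  out
}
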
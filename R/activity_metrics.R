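# Per-activity metric extraction: the 18 sensor metrics summarising
# stability, mobility and posture across the five assessment activities.

#' Names of the sensor-derived activity metrics
#'
#' One name per extracted metric, grouped by activity prefix: `postural_sway`
#' ((m/s^2)^2), `toe_taps` (count, averaged over both stance phases),
#' trunk maxima (deg) and variances (deg^2), knee-ground distance (m),
#' pelvis depths below the knees (m), and outlier-damped joint-angle maxima
#' (deg).
#' @return Character vector of 18 metric names.
#' @export
activity_metric_names <- function() {
  c("postural_sway", "toe_taps", "slb_trunk_max", "slb_trunk_var",
    "lunge_knee_ground", "lunge_trunk_max", "lunge_trunk_var",
    "ohs_pelvis_depth", "ohs_hip_max", "ohs_knee_max", "ohs_trunk_max",
    "ohs_elbow_var",
    "reach_shoulder_max", "reach_elbow_max", "reach_elbow_var",
    "fts_pelvis_depth", "fts_hip_max", "fts_knee_max")
}

#' Hypothesised correlation directions for the sensor metrics
#'
#' Direction each metric is expected to correlate with the overall movement
#' health score for the score to be valid: deeper squats and larger joint
#' range of motion indicate better movement health (`"+"`); sway, toe taps,
#' trunk deviation/variance, knee-ground distance and elbow flexion
#' metrics indicate faults (`"-"`).
#' @return Named character vector (`"+"` or `"-"`) over
#'   [activity_metric_names()].
#' @export
metric_hypotheses <- function() {
  c(postural_sway = "-", toe_taps = "-", slb_trunk_max = "-",
    slb_trunk_var = "-", lunge_knee_ground = "-", lunge_trunk_max = "-",
    lunge_trunk_var = "-", ohs_pelvis_depth = "+", ohs_hip_max = "+",
    ohs_knee_max = "+", ohs_trunk_max = "-", ohs_elbow_var = "-",
    reach_shoulder_max = "+", reach_elbow_max = "-", reach_elbow_var = "-",
    fts_pelvis_depth = "+", fts_hip_max = "+", fts_knee_max = "+")
}

check_activity <- function(trace, activity) {
  if (!inherits(trace, "motion_trace")) {
    mvh_stop("trace must be a motion_trace object")
  }
  if (trace$activity != activity) {
    mvh_stop(sprintf("expected a %s trace, got %s", activity, trace$activity))
  }
}

bilateral_mean <- function(left, right) (left + right) / 2

#' Extract single-leg balance metrics
#'
#' Computes postural sway (95% prediction-ellipse area of transverse-plane
#' centre-of-mass acceleration), toe-tap count, and the maximum and variance
#' of the lateral trunk angle, separately during the left- and right-stance
#' balance phases, then averages each metric over the two feet. During the
#' `balance_left` phase (stance on the left foot) the raised toe is the
#' right one, and vice versa.
#'
#' @param trace A `single_leg_balance` [motion_trace] with `balance_left`
#'   and `balance_right` phase annotations.
#' @param hysteresis Toe-tap dead band (m), see [count_toe_taps()].
#' @return Named list: `postural_sway`, `toe_taps`, `slb_trunk_max`,
#'   `slb_trunk_var`.
#' @export
extract_single_leg_balance <- function(trace, hysteresis = 0.005) {
  check_activity(trace, "single_leg_balance")
  per_phase <- lapply(c("balance_left", "balance_right"), function(lab) {
    w <- trace$phases[trace$phases$label == lab, , drop = FALSE]
    if (nrow(w) != 1) {
      mvh_stop(sprintf("missing phase annotation '%s'", lab))
    }
    raised <- if (lab == "balance_left") "toe_z_R" else "toe_z_L"
    plant <- if (lab == "balance_left") "toe_z_L" else "toe_z_R"
    trunk <- phase_slice(trace, "trunk_lateral", w$start, w$end)
    list(
      sway = ellipse_area_95(phase_slice(trace, "com_acc_x", w$start, w$end),
                             phase_slice(trace, "com_acc_y", w$start, w$end)),
      taps = count_toe_taps(phase_slice(trace, raised, w$start, w$end),
                            phase_slice(trace, plant, w$start, w$end),
                            hysteresis = hysteresis),
      trunk_max = max_trunk_deviation(trunk),
      trunk_var = angle_variance(trunk)
    )
  })
  list(
    postural_sway = mean(vapply(per_phase, `[[`, numeric(1), "sway")),
    toe_taps = mean(vapply(per_phase, function(p) as.numeric(p$taps), numeric(1))),
    slb_trunk_max = mean(vapply(per_phase, `[[`, numeric(1), "trunk_max")),
    slb_trunk_var = mean(vapply(per_phase, `[[`, numeric(1), "trunk_var"))
  )
}

#' Extract forward-lunge metrics
#'
#' The knee-ground distance is the minimum height of the lunging (lower)
#' knee within each repetition, averaged over the repetitions (nominally six,
#' three per leg). Trunk maximum and variance span the whole activity.
#'
#' @param trace A `forward_lunge` [motion_trace].
#' @return Named list: `lunge_knee_ground`, `lunge_trunk_max`,
#'   `lunge_trunk_var`.
#' @export
extract_forward_lunge <- function(trace) {
  check_activity(trace, "forward_lunge")
  reps <- segment_repetitions(trace, expected = 6)
  if (nrow(reps) < 2) {
    mvh_stop(sprintf(
      "only %d repetition(s) detected in forward lunge; need at least 2",
      nrow(reps)), class = "mvh_extraction_error")
  }
  lower_knee <- pmin(trace$channels$knee_z_L, trace$channels$knee_z_R)
  per_rep <- mapply(function(s, e) min(lower_knee[s:e]), reps$start, reps$end)
  trunk <- trace$channels$trunk_lateral
  list(
    lunge_knee_ground = mean(per_rep),
    lunge_trunk_max = max_trunk_deviation(trunk),
    lunge_trunk_var = angle_variance(trunk)
  )
}

squat_metrics <- function(trace, expected_reps) {
  reps <- segment_repetitions(trace, expected = expected_reps)
  depth_per_rep <- mapply(function(s, e) {
    knee_min <- bilateral_mean(min(trace$channels$knee_z_L[s:e]),
                               min(trace$channels$knee_z_R[s:e]))
    knee_min - min(trace$channels$pelvis_z[s:e])  # > 0: pelvis below knees
  }, reps$start, reps$end)
  list(
    reps = reps,
    pelvis_depth = mean(depth_per_rep),
    hip_max = bilateral_mean(robust_extremum(trace$channels$hip_flexion_L, "max"),
                             robust_extremum(trace$channels$hip_flexion_R, "max")),
    knee_max = bilateral_mean(robust_extremum(trace$channels$knee_flexion_L, "max"),
                              robust_extremum(trace$channels$knee_flexion_R, "max"))
  )
}

#' Extract overhead-squat metrics
#'
#' Pelvis depth below the knees is `min(knee_z) - min(pelvis_z)` per
#' repetition (positive when the pelvis descends below the knees), averaged
#' over repetitions. Hip and knee flexion maxima are outlier-damped maxima
#' over the whole activity, averaged bilaterally; the trunk maximum spans the
#' whole activity; elbow flexion variance is computed over the repetition
#' spans only, averaged bilaterally.
#'
#' @param trace An `overhead_squat` [motion_trace].
#' @return Named list: `ohs_pelvis_depth`, `ohs_hip_max`, `ohs_knee_max`,
#'   `ohs_trunk_max`, `ohs_elbow_var`.
#' @export
extract_overhead_squat <- function(trace) {
  check_activity(trace, "overhead_squat")
  sq <- squat_metrics(trace, expected_reps = 6)
  rep_idx <- unlist(mapply(seq, sq$reps$start, sq$reps$end, SIMPLIFY = FALSE))
  list(
    ohs_pelvis_depth = sq$pelvis_depth,
    ohs_hip_max = sq$hip_max,
    ohs_knee_max = sq$knee_max,
    ohs_trunk_max = max_trunk_deviation(trace$channels$trunk_lateral),
    ohs_elbow_var = bilateral_mean(
      angle_variance(trace$channels$elbow_flexion_L[rep_idx]),
      angle_variance(trace$channels$elbow_flexion_R[rep_idx]))
  )
}

#' Extract overhead-reach metrics
#'
#' Shoulder range of motion is the outlier-damped maximum flexion angle and
#' the elbow metrics quantify arm steadiness (the arms should stay straight);
#' all are averaged bilaterally and computed over the whole activity span.
#'
#' @param trace An `overhead_reach` [motion_trace].
#' @return Named list: `reach_shoulder_max`, `reach_elbow_max`,
#'   `reach_elbow_var`.
#' @export
extract_overhead_reach <- function(trace) {
  check_activity(trace, "overhead_reach")
  list(
    reach_shoulder_max = bilateral_mean(
      robust_extremum(trace$channels$shoulder_flexion_L, "max"),
      robust_extremum(trace$channels$shoulder_flexion_R, "max")),
    reach_elbow_max = bilateral_mean(
      robust_extremum(trace$channels$elbow_flexion_L, "max"),
      robust_extremum(trace$channels$elbow_flexion_R, "max")),
    reach_elbow_var = bilateral_mean(
      angle_variance(trace$channels$elbow_flexion_L),
      angle_variance(trace$channels$elbow_flexion_R))
  )
}

#' Extract feet-together-squat metrics
#'
#' Same depth and joint-angle contracts as [extract_overhead_squat()],
#' restricted to pelvis depth and the hip/knee flexion maxima (nominally
#' three repetitions).
#'
#' @param trace A `feet_together_squat` [motion_trace].
#' @return Named list: `fts_pelvis_depth`, `fts_hip_max`, `fts_knee_max`.
#' @export
extract_feet_together_squat <- function(trace) {
  check_activity(trace, "feet_together_squat")
  sq <- squat_metrics(trace, expected_reps = 3)
  list(
    fts_pelvis_depth = sq$pelvis_depth,
    fts_hip_max = sq$hip_max,
    fts_knee_max = sq$knee_max
  )
}

#' Extract the full activity metric set for one participant
#'
#' Applies the five per-activity extractors and unites their outputs in one
#' row. Activities whose trace is absent contribute `NA` metrics (recorded in
#' the `"missing_activities"` attribute) rather than failing: participants
#' unable to perform an activity stay in the analysis.
#'
#' @param traces Named list of [motion_trace] objects, keyed by activity.
#' @param participant_id Optional identifier; taken from the first trace if
#'   absent.
#' @return One-row data frame with `participant_id` plus the columns of
#'   [activity_metric_names()]. Angle maxima outside the physiologic
#'   0-220 deg band raise a validation warning.
#' @export
extract_all <- function(traces, participant_id = NULL) {
  if (is.null(participant_id) && length(traces)) {
    participant_id <- traces[[1]]$participant_id
  }
  out <- stats::setNames(as.list(rep(NA_real_, length(activity_metric_names()))),
                         activity_metric_names())
  extractors <- list(
    single_leg_balance = extract_single_leg_balance,
    forward_lunge = extract_forward_lunge,
    overhead_squat = extract_overhead_squat,
    overhead_reach = extract_overhead_reach,
    feet_together_squat = extract_feet_together_squat
  )
  missing_acts <- character()
  for (act in assessment_activities()) {
    if (is.null(traces[[act]])) {
      missing_acts <- c(missing_acts, act)
      next
    }
    vals <- extractors[[act]](traces[[act]])
    out[names(vals)] <- vals
  }
  angles <- unlist(out[grepl("max$", names(out)) & !grepl("trunk", names(out))])
  angles <- angles[is.finite(angles)]
  if (length(angles) && (any(angles < 0) || any(angles > 220))) {
    warning("joint-angle maximum outside the physiologic 0-220 deg band",
            call. = FALSE)
  }
  res <- cbind(data.frame(participant_id = participant_id %||% NA_character_,
                          stringsAsFactors = FALSE),
               as.data.frame(out))
  attr(res, "missing_activities") <- missing_acts
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
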
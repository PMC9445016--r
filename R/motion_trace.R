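# The motion_trace container: annotated multichannel kinematic time series
# for one participant performing one assessment activity.

#' Assessment activities
#'
#' The five activities of the movement-health assessment, in protocol order.
#' @return Character vector of activity identifiers.
#' @export
assessment_activities <- function() {
  c("single_leg_balance", "forward_lunge", "overhead_squat",
    "overhead_reach", "feet_together_squat")
}

# Channels each activity's extractor needs. Extra channels are allowed.
required_channels <- function(activity) {
  switch(activity,
    single_leg_balance = c("trunk_lateral", "toe_z_L", "toe_z_R",
                           "com_acc_x", "com_acc_y"),
    forward_lunge = c("trunk_lateral", "knee_z_L", "knee_z_R"),
    overhead_squat = c("pelvis_z", "knee_z_L", "knee_z_R",
                       "hip_flexion_L", "hip_flexion_R",
                       "knee_flexion_L", "knee_flexion_R",
                       "elbow_flexion_L", "elbow_flexion_R", "trunk_lateral"),
    overhead_reach = c("shoulder_flexion_L", "shoulder_flexion_R",
                       "elbow_flexion_L", "elbow_flexion_R"),
    feet_together_squat = c("pelvis_z", "knee_z_L", "knee_z_R",
                            "hip_flexion_L", "hip_flexion_R",
                            "knee_flexion_L", "knee_flexion_R"),
    mvh_stop(sprintf("unknown activity '%s'", activity))
  )
}

# Linear interpolation of short sensor dropouts; long gaps are rejected.
fill_gaps <- function(x, fs, max_gap_s = 0.5, channel = "channel") {
  if (!anyNA(x)) {
    return(list(values = x, n_filled = 0L))
  }
  r <- rle(is.na(x))
  if (all(r$values)) {
    mvh_stop(sprintf("channel '%s' is entirely missing", channel))
  }
  if (max(r$lengths[r$values]) > max_gap_s * fs) {
    mvh_stop(sprintf(
      "channel '%s' has a dropout longer than %.2f s; trace rejected",
      channel, max_gap_s))
  }
  idx <- which(!is.na(x))
  filled <- stats::approx(idx, x[idx], xout = seq_along(x), rule = 2)$y
  list(values = filled, n_filled = sum(is.na(x)))
}

#' Construct an annotated motion trace
#'
#' Bundles the named kinematic channels of one activity recording with its
#' sampling rate and phase annotations, validating the channel set required
#' by the activity's metric extractor. Angle channels are in degrees,
#' position channels in metres (Z up-positive), centre-of-mass acceleration
#' in m/s^2 in the transverse (X-Y) plane.
#'
#' Sensor dropouts shorter than `max_gap_s` are linearly interpolated (the
#' number of filled samples is recorded in the `"n_filled"` attribute);
#' longer dropouts reject the trace.
#'
#' @param activity One of [assessment_activities()].
#' @param fs Sampling rate in Hz (> 0).
#' @param channels Named list (or data frame) of equal-length numeric
#'   vectors; must include the required channels for the activity.
#' @param phases Optional data frame with columns `label`, `start`, `end`
#'   (1-based sample indices, inclusive). Single-leg balance traces must
#'   annotate `balance_left` and `balance_right` stance phases.
#' @param participant_id Optional identifier carried through to outputs.
#' @param max_gap_s Longest sensor dropout (s) that may be interpolated.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(activity, fs, channels, phases = NULL,
                         participant_id = NULL, max_gap_s = 0.5) {
  if (!is.character(activity) || length(activity) != 1 ||
      !activity %in% assessment_activities()) {
    mvh_stop(sprintf(
      "activity must be one of: %s",
      paste(assessment_activities(), collapse = ", ")))
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    mvh_stop("fs must be a single positive sampling rate in Hz")
  }
  channels <- as.list(channels)
  if (is.null(names(channels)) || any(names(channels) == "")) {
    mvh_stop("channels must be a named list of numeric vectors")
  }
  need <- required_channels(activity)
  missing_ch <- setdiff(need, names(channels))
  if (length(missing_ch)) {
    mvh_stop(sprintf("activity '%s' is missing required channel(s): %s",
                     activity, paste(missing_ch, collapse = ", ")))
  }
  lens <- vapply(channels, length, integer(1))
  if (length(unique(lens)) != 1) {
    mvh_stop("all channels must have equal length")
  }
  n <- lens[[1]]
  if (n < 1) {
    mvh_stop("channels must contain at least one sample")
  }
  n_filled <- 0L
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch)) {
      mvh_stop(sprintf("channel '%s' is not numeric", nm))
    }
    g <- fill_gaps(as.double(ch), fs, max_gap_s, channel = nm)
    channels[[nm]] <- g$values
    n_filled <- n_filled + g$n_filled
  }
  phases <- validate_phases(phases, n, activity)
  structure(
    list(activity = activity, fs = fs, n = n, channels = channels,
         phases = phases, participant_id = participant_id),
    n_filled = n_filled,
    class = "motion_trace"
  )
}

validate_phases <- function(phases, n, activity) {
  if (is.null(phases)) {
    if (activity == "single_leg_balance") {
      mvh_stop("single_leg_balance traces require balance_left/balance_right phase annotations")
    }
    return(data.frame(label = character(), start = integer(), end = integer()))
  }
  phases <- as.data.frame(phases)
  if (!all(c("label", "start", "end") %in% names(phases))) {
    mvh_stop("phases must have columns label, start, end")
  }
  phases$start <- as.integer(phases$start)
  phases$end <- as.integer(phases$end)
  if (any(is.na(phases$start)) || any(is.na(phases$end))) {
    mvh_stop("phase start/end must be integer sample indices")
  }
  bad <- phases$start < 1 | phases$end > n | phases$start > phases$end
  if (any(bad)) {
    mvh_stop(sprintf("phase '%s' is out of bounds for a trace of %d samples",
                     phases$label[which(bad)[1]], n))
  }
  for (lab in unique(phases$label)) {
    w <- phases[phases$label == lab, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    if (nrow(w) > 1 && any(w$start[-1] <= w$end[-nrow(w)])) {
      mvh_stop(sprintf("phase windows for label '%s' overlap", lab))
    }
  }
  if (activity == "single_leg_balance" &&
      !all(c("balance_left", "balance_right") %in% phases$label)) {
    mvh_stop("single_leg_balance traces require balance_left and balance_right phases")
  }
  phases[, c("label", "start", "end")]
}

#' @export
print.motion_trace <- function(x, ...) {
  cat(sprintf("<motion_trace> %s%s\n", x$activity,
              if (!is.null(x$participant_id)) paste0(" [", x$participant_id, "]") else ""))
  cat(sprintf("  %d samples @ %g Hz (%.1f s), %d channels, %d phase window(s)\n",
              x$n, x$fs, x$n / x$fs, length(x$channels), nrow(x$phases)))
  invisible(x)
}

# slice a channel by a phase window (inclusive indices)
phase_slice <- function(trace, channel, start, end) {
  trace$channels[[channel]][start:end]
}
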
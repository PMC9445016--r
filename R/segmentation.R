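# Repetition segmentation for squatting and lunging activities. The driving
# channel (pelvis height for squats, lower knee height for lunges) dips once
# per repetition; windows are recovered from its smoothed local minima.

#' Segment repetitions of a squat or lunge trace
#'
#' Detects repetition windows from the vertical driving channel: pelvis
#' height (`pelvis_z`) when present, otherwise the pointwise minimum of the
#' two knee heights. The channel is smoothed with a 0.5 s moving average;
#' repetitions are the contiguous spans that dip below 25% of the smoothed
#' channel's peak-to-peak range (measured down from its maximum), with dips
#' closer than 1 s merged into one. Each returned window is at least 0.5 s
#' long.
#'
#' @param trace A [motion_trace] with a `pelvis_z` or `knee_z_L`/`knee_z_R`
#'   channel, or a bare numeric vector (then `fs` is required).
#' @param expected Expected repetition count, or `NULL`. A mismatch between
#'   `expected` and the detected count raises a warning (participants unable
#'   to complete all repetitions are kept, not rejected) and the detected
#'   windows are returned.
#' @param fs Sampling rate, only used when `trace` is a bare vector.
#' @return Data frame with columns `start`, `end` (1-based inclusive sample
#'   indices), ordered and non-overlapping, one row per repetition.
#' @export
segment_repetitions <- function(trace, expected = NULL, fs = NULL) {
  if (inherits(trace, "motion_trace")) {
    fs <- trace$fs
    if ("pelvis_z" %in% names(trace$channels)) {
      y <- trace$channels$pelvis_z
    } else if (all(c("knee_z_L", "knee_z_R") %in% names(trace$channels))) {
      y <- pmin(trace$channels$knee_z_L, trace$channels$knee_z_R)
    } else {
      mvh_stop("trace has neither pelvis_z nor knee_z_L/knee_z_R channels")
    }
  } else {
    y <- trace
    if (is.null(fs)) mvh_stop("fs is required when segmenting a bare vector")
  }
  mvh_check_numeric(y, "driving channel")
  if (diff(range(y)) < 0.02) {
    mvh_stop("driving channel is flat (range < 0.02 m); no repetitions found",
             class = "mvh_no_repetitions_error")
  }

  k <- max(1L, as.integer(round(0.5 * fs)))
  sm <- moving_average(y, k)
  rng <- range(sm)
  thr <- rng[2] - 0.25 * diff(rng)
  below <- sm < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (nrow(seg) == 0) {
    mvh_stop("no repetition dips found in driving channel",
             class = "mvh_no_repetitions_error")
  }
  seg$min_idx <- mapply(function(s, e) s - 1L + which.min(sm[s:e]),
                        seg$start, seg$end)
  seg$min_val <- sm[seg$min_idx]

  # merge dips whose minima are closer than 1 s (keep the union span)
  min_sep <- as.integer(round(fs))
  merged <- seg[1, , drop = FALSE]
  if (nrow(seg) > 1) {
    for (i in 2:nrow(seg)) {
      j <- nrow(merged)
      if (seg$min_idx[i] - merged$min_idx[j] < min_sep) {
        merged$end[j] <- seg$end[i]
        if (seg$min_val[i] < merged$min_val[j]) {
          merged$min_idx[j] <- seg$min_idx[i]
          merged$min_val[j] <- seg$min_val[i]
        }
      } else {
        merged <- rbind(merged, seg[i, ])
      }
    }
  }

  # enforce the minimum window length without creating overlap
  n <- length(y)
  half <- as.integer(ceiling(0.25 * fs))
  for (i in seq_len(nrow(merged))) {
    if (merged$end[i] - merged$start[i] + 1L < 2L * half) {
      merged$start[i] <- max(1L, merged$min_idx[i] - half)
      merged$end[i] <- min(n, merged$min_idx[i] + half)
    }
  }
  if (nrow(merged) > 1) {
    for (i in 2:nrow(merged)) {
      if (merged$start[i] <= merged$end[i - 1]) {
        mid <- (merged$min_idx[i - 1] + merged$min_idx[i]) %/% 2L
        merged$end[i - 1] <- mid
        merged$start[i] <- mid + 1L
      }
    }
  }

  windows <- merged[, c("start", "end")]
  rownames(windows) <- NULL
  if (!is.null(expected) && nrow(windows) != expected) {
    warning(sprintf("detected %d repetition(s) where %d were expected",
                    nrow(windows), expected),
            call. = FALSE)
    attr(windows, "expected_mismatch") <- TRUE
  }
  windows
}

# centred moving average with shrinking windows at the edges
moving_average <- function(y, k) {
  if (k <= 1) return(y)
  n <- length(y)
  cs <- cumsum(c(0, y))
  half <- k %/% 2
  lo <- pmax(1, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}
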
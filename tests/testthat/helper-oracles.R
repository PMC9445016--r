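# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately avoid the implementation's code path.

# hysteresis edge scan, one sample at a time
bf_toe_taps <- function(z_raised, z_plant, h = 0.005) {
  d <- z_raised - z_plant
  armed <- FALSE
  count <- 0L
  for (di in d) {
    if (di > h) {
      armed <- TRUE
    } else if (armed && di < -h) {
      count <- count + 1L
      armed <- FALSE
    }
  }
  count
}

# full-sort decile-median oracle: manual type-7 percentile, manual median
bf_robust_extremum <- function(x, which) {
  s <- sort(x)
  n <- length(s)
  prob <- if (which == "max") 0.9 else 0.1
  h <- (n - 1) * prob
  lo <- floor(h)
  q <- if (lo + 1 >= n) s[n] else s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
  subset <- if (which == "max") s[s >= q] else s[s <= q]
  k <- length(subset)
  if (k %% 2 == 1) subset[(k + 1) / 2] else mean(subset[k / 2 + 0:1])
}

# minimal single-leg-balance trace built from explicit per-phase channels
make_slb_trace <- function(com_left, com_right, toe_raised_left = NULL,
                           toe_raised_right = NULL, trunk = NULL, fs = 60) {
  n_phase <- nrow(com_left)
  gap <- 30L
  n <- 2L * n_phase + gap
  left <- 1:n_phase
  right <- (n_phase + gap + 1L):n
  z <- function(phase_vals, idx) {
    out <- rep(0.02, n)
    if (!is.null(phase_vals)) out[idx] <- phase_vals else out[idx] <- 0.12
    out
  }
  acc_x <- acc_y <- rep(0.1, n)  # constant outside phases is irrelevant
  acc_x[left] <- com_left$x
  acc_y[left] <- com_left$y
  acc_x[right] <- com_right$x
  acc_y[right] <- com_right$y
  if (is.null(trunk)) trunk <- rep(1, n)
  motion_trace(
    "single_leg_balance", fs = fs,
    channels = list(
      trunk_lateral = trunk,
      toe_z_L = z(toe_raised_right, right),  # raised during right-stance
      toe_z_R = z(toe_raised_left, left),    # raised during left-stance
      com_acc_x = acc_x, com_acc_y = acc_y),
    phases = data.frame(label = c("balance_left", "balance_right"),
                        start = c(1L, n_phase + gap + 1L),
                        end = c(n_phase, n)))
}

# squat-like trace with hand-placed dips in pelvis_z
make_squat_trace <- function(activity = "feet_together_squat", dips = 3,
                             depth = 0.5, fs = 60, duration = NULL,
                             spacing = 3.5, width = 2) {
  centers <- 2 + spacing * (0:(dips - 1))
  if (is.null(duration)) duration <- max(centers) + 2.5
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  shape <- rep(0, n)
  for (c0 in centers) {
    idx <- which(abs(t - c0) <= width / 2)
    u <- (t[idx] - (c0 - width / 2)) / width
    shape[idx] <- pmax(shape[idx], 0.5 * (1 - cos(2 * pi * u)))
  }
  ch <- list(
    pelvis_z = 0.95 - depth * shape,
    knee_z_L = 0.50 - 0.05 * shape, knee_z_R = 0.50 - 0.05 * shape,
    hip_flexion_L = 100 * shape, hip_flexion_R = 100 * shape,
    knee_flexion_L = 110 * shape, knee_flexion_R = 110 * shape)
  if (activity == "overhead_squat") {
    ch$elbow_flexion_L <- 5 + 0 * shape
    ch$elbow_flexion_R <- 5 + 0 * shape
    ch$trunk_lateral <- 2 + 0 * shape
  }
  list(trace = motion_trace(activity, fs = fs, channels = ch),
       centers = centers, fs = fs)
}

default_profile <- function(theta, idx = 1L) {
  impairment_profile(theta, class_label = "healthy", id_index = idx)
}
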
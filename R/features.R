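#' Causal moving-average filter
#'
#' Trailing mean over the last `window` samples; at the start of the series
#' the window grows with the prefix (`mean(x[1:t])` for `t < window`), so
#' the output has the same length as the input and uses no future samples.
#'
#' @param x Numeric series.
#' @param window Window length in frames (default 100).
#' @return Filtered series, same length as `x`.
#' @export
moving_average <- function(x, window = 100) {
  assert_that(is.numeric(window) && length(window) == 1L && window >= 1,
              "window must be >= 1")
  window <- as.integer(window)
  n <- length(x)
  if (n == 0L) return(numeric(0))
  denom <- pmin(seq_len(n), window)
  rolling_sum(x, window) / denom
}

#' Gravity-referenced tilt angle of an accelerometer triplet
#'
#' Angle of the sensor's y axis against the horizontal plane,
#' `atan(ay / sqrt(ax^2 + az^2))`, in degrees within (-90, 90\].
#' Invariant to positive rescaling of the acceleration vector, so it can be
#' applied to raw counts, g units, or unit-scaled values alike.
#'
#' @param ax,ay,az Acceleration components (any common unit); vectors are
#'   processed element-wise.
#' @return Tilt angle(s) in degrees.
#' @export
tilt_angle <- function(ax, ay, az) {
  zero <- ax == 0 & ay == 0 & az == 0
  if (any(zero))
    stop_gi("undefined orientation: zero acceleration vector at position %d",
            which(zero)[1L])
  atan2(ay, sqrt(ax^2 + az^2)) * 180 / pi
}

#' Integrate angular velocity into an angle series
#'
#' Cumulative rectangular integration with step `1/fs`:
#' `theta[t] = theta_start + sum(omega[1:t]) / fs`.
#'
#' @param theta_start Initial angle in degrees.
#' @param omega Angular-velocity series in degrees/second.
#' @param fs Sampling rate in Hz.
#' @return Angle series in degrees, same length as `omega`.
#' @export
integrate_angle <- function(theta_start, omega, fs) {
  assert_that(is.numeric(fs) && length(fs) == 1L && fs > 0, "fs must be > 0")
  theta_start + cumsum(omega) / fs
}

# Population (divide-by-n) standard deviation over trailing windows of
# length `width`, computed with rolling sums; positions with fewer than
# `width` valid samples (given `lead` undefined leading values) are zero.
# The series is centered on its global mean first so the sum-of-squares
# cancellation stays benign (and a constant series yields exactly zero).
rolling_pop_sd <- function(x, width, lead = 0L) {
  n <- length(x)
  if (n == 0L || lead >= n) return(numeric(n))
  valid <- seq.int(lead + 1L, n)
  x0 <- x - mean(x[valid])
  x0[seq_len(min(lead, n))] <- 0
  s1 <- rolling_sum(x0, width)
  s2 <- rolling_sum(x0^2, width)
  v <- pmax(s2 / width - (s1 / width)^2, 0)
  out <- sqrt(v)
  undef <- min(width - 1L + lead, n)
  out[seq_len(undef)] <- 0
  out
}

#' Standard deviation of recent EMG gradients
#'
#' At frame `t`, the population standard deviation of the `w + 1` most
#' recent backward first differences of the EMG signal,
#' `d[t - i] = emg[t - i] - emg[t - i - 1]`, `i = 0..w`. Leading frames
#' where the window is undefined are filled with 0. This is the burst
#' feature `v_w` used for stand-up/sit-down intention recognition.
#'
#' @param emg EMG series (scaled or raw; the feature is level-invariant).
#' @param w Window parameter; the window holds `w + 1` differences.
#' @return Series of the same length as `emg`.
#' @export
emg_grad_std <- function(emg, w) {
  assert_that(is.numeric(w) && length(w) == 1L && w >= 1, "w must be >= 1")
  w <- as.integer(w)
  n <- length(emg)
  assert_that(n > w + 1L, "series length must exceed w + 1")
  d <- c(0, diff(emg))  # d[1] undefined -> masked by lead
  rolling_pop_sd(d, width = w + 1L, lead = 1L)
}

#' Standard deviation of recent left/right differences
#'
#' At frame `t`, the population standard deviation of
#' `|left - right|` over the last `w + 1` frames. Captures how differently
#' the two thighs move; near zero when both thighs hold a similar, steady
#' posture. Leading frames are filled with 0.
#'
#' @param left,right Equal-length series (e.g. x-axis thigh accelerometer,
#'   left and right).
#' @param w Window parameter (default 10, i.e. an 11-frame window).
#' @return Series of the same length as the inputs.
#' @export
paired_diff_std <- function(left, right, w = 10) {
  assert_that(length(left) == length(right),
              "left and right must have equal length")
  assert_that(is.numeric(w) && length(w) == 1L && w >= 1, "w must be >= 1")
  rolling_pop_sd(abs(left - right), width = as.integer(w) + 1L, lead = 0L)
}

#' Derive sagittal-plane angles and angular speeds from a scaled recording
#'
#' Converts scaled channels back to physical units (accelerometer to g,
#' gyroscope to degrees/second), estimates each segment's start angle from
#' the gravity direction in the moving-average-filtered accelerometer
#' ([tilt_angle()]), and integrates the sagittal (z-axis) gyroscope rate
#' ([integrate_angle()]) to obtain thigh and shank angle series.
#'
#' The drift filter is applied to the accelerometer path only: a trailing
#' 100-sample mean spans ~1.8 s at ~56 Hz — longer than a gait cycle — so
#' smoothing the gyroscope before integration would suppress the
#' gait-frequency rotation itself. `gyro_window = 1` (no smoothing) is
#' therefore the default; both windows are configurable.
#'
#' @param rec A `scaled_recording` (see [scale_raw()]) containing thigh
#'   channels (`*_lt_*`, `*_rt_*`) and, if shank angles are wanted, shin
#'   channels (`*_ls_*`, `*_rs_*`).
#' @param acc_window Moving-average window for accelerometer channels
#'   (default 100).
#' @param gyro_window Moving-average window for gyroscope channels
#'   (default 1 = unfiltered).
#' @return Object of class `angular_series` with elements `theta_L`,
#'   `theta_R` (thigh angles, degrees), `phi_L`, `phi_R` (shank angles,
#'   degrees; `NULL` without shin channels), `omega_TL`, `omega_TR` (thigh
#'   angular speeds, degrees/s), `fs`, `labels`, `participant_id`.
#' @export
derive_angles <- function(rec, acc_window = 100, gyro_window = 1) {
  stopifnot(inherits(rec, "scaled_recording"))
  seg_angle <- function(site) {
    need <- paste0(c("acc_", "acc_", "acc_", "gyro_"), site, "_",
                   c("x", "y", "z", "z"))
    miss <- setdiff(need, names(rec$channels))
    assert_that(length(miss) == 0L, "missing channel(s): %s",
                paste(miss, collapse = ", "))
    ax <- moving_average(rec$channels[[need[1L]]] * 2, acc_window)  # g
    ay <- moving_average(rec$channels[[need[2L]]] * 2, acc_window)
    az <- moving_average(rec$channels[[need[3L]]] * 2, acc_window)
    omega <- rec$channels[[need[4L]]] * 32768 / GYRO_LSB_PER_DPS    # deg/s
    if (gyro_window > 1) omega <- moving_average(omega, gyro_window)
    start <- tilt_angle(ax[1L], ay[1L], az[1L])
    list(angle = integrate_angle(start, omega, rec$fs), omega = omega)
  }
  lt <- seg_angle("lt")
  rt <- seg_angle("rt")
  has_shank <- all(c("acc_ls_y", "gyro_ls_z", "acc_rs_y", "gyro_rs_z") %in%
                     names(rec$channels))
  ls <- if (has_shank) seg_angle("ls")
  rs <- if (has_shank) seg_angle("rs")
  structure(
    list(theta_L = lt$angle, theta_R = rt$angle,
         phi_L = if (has_shank) ls$angle, phi_R = if (has_shank) rs$angle,
         omega_TL = lt$omega, omega_TR = rt$omega,
         fs = rec$fs, labels = rec$labels,
         participant_id = rec$participant_id),
    class = "angular_series")
}

#' @export
print.angular_series <- function(x, ...) {
  cat(sprintf("<angular_series> participant %s: %d frames @ %.2f Hz%s\n",
              x$participant_id, length(x$theta_L), x$fs,
              if (is.null(x$phi_L)) " (thigh only)" else ""))
  invisible(x)
}

FEATURE_KINDS <- c("gait_inference", "standing_up", "sitting_down",
                   "sitting_standing")

feature_window_length <- function(kind) {
  if (kind == "gait_inference") 15L else 20L
}

#' Fit min-max feature-scaling bounds
#'
#' @param x Data frame or matrix of raw feature columns.
#' @return Object of class `feature_scaling` holding per-column min and max.
#' @export
fit_feature_scaling <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2L, min), max = apply(x, 2L, max),
                 columns = colnames(x)),
            class = "feature_scaling")
}

#' Apply min-max scaling bounds
#'
#' Maps each column to \[0, 1\] using stored bounds (fitted on training
#' data), clipping values outside the training range; columns with zero
#' training range map to 0.
#'
#' @param x Data frame or matrix of raw feature columns.
#' @param scaling A `feature_scaling` from [fit_feature_scaling()].
#' @return Matrix of scaled features in \[0, 1\].
#' @export
apply_feature_scaling <- function(x, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  x <- as.matrix(x)
  assert_that(identical(colnames(x), scaling$columns),
              "feature columns do not match the fitted scaling")
  rng <- scaling$max - scaling$min
  out <- sweep(x, 2L, scaling$min, "-")
  zero <- rng == 0
  rng[zero] <- 1
  out <- sweep(out, 2L, rng, "/")
  out[, zero] <- 0
  pmin(pmax(out, 0), 1)
}

# Raw (pre-scaling) feature columns for one recording and kind.
raw_feature_columns <- function(rec, kind, angles = NULL) {
  need <- function(chs) {
    miss <- setdiff(chs, names(rec$channels))
    assert_that(length(miss) == 0L, "missing channel(s): %s",
                paste(miss, collapse = ", "))
  }
  switch(kind,
    gait_inference = {
      if (is.null(angles)) angles <- derive_angles(rec)
      data.frame(theta_L = angles$theta_L, theta_R = angles$theta_R,
                 omega_TL = angles$omega_TL, omega_TR = angles$omega_TR)
    },
    standing_up = {
      need(c("EMG_l", "EMG_r"))
      data.frame(v5_L = emg_grad_std(rec$channels$EMG_l, 5),
                 v5_R = emg_grad_std(rec$channels$EMG_r, 5))
    },
    sitting_down = {
      need(c("EMG_l", "EMG_r", "acc_lt_x", "acc_rt_x", "acc_lt_z", "acc_rt_z"))
      data.frame(
        v10_L = emg_grad_std(rec$channels$EMG_l, 10),
        v10_R = emg_grad_std(rec$channels$EMG_r, 10),
        d_x = paired_diff_std(rec$channels$acc_lt_x, rec$channels$acc_rt_x, 10),
        d_z = paired_diff_std(rec$channels$acc_lt_z, rec$channels$acc_rt_z, 10))
    },
    sitting_standing = {
      need(c("acc_lt_x", "acc_rt_x", "acc_lt_z", "acc_rt_z"))
      data.frame(Tx_L = moving_average(rec$channels$acc_lt_x, 100),
                 Tx_R = moving_average(rec$channels$acc_rt_x, 100),
                 Tz_L = moving_average(rec$channels$acc_lt_z, 100),
                 Tz_R = moving_average(rec$channels$acc_rt_z, 100))
    },
    stop_gi("unknown feature kind: %s", kind))
}

#' Build the model input features for a recognition or inference module
#'
#' Assembles the feature columns a module consumes — gait inference: left
#' and right thigh angle and angular speed; standing-up intention: EMG
#' gradient-spread `v5` of both thighs; sitting-down intention: `v10` of
#' both thighs plus the left/right accelerometer difference spreads `d_x`,
#' `d_z`; sitting/standing/moving: filtered x- and z-axis thigh
#' accelerometer values — and min-max-scales them to \[0, 1\].
#'
#' Scaling bounds are fitted on training data and stored for reuse at test
#' time: pass `scaling = NULL` to fit on this recording (and read the fit
#' back from the `"scaling"` attribute), or a stored `feature_scaling` to
#' apply training bounds.
#'
#' @param rec A `scaled_recording`.
#' @param kind One of `"gait_inference"`, `"standing_up"`,
#'   `"sitting_down"`, `"sitting_standing"`.
#' @param scaling Optional `feature_scaling` fitted on training data.
#' @param angles Optional precomputed [derive_angles()] result (gait
#'   inference only), to avoid recomputation.
#' @return Object of class `feature_table`: a data frame of scaled features
#'   with attributes `kind`, `window_length`, `scaling`, `labels`, `fs`.
#' @export
build_features <- function(rec, kind = FEATURE_KINDS, scaling = NULL,
                           angles = NULL) {
  kind <- match.arg(kind)
  raw <- raw_feature_columns(rec, kind, angles)
  if (is.null(scaling)) scaling <- fit_feature_scaling(raw)
  scaled <- as.data.frame(apply_feature_scaling(raw, scaling))
  structure(scaled, kind = kind,
            window_length = feature_window_length(kind),
            scaling = scaling, labels = rec$labels, fs = rec$fs,
            class = c("feature_table", "data.frame"))
}
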
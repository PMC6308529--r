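#' @title Synthetic gait and EMG generator
#'
#' @description
#' Generates recordings in the package's tab-separated sensor format with
#' full ground truth, so the whole pipeline is testable without any data
#' download. The generator emulates: smooth periodic thigh/shank angle
#' coupling per activity (a nonlinear, lagged coupling whose thigh-shank
#' scatter forms a closed loop), stance/swing timing with a configurable
#' stance fraction (default 0.62), raw accelerometer traces consistent with
#' gravity-referenced tilt, gyroscope traces equal to the angle derivative
#' plus noise and slow bias drift, EMG bursts at stand-up/sit-down
#' intentions, and label sequences restricted to the controller's
#' transition graph. Inter-subject variability is larger in the swing phase
#' than in stance (default 2x), implementing the observation that legs move
#' more freely in swing; this is a generator assumption, not a measured
#' fact.
#'
#' @name synthetic
NULL

# Legal adjacency for 8-activity label scripts.
SCRIPT_EDGES <- list(
  sitting = c("standing_up"),
  standing_up = c("standing"),
  standing = c("walking", "running", "going_up", "going_down", "sitting_down"),
  walking = c("running", "going_up", "going_down", "standing"),
  running = c("walking", "going_up", "going_down", "standing"),
  going_up = c("walking", "running", "going_down", "standing"),
  going_down = c("walking", "running", "going_up", "standing"),
  sitting_down = c("sitting"))

#' Synthetic-generator configuration
#'
#' All tunable parameters of the generator with their defaults; any can be
#' overridden by name. Angles are degrees against the horizontal, rates
#' degrees/second, noise levels in physical sensor units.
#'
#' @param n_participants Cohort size (default 6).
#' @param fs Sampling rate in Hz (default 56.35).
#' @param duration_s Approximate recording length per subject in seconds
#'   (default 90). Static bouts are kept long relative to the ~1.8 s
#'   settling of the causal drift filter, as in real recording protocols.
#' @param stance_fraction Fraction of the gait cycle in stance
#'   (default 0.62).
#' @param ... Named overrides of any other field (see the returned list).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_participants = 6L, fs = 56.35,
                             duration_s = 90, stance_fraction = 0.62, ...) {
  cfg <- list(
    n_participants = n_participants, fs = fs, duration_s = duration_s,
    stance_fraction = stance_fraction,
    # per-activity gait parameters: cycle duration (s), thigh two-harmonic
    # amplitudes and offset (deg), shank wave amplitude and offset (deg)
    gait = list(
      walking = list(cycle_s = 1.10, amp1 = 15, amp2 = 4, thigh_off = 65,
                     shank_amp = 28, shank_off = 40),
      running = list(cycle_s = 0.75, amp1 = 22, amp2 = 6, thigh_off = 62,
                     shank_amp = 34, shank_off = 38),
      going_up = list(cycle_s = 1.35, amp1 = 18, amp2 = 5, thigh_off = 63,
                      shank_amp = 30, shank_off = 40),
      going_down = list(cycle_s = 1.15, amp1 = 14, amp2 = 4, thigh_off = 66,
                        shank_amp = 26, shank_off = 42)),
    # static poses (deg)
    pose = list(sitting = c(theta = 8, phi = 75),
                standing = c(theta = 85, phi = 80)),
    transition_s = 1.5,        # stand-up / sit-down motion duration
    blend_s = 0.3,             # cross-fade at segment boundaries
    sway_deg = 0.5,            # postural sway amplitude in static poses
    sway_hz = 0.3,
    # inter-subject variability (STDs of subject-level parameter draws);
    # swing-phase shank variability is twice the stance-phase variability
    subject_sd = list(amp = 0.05, a = 0.06, b = 0.0015, lag = 0.015,
                      swing_deg = 2.0, stance_deg = 1.0),
    coupling = list(a = 1.0, b = 0.006, lag = 0.06),
    cycle_jitter = 0.04,       # per-cycle duration jitter (fraction)
    amp_jitter = 0.03,         # per-cycle amplitude jitter (fraction)
    # sensor noise
    acc_noise_g = 0.02,
    gyro_noise_dps = 1.5,
    gyro_bias_sd_dps = 0.02,
    gyro_drift_dps_per_s = 0.01,
    # EMG amplitude schedule (uint8 counts around the 127.5 midpoint)
    emg = list(sitting = 1.5, standing = 4, moving = 12, transition = 10,
               burst = 45, burst_pre_s = 0.3, burst_len_s = 0.9))
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  assert_that(cfg$stance_fraction > 0 && cfg$stance_fraction < 1,
              "stance_fraction must lie in (0, 1)")
  assert_that(cfg$fs > 0, "fs must be > 0")
  structure(cfg, class = "synthetic_config")
}

# Time-warp of the cycle fraction so stance occupies `sf` of the cycle.
warp_phase <- function(u, sf) {
  u <- u %% 1
  ifelse(u < sf, 0.5 * u / sf, 0.5 + 0.5 * (u - sf) / (1 - sf))
}

# Shank base wave: falls through stance (+1 -> -1), rises through swing.
shank_wave <- function(u, sf) {
  u <- u %% 1
  ifelse(u < sf, cos(pi * u / sf), -cos(pi * (u - sf) / (1 - sf)))
}

bump_swing <- function(u, sf) {
  u <- u %% 1
  ifelse(u >= sf, 0.5 * (1 - cos(2 * pi * (u - sf) / (1 - sf))), 0)
}

bump_stance <- function(u, sf) {
  u <- u %% 1
  ifelse(u < sf, 0.5 * (1 - cos(2 * pi * u / sf)), 0)
}

#' Draw subject-level gait parameters
#'
#' @param config A [synthetic_config()].
#' @return Named list of subject parameters (amplitude scale, coupling
#'   coefficients `a`, `b`, phase lag, swing/stance shape deviations).
#' @keywords internal
draw_subject_params <- function(config) {
  sd <- config$subject_sd
  cp <- config$coupling
  list(amp_scale = 1 + stats::rnorm(1, 0, sd$amp),
       a = cp$a + stats::rnorm(1, 0, sd$a),
       b = cp$b + stats::rnorm(1, 0, sd$b),
       lag = max(0, cp$lag + stats::rnorm(1, 0, sd$lag)),
       s_swing = stats::rnorm(1, 0, sd$swing_deg),
       s_stance = stats::rnorm(1, 0, sd$stance_deg))
}

#' Thigh and shank angles at one point of the gait cycle
#'
#' The deterministic per-subject trajectory: the thigh follows a
#' two-harmonic sinusoid of the time-warped cycle phase (stance occupying
#' `stance_fraction` of the cycle), and the shank follows a nonlinear,
#' lagged function of the same cycle phase — a linear-plus-quadratic map of
#' a lag-shifted base wave, plus the subject's smooth swing/stance shape
#' deviations. The (theta, phi) scatter over a cycle therefore forms a
#' closed loop rather than a single-valued curve.
#'
#' @param activity One of `walking`, `running`, `going_up`, `going_down`.
#' @param phase Cycle fraction(s) in \[0, 1).
#' @param subject Subject parameters from [draw_subject_params()] (defaults
#'   to the population-center subject).
#' @param config A [synthetic_config()].
#' @param cycle_amp Optional per-cycle amplitude factor (default 1).
#' @return List with `theta` and `phi` in degrees.
#' @export
thigh_shank_trajectory <- function(activity, phase,
                                   subject = NULL,
                                   config = synthetic_config(),
                                   cycle_amp = 1) {
  g <- config$gait[[activity]]
  if (is.null(g)) stop_gi("unknown activity: %s", activity)
  if (is.null(subject))
    subject <- list(amp_scale = 1, a = config$coupling$a,
                    b = config$coupling$b, lag = config$coupling$lag,
                    s_swing = 0, s_stance = 0)
  sf <- config$stance_fraction
  p <- warp_phase(phase, sf)
  theta_c <- (g$amp1 * cos(2 * pi * p) + g$amp2 * cos(4 * pi * p + 0.6)) *
    subject$amp_scale * cycle_amp
  W <- g$shank_amp * shank_wave(phase - subject$lag, sf) *
    subject$amp_scale * cycle_amp
  phi <- g$shank_off + subject$a * W + subject$b * W^2 +
    subject$s_swing * bump_swing(phase, sf) +
    subject$s_stance * bump_stance(phase, sf)
  list(theta = g$thigh_off + theta_c, phi = phi)
}

#' Validate an activity script against the transition graph
#'
#' @param script Data frame with columns `activity`, `duration_s`.
#' @return Invisibly `TRUE`; errors naming the first illegal edge.
#' @export
validate_script <- function(script) {
  acts <- script$activity
  assert_that(all(acts %in% ACTIVITY_LEVELS), "unknown activity in script")
  if (length(acts) > 1L) {
    for (i in seq_len(length(acts) - 1L)) {
      if (!(acts[i + 1L] %in% SCRIPT_EDGES[[acts[i]]]))
        stop_gi("illegal activity transition in script: %s -> %s",
                acts[i], acts[i + 1L])
    }
  }
  invisible(TRUE)
}

# Random legal activity script of roughly duration_s seconds. Uses the
# current RNG stream.
build_script <- function(config) {
  segs <- list()
  push <- function(a, d) segs[[length(segs) + 1L]] <<- list(activity = a,
                                                            duration_s = d)
  total <- function() sum(vapply(segs, function(s) s$duration_s, numeric(1)))
  repeat {
    push("sitting", stats::runif(1, 3, 5))
    push("standing_up", config$transition_s)
    push("standing", stats::runif(1, 3.5, 6))
    for (block in seq_len(sample(1:2, 1))) {
      prev <- "standing"
      for (j in seq_len(sample(1:3, 1))) {
        choices <- setdiff(intersect(SCRIPT_EDGES[[prev]], MOVING_ACTIVITIES),
                           prev)
        act <- if (j == 1L) sample(c("walking", choices), 1L,
                                   prob = c(2, rep(1, length(choices))) /
                                     (2 + length(choices)))
               else sample(choices, 1L)
        push(act, stats::runif(1, 7, 12))
        prev <- act
      }
      push("standing", stats::runif(1, 2.5, 5))
    }
    push("sitting_down", config$transition_s)
    push("sitting", stats::runif(1, 3, 4))
    if (total() >= config$duration_s) break
  }
  acts <- vapply(segs, function(s) s$activity, character(1))
  durs <- vapply(segs, function(s) s$duration_s, numeric(1))
  # merge consecutive identical activities (episode boundaries)
  grp <- cumsum(c(TRUE, acts[-1L] != acts[-length(acts)]))
  script <- data.frame(
    activity = acts[!duplicated(grp)],
    duration_s = as.numeric(tapply(durs, grp, sum)))
  validate_script(script)
  script
}

# Smoothstep ramp 0..1 over n frames.
smoothstep <- function(n) {
  x <- seq(0, 1, length.out = n)
  x * x * (3 - 2 * x)
}

# Synthesize ground-truth angle series for one subject from a script.
# Returns per-frame theta/phi for both legs, labels, phases, spans.
synth_angles <- function(script, subject, config) {
  fs <- config$fs
  sf <- config$stance_fraction
  th_L <- c(); th_R <- c(); ph_L <- c(); ph_R <- c()
  labels <- integer(0); phase_L <- c(); phase_R <- c()
  u <- 0                       # right-leg cycle fraction; left = u + 0.5
  cyc_dur <- NA; cyc_amp <- 1
  last <- c(th_L = NA, th_R = NA, ph_L = NA, ph_R = NA)
  blend_n <- round(config$blend_s * fs)
  codes <- activity_codes()

  append_seg <- function(thL, thR, phL, phR, act, pL, pR) {
    n <- length(thL)
    if (!is.na(last["th_L"]) && blend_n > 1L && n >= blend_n) {
      w <- smoothstep(blend_n)
      idx <- seq_len(blend_n)
      thL[idx] <- (1 - w) * last[["th_L"]] + w * thL[idx]
      thR[idx] <- (1 - w) * last[["th_R"]] + w * thR[idx]
      phL[idx] <- (1 - w) * last[["ph_L"]] + w * phL[idx]
      phR[idx] <- (1 - w) * last[["ph_R"]] + w * phR[idx]
    }
    th_L <<- c(th_L, thL); th_R <<- c(th_R, thR)
    ph_L <<- c(ph_L, phL); ph_R <<- c(ph_R, phR)
    labels <<- c(labels, rep(codes[[act]], n))
    phase_L <<- c(phase_L, pL); phase_R <<- c(phase_R, pR)
    last <<- c(th_L = thL[n], th_R = thR[n], ph_L = phL[n], ph_R = phR[n])
  }

  for (i in seq_len(nrow(script))) {
    act <- script$activity[i]
    n <- max(2L, round(script$duration_s[i] * fs))
    tt <- seq_len(n) / fs
    if (act %in% MOVING_ACTIVITIES) {
      g <- config$gait[[act]]
      if (is.na(cyc_dur)) {
        cyc_dur <- g$cycle_s * (1 + stats::rnorm(1, 0, config$cycle_jitter))
        cyc_amp <- 1 + stats::rnorm(1, 0, config$amp_jitter)
      }
      us <- numeric(n); amps <- numeric(n)
      for (t in seq_len(n)) {
        u <- u + 1 / (fs * cyc_dur)
        if (u >= 1) {
          u <- u - 1
          cyc_dur <- g$cycle_s * (1 + stats::rnorm(1, 0, config$cycle_jitter))
          cyc_amp <- 1 + stats::rnorm(1, 0, config$amp_jitter)
        }
        us[t] <- u; amps[t] <- cyc_amp
      }
      R <- thigh_shank_trajectory(act, us, subject, config, amps)
      L <- thigh_shank_trajectory(act, (us + 0.5) %% 1, subject, config, amps)
      pR <- ifelse(us < sf, "stance", "swing")
      pL <- ifelse(((us + 0.5) %% 1) < sf, "stance", "swing")
      append_seg(L$theta, R$theta, L$phi, R$phi, act, pL, pR)
    } else if (act %in% c("sitting", "standing")) {
      pose <- config$pose[[act]]
      sway <- config$sway_deg * sin(2 * pi * config$sway_hz * tt)
      append_seg(rep(pose[["theta"]], n) + sway,
                 rep(pose[["theta"]], n) - sway,
                 rep(pose[["phi"]], n) + 0.5 * sway,
                 rep(pose[["phi"]], n) - 0.5 * sway,
                 act, rep("undefined", n), rep("undefined", n))
      cyc_dur <- NA
    } else {                   # standing_up / sitting_down ramps
      from <- config$pose[[if (act == "standing_up") "sitting" else "standing"]]
      to <- config$pose[[if (act == "standing_up") "standing" else "sitting"]]
      w <- smoothstep(n)
      th <- from[["theta"]] + w * (to[["theta"]] - from[["theta"]])
      ph <- from[["phi"]] + w * (to[["phi"]] - from[["phi"]])
      append_seg(th, th, ph, ph, act, rep("undefined", n),
                 rep("undefined", n))
      cyc_dur <- NA
    }
  }

  # intention spans: the EMG burst starts shortly before the transitional
  # label and overlaps its beginning
  n_tot <- length(labels)
  span_for <- function(code) {
    runs <- true_runs(labels == code)
    lapply(seq_len(nrow(runs)), function(r) {
      s <- max(1L, runs[r, 1L] - round(config$emg$burst_pre_s * fs))
      e <- min(n_tot, runs[r, 1L] +
                 round((config$emg$burst_len_s - config$emg$burst_pre_s) * fs))
      c(s, e)
    })
  }
  list(theta_L = th_L, theta_R = th_R, phi_L = ph_L, phi_R = ph_R,
       labels = labels, phase_L = phase_L, phase_R = phase_R,
       standup_spans = span_for(codes[["standing_up"]]),
       sitdown_spans = span_for(codes[["sitting_down"]]))
}

#' Emit raw sensor channels for ground-truth angle series
#'
#' The inverse of the angle pipeline: the accelerometer of a segment at
#' angle `theta` reads the unit-gravity projection (`x = cos(theta)` g,
#' `y = sin(theta)` g, `z = 0`) plus white noise, quantized to int16 at
#' 16384 LSB/g; the gyroscope z-axis reads the backward finite difference
#' of the angle plus white noise, a constant per-channel bias and a slow
#' random-walk drift, quantized at 16.4 LSB/(deg/s); EMG channels read the
#' uint8 midpoint plus noise whose spread follows the activity/burst
#' schedule. Uses the current RNG stream unless a seed is supplied.
#'
#' @param gt Ground-truth list from the generator (per-frame angles,
#'   labels, intention spans).
#' @param config A [synthetic_config()].
#' @param seed Optional integer seed (restores the caller's RNG stream).
#' @return Named list of integer channel series.
#' @export
sensor_model <- function(gt, config, seed = NULL) {
  if (!is.null(seed)) return(with_local_seed(seed, sensor_model(gt, config)))
  fs <- config$fs
  n <- length(gt$labels)
  chans <- list()
  imu_site <- function(angle_deg, site) {
    rad <- angle_deg * pi / 180
    ax <- cos(rad) + stats::rnorm(n, 0, config$acc_noise_g)
    ay <- sin(rad) + stats::rnorm(n, 0, config$acc_noise_g)
    az <- stats::rnorm(n, 0, config$acc_noise_g)
    omega <- c(0, diff(angle_deg)) * fs
    if (n >= 2L) omega[1L] <- omega[2L]
    bias <- stats::rnorm(1, 0, config$gyro_bias_sd_dps)
    drift <- cumsum(stats::rnorm(n, 0, config$gyro_drift_dps_per_s /
                                   sqrt(fs)))
    gz <- omega + stats::rnorm(n, 0, config$gyro_noise_dps) + bias + drift
    gx <- stats::rnorm(n, 0, config$gyro_noise_dps)
    gy <- stats::rnorm(n, 0, config$gyro_noise_dps)
    q16 <- function(v, lsb) pmin(pmax(round(v * lsb), INT16_MIN), INT16_MAX)
    chans[[paste0("acc_", site, "_x")]] <<- q16(ax, ACC_LSB_PER_G)
    chans[[paste0("acc_", site, "_y")]] <<- q16(ay, ACC_LSB_PER_G)
    chans[[paste0("acc_", site, "_z")]] <<- q16(az, ACC_LSB_PER_G)
    chans[[paste0("gyro_", site, "_x")]] <<- q16(gx, GYRO_LSB_PER_DPS)
    chans[[paste0("gyro_", site, "_y")]] <<- q16(gy, GYRO_LSB_PER_DPS)
    chans[[paste0("gyro_", site, "_z")]] <<- q16(gz, GYRO_LSB_PER_DPS)
  }
  imu_site(gt$theta_L, "lt")
  imu_site(gt$theta_R, "rt")
  imu_site(gt$phi_L, "ls")
  imu_site(gt$phi_R, "rs")

  lab <- activity_name(gt$labels)
  emg_sd <- rep(config$emg$sitting, n)
  emg_sd[lab == "standing"] <- config$emg$standing
  emg_sd[lab %in% MOVING_ACTIVITIES] <- config$emg$moving
  emg_sd[lab %in% c("standing_up", "sitting_down")] <- config$emg$transition
  for (sp in c(gt$standup_spans, gt$sitdown_spans))
    emg_sd[sp[1L]:sp[2L]] <- config$emg$burst
  for (ch in c("EMG_l", "EMG_r"))
    chans[[ch]] <- pmin(pmax(round(127.5 + stats::rnorm(n, 0, emg_sd)), 0L),
                        UINT8_MAX)
  chans
}

#' Generate one synthetic subject
#'
#' Draws subject-level gait parameters, builds a legal activity script
#' (or uses the supplied one), synthesizes ground-truth thigh/shank angles,
#' and emits a raw recording through the sensor model. Deterministic for a
#' given seed.
#'
#' @param config A [synthetic_config()].
#' @param participant_id Identifier string.
#' @param seed Integer seed.
#' @param script Optional data frame (`activity`, `duration_s`); validated
#'   against the transition graph.
#' @return List with `recording` (a [raw_recording()]), `truth` (per-frame
#'   ground-truth angles, phases, labels, intention spans) and `params`
#'   (the subject's drawn parameters).
#' @export
generate_subject <- function(config = synthetic_config(),
                             participant_id = "S01", seed = 1L,
                             script = NULL) {
  if (!is.null(script)) validate_script(script)
  with_local_seed(seed, {
    subject <- draw_subject_params(config)
    if (is.null(script)) script <- build_script(config)
    gt <- synth_angles(script, subject, config)
    chans <- sensor_model(gt, config)
    rec <- raw_recording(chans, labels = gt$labels, fs = config$fs,
                         participant_id = participant_id,
                         metadata = list(origin = "synthetic"))
    list(recording = rec, truth = gt, params = subject, script = script)
  })
}

#' Generate a synthetic cohort
#'
#' Per-subject parameters are drawn independently from the variability
#' distributions; one global seed fans out to per-subject seeds, so
#' individual subjects can be regenerated without the rest.
#'
#' @param config A [synthetic_config()].
#' @param n Number of participants (default `config$n_participants`).
#' @param seed Integer seed.
#' @return List of [generate_subject()] results.
#' @export
generate_cohort <- function(config = synthetic_config(),
                            n = config$n_participants, seed = 1L) {
  assert_that(n >= 1L, "n must be >= 1")
  sub_seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  lapply(seq_len(n), function(i)
    generate_subject(config, participant_id = sprintf("S%02d", i),
                     seed = sub_seeds[i]))
}

#' Write a synthetic cohort to disk
#'
#' One recording file per subject (the tab-separated sensor dialect) plus a
#' parallel ground-truth TSV (`*_truth.tsv`) with per-frame angles, phases
#' and labels.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of recording paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sub in cohort) {
    id <- sub$recording$participant_id
    p <- file.path(dir, paste0(id, ".tsv"))
    write_recording(sub$recording, p)
    gt <- sub$truth
    utils::write.table(
      data.frame(theta_L = gt$theta_L, theta_R = gt$theta_R,
                 phi_L = gt$phi_L, phi_R = gt$phi_R,
                 phase_L = gt$phase_L, phase_R = gt$phase_R,
                 act = gt$labels),
      file.path(dir, paste0(id, "_truth.tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
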
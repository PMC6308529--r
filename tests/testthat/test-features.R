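test_that("moving average matches a direct growing-prefix convolution", {
  expect_equal(moving_average(rep(3.5, 20), 5), rep(3.5, 20))
  # unit impulse: value 1/k at position k - 1 while the prefix grows
  x <- c(1, rep(0, 149))
  out <- moving_average(x, 100)
  direct <- vapply(seq_along(x), function(t)
    mean(x[max(1, t - 99):t]), numeric(1))
  expect_equal(out, direct)
  expect_equal(out[1:100], 1 / (1:100))
  expect_equal(out[101:150], rep(0, 50))
  # random series vs direct computation
  set.seed(7)
  y <- rnorm(80)
  expect_equal(moving_average(y, 7),
               vapply(seq_along(y), function(t)
                 mean(y[max(1, t - 6):t]), numeric(1)))
  expect_error(moving_average(y, 0), "window")
})

test_that("moving average of a ramp lags by (window-1)/2 in steady state", {
  x <- as.numeric(1:200)
  w <- 11
  out <- moving_average(x, w)
  # mean of an arithmetic run t-w+1..t is t - (w-1)/2
  expect_equal(out[w:200], x[w:200] - (w - 1) / 2)
})

test_that("tilt angle evaluates the gravity arctangent in degrees", {
  expect_equal(tilt_angle(0, 1, 0), 90)
  expect_equal(tilt_angle(1, 0, 0), 0)
  expect_equal(tilt_angle(1, 1, 1), atan(1 / sqrt(2)) * 180 / pi)
  expect_equal(tilt_angle(1, 1, 1), 35.26439, tolerance = 1e-6)
  expect_error(tilt_angle(0, 0, 0), "undefined orientation")
})

test_that("tilt angle is invariant to positive rescaling", {
  set.seed(11)
  for (i in 1:20) {
    v <- rnorm(3)
    if (all(v == 0)) next
    k <- runif(1, 0.1, 100)
    expect_equal(tilt_angle(v[1], v[2], v[3]),
                 tilt_angle(k * v[1], k * v[2], k * v[3]))
  }
})

test_that("rectangular integration follows its closed forms", {
  fs <- 56.35
  expect_equal(integrate_angle(12, rep(0, 30), fs), rep(12, 30))
  # constant rate: theta_start + w0 * t at the grid points t = k/fs
  w0 <- 18
  out <- integrate_angle(5, rep(w0, 100), fs)
  expect_equal(out, 5 + w0 * (1:100) / fs)
  # derivative of a sinusoid integrates back to it with O(1/fs) error
  t <- (1:2000) / fs
  theta <- 20 * sin(2 * pi * 0.9 * t)
  omega <- 20 * 2 * pi * 0.9 * cos(2 * pi * 0.9 * t)
  rec <- integrate_angle(0, omega, fs)
  expect_lt(max(abs(rec - theta)), 20 * 2 * pi * 0.9 / fs * 1.5)
})

test_that("integration inverts differencing up to a constant offset", {
  set.seed(3)
  fs <- 50
  series <- cumsum(rnorm(300))
  omega <- c(0, diff(series)) * fs
  rec <- integrate_angle(series[1], omega[-1], fs)
  expect_equal(rec, series[-1], tolerance = 1e-10)
})

test_that("EMG gradient spread matches the population-SD formula", {
  expect_equal(emg_grad_std(rep(4, 30), 5), rep(0, 30))
  expect_equal(emg_grad_std(seq(0, 29), 5), rep(0, 30))  # constant gradient
  e <- c(0, 1, 0, 1, 0, 1)
  out <- emg_grad_std(e, 4)
  # last frame: diffs {1,-1,1,-1,1}, population SD = sqrt(1 - 0.2^2)
  expect_equal(out[6], sqrt(0.96), tolerance = 1e-12)
  expect_equal(out[6], 0.9798, tolerance = 1e-4)
  expect_error(emg_grad_std(e, 0), "w")
  expect_error(emg_grad_std(c(1, 2), 5), "length")
})

test_that("left/right difference spread matches its direct oracle", {
  n <- 40
  x <- rnorm(n)
  expect_equal(paired_diff_std(x, x, 10), rep(0, n))
  expect_equal(paired_diff_std(x, x - 3.2, 10), rep(0, n))
  # alternating |diff| in {0, 2}: six 2s and five 0s in an 11-frame window
  left <- rep(c(2, 0), 20)[1:n]
  right <- numeric(n)
  out <- paired_diff_std(left, right, 10)
  expect_equal(out[n], sqrt(120) / 11, tolerance = 1e-12)
  expect_equal(out[n], 0.9959, tolerance = 1e-4)
  expect_error(paired_diff_std(1:3, 1:4), "equal length")
})

test_that("windowed spread features ignore the signal level", {
  set.seed(5)
  x <- cumsum(rnorm(60)); y <- cumsum(rnorm(60))
  expect_equal(emg_grad_std(x, 5), emg_grad_std(x + 17.3, 5))
  expect_equal(paired_diff_std(x, y, 10),
               paired_diff_std(x + 4, y + 4, 10))
})

test_that("feature tables carry the documented columns and windows", {
  sub <- generate_subject(fast_config(), "S01", seed = 2)
  sc <- scale_raw(sub$recording)
  gi <- build_features(sc, "gait_inference")
  expect_named(gi, c("theta_L", "theta_R", "omega_TL", "omega_TR"))
  expect_equal(attr(gi, "window_length"), 15L)
  sd_tab <- build_features(sc, "sitting_down")
  expect_named(sd_tab, c("v10_L", "v10_R", "d_x", "d_z"))
  expect_equal(attr(sd_tab, "window_length"), 20L)
  su <- build_features(sc, "standing_up")
  expect_named(su, c("v5_L", "v5_R"))
  ssm <- build_features(sc, "sitting_standing")
  expect_named(ssm, c("Tx_L", "Tx_R", "Tz_L", "Tz_R"))
  for (tab in list(gi, sd_tab, su, ssm)) {
    expect_true(all(as.matrix(tab) >= 0 & as.matrix(tab) <= 1))
  }
})

test_that("zero-range columns scale to zero and missing channels are named", {
  n <- 60
  rec <- raw_recording(
    list(acc_lt_x = rep(5, n), acc_rt_x = rep(5, n),
         acc_lt_z = rep(2, n), acc_rt_z = rep(2, n),
         EMG_l = rep(100, n), EMG_r = rep(100, n)),
    labels = rep(1L, n))
  sc <- scale_raw(rec)
  tab <- build_features(sc, "sitting_down")
  expect_true(all(as.matrix(tab) == 0))
  expect_error(build_features(sc, "gait_inference"), "gyro_lt_z")
})

test_that("stored scaling bounds are reused verbatim at test time", {
  subs <- lapply(1:2, function(i)
    scale_raw(generate_subject(fast_config(), paste0("S", i), seed = i)$recording))
  tr <- build_features(subs[[1]], "sitting_down")
  te <- build_features(subs[[2]], "sitting_down", scaling = attr(tr, "scaling"))
  raw_te <- gaitinfer:::raw_feature_columns(subs[[2]], "sitting_down")
  expect_equal(as.matrix(te),
               apply_feature_scaling(as.matrix(raw_te), attr(tr, "scaling")),
               ignore_attr = TRUE)
})

test_that("angle pipeline recovers ground truth within 2 degrees noise-free", {
  sub <- generate_subject(noiseless_config(duration_s = 32), "S01", seed = 9)
  ang <- derive_angles(scale_raw(sub$recording))
  expect_lt(max(abs(ang$theta_L - sub$truth$theta_L)), 2)
  expect_lt(max(abs(ang$theta_R - sub$truth$theta_R)), 2)
  expect_lt(max(abs(ang$phi_L - sub$truth$phi_L)), 2)
  expect_lt(max(abs(ang$phi_R - sub$truth$phi_R)), 2)
})
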
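test_that("gait trajectories are periodic, smooth and loop-shaped", {
  cfg <- synthetic_config()
  for (act in c("walking", "running", "going_up", "going_down")) {
    a <- thigh_shank_trajectory(act, 0, config = cfg)
    b <- thigh_shank_trajectory(act, 1 - 1e-9, config = cfg)
    expect_equal(a$theta, b$theta, tolerance = 1e-4)
    expect_equal(a$phi, b$phi, tolerance = 1e-4)
  }
  # with zero per-cycle variability, consecutive cycles are identical
  u <- seq(0, 1, length.out = 200)[-200]
  t1 <- thigh_shank_trajectory("walking", u, config = cfg)
  t2 <- thigh_shank_trajectory("walking", u + 1, config = cfg)
  expect_equal(t1$theta, t2$theta)
  expect_equal(t1$phi, t2$phi)
  # the (theta, phi) scatter over a cycle encloses positive area
  # (nonfunctional, looped coupling); shoelace formula
  area <- abs(sum(t1$theta * c(t1$phi[-1], t1$phi[1]) -
                  c(t1$theta[-1], t1$theta[1]) * t1$phi)) / 2
  expect_gt(area, 10)
  expect_error(thigh_shank_trajectory("flying", 0.5, config = cfg),
               "unknown activity")
})

test_that("the sensor model inverts through the angle pipeline", {
  # static pose: tilt of the emitted accelerometer recovers the angle
  cfg <- noiseless_config()
  n <- 300
  gt <- list(theta_L = rep(30, n), theta_R = rep(30, n),
             phi_L = rep(50, n), phi_R = rep(50, n),
             labels = rep(8L, n), standup_spans = list(),
             sitdown_spans = list())
  chans <- withr::with_seed(1, gaitinfer:::sensor_model(gt, cfg))
  sc <- scale_raw(raw_recording(chans, labels = gt$labels, fs = cfg$fs))
  tilt <- tilt_angle(sc$channels$acc_lt_x * 2, sc$channels$acc_lt_y * 2,
                     sc$channels$acc_lt_z * 2)
  expect_lt(max(abs(tilt - 30)), 0.1)
})

test_that("subject generation is deterministic given the seed", {
  s1 <- generate_subject(fast_config(), "S01", seed = 77)
  s2 <- generate_subject(fast_config(), "S01", seed = 77)
  expect_identical(s1$recording$channels, s2$recording$channels)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_subject(fast_config(), "S01", seed = 78)
  expect_false(identical(s1$recording$channels, s3$recording$channels))
})

test_that("cohorts draw distinct subject parameters deterministically", {
  coh <- generate_cohort(fast_config(), n = 3, seed = 5)
  coh2 <- generate_cohort(fast_config(), n = 3, seed = 5)
  expect_identical(lapply(coh, function(s) s$truth),
                   lapply(coh2, function(s) s$truth))
  amps <- vapply(coh, function(s) s$params$amp_scale, numeric(1))
  expect_gt(length(unique(amps)), 1)
})

test_that("label sequences respect the activity transition graph", {
  codes <- activity_codes()
  legal <- gaitinfer:::SCRIPT_EDGES
  for (seed in c(3, 14, 25)) {
    sub <- generate_subject(fast_config(), "S01", seed = seed)
    lab <- activity_name(sub$truth$labels)
    chg <- which(lab[-1] != lab[-length(lab)])
    for (t in chg)
      expect_true(lab[t + 1] %in% legal[[lab[t]]],
                  label = sprintf("edge %s->%s", lab[t], lab[t + 1]))
    # in particular, never sitting -> walking
    expect_false(any(lab[chg] == "sitting" & lab[chg + 1] == "walking"))
  }
  bad <- data.frame(activity = c("sitting", "walking"), duration_s = c(2, 2))
  expect_error(generate_subject(fast_config(), "S01", 1, script = bad),
               "sitting -> walking")
})

test_that("scripted recordings put one EMG burst before each transition", {
  script <- data.frame(activity = c("sitting", "standing_up", "standing"),
                       duration_s = c(4, 1.5, 3))
  sub <- generate_subject(synthetic_config(), "S01", seed = 8,
                          script = script)
  lab <- activity_name(sub$truth$labels)
  expect_equal(rle(lab)$values, c("sitting", "standing_up", "standing"))
  expect_length(sub$truth$standup_spans, 1)
  sp <- sub$truth$standup_spans[[1]]
  onset <- which(lab == "standing_up")[1]
  expect_lt(sp[1], onset)          # burst precedes the transition label
  expect_gte(sp[2], onset)
  # the burst is visible in the EMG spread feature
  sc <- scale_raw(sub$recording)
  v5 <- emg_grad_std(sc$channels$EMG_l, 5)
  inside <- mean(v5[sp[1]:sp[2]])
  outside <- mean(v5[lab == "sitting" & !gaitinfer:::in_spans(length(lab),
                                                              list(sp))])
  expect_gt(inside, 5 * outside)
})

test_that("the stance fraction of walking cycles matches the configuration", {
  cfg <- synthetic_config(duration_s = 40)
  script <- data.frame(
    activity = c("sitting", "standing_up", "standing", "walking", "standing"),
    duration_s = c(2, 1.5, 2, 130, 2))   # >100 cycles at ~1.1 s
  sub <- generate_subject(cfg, "S01", seed = 4, script = script)
  walk <- activity_name(sub$truth$labels) == "walking"
  ph <- sub$truth$phase_R[walk]
  expect_gt(sum(walk) / (cfg$fs * 1.1), 100)
  frac <- mean(ph == "stance")
  expect_lt(abs(frac - cfg$stance_fraction), 0.03)
})

test_that("swing-phase shank variability across subjects exceeds stance", {
  cfg <- noiseless_config(duration_s = 30)
  script <- data.frame(
    activity = c("sitting", "standing_up", "standing", "walking"),
    duration_s = c(2, 1.5, 2, 25))
  # resample many subjects on a common phase grid and compare phase-wise
  # cross-subject dispersion of the shank angle
  u <- seq(0, 1, length.out = 120)[-120]
  phis <- vapply(1:12, function(i) {
    p <- withr::with_seed(1000 + i, gaitinfer:::draw_subject_params(cfg))
    thigh_shank_trajectory("walking", u, subject = p, config = cfg)$phi
  }, numeric(length(u)))
  sds <- apply(phis, 1, sd)
  sf <- cfg$stance_fraction
  expect_gt(mean(sds[u >= sf]), mean(sds[u < sf]))
})

test_that("default-noise generator output passes validation cleanly", {
  sub <- generate_subject(fast_config(), "S01", seed = 31)
  expect_equal(nrow(validate_recording(sub$recording)), 0L)
  # ground-truth lengths match the emitted recording
  expect_length(sub$truth$phi_L, length(sub$recording))
  expect_length(sub$truth$phase_R, length(sub$recording))
})

test_that("cohorts round-trip through disk including ground truth", {
  dir <- withr::local_tempdir()
  coh <- generate_cohort(fast_config(), n = 2, seed = 9)
  paths <- write_cohort(coh, dir)
  expect_length(list.files(dir, pattern = "_truth\\.tsv$"), 2)
  back <- read_recording(file.path(dir, "S01.tsv"))
  expect_identical(back$channels, coh[[1]]$recording$channels)
  gt <- utils::read.delim(file.path(dir, "S01_truth.tsv"))
  expect_equal(gt$phi_L, coh[[1]]$truth$phi_L, tolerance = 1e-9)
})
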
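# Shared fixtures: all test data is generated in code.

# A small random-but-valid recording with a handful of channels.
make_tiny_recording <- function(n = 50, seed = 1) {
  set.seed(seed)
  chans <- list(
    acc_lt_x = sample(-32768:32767, n, replace = TRUE),
    acc_lt_y = sample(-32768:32767, n, replace = TRUE),
    acc_lt_z = sample(-32768:32767, n, replace = TRUE),
    gyro_lt_z = sample(-32768:32767, n, replace = TRUE),
    EMG_l = sample(0:255, n, replace = TRUE),
    EMG_r = sample(0:255, n, replace = TRUE))
  raw_recording(chans, labels = sample(c(0:8), n, replace = TRUE),
                fs = 56.35, participant_id = "T01")
}

# Fast synthetic config: short recording, small everything.
fast_config <- function(...) {
  synthetic_config(duration_s = 25, ...)
}

noiseless_config <- function(...) {
  synthetic_config(acc_noise_g = 0, gyro_noise_dps = 0,
                   gyro_bias_sd_dps = 0, gyro_drift_dps_per_s = 0, ...)
}

# Independent LSTM-cell oracle: scalar-loop transcription of the gate
# equations, deliberately written without matrix shortcuts so it shares no
# code path with the implementation.
oracle_lstm_step <- function(params, x, h, c) {
  nh <- params$hidden
  z <- c(x, h)
  gate <- function(W, b, squash) {
    out <- numeric(length(b))
    for (j in seq_along(b)) {
      acc <- b[j]
      for (i in seq_along(z)) acc <- acc + z[i] * W[i, j]
      out[j] <- squash(acc)
    }
    out
  }
  sig <- function(a) 1 / (1 + exp(-a))
  f <- gate(params$W_f, params$b_f, sig)
  i <- gate(params$W_i, params$b_i, sig)
  g <- gate(params$W_g, params$b_g, tanh)
  o <- gate(params$W_o, params$b_o, sig)
  c_new <- numeric(nh); h_new <- numeric(nh)
  for (j in seq_len(nh)) {
    c_new[j] <- f[j] * c[j] + i[j] * g[j]
    h_new[j] <- o[j] * tanh(c_new[j])
  }
  y <- numeric(params$output_dim)
  for (k in seq_len(params$output_dim)) {
    acc <- params$b_y[k]
    for (j in seq_len(nh)) acc <- acc + h_new[j] * params$W_y[j, k]
    y[k] <- tanh(acc)
  }
  list(h = h_new, c = c_new, y = y)
}

random_lstm_params <- function(d, h, o, seed) {
  set.seed(seed)
  mk <- function(nr, nc) matrix(rnorm(nr * nc, sd = 0.5), nr, nc)
  list(W_f = mk(d + h, h), b_f = rnorm(h), W_i = mk(d + h, h), b_i = rnorm(h),
       W_g = mk(d + h, h), b_g = rnorm(h), W_o = mk(d + h, h), b_o = rnorm(h),
       W_y = mk(h, o), b_y = rnorm(o),
       input_dim = d, hidden = h, output_dim = o)
}

# Tiny sinusoidal gait-like angular series for fast LSTM tests.
make_training_angles <- function(n_sub = 2, seed = 31, n = 400) {
  fs <- 56.35
  lapply(seq_len(n_sub), function(s) {
    set.seed(seed + s)
    t <- (1:n) / fs
    th <- 60 + 15 * sin(2 * pi * 0.9 * t + s / 10)
    structure(list(theta_L = th, theta_R = 60 + 15 * sin(2 * pi * 0.9 * t + pi),
                   phi_L = 40 + 25 * sin(2 * pi * 0.9 * t - 0.5),
                   phi_R = 40 + 25 * sin(2 * pi * 0.9 * t + pi - 0.5),
                   omega_TL = 15 * 2 * pi * 0.9 * cos(2 * pi * 0.9 * t + s / 10),
                   omega_TR = 15 * 2 * pi * 0.9 * cos(2 * pi * 0.9 * t + pi),
                   fs = fs, labels = rep(1L, n), participant_id = paste0("A", s)),
              class = "angular_series")
  })
}

# Hand-built 1-D/2-class GMM bank for classifier tests.
make_gauss_bank <- function(means, sds, window = 20L,
                            classes = paste0("c", seq_along(means))) {
  models <- Map(function(m, s) {
    structure(list(weights = 1, means = matrix(m, 1, 1),
                   covs = list(matrix(s^2, 1, 1)),
                   loglik_trace = numeric(0), reg = 0),
              class = "gmm")
  }, means, sds)
  names(models) <- classes
  gmm_bank("sitting_standing_moving", models, window = window)
}
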
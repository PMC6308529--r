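test_that("the cell's fixed points match the gate algebra", {
  # all-zero parameters: sigma(0)=0.5, tanh(0)=0 force y = 0
  p <- random_lstm_params(3, 4, 2, seed = 1)
  for (nm in gaitinfer:::PARAM_NAMES) p[[nm]] <- p[[nm]] * 0
  st <- lstm_cell_step(p, rnorm(3), rep(0, 4), rep(0, 4))
  expect_equal(st$y, rep(0, 2))
  expect_equal(st$h, rep(0, 4))
  expect_equal(st$c, rep(0, 4))
  # saturated-negative forget bias: the old state is fully forgotten
  p2 <- random_lstm_params(3, 4, 2, seed = 2)
  p2$W_f <- p2$W_f * 0
  p2$b_f <- rep(-50, 4)
  x <- rnorm(3)
  a <- lstm_cell_step(p2, x, rep(0, 4), rep(5, 4))
  b <- lstm_cell_step(p2, x, rep(0, 4), rep(-7, 4))
  expect_equal(a$c, b$c, tolerance = 1e-12)
})

test_that("the cell equals an independent equation-by-equation oracle", {
  for (h in 1:5) {
    p <- random_lstm_params(4, h, 2, seed = 100 + h)
    set.seed(200 + h)
    x <- rnorm(4); hh <- rnorm(h); cc <- rnorm(h)
    got <- lstm_cell_step(p, x, hh, cc)
    want <- oracle_lstm_step(p, x, hh, cc)
    expect_equal(got$h, want$h, tolerance = 1e-12)
    expect_equal(got$c, want$c, tolerance = 1e-12)
    expect_equal(got$y, want$y, tolerance = 1e-12)
  }
})

test_that("batched chunk forward agrees with repeated single steps", {
  p <- random_lstm_params(4, 6, 2, seed = 5)
  set.seed(6)
  Tn <- 7; B <- 3
  X <- lapply(1:Tn, function(t) matrix(rnorm(B * 4), B, 4))
  fw <- gaitinfer:::lstm_forward_chunks(p, X)
  for (b in 1:B) {
    h <- rep(0, 6); c <- rep(0, 6)
    for (t in 1:Tn) {
      st <- lstm_cell_step(p, X[[t]][b, ], h, c)
      h <- st$h; c <- st$c
      expect_equal(unname(fw$cache[[t]]$y[b, ]), st$y, tolerance = 1e-12)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  p <- random_lstm_params(2, 3, 2, seed = 7)
  set.seed(8)
  Tn <- 5; B <- 4
  X <- lapply(1:Tn, function(t) matrix(rnorm(B * 2), B, 2))
  Y <- lapply(1:Tn, function(t) matrix(tanh(rnorm(B * 2)), B, 2))
  fw <- gaitinfer:::lstm_forward_chunks(p, X, Y)
  gr <- gaitinfer:::lstm_backward_chunks(p, X, Y, fw)
  eps <- 1e-5
  for (nm in c("W_f", "b_i", "W_g", "b_o", "W_y", "b_y")) {
    v <- p[[nm]]
    idx <- sample(length(v), min(4, length(v)))
    for (i in idx) {
      pp <- p; pp[[nm]][i] <- v[i] + eps
      lp <- gaitinfer:::lstm_forward_chunks(pp, X, Y)$loss
      pm <- p; pm[[nm]][i] <- v[i] - eps
      lm <- gaitinfer:::lstm_forward_chunks(pm, X, Y)$loss
      num <- (lp - lm) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-6)
    }
  }
})

test_that("training is deterministic and its loss decreases", {
  angs <- make_training_angles()
  m1 <- train_gait_model(angs, hidden = 8, max_epochs = 15, patience = 15,
                         seed = 4)
  m2 <- train_gait_model(angs, hidden = 8, max_epochs = 15, patience = 15,
                         seed = 4)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  # full-batch training loss is non-increasing apart from small wobble
  m3 <- train_gait_model(angs[1], hidden = 8, max_epochs = 25, patience = 25,
                         batch_size = 1e6, lr = 5e-3, seed = 4)
  expect_lt(tail(m3$loss_trace, 1), m3$loss_trace[1])
  expect_true(all(diff(m3$loss_trace) < 0.02 * m3$loss_trace[1] + 1e-8))
})

test_that("a constant shank target is reproduced within half a degree", {
  angs <- make_training_angles(n_sub = 1, n = 360)
  angs[[1]]$phi_L <- rep(33, 360)
  angs[[1]]$phi_R <- rep(33, 360)
  m <- train_gait_model(angs, hidden = 6, max_epochs = 40, patience = 40,
                        lr = 5e-3, seed = 2)
  pred <- predict_gait(m, angs[[1]])
  expect_lt(max(abs(pred - 33)), 0.5)
})

test_that("streaming prediction equals whole-sequence prediction", {
  angs <- make_training_angles()
  m <- train_gait_model(angs, hidden = 8, max_epochs = 10, patience = 10,
                        seed = 6)
  feats <- gaitinfer:::gait_feature_matrix(angs[[1]])[1:120, ]
  batch <- predict_gait(m, feats)
  pr <- gait_predictor(m)
  one_by_one <- do.call(rbind, lapply(seq_len(nrow(feats)), function(t)
    predict_frames(pr, feats[t, , drop = FALSE])))
  expect_equal(one_by_one, batch, tolerance = 1e-12)
  # reset and replay reproduces the original outputs
  reset_state(pr)
  replay <- predict_frames(pr, feats)
  expect_equal(replay, batch, tolerance = 1e-12)
  # scaled-space emissions stay strictly inside (-1, 1)
  sc <- gaitinfer:::scale_angles(batch, m$angle_scale)
  expect_true(all(abs(sc) < 1))
})

test_that("predictions are causal: future frames cannot change the past", {
  angs <- make_training_angles()
  m <- train_gait_model(angs, hidden = 8, max_epochs = 10, patience = 10,
                        seed = 6)
  feats <- gaitinfer:::gait_feature_matrix(angs[[1]])[1:80, ]
  base <- predict_gait(m, feats)
  set.seed(12)
  perturbed <- feats
  perturbed[61:80, ] <- perturbed[61:80, ] + rnorm(20 * 4, sd = 5)
  alt <- predict_gait(m, perturbed)
  expect_equal(alt[1:60, ], base[1:60, ], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(alt[61:80, ], base[61:80, ])))
})

test_that("gait models survive JSON serialization", {
  angs <- make_training_angles()
  m <- train_gait_model(angs, hidden = 8, max_epochs = 8, patience = 8,
                        seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_gait_model(m, path)
  back <- read_gait_model(path)
  feats <- gaitinfer:::gait_feature_matrix(angs[[2]])[1:60, ]
  expect_equal(predict_gait(back, feats), predict_gait(m, feats),
               tolerance = 1e-12)
  expect_equal(back$chunk_length, m$chunk_length)
})
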
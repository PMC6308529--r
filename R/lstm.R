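#' @title LSTM shank-angle regression
#'
#' @description
#' The gait-inference model is a single-hidden-layer recurrent network of
#' LSTM cells that maps, frame by frame, the four thigh features (left and
#' right thigh angle and angular speed) to the two shank angles. The cell
#' follows the standard gate equations: forget gate
#' `f = sigma(W_f [v_t, h_{t-1}] + b_f)`, input gate
#' `i = sigma(W_i [v_t, h_{t-1}] + b_i)`, input modulation
#' `g = tanh(W_g [v_t, h_{t-1}] + b_g)`, state update
#' `c_t = f * c_{t-1} + i * g`, output gate
#' `o = sigma(W_o [v_t, h_{t-1}] + b_o)`, hidden update
#' `h_t = o * tanh(c_t)`, and emission `y_t = tanh(W_y h_t + b_y)`
#' (element-wise products throughout). Training minimizes the mean squared
#' error between `y_t` and the scaled true shank angles over non-overlapping
#' 15-frame chunks, by backpropagation through the chunk.
#'
#' @name lstm
NULL

# Weight matrices are stored (input_dim + hidden) x hidden so a batch of
# concatenated [v_t, h_{t-1}] rows multiplies on the left: z %*% W + b.
init_lstm_params <- function(input_dim = 4L, hidden = 50L, output_dim = 2L,
                             seed = 1L) {
  d <- input_dim; h <- hidden; o <- output_dim
  r <- sqrt(6 / (d + 2 * h))
  ry <- sqrt(6 / (h + o))
  with_local_seed(seed, {
    mk <- function(nr, nc, rr) matrix(stats::runif(nr * nc, -rr, rr), nr, nc)
    list(W_f = mk(d + h, h, r), b_f = rep(1, h),   # forget bias starts open
         W_i = mk(d + h, h, r), b_i = rep(0, h),
         W_g = mk(d + h, h, r), b_g = rep(0, h),
         W_o = mk(d + h, h, r), b_o = rep(0, h),
         W_y = mk(h, o, ry),    b_y = rep(0, o),
         input_dim = d, hidden = h, output_dim = o)
  })
}

#' One LSTM cell step
#'
#' Evaluates the gate equations for a single frame: given the input vector
#' `x`, previous hidden vector `h` and previous state vector `c`, returns
#' the new hidden and state vectors and the emission `y`.
#'
#' @param params LSTM parameter list (fields `W_f`, `b_f`, `W_i`, `b_i`,
#'   `W_g`, `b_g`, `W_o`, `b_o`, `W_y`, `b_y`, `input_dim`, `hidden`,
#'   `output_dim`).
#' @param x Input vector of length `input_dim`.
#' @param h Hidden vector of length `hidden`.
#' @param c State vector of length `hidden`.
#' @return List with `h`, `c` (updated vectors) and `y` (emission).
#' @export
lstm_cell_step <- function(params, x, h, c) {
  assert_that(length(x) == params$input_dim,
              "input dimension %d does not match the model (%d)",
              length(x), params$input_dim)
  assert_that(length(h) == params$hidden && length(c) == params$hidden,
              "hidden/state dimension does not match the model")
  z <- c(x, h)
  f <- sigmoid(drop(z %*% params$W_f) + params$b_f)
  i <- sigmoid(drop(z %*% params$W_i) + params$b_i)
  g <- tanh(drop(z %*% params$W_g) + params$b_g)
  c_new <- f * c + i * g
  o <- sigmoid(drop(z %*% params$W_o) + params$b_o)
  h_new <- o * tanh(c_new)
  y <- tanh(drop(h_new %*% params$W_y) + params$b_y)
  list(h = h_new, c = c_new, y = y)
}

# Batched forward over a chunk tensor: X and Y are lists of length T with
# (B x d) / (B x o) matrices. Returns loss, per-step caches for backprop.
lstm_forward_chunks <- function(params, X, Y = NULL) {
  Tn <- length(X); B <- nrow(X[[1L]])
  h <- matrix(0, B, params$hidden); c <- matrix(0, B, params$hidden)
  cache <- vector("list", Tn)
  preds <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    z <- cbind(X[[t]], h)
    f <- sigmoid(sweep(z %*% params$W_f, 2L, params$b_f, "+"))
    i <- sigmoid(sweep(z %*% params$W_i, 2L, params$b_i, "+"))
    g <- tanh(sweep(z %*% params$W_g, 2L, params$b_g, "+"))
    o <- sigmoid(sweep(z %*% params$W_o, 2L, params$b_o, "+"))
    c_prev <- c
    c <- f * c_prev + i * g
    hc <- tanh(c)
    h <- o * hc
    y <- tanh(sweep(h %*% params$W_y, 2L, params$b_y, "+"))
    cache[[t]] <- list(z = z, f = f, i = i, g = g, o = o,
                       c_prev = c_prev, c = c, hc = hc, h = h, y = y)
    preds[[t]] <- y
  }
  loss <- NA_real_
  if (!is.null(Y)) {
    se <- 0
    for (t in seq_len(Tn)) se <- se + sum((preds[[t]] - Y[[t]])^2)
    loss <- se / (B * Tn * params$output_dim)
  }
  list(loss = loss, cache = cache, preds = preds)
}

# Backprop through the chunk; returns gradients named like the parameters.
lstm_backward_chunks <- function(params, X, Y, fw) {
  Tn <- length(X); B <- nrow(X[[1L]])
  d <- params$input_dim; h_n <- params$hidden
  norm <- B * Tn * params$output_dim
  g0m <- function(w) matrix(0, nrow(w), ncol(w))
  grads <- list(W_f = g0m(params$W_f), b_f = rep(0, h_n),
                W_i = g0m(params$W_i), b_i = rep(0, h_n),
                W_g = g0m(params$W_g), b_g = rep(0, h_n),
                W_o = g0m(params$W_o), b_o = rep(0, h_n),
                W_y = g0m(params$W_y), b_y = rep(0, params$output_dim))
  dh_next <- matrix(0, B, h_n); dc_next <- matrix(0, B, h_n)
  for (t in rev(seq_len(Tn))) {
    cc <- fw$cache[[t]]
    dy <- 2 * (cc$y - Y[[t]]) / norm
    da_y <- dy * (1 - cc$y^2)
    grads$W_y <- grads$W_y + crossprod(cc$h, da_y)
    grads$b_y <- grads$b_y + colSums(da_y)
    dh <- tcrossprod(da_y, params$W_y) + dh_next
    do_ <- dh * cc$hc
    dc <- dc_next + dh * cc$o * (1 - cc$hc^2)
    df <- dc * cc$c_prev
    di <- dc * cc$g
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    da_f <- df * cc$f * (1 - cc$f)
    da_i <- di * cc$i * (1 - cc$i)
    da_g <- dg * (1 - cc$g^2)
    da_o <- do_ * cc$o * (1 - cc$o)
    grads$W_f <- grads$W_f + crossprod(cc$z, da_f)
    grads$b_f <- grads$b_f + colSums(da_f)
    grads$W_i <- grads$W_i + crossprod(cc$z, da_i)
    grads$b_i <- grads$b_i + colSums(da_i)
    grads$W_g <- grads$W_g + crossprod(cc$z, da_g)
    grads$b_g <- grads$b_g + colSums(da_g)
    grads$W_o <- grads$W_o + crossprod(cc$z, da_o)
    grads$b_o <- grads$b_o + colSums(da_o)
    dz <- tcrossprod(da_f, params$W_f) + tcrossprod(da_i, params$W_i) +
      tcrossprod(da_g, params$W_g) + tcrossprod(da_o, params$W_o)
    dh_next <- dz[, (d + 1L):(d + h_n), drop = FALSE]
  }
  grads
}

PARAM_NAMES <- c("W_f", "b_f", "W_i", "b_i", "W_g", "b_g", "W_o", "b_o",
                 "W_y", "b_y")

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (nm in PARAM_NAMES) {
    st$m[[nm]] <- params[[nm]] * 0
    st$v[[nm]] <- params[[nm]] * 0
  }
  st
}

adam_update <- function(params, grads, st, lr = 1e-3, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in PARAM_NAMES) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = st)
}

# Cut contiguous frame runs into non-overlapping chunks of `chunk` frames
# and stack them as lists of per-step (B x k) matrices.
stack_chunks <- function(feat, tgt, runs, chunk) {
  starts <- integer(0)
  run_of <- integer(0)
  for (r in seq_len(nrow(runs))) {
    s <- runs[r, 1L]; e <- runs[r, 2L]
    n_ch <- (e - s + 1L) %/% chunk
    if (n_ch > 0L) starts <- c(starts, s + chunk * (seq_len(n_ch) - 1L))
  }
  if (length(starts) == 0L) return(NULL)
  X <- vector("list", chunk); Y <- vector("list", chunk)
  for (t in seq_len(chunk)) {
    X[[t]] <- feat[starts + t - 1L, , drop = FALSE]
    Y[[t]] <- tgt[starts + t - 1L, , drop = FALSE]
  }
  list(X = X, Y = Y, n_chunks = length(starts))
}

# Linear degree <-> scaled (-1, 1) map for the tanh output, fitted on the
# training shank-angle range expanded by a 10% margin (tanh cannot reach
# its endpoints, so the margin keeps training targets away from +/-1).
fit_angle_scale <- function(tgt_deg, margin = 0.1) {
  lo <- apply(tgt_deg, 2L, min); hi <- apply(tgt_deg, 2L, max)
  center <- (lo + hi) / 2
  half <- pmax((hi - lo) / 2 * (1 + margin), 1e-3)
  list(center = center, half = half)
}

scale_angles <- function(deg, sc) sweep(sweep(deg, 2L, sc$center), 2L, sc$half, "/")
unscale_angles <- function(y, sc) sweep(sweep(y, 2L, sc$half, "*"), 2L, sc$center, "+")

# Gait feature matrix (unscaled, degrees and deg/s) from an angular_series.
gait_feature_matrix <- function(a) {
  cbind(theta_L = a$theta_L, theta_R = a$theta_R,
        omega_TL = a$omega_TL, omega_TR = a$omega_TR)
}

gait_target_matrix <- function(a) {
  assert_that(!is.null(a$phi_L) && !is.null(a$phi_R),
              "angular series has no shank angles (training needs them)")
  cbind(phi_L = a$phi_L, phi_R = a$phi_R)
}

# Frame runs used for gait training/evaluation: contiguous stretches of
# walking-related or standing labels (all frames when unlabeled).
gait_frame_runs <- function(labels, min_len = 1L) {
  if (is.null(labels) || all(labels == 0L))
    return(cbind(start = 1L, end = length(labels)))
  ok <- activity_name(labels) %in% GAIT_ACTIVITIES
  runs <- true_runs(ok)
  runs[runs[, 2L] - runs[, 1L] + 1L >= min_len, , drop = FALSE]
}

#' Train the LSTM gait-inference model
#'
#' Builds the four thigh features and two shank-angle targets for each
#' training participant, min-max-scales features to \[0, 1\] and targets
#' linearly to (-1, 1) (bounds fitted on the training split only and
#' persisted with the model), cuts contiguous gait frames into
#' non-overlapping chunks of `chunk_length` frames with hidden state reset
#' per chunk, and minimizes the mean squared error of the emissions by
#' full-batch adaptive-moment gradient descent with backpropagation through
#' the chunk. One training participant (the last) is held out for early
#' stopping when at least two are supplied. Deterministic for a given seed.
#'
#' @param train List of `angular_series` (one per training participant)
#'   with shank angles present.
#' @param hidden Number of LSTM units (default 50).
#' @param chunk_length Chunk length in frames (default 15).
#' @param lr Adam learning rate (default 1e-3).
#' @param max_epochs Epoch cap (default 200).
#' @param patience Early-stopping patience in epochs (default 10).
#' @param batch_size Minibatch size in chunks (default 64; shuffled each
#'   epoch from the seeded stream, so training is reproducible).
#' @param seed Integer seed for parameter initialization.
#' @param verbose Print per-epoch losses.
#' @return Object of class `gait_model`: `params`, `feature_scaling`,
#'   `angle_scale`, `chunk_length`, `loss_trace` (training MSE per epoch,
#'   scaled space), `val_trace`, `seed`.
#' @export
train_gait_model <- function(train, hidden = 50L, chunk_length = 15L,
                             lr = 1e-3, max_epochs = 200L, patience = 10L,
                             batch_size = 64L, seed = 1L, verbose = FALSE) {
  assert_that(length(train) >= 1L, "need at least one training sequence")
  for (a in train) stopifnot(inherits(a, "angular_series"))

  feats <- lapply(train, gait_feature_matrix)
  tgts <- lapply(train, gait_target_matrix)
  runs <- lapply(train, function(a) gait_frame_runs(a$labels,
                                                    min_len = chunk_length))
  used <- function(m, rs) do.call(rbind, lapply(seq_len(nrow(rs)), function(r)
    m[rs[r, 1L]:rs[r, 2L], , drop = FALSE]))
  pooled_f <- do.call(rbind, Map(used, feats, runs))
  pooled_t <- do.call(rbind, Map(used, tgts, runs))
  assert_that(nrow(pooled_f) >= chunk_length,
              "no contiguous gait segment of at least %d frames", chunk_length)
  fscale <- fit_feature_scaling(pooled_f)
  ascale <- fit_angle_scale(pooled_t)

  sets <- Map(function(f, tg, rs) stack_chunks(
    apply_feature_scaling(f, fscale), scale_angles(tg, ascale), rs,
    chunk_length), feats, tgts, runs)
  sets <- sets[!vapply(sets, is.null, logical(1))]
  assert_that(length(sets) >= 1L, "no training sequence is long enough")

  if (length(sets) >= 2L) {
    val <- sets[[length(sets)]]
    trn <- sets[-length(sets)]
  } else {
    val <- NULL
    trn <- sets
  }
  bindt <- function(lst, fld) {
    Tn <- length(lst[[1L]][[fld]])
    lapply(seq_len(Tn), function(t)
      do.call(rbind, lapply(lst, function(s) s[[fld]][[t]])))
  }
  Xtr <- bindt(trn, "X"); Ytr <- bindt(trn, "Y")

  n_chunks <- nrow(Xtr[[1L]])
  bs <- min(batch_size, n_chunks)
  slice <- function(lst, idx) lapply(lst, function(m) m[idx, , drop = FALSE])

  params <- init_lstm_params(4L, hidden, 2L, seed = seed)
  opt <- adam_init(params)
  best <- params; best_val <- Inf; best_epoch <- 0L
  loss_trace <- numeric(0); val_trace <- numeric(0)
  with_local_seed(seed + 1L, for (epoch in seq_len(max_epochs)) {
    perm <- if (bs < n_chunks) sample.int(n_chunks) else seq_len(n_chunks)
    ep_loss <- 0; nb <- 0L
    for (b0 in seq(1L, n_chunks, by = bs)) {
      idx <- perm[b0:min(b0 + bs - 1L, n_chunks)]
      Xb <- slice(Xtr, idx); Yb <- slice(Ytr, idx)
      fw <- lstm_forward_chunks(params, Xb, Yb)
      gr <- lstm_backward_chunks(params, Xb, Yb, fw)
      up <- adam_update(params, gr, opt, lr = lr)
      params <- up$params; opt <- up$state
      ep_loss <- ep_loss + fw$loss * length(idx); nb <- nb + length(idx)
    }
    loss_trace <- c(loss_trace, ep_loss / nb)
    vl <- if (is.null(val)) ep_loss / nb
          else lstm_forward_chunks(params, val$X, val$Y)$loss
    val_trace <- c(val_trace, vl)
    if (verbose) message(sprintf("epoch %3d train %.6f val %.6f",
                                 epoch, ep_loss / nb, vl))
    if (vl < best_val - 1e-9) {
      best_val <- vl; best <- params; best_epoch <- epoch
    } else if (epoch - best_epoch >= patience) break
  })
  structure(list(params = best, feature_scaling = fscale,
                 angle_scale = ascale, chunk_length = as.integer(chunk_length),
                 loss_trace = loss_trace, val_trace = val_trace,
                 seed = as.integer(seed)),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat(sprintf("<gait_model> %d LSTM units, chunk %d, %d training epochs\n",
              x$params$hidden, x$chunk_length, length(x$loss_trace)))
  invisible(x)
}

#' Create a streaming gait predictor
#'
#' The predictor carries the LSTM hidden and state vectors across calls, so
#' frames can be fed one at a time (or in arbitrary batches) and each
#' prediction is emitted causally, before the next frame is read. Feeding a
#' sequence whole or frame-by-frame yields identical outputs;
#' [reset_state()] returns the predictor to its initial state.
#'
#' @param model A [train_gait_model()] fit.
#' @return Object of class `gait_predictor`.
#' @export
gait_predictor <- function(model) {
  stopifnot(inherits(model, "gait_model"))
  env <- new.env(parent = emptyenv())
  env$model <- model
  env$h <- rep(0, model$params$hidden)
  env$c <- rep(0, model$params$hidden)
  structure(env, class = "gait_predictor")
}

#' Reset a streaming predictor's recurrent state
#'
#' @param predictor A [gait_predictor()].
#' @return The predictor, invisibly.
#' @export
reset_state <- function(predictor) {
  stopifnot(inherits(predictor, "gait_predictor"))
  predictor$h <- rep(0, predictor$model$params$hidden)
  predictor$c <- rep(0, predictor$model$params$hidden)
  invisible(predictor)
}

#' Predict shank angles for incoming frames
#'
#' Runs the LSTM one frame at a time over the supplied gait features
#' (thigh angles in degrees and angular speeds in degrees/s, columns
#' `theta_L`, `theta_R`, `omega_TL`, `omega_TR`), applying the model's
#' stored feature scaling, and returns the predicted shank angles mapped
#' back to degrees. Strictly causal: the prediction at frame `t` depends
#' only on frames up to `t`.
#'
#' @param predictor A [gait_predictor()] (state is carried across calls).
#' @param frames Matrix or data frame of feature frames, or an
#'   `angular_series`.
#' @return Matrix with columns `phi_L`, `phi_R` (degrees), one row per
#'   input frame.
#' @export
predict_frames <- function(predictor, frames) {
  stopifnot(inherits(predictor, "gait_predictor"))
  model <- predictor$model
  if (inherits(frames, "angular_series")) frames <- gait_feature_matrix(frames)
  frames <- as.matrix(frames)
  assert_that(ncol(frames) == model$params$input_dim,
              "feature dimension %d does not match the model (%d)",
              ncol(frames), model$params$input_dim)
  colnames(frames) <- model$feature_scaling$columns
  Xs <- apply_feature_scaling(frames, model$feature_scaling)
  out <- matrix(NA_real_, nrow(frames), 2L,
                dimnames = list(NULL, c("phi_L", "phi_R")))
  for (t in seq_len(nrow(Xs))) {
    st <- lstm_cell_step(model$params, Xs[t, ], predictor$h, predictor$c)
    predictor$h <- st$h
    predictor$c <- st$c
    out[t, ] <- st$y
  }
  unscale_angles(out, model$angle_scale)
}

#' Batch prediction from a fresh state
#'
#' Convenience wrapper: creates a fresh [gait_predictor()] and feeds the
#' whole series; equivalent to streaming the frames one at a time.
#'
#' @param model A [train_gait_model()] fit.
#' @param newdata An `angular_series` or feature matrix (see
#'   [predict_frames()]).
#' @return Matrix with columns `phi_L`, `phi_R` in degrees.
#' @export
predict_gait <- function(model, newdata) {
  predict_frames(gait_predictor(model), newdata)
}

#' Serialize a gait model to portable JSON text
#'
#' @param model A `gait_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gait_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  p <- model$params
  obj <- list(
    hidden = p$hidden, input_dim = p$input_dim, output_dim = p$output_dim,
    chunk_length = model$chunk_length, seed = model$seed,
    params = lapply(p[PARAM_NAMES], identity),
    feature_scaling = list(min = model$feature_scaling$min,
                           max = model$feature_scaling$max,
                           columns = model$feature_scaling$columns),
    angle_scale = model$angle_scale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gait model written by [write_gait_model()]
#'
#' @param path File path.
#' @return A `gait_model`.
#' @export
read_gait_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  d <- obj$input_dim; h <- obj$hidden; o <- obj$output_dim
  shape <- list(W_f = c(d + h, h), b_f = h, W_i = c(d + h, h), b_i = h,
                W_g = c(d + h, h), b_g = h, W_o = c(d + h, h), b_o = h,
                W_y = c(h, o), b_y = o)
  params <- list(input_dim = d, hidden = h, output_dim = o)
  for (nm in PARAM_NAMES) {
    v <- obj$params[[nm]]
    sh <- shape[[nm]]
    params[[nm]] <- if (length(sh) == 2L) matrix(unlist(v), sh[1L], sh[2L])
                    else as.numeric(unlist(v))
  }
  structure(list(
    params = params,
    feature_scaling = structure(list(min = unlist(obj$feature_scaling$min),
                                     max = unlist(obj$feature_scaling$max),
                                     columns = obj$feature_scaling$columns),
                                class = "feature_scaling"),
    angle_scale = list(center = unlist(obj$angle_scale$center),
                       half = unlist(obj$angle_scale$half)),
    chunk_length = obj$chunk_length, loss_trace = numeric(0),
    val_trace = numeric(0), seed = obj$seed),
    class = "gait_model")
}
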
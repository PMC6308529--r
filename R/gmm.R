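#' Fit a Gaussian mixture by expectation-maximization
#'
#' Full-covariance mixture fitted by EM with k-means initialization,
#' ridge-regularized covariances (`reg * I` added after every M-step), and
#' convergence when the mean log-likelihood gain drops below `tol` or
#' `max_iter` iterations are reached. The per-iteration log-likelihood
#' trace is non-decreasing (up to the regularizer) and is returned for
#' inspection.
#'
#' @param X Numeric matrix (rows = observations, columns = features) or
#'   vector (treated as one column).
#' @param n_components Number of mixture components.
#' @param seed Integer seed for the k-means initialization.
#' @param reg Covariance ridge (default 1e-6).
#' @param tol Log-likelihood convergence tolerance (default 1e-4).
#' @param max_iter Maximum EM iterations (default 200).
#' @return Object of class `gmm`: `weights`, `means` (components x
#'   features), `covs` (list of covariance matrices), `loglik_trace`.
#' @export
fit_gmm <- function(X, n_components, seed = 1L, reg = 1e-6, tol = 1e-4,
                    max_iter = 200L) {
  if (is.vector(X)) X <- matrix(X, ncol = 1L)
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  assert_that(all(is.finite(X)), "features must be finite")
  assert_that(n_components >= 1L && n_components <= n,
              "n_components (%d) must be between 1 and nrow(X) (%d)",
              n_components, n)
  k <- as.integer(n_components)

  if (k == 1L) {
    member <- rep(1L, n)
  } else {
    km <- with_local_seed(seed, tryCatch(
      stats::kmeans(X, centers = k, nstart = 5L, iter.max = 50L),
      error = function(e) NULL))
    if (is.null(km)) stop_gi("k-means initialization failed (degenerate data?)")
    member <- km$cluster
  }

  resp <- matrix(0, n, k)
  resp[cbind(seq_len(n), member)] <- 1
  weights <- numeric(k); means <- matrix(0, k, d); covs <- vector("list", k)

  m_step <- function(resp) {
    nk <- colSums(resp)
    for (j in seq_len(k)) {
      if (nk[j] < .Machine$double.eps)
        stop_gi("component %d collapsed to zero weight", j)
      mu <- colSums(resp[, j] * X) / nk[j]
      Xc <- sweep(X, 2L, mu)
      S <- crossprod(Xc * resp[, j], Xc) / nk[j] + diag(reg, d)
      weights[j] <<- nk[j] / n
      means[j, ] <<- mu
      covs[[j]] <<- S
    }
  }
  m_step(resp)

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    lw <- matrix(0, n, k)
    for (j in seq_len(k))
      lw[, j] <- log(weights[j]) + dmvnorm_log(X, means[j, ], covs[[j]])
    ll_rows <- row_log_sum_exp(lw)
    ll <- mean(ll_rows)
    trace <- c(trace, ll)
    if (iter > 1L && (ll - trace[iter - 1L]) < tol) break
    resp <- exp(lw - ll_rows)
    m_step(resp)
  }
  structure(list(weights = weights, means = means, covs = covs,
                 loglik_trace = trace, reg = reg),
            class = "gmm")
}

# Log-density of rows of X under a multivariate normal, via Cholesky.
dmvnorm_log <- function(X, mean, cov) {
  if (is.vector(X)) X <- matrix(X, ncol = length(mean))
  d <- length(mean)
  R <- tryCatch(chol(cov), error = function(e)
    stop_gi("singular covariance despite regularization"))
  z <- backsolve(R, t(sweep(X, 2L, mean)), transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * d * log(2 * pi)
}

#' Log-density of observations under a fitted mixture
#'
#' Computed in the log domain (log-sum-exp over components) for numerical
#' safety in the tails.
#'
#' @param model A [fit_gmm()] result.
#' @param X Observation matrix or single vector.
#' @return Vector of per-row log-densities.
#' @export
gmm_loglik <- function(model, X) {
  stopifnot(inherits(model, "gmm"))
  d <- ncol(model$means)
  if (is.vector(X)) X <- matrix(X, ncol = d, byrow = FALSE)
  assert_that(ncol(X) == d, "feature dimension %d does not match model (%d)",
              ncol(X), d)
  k <- length(model$weights)
  lw <- matrix(0, nrow(X), k)
  for (j in seq_len(k))
    lw[, j] <- log(model$weights[j]) + dmvnorm_log(X, model$means[j, ],
                                                   model$covs[[j]])
  if (k == 1L) drop(lw) else row_log_sum_exp(lw)
}

#' Construct a recognition model bank
#'
#' A bank holds one fitted mixture per activity class for one recognition
#' module, the context-window length, the feature scaling of the module,
#' and (for intention modules) the calibrated decision threshold.
#'
#' @param module_kind `"standing_up"`, `"sitting_down"` or
#'   `"sitting_standing_moving"`.
#' @param models Named list of `gmm` objects (fixed class order; first name
#'   wins ties).
#' @param window Context-window length in frames (default 20).
#' @param scaling `feature_scaling` used to build the module's features.
#' @param threshold Log-likelihood-ratio decision threshold for the
#'   module's intention class (`NA` until calibrated; not used by the
#'   sitting/standing/moving module).
#' @param intention_class Name of the thresholded class, if any.
#' @return Object of class `gmm_bank`.
#' @export
gmm_bank <- function(module_kind, models, window = 20L, scaling = NULL,
                     threshold = NA_real_, intention_class = NULL) {
  assert_that(module_kind %in% c("standing_up", "sitting_down",
                                 "sitting_standing_moving"),
              "unknown module kind: %s", module_kind)
  assert_that(is.list(models) && !is.null(names(models)),
              "models must be a named list of gmm fits")
  for (m in models) stopifnot(inherits(m, "gmm"))
  structure(list(module_kind = module_kind, classes = names(models),
                 models = models, window = as.integer(window),
                 scaling = scaling, threshold = threshold,
                 intention_class = intention_class),
            class = "gmm_bank")
}

#' Per-class log-density of one feature vector
#'
#' @param bank A [gmm_bank()].
#' @param class Class name present in the bank.
#' @param v Feature vector (or matrix of rows).
#' @return Log mixture density (vector for matrix input).
#' @export
class_loglik <- function(bank, class, v) {
  stopifnot(inherits(bank, "gmm_bank"))
  assert_that(class %in% bank$classes, "unknown class: %s", class)
  gmm_loglik(bank$models[[class]], v)
}

#' Classify a context window of feature vectors
#'
#' The context-window decision rule: the predicted class maximizes the
#' product over the window of per-frame class-conditional mixture
#' densities (equivalently, the sum of log-densities; uniform class
#' prior). Windows shorter than the bank's length are allowed at sequence
#' start. Ties break by the bank's fixed class order.
#'
#' @param bank A [gmm_bank()].
#' @param window Matrix whose rows are the last (up to `bank$window`)
#'   feature vectors, oldest first.
#' @return List with `class` (name) and `scores` (named per-class summed
#'   log-likelihoods).
#' @export
classify_window <- function(bank, window) {
  stopifnot(inherits(bank, "gmm_bank"))
  if (is.vector(window)) window <- matrix(window, nrow = 1L)
  assert_that(nrow(window) >= 1L, "empty context window")
  assert_that(nrow(window) <= bank$window,
              "window of %d frames exceeds the bank's context length (%d)",
              nrow(window), bank$window)
  scores <- vapply(bank$classes,
                   function(cl) sum(class_loglik(bank, cl, window)),
                   numeric(1))
  list(class = bank$classes[which.max(scores)], scores = scores)
}

#' Classify every frame of a feature stream
#'
#' Applies the context-window rule at each frame `t` over frames
#' `max(1, t - window + 1) .. t` using rolling sums of per-frame
#' log-densities, so a whole recording is scored in one pass. Also returns
#' the intention log-likelihood-ratio trace (intention score minus the
#' best competing score) when the bank has an intention class.
#'
#' @param bank A [gmm_bank()].
#' @param features Matrix or `feature_table` of per-frame feature vectors.
#' @return List with `class` (per-frame predicted class), `scores`
#'   (frames x classes summed log-likelihoods), `llr` (per-frame intention
#'   log-likelihood ratio, or `NULL`), and `decision` (per-frame logical,
#'   `llr >= threshold`, or `NULL` when no threshold is set).
#' @export
classify_stream <- function(bank, features) {
  stopifnot(inherits(bank, "gmm_bank"))
  X <- as.matrix(features)
  n <- nrow(X)
  scores <- matrix(0, n, length(bank$classes),
                   dimnames = list(NULL, bank$classes))
  for (cl in bank$classes)
    scores[, cl] <- rolling_sum(class_loglik(bank, cl, X), bank$window)
  pred <- bank$classes[max.col(scores, ties.method = "first")]
  llr <- NULL; decision <- NULL
  if (!is.null(bank$intention_class)) {
    ic <- bank$intention_class
    others <- scores[, setdiff(bank$classes, ic), drop = FALSE]
    llr <- scores[, ic] - apply(others, 1L, max)
    if (!is.na(bank$threshold)) decision <- llr >= bank$threshold
  }
  list(class = pred, scores = scores, llr = llr, decision = decision)
}

# Event-level confusion for intention detection: a true span is detected
# (one TP) if any positive frame falls inside it; each maximal positive run
# entirely outside all true spans is one FP.
event_confusion <- function(positive, spans) {
  n <- length(positive)
  in_span <- rep(FALSE, n)
  tp <- 0L; fn <- 0L
  if (length(spans) > 0L) {
    for (sp in spans) {
      idx <- seq.int(max(1L, sp[1L]), min(n, sp[2L]))
      in_span[idx] <- TRUE
      if (any(positive[idx])) tp <- tp + 1L else fn <- fn + 1L
    }
  }
  runs <- true_runs(positive)
  fp <- 0L
  if (nrow(runs) > 0L)
    for (r in seq_len(nrow(runs)))
      if (!any(in_span[runs[r, 1L]:runs[r, 2L]])) fp <- fp + 1L
  list(tp = tp, fp = fp, fn = fn)
}

#' Calibrate the intention decision threshold for a target precision
#'
#' Sweeps candidate thresholds (the midpoints of sorted unique scores) over
#' the calibration traces and returns the smallest threshold whose
#' event-level precision reaches `target_precision` with non-zero recall. A true event counts as detected when any
#' positive frame falls inside its span; every maximal positive run outside
#' all spans counts as one false positive. If no threshold attains the
#' target, `Inf` is returned with a warning (the module then never fires).
#'
#' @param traces List of numeric log-likelihood-ratio traces (one per
#'   calibration recording).
#' @param spans List (parallel to `traces`) of lists of `c(start, end)`
#'   true intention spans in frames.
#' @param target_precision Required event-level precision (default 0.99).
#' @param max_candidates Cap on the number of candidate thresholds; when the
#'   number of unique scores exceeds it, quantile-spaced candidates are used.
#' @return List with `threshold`, `precision`, `recall` achieved on the
#'   calibration data.
#' @export
calibrate_threshold <- function(traces, spans, target_precision = 0.99,
                                max_candidates = 2000L) {
  assert_that(length(traces) > 0L, "empty calibration set")
  assert_that(length(traces) == length(spans),
              "traces and spans must be parallel lists")
  n_pos <- sum(lengths(spans))
  assert_that(n_pos > 0L, "calibration set has no positive event")
  u <- sort(unique(unlist(traces)))
  u <- u[is.finite(u)]
  if (length(u) > max_candidates)
    u <- unique(stats::quantile(u, probs = seq(0, 1, length.out = max_candidates),
                                names = FALSE, type = 1L))
  # candidates are the midpoints of sorted unique scores: a threshold below
  # every score declares the whole trace positive, which trivially attains
  # event precision 1 whenever any span exists, so it is never a candidate
  cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
  eval_thr <- function(thr) {
    tp <- 0L; fp <- 0L; fn <- 0L
    for (i in seq_along(traces)) {
      cm <- event_confusion(traces[[i]] >= thr, spans[[i]])
      tp <- tp + cm$tp; fp <- fp + cm$fp; fn <- fn + cm$fn
    }
    c(prec = if (tp + fp == 0L) 1 else tp / (tp + fp),
      rec = tp / (tp + fn))
  }
  for (thr in cand) {
    pr <- eval_thr(thr)
    if (pr["prec"] >= target_precision && pr["rec"] > 0)
      return(list(threshold = thr, precision = unname(pr["prec"]),
                  recall = unname(pr["rec"])))
  }
  warning("target precision unattainable on the calibration set; ",
          "returning an infinite threshold (recall 0)", call. = FALSE)
  list(threshold = Inf, precision = 1, recall = 0)
}

#' Serialize a model bank to portable JSON text
#'
#' @param bank A [gmm_bank()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmm_bank <- function(bank, path) {
  stopifnot(inherits(bank, "gmm_bank"))
  obj <- list(
    module_kind = bank$module_kind, classes = bank$classes,
    window = bank$window, threshold = bank$threshold,
    intention_class = bank$intention_class,
    scaling = if (!is.null(bank$scaling))
      list(min = as.list(bank$scaling$min), max = as.list(bank$scaling$max),
           columns = bank$scaling$columns),
    models = lapply(bank$models, function(m)
      list(weights = m$weights, means = m$means, covs = m$covs, reg = m$reg)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a model bank written by [write_gmm_bank()]
#'
#' @param path File path.
#' @return A [gmm_bank()].
#' @export
read_gmm_bank <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(obj$models, function(m) {
    means <- matrix(unlist(m$means), nrow = length(m$weights))
    covs <- m$covs
    if (is.array(covs) && length(dim(covs)) == 3L)
      covs <- lapply(seq_len(dim(covs)[1L]), function(j) covs[j, , ])
    if (is.numeric(covs)) covs <- list(matrix(covs, ncol = ncol(means)))
    covs <- lapply(covs, function(S) matrix(unlist(S), ncol = ncol(means)))
    structure(list(weights = as.numeric(m$weights), means = means,
                   covs = covs, loglik_trace = numeric(0),
                   reg = m$reg %||% 1e-6),
              class = "gmm")
  })
  scaling <- NULL
  if (!is.null(obj$scaling))
    scaling <- structure(list(min = unlist(obj$scaling$min),
                              max = unlist(obj$scaling$max),
                              columns = obj$scaling$columns),
                         class = "feature_scaling")
  gmm_bank(obj$module_kind, models, window = obj$window, scaling = scaling,
           threshold = obj$threshold %||% NA_real_,
           intention_class = obj$intention_class)
}
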
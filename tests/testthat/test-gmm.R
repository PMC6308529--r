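test_that("single-component fit reduces to the sample moments", {
  set.seed(2)
  X <- matrix(rnorm(600, sd = 2), ncol = 3)
  fit <- fit_gmm(X, 1, seed = 1, reg = 1e-6)
  expect_equal(fit$weights, 1)
  expect_equal(drop(fit$means), colMeans(X), tolerance = 1e-10)
  n <- nrow(X)
  pop_cov <- stats::cov(X) * (n - 1) / n
  expect_equal(fit$covs[[1]], pop_cov + diag(1e-6, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("EM recovers two well-separated spherical clusters", {
  set.seed(4)
  mu1 <- c(0, 0); mu2 <- c(10, 10)   # separation 10 sigma at sigma = 1
  X <- rbind(matrix(rnorm(400) + rep(mu1, each = 200), ncol = 2),
             matrix(rnorm(400) + rep(mu2, each = 200), ncol = 2))
  fit <- fit_gmm(X, 2, seed = 3)
  got <- fit$means[order(fit$means[, 1]), ]
  expect_lt(max(abs(got[1, ] - mu1)), 0.1)
  expect_lt(max(abs(got[2, ] - mu2)), 0.1)
  expect_equal(sum(fit$weights), 1)
  expect_true(all(fit$weights > 0.45))
})

test_that("the EM log-likelihood trace never decreases", {
  set.seed(9)
  for (rep in 1:3) {
    X <- cbind(c(rnorm(120), rnorm(80, 3), rnorm(60, -2.5)),
               c(rnorm(120), rnorm(80, -1), rnorm(60, 2)))
    fit <- fit_gmm(X, 3, seed = rep)
    expect_gte(length(fit$loglik_trace), 2)
    expect_true(all(diff(fit$loglik_trace) > -1e-8))
  }
})

test_that("mixture log-density matches closed forms and brute force", {
  bank <- make_gauss_bank(0, 1)
  expect_equal(class_loglik(bank, "c1", 0), log(1 / sqrt(2 * pi)))
  expect_equal(class_loglik(bank, "c1", 0), -0.9189385, tolerance = 1e-6)
  # random 3-component 2-D mixtures against direct density summation
  set.seed(13)
  for (rep in 1:10) {
    w <- runif(3); w <- w / sum(w)
    mus <- matrix(rnorm(6, sd = 2), 3, 2)
    covs <- lapply(1:3, function(j) {
      A <- matrix(rnorm(4, sd = 0.7), 2, 2)
      crossprod(A) + diag(0.3, 2)
    })
    g <- structure(list(weights = w, means = mus, covs = covs,
                        loglik_trace = numeric(0), reg = 0), class = "gmm")
    V <- matrix(rnorm(20, sd = 2), 10, 2)
    direct <- vapply(seq_len(nrow(V)), function(i) {
      dens <- 0
      for (j in 1:3) {
        d <- V[i, ] - mus[j, ]
        S <- covs[[j]]
        q <- drop(t(d) %*% solve(S) %*% d)
        dens <- dens + w[j] * exp(-q / 2) / (2 * pi * sqrt(det(S)))
      }
      log(dens)
    }, numeric(1))
    expect_equal(gmm_loglik(g, V), direct, tolerance = 1e-10)
  }
})

test_that("mixture density dominates every weighted component", {
  set.seed(21)
  w <- c(0.2, 0.5, 0.3)
  mus <- matrix(rnorm(3), 3, 1)
  covs <- lapply(1:3, function(j) matrix(runif(1, 0.2, 2), 1, 1))
  g <- structure(list(weights = w, means = mus, covs = covs,
                      loglik_trace = numeric(0), reg = 0), class = "gmm")
  for (v in rnorm(10)) {
    total <- gmm_loglik(g, v)
    for (j in 1:3) {
      lb <- log(w[j]) + dnorm(v, mus[j, 1], sqrt(covs[[j]][1, 1]), log = TRUE)
      expect_gte(total, lb)
    }
  }
})

test_that("context-window classification follows the density product", {
  bank <- make_gauss_bank(c(0, 5), c(1, 1), window = 20L)
  expect_equal(classify_window(bank, 0.1)$class, "c1")
  # duplicating the window's frames rescales all scores equally
  win <- matrix(c(0.4, 0.6, 0.2), ncol = 1)
  one <- classify_window(bank, win)
  two <- classify_window(bank, rbind(win, win))
  expect_equal(two$class, one$class)
  expect_equal(two$scores, 2 * one$scores)
  expect_error(classify_window(bank, matrix(numeric(0), 0, 1)), "empty")
})

test_that("windowed argmax equals brute-force product of densities", {
  set.seed(31)
  for (rep in 1:25) {
    m <- sort(rnorm(2, sd = 2))
    s <- runif(2, 0.5, 2)
    bank <- make_gauss_bank(m, s, window = 6L)
    v <- rnorm(6, mean = sample(m, 1), sd = 1)
    res <- classify_window(bank, matrix(v, ncol = 1))
    prod1 <- prod(dnorm(v, m[1], s[1]))
    prod2 <- prod(dnorm(v, m[2], s[2]))
    expect_equal(res$class, c("c1", "c2")[which.max(c(prod1, prod2))])
    expect_equal(unname(res$scores),
                 log(c(prod1, prod2)), tolerance = 1e-9)
  }
})

test_that("streaming classification equals per-frame window classification", {
  set.seed(8)
  bank <- make_gauss_bank(c(-1, 2), c(1, 0.8), window = 5L)
  x <- matrix(rnorm(40), ncol = 1)
  st <- classify_stream(bank, x)
  for (t in c(1, 3, 5, 17, 40)) {
    win <- x[max(1, t - 4):t, , drop = FALSE]
    expect_equal(unname(st$scores[t, ]),
                 unname(classify_window(bank, win)$scores), tolerance = 1e-9)
  }
})

test_that("threshold calibration finds the smallest passing threshold", {
  # perfectly separated: positives in spans score high
  tr <- c(rep(-5, 30), rep(5, 10), rep(-5, 30))
  spans <- list(c(31, 40))
  cal <- calibrate_threshold(list(tr), list(spans))
  expect_lte(cal$threshold, 5)
  expect_gt(cal$threshold, -5)
  expect_equal(cal$precision, 1)
  expect_equal(cal$recall, 1)
  # all negatives above all positives: unattainable -> sentinel
  tr2 <- c(rep(5, 30), rep(-5, 10), rep(5, 30))
  expect_warning(cal2 <- calibrate_threshold(list(tr2), list(list(c(31, 40))),
                                             target_precision = 0.99))
  expect_identical(cal2$threshold, Inf)
  expect_equal(cal2$recall, 0)
  expect_error(calibrate_threshold(list(), list()), "empty")
})

test_that("calibration agrees with an exhaustive midpoint sweep", {
  set.seed(17)
  n <- 400
  tr <- rnorm(n)
  spans <- list(c(50, 70), c(200, 230), c(300, 320))
  for (sp in spans) {
    idx <- sp[1]:sp[2]
    tr[idx] <- tr[idx] + rnorm(length(idx), 2.5)
  }
  cal <- calibrate_threshold(list(tr), list(spans), target_precision = 0.9)
  # independent sweep over midpoints of sorted unique scores
  u <- sort(unique(tr))
  cands <- (u[-1] + u[-length(u)]) / 2
  ok <- vapply(cands, function(th) {
    cm <- gaitinfer:::event_confusion(tr >= th, spans)
    prec <- if (cm$tp + cm$fp == 0) 1 else cm$tp / (cm$tp + cm$fp)
    prec >= 0.9 && cm$tp > 0
  }, logical(1))
  expect_equal(cal$threshold, min(cands[ok]))
})

test_that("log-densities agree with an external multivariate-normal oracle", {
  skip_if_not_installed("mclust")
  set.seed(41)
  mu <- c(0.3, -1.2, 2)
  A <- matrix(rnorm(9, sd = 0.6), 3, 3)
  S <- crossprod(A) + diag(0.4, 3)
  X <- matrix(rnorm(60, sd = 1.5), 20, 3)
  expect_equal(gaitinfer:::dmvnorm_log(X, mu, S),
               mclust::dmvnorm(X, mu, S, log = TRUE), tolerance = 1e-10)
})

test_that("model banks survive JSON serialization bit-faithfully enough", {
  set.seed(3)
  X1 <- matrix(rnorm(300), ncol = 2)
  X2 <- matrix(rnorm(300, 3), ncol = 2)
  bank <- gmm_bank("sitting_down",
                   list(intention = fit_gmm(X1, 2, seed = 1),
                        standing = fit_gmm(X2, 1, seed = 1)),
                   window = 20L, threshold = 1.25,
                   intention_class = "intention")
  path <- withr::local_tempfile(fileext = ".json")
  write_gmm_bank(bank, path)
  back <- read_gmm_bank(path)
  expect_equal(back$classes, bank$classes)
  expect_equal(back$threshold, 1.25)
  V <- matrix(rnorm(40), ncol = 2)
  for (cl in bank$classes)
    expect_equal(class_loglik(back, cl, V), class_loglik(bank, cl, V),
                 tolerance = 1e-12)
  s1 <- classify_stream(bank, V); s2 <- classify_stream(back, V)
  expect_equal(s2$class, s1$class)
  expect_equal(s2$llr, s1$llr, tolerance = 1e-12)
})
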
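# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gi <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_gi(...)
  invisible(TRUE)
}

# Rolling sum of the trailing `width` samples (growing prefix at the start).
rolling_sum <- function(x, width) {
  cs <- cumsum(x)
  n <- length(x)
  if (n <= width) return(cs)
  c(cs[seq_len(width)], cs[(width + 1):n] - cs[1:(n - width)])
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix.
row_log_sum_exp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate expr under set.seed(seed) without disturbing the caller's RNG
# stream (all randomized fits are reproducible and side-effect free).
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Maximal runs of TRUE in a logical vector, as a two-column matrix
# (start, end), 1-based inclusive.
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}
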
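# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Survey-weighted mean.
wmean <- function(x, w) sum(w * x) / sum(w)

# Survey-weighted population variance (denominator = total mass).
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Weighted quantiles of type "inverse empirical cdf" (lower-closed, ties low).
wquantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

stop_dp <- function(...) stop(..., call. = FALSE)

check_weights <- function(weights, n) {
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) stop_dp("`weights` must have length ", n)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop_dp("survey weights must be finite and strictly positive")
  }
  weights
}
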
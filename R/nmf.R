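#' Weighted least-squares non-negative matrix factorisation
#'
#' Factorises a non-negative consumption matrix `X` (individuals x food
#' groups) as `X ~ W %*% H` with `W, H >= 0`, minimising the survey-weighted
#' squared error
#' \deqn{f(W, H) = \sum_i s_i \sum_j (x_{ij} - (WH)_{ij})^2,}
#' where `s_i` is the survey weight of individual `i`. The solver alternates
#' the multiplicative updates of least-squares NMF with an elementwise weight
#' matrix (here constant within rows), which keeps both factors non-negative
#' and decreases the objective at every iteration. Each row of `H` is a
#' consumption system (CS): a non-negative combination of food groups; each
#' row of `W` holds the weights of the CS in one individual's diet.
#'
#' Initial factors are drawn uniformly on `(0, mean(X)/k]`; with
#' `n_restarts > 1` the fit with the lowest final objective is returned.
#' Denominators carry an additive `1e-12` guard against 0/0.
#'
#' @param X Non-negative numeric matrix (individuals x food groups).
#' @param weights Positive per-individual survey weights (default all 1).
#' @param k Rank: the number of consumption systems.
#' @param seed Integer seed for the random initialisation.
#' @param init Optional list `list(W =, H =)` overriding random
#'   initialisation (then `n_restarts` is forced to 1).
#' @param tol Relative objective-change convergence threshold.
#' @param max_iter Maximum iterations per restart.
#' @param n_restarts Number of random restarts.
#' @return Object of class `ls_nmf_fit`: list with `W`, `H`, `k`,
#'   `objective`, `objective_trace`, `converged`, `n_iter`, `weights`,
#'   `restart` (index of the winning restart).
#' @export
#' @examples
#' X <- matrix(runif(60), 10, 6)
#' fit <- ls_nmf(X, k = 2, seed = 1)
#' all(diff(fit$objective_trace) <= 1e-8)
ls_nmf <- function(X, weights = NULL, k, seed = 1L, init = NULL,
                   tol = 1e-6, max_iter = 2000L, n_restarts = 1L) {
  X <- as.matrix(X)
  if (any(X < 0)) stop_dp("X must be non-negative")
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n, p)) {
    stop_dp("invalid rank k = ", k, ": must be in [1, ", min(n, p), "]")
  }
  s <- check_weights(weights, n)
  if (!is.null(init)) n_restarts <- 1L

  sX <- s * X                     # rows scaled by survey weight
  best <- NULL
  for (r in seq_len(n_restarts)) {
    if (is.null(init)) {
      fac <- with_seed(seed + (r - 1L) * 1000L, {
        m <- mean(X) / k
        list(W = matrix(stats::runif(n * k, 0, m), n, k),
             H = matrix(stats::runif(k * p, 0, m), k, p))
      })
    } else {
      fac <- list(W = as.matrix(init$W), H = as.matrix(init$H))
      if (any(fac$W < 0) || any(fac$H < 0)) stop_dp("init factors must be >= 0")
    }
    fit <- .ls_nmf_run(X, sX, s, fac$W, fac$H, tol, max_iter)
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$restart <- r
    }
  }
  best$k <- k
  best$weights <- s
  dimnames(best$W) <- list(rownames(X), paste0("CS", seq_len(k)))
  dimnames(best$H) <- list(paste0("CS", seq_len(k)), colnames(X))
  class(best) <- "ls_nmf_fit"
  best
}

.ls_nmf_run <- function(X, sX, s, W, H, tol, max_iter) {
  eps <- 1e-12
  trace <- numeric(max_iter)
  f_prev <- Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    # H-update with W fixed, then W-update with the new H; each step is a
    # monotone multiplicative update for the row-weighted objective.
    sWH <- s * (W %*% H)
    H <- H * (crossprod(W, sX) / (crossprod(W, sWH) + eps))
    sWH <- s * (W %*% H)
    W <- W * (tcrossprod(sX, H) / (tcrossprod(sWH, H) + eps))
    R <- X - W %*% H
    f <- sum(s * R * R)
    trace[it] <- f
    if (is.finite(f_prev) &&
        abs(f_prev - f) <= tol * max(f_prev, .Machine$double.xmin)) {
      converged <- TRUE
      break
    }
    f_prev <- f
  }
  list(W = W, H = H, objective = trace[it],
       objective_trace = trace[seq_len(it)],
       converged = converged, n_iter = it)
}

#' @export
print.ls_nmf_fit <- function(x, ...) {
  cat("Weighted LS-NMF fit: ", nrow(x$W), " individuals x ", ncol(x$H),
      " food groups, k = ", x$k, "\n", sep = "")
  cat("  objective ", format(x$objective, digits = 6), " after ", x$n_iter,
      " iterations (", if (x$converged) "converged" else "max_iter reached",
      ")\n", sep = "")
  invisible(x)
}

#' Scan factorisation ranks and suggest one by the elbow of the error curve
#'
#' Fits the weighted LS-NMF at each rank in `k_range` (best of `n_restarts`
#' seeded starts) and records the final objective. The suggested rank is a
#' scree-style elbow of the objective-vs-rank curve: the marginal objective
#' drop of the largest ranks scanned estimates the rate at which extra
#' components merely absorb noise, and the suggested rank is the largest one
#' whose drop exceeds twice that rate (falling back to the largest relative
#' drop ratio when no rank clears the threshold). The full curve is returned
#' because the final choice also weighs the interpretability of the systems,
#' which no numeric rule captures; a user-specified rank is never
#' overridden.
#'
#' @inheritParams ls_nmf
#' @param k_range Integer vector of candidate ranks (need not be contiguous,
#'   but the elbow is computed on the sorted grid).
#' @param n_restarts Random restarts per rank.
#' @return Object of class `rank_diagnostics`: data frame `curve` (columns
#'   `k`, `objective`, `elbow_score`) and `suggested_k`.
#' @export
select_rank <- function(X, weights = NULL, k_range = 2:10, n_restarts = 5L,
                        seed = 1L, tol = 1e-6, max_iter = 2000L) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 1) || any(k_range > min(dim(X)))) {
    stop_dp("k_range outside valid ranks")
  }
  obj <- vapply(seq_along(k_range), function(i) {
    ls_nmf(X, weights, k = k_range[i], seed = seed + 131L * i,
           tol = tol, max_iter = max_iter, n_restarts = n_restarts)$objective
  }, numeric(1))
  m <- length(k_range)
  drop <- c(NA_real_, -diff(obj) / diff(k_range))  # per-unit-rank drop at k
  if (m >= 4) {
    tail_rate <- mean(drop[c(m - 1, m)])
    cand <- which(!is.na(drop) & drop > 2 * tail_rate)
    cand <- cand[cand <= m - 2]
    if (length(cand)) {
      suggested <- k_range[max(cand)]
    } else {
      ratio <- drop[2:(m - 1)] / pmax(drop[3:m], .Machine$double.xmin)
      suggested <- k_range[1 + which.max(ratio)]
    }
  } else {
    suggested <- k_range[which.min(obj)]
  }
  structure(list(curve = data.frame(k = k_range, objective = obj,
                                    drop = drop),
                 suggested_k = suggested),
            class = "rank_diagnostics")
}

#' @export
print.rank_diagnostics <- function(x, ...) {
  cat("Rank scan over k =", paste(x$curve$k, collapse = ", "), "\n")
  cat("Suggested k (elbow):", x$suggested_k, "\n")
  invisible(x)
}

#' Normalise an NMF fit so each consumption system sums to one
#'
#' Rescales every row of `H` to sum to 1 and moves the compensating scale
#' into the corresponding column of `W`, leaving the product `W %*% H`
#' unchanged. Under this convention the loadings read directly as the
#' proportional contribution of each food group to the consumption system.
#'
#' @param fp An `ls_nmf_fit`.
#' @return The fit with normalised factors (idempotent).
#' @export
normalize_factors <- function(fp) {
  stopifnot(inherits(fp, "ls_nmf_fit"))
  rs <- rowSums(fp$H)
  if (any(rs == 0)) {
    stop_dp("degenerate factor: consumption system(s) ",
            paste(which(rs == 0), collapse = ", "), " have all-zero loadings")
  }
  fp$H <- fp$H / rs
  fp$W <- sweep(fp$W, 2, rs, `*`)
  fp
}

#' Food-group contributions to each consumption system
#'
#' Expresses the normalised loadings as percentages and flags the main
#' contributors: food groups contributing at least `cutoff` (default 2.5%)
#' of a consumption system's mass.
#'
#' @param fp An `ls_nmf_fit` (normalised internally if needed).
#' @param cutoff Main-contributor threshold as a proportion. Default 0.025.
#' @return Named list (one element per CS) of data frames with columns
#'   `food_group`, `contribution_pct`, `main_contributor`, sorted by
#'   decreasing contribution.
#' @export
loading_contributions <- function(fp, cutoff = 0.025) {
  fp <- normalize_factors(fp)
  lapply(stats::setNames(seq_len(fp$k), rownames(fp$H)), function(j) {
    contrib <- fp$H[j, ] * 100
    o <- order(contrib, decreasing = TRUE)
    data.frame(food_group = colnames(fp$H)[o],
               contribution_pct = unname(contrib[o]),
               main_contributor = unname(contrib[o]) >= cutoff * 100,
               stringsAsFactors = FALSE)
  })
}

#' Match estimated consumption systems to a reference set
#'
#' NMF is identifiable only up to permutation and scale, so recovery tests
#' need an alignment step. Finds the one-to-one assignment of estimated to
#' reference rows maximising the total cosine similarity — exhaustively for
#' up to 9 systems, by greedy assignment beyond.
#'
#' @param H_est Estimated loadings (k x foods).
#' @param H_ref Reference loadings (k x foods).
#' @return List with `permutation` (`H_ref[j, ]` is matched by
#'   `H_est[permutation[j], ]`) and `cosine` (per matched pair).
#' @export
match_factors <- function(H_est, H_ref) {
  H_est <- as.matrix(H_est); H_ref <- as.matrix(H_ref)
  if (nrow(H_est) != nrow(H_ref) || ncol(H_est) != ncol(H_ref)) {
    stop_dp("rank or dimension mismatch between estimated and reference loadings")
  }
  k <- nrow(H_ref)
  nrm <- function(M) M / pmax(sqrt(rowSums(M^2)), 1e-300)
  C <- nrm(H_ref) %*% t(nrm(H_est))   # C[r, e] = cos(ref_r, est_e)
  if (k <= 9) {
    perms <- .permutations(k)
    tot <- apply(perms, 1, function(p) sum(C[cbind(seq_len(k), p)]))
    best <- as.integer(perms[which.max(tot), ])
  } else {
    best <- integer(k)
    avail <- rep(TRUE, k)
    for (r in order(apply(C, 1, max), decreasing = TRUE)) {
      e <- which.max(ifelse(avail, C[r, ], -Inf))
      best[r] <- e
      avail[e] <- FALSE
    }
  }
  list(permutation = best, cosine = C[cbind(seq_len(k), best)])
}

.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- seq_len(k)[-first]
    cbind(first, matrix(rest[sub], nrow(sub), k - 1L))
  }))
}
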
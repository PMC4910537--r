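# Independent oracles used across tests. Each is implemented from the
# defining formula, separately from the package's own code paths.

# Plain (unweighted) Lee-Seung multiplicative-update NMF.
lee_seung_nmf <- function(X, W, H, iters) {
  eps <- 1e-12
  for (i in seq_len(iters)) {
    H <- H * (crossprod(W, X) / (crossprod(W, W %*% H) + eps))
    W <- W * (tcrossprod(X, H) / (tcrossprod(W %*% H, H) + eps))
  }
  list(W = W, H = H)
}

# Naive mass-weighted Ward agglomeration from centroids; returns the sorted
# merge heights (inertia increments).
naive_ward_heights <- function(X, m = rep(1, nrow(X))) {
  n <- nrow(X)
  cent <- lapply(seq_len(n), function(i) X[i, ])
  mass <- m
  active <- rep(TRUE, n)
  heights <- numeric(0)
  while (sum(active) > 1) {
    act <- which(active)
    best <- c(NA, NA); bc <- Inf
    for (a in act) for (b in act) if (a < b) {
      cost <- mass[a] * mass[b] / (mass[a] + mass[b]) *
        sum((cent[[a]] - cent[[b]])^2)
      if (cost < bc - 1e-12) { bc <- cost; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    cent[[a]] <- (mass[a] * cent[[a]] + mass[b] * cent[[b]]) /
      (mass[a] + mass[b])
    mass[a] <- mass[a] + mass[b]
    active[b] <- FALSE
    heights <- c(heights, bc)
  }
  sort(heights)
}

# Direct-formula V-test for one cluster and one variable.
v_test_direct <- function(x, in_cluster, w = rep(1, length(x))) {
  N <- sum(w)
  nc <- sum(w[in_cluster])
  m <- sum(w * x) / N
  mc <- sum(w[in_cluster] * x[in_cluster]) / nc
  s2 <- sum(w * (x - m)^2) / N
  (mc - m) / sqrt(((N - nc) / (N - 1)) * s2 / nc)
}

# First-axis row principal coordinates of a correspondence analysis of a
# (possibly weighted) indicator table, by direct SVD of the standardised
# residuals.
ca_scores_oracle <- function(Z, w = rep(1, nrow(Z))) {
  Tm <- w * Z
  P <- Tm / sum(Tm)
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  sv$u[, 1] * sv$d[1] / sqrt(r)
}

# Adjusted Rand index between two partitions.
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small survey configuration shared by several tests.
small_config <- function(seed = 1, ...) {
  args <- list(n_individuals = 150, n_food_groups = 30, n_cs = 3,
               n_patterns = 3, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

# Categorical wealth-item fixture driven by a latent affluence score.
wealth_fixture <- function(n = 20, seed = 71) {
  set.seed(seed)
  u <- rnorm(n)
  data.frame(
    holiday = factor(ifelse(u + rnorm(n, sd = 0.6) > 0, "yes", "no"),
                     levels = c("no", "yes")),
    cars = factor(cut(u + rnorm(n, sd = 0.6), c(-Inf, -0.5, 0.5, Inf),
                      labels = c("none", "one", "two")), ordered = FALSE),
    owner = factor(ifelse(u + rnorm(n, sd = 0.6) > 0.2, "yes", "no"),
                   levels = c("no", "yes"))
  )
}

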
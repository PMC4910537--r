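#' Mass-weighted Ward hierarchical clustering of consumption-system scores
#'
#' Agglomerates individuals in CS-score space under the Ward criterion, with
#' survey weights entering as point masses: merging clusters `a`, `b` with
#' masses `m_a`, `m_b` and centroids `c_a`, `c_b` costs
#' `m_a m_b / (m_a + m_b) * ||c_a - c_b||^2`, the increase in weighted
#' within-cluster inertia. The dendrogram is built by [stats::hclust()]'s
#' Lance-Williams recurrence for Ward, seeded with the pairwise singleton
#' merge costs and the masses, so merge heights equal inertia increments and
#' their cumulative sums decompose the total weighted inertia.
#'
#' @param W Score matrix (individuals x CS), non-negative and finite.
#' @param weights Positive survey weights (default all 1; with unit weights
#'   the tree coincides with classical Ward clustering).
#' @return An [stats::hclust] tree with attributes `weights` and
#'   `total_inertia`.
#' @export
hca_ward <- function(W, weights = NULL) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n < 2) stop_dp("need at least 2 individuals to cluster")
  if (any(!is.finite(W))) stop_dp("scores must be finite")
  m <- check_weights(weights, n)
  d2 <- as.matrix(stats::dist(W))^2
  mass <- outer(m, m) / outer(m, m, `+`)   # m_i m_j / (m_i + m_j)
  D <- stats::as.dist(mass * d2)
  tree <- stats::hclust(D, method = "ward.D", members = m)
  tree$labels <- rownames(W)
  gm <- colSums(m * W) / sum(m)
  attr(tree, "weights") <- m
  attr(tree, "total_inertia") <- sum(m * rowSums(sweep(W, 2, gm)^2))
  tree
}

#' Choose the number of dietary patterns from the inertia-ratio curve
#'
#' For a Ward tree whose heights are inertia increments, the
#' between-cluster : total inertia ratio of the `C`-cluster partition is the
#' share of total inertia contained in the `C - 1` highest merges. The ratio
#' is non-decreasing in `C` and reaches 1 at singletons. The chosen `C`
#' maximises the relative drop in marginal gain — the ratio of consecutive
#' merge heights, a scale-free elbow — over `c_range`; the full curve is
#' returned because the final choice also involves the interpretability of
#' the clusters.
#'
#' @param tree A tree from [hca_ward()].
#' @param c_range Candidate cluster counts, within `[2, n]` (`n` singletons
#'   give ratio 1).
#' @return List with `chosen_c` and `curve` (data frame: `c`, `inertia_ratio`,
#'   `marginal_gain`).
#' @export
select_n_clusters <- function(tree, c_range = 2:12) {
  h <- tree$height
  n <- length(h) + 1L
  c_range <- sort(unique(as.integer(c_range)))
  if (any(c_range < 2) || any(c_range > n)) {
    stop_dp("c_range must lie within [2, n]")
  }
  total <- sum(h)
  # ratio(C) = (sum of the C-1 largest merge costs) / total inertia
  hs <- sort(h, decreasing = TRUE)
  ratio <- function(C) if (C <= 1) 0 else sum(hs[seq_len(C - 1)]) / total
  r <- vapply(c_range, ratio, numeric(1))
  gain <- vapply(c_range, function(C) ratio(C) - ratio(C - 1), numeric(1))
  gain_next <- vapply(c_range, function(C) ratio(C + 1) - ratio(C), numeric(1))
  chosen <- c_range[which.max(gain / pmax(gain_next, .Machine$double.xmin))]
  list(chosen_c = chosen,
       curve = data.frame(c = c_range, inertia_ratio = r,
                          marginal_gain = gain))
}

#' Cut a pattern tree into dietary-pattern labels
#'
#' @param tree A tree from [hca_ward()].
#' @param c Number of patterns.
#' @return Integer labels in `1..c`, named by individual.
#' @export
assign_patterns <- function(tree, c) {
  stats::cutree(tree, k = c)
}

#' Survey-weighted population share of each dietary pattern
#'
#' @param labels Pattern labels per individual.
#' @param weights Positive survey weights (default all 1).
#' @return Named numeric vector of percentages summing to 100.
#' @export
weighted_share <- function(labels, weights = NULL) {
  weights <- check_weights(weights, length(labels))
  s <- tapply(weights, labels, sum)
  stats::setNames(as.numeric(100 * s / sum(weights)), names(s))
}

#' V-test comparison of pattern means against the population mean
#'
#' For each dietary pattern and each consumption system, compares the
#' survey-weighted mean score inside the pattern with the population mean:
#' \deqn{v = \frac{m_c - m}{\sqrt{\frac{N - n_c}{N - 1} \cdot \frac{s^2}{n_c}}}}
#' with weighted pattern mean `m_c`, population mean `m`, population variance
#' `s^2`, pattern mass `n_c` and total mass `N` — the finite-population
#' (sampling without replacement) standardisation. A pattern is described by
#' the consumption systems with significant and positive V-tests
#' (`v >= threshold`, default 1.96, the two-sided 5% point).
#'
#' @param W Score matrix (individuals x CS) or a numeric vector.
#' @param labels Pattern labels.
#' @param weights Positive survey weights (default all 1).
#' @param threshold Significance threshold on `|v|`. Default 1.96.
#' @return Object of class `v_test`: list with `v` (patterns x CS matrix),
#'   `significant` (logical matrix, `|v| >=` threshold) and `descriptors`
#'   (per pattern, the CS with significant positive v, strongest first).
#' @export
v_test <- function(W, labels, weights = NULL, threshold = 1.96) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n < 2) stop_dp("need at least 2 individuals")
  if (length(labels) != n) stop_dp("labels length mismatch")
  w <- check_weights(weights, n)
  pats <- sort(unique(labels))
  N <- sum(w)
  V <- matrix(NA_real_, length(pats), ncol(W),
              dimnames = list(as.character(pats), colnames(W)))
  for (j in seq_len(ncol(W))) {
    x <- W[, j]
    m <- wmean(x, w)
    s2 <- wvar(x, w)
    for (ci in seq_along(pats)) {
      in_c <- labels == pats[ci]
      if (!any(in_c)) stop_dp("empty pattern: ", pats[ci])
      nc <- sum(w[in_c])
      mc <- wmean(x[in_c], w[in_c])
      denom2 <- ((N - nc) / (N - 1)) * s2 / nc
      if (denom2 <= 0) {
        V[ci, j] <- if (isTRUE(all.equal(mc, m))) 0 else sign(mc - m) * Inf
      } else {
        V[ci, j] <- (mc - m) / sqrt(denom2)
      }
    }
  }
  sig <- abs(V) >= threshold
  desc <- lapply(seq_along(pats), function(ci) {
    pos <- which(sig[ci, ] & V[ci, ] > 0)
    colnames(W)[pos[order(V[ci, pos], decreasing = TRUE)]]
  })
  names(desc) <- as.character(pats)
  structure(list(v = V, significant = sig, descriptors = desc,
                 threshold = threshold), class = "v_test")
}

#' @export
print.v_test <- function(x, ...) {
  cat("V-tests (|v| >=", x$threshold, "significant):\n")
  print(round(x$v, 2))
  invisible(x)
}

#' Relative contribution of each consumption system within each pattern
#'
#' Within pattern `c`, the contribution of CS `k` is the ratio of the summed
#' individual CS-`k` weights to the summed weights of all CS:
#' `r_ck = sum_{i in c} W_ik / sum_{i in c} sum_k' W_ik'`. Rows sum to 1.
#'
#' @param W Non-negative score matrix (individuals x CS).
#' @param labels Pattern labels.
#' @return Patterns x CS matrix of proportions.
#' @export
relative_contribution <- function(W, labels) {
  W <- as.matrix(W)
  if (any(W < 0)) stop_dp("scores must be non-negative")
  pats <- sort(unique(labels))
  R <- matrix(0, length(pats), ncol(W))
  for (ci in seq_along(pats)) {
    R[ci, ] <- colSums(W[labels == pats[ci], , drop = FALSE])
  }
  tot <- rowSums(R)
  if (any(tot == 0)) {
    stop_dp("undefined contribution: pattern(s) ",
            paste(pats[tot == 0], collapse = ", "), " have all-zero scores")
  }
  R <- R / tot
  dimnames(R) <- list(as.character(pats), colnames(W))
  R
}
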
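test_that("exactly factorizable matrices are fit to numerical zero", {
  set.seed(21)
  W0 <- matrix(runif(30 * 2), 30, 2)
  H0 <- matrix(runif(2 * 12), 2, 12)
  X <- W0 %*% H0
  fit <- ls_nmf(X, k = 2, seed = 1, n_restarts = 5)
  expect_lte(fit$objective, 1e-8 * sum(X^2))
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("input validation rejects negative data and invalid ranks", {
  X <- matrix(1, 5, 4)
  expect_error(ls_nmf(X - 2, k = 2), "non-negative")
  expect_error(ls_nmf(X, k = 9), "rank")
  expect_error(ls_nmf(X, k = 2, weights = rep(-1, 5)), "positive")
})

test_that("objective trace is non-increasing on random problems", {
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rexp(20 * 8), 20, 8)
    w <- rlnorm(20, 0, 0.5)
    fit <- ls_nmf(X, weights = w, k = 3, seed = s, max_iter = 150)
    expect_true(all(diff(fit$objective_trace) <=
                      1e-8 * fit$objective_trace[1] + 1e-12))
  }
})

test_that("unit weights reproduce the plain multiplicative-update oracle", {
  set.seed(22)
  X <- matrix(runif(30 * 10), 30, 10)
  Wi <- matrix(runif(30 * 3), 30, 3)
  Hi <- matrix(runif(3 * 10), 3, 10)
  fit <- ls_nmf(X, weights = rep(1, 30), k = 3, init = list(W = Wi, H = Hi),
                tol = 0, max_iter = 100)
  orc <- lee_seung_nmf(X, Wi, Hi, 100)
  expect_lt(max(abs(fit$W - orc$W)), 1e-10)
  expect_lt(max(abs(fit$H - orc$H)), 1e-10)
})

test_that("constant weights scale the objective but not the trajectory", {
  set.seed(23)
  X <- matrix(runif(24 * 8), 24, 8)
  Wi <- matrix(runif(24 * 2), 24, 2)
  Hi <- matrix(runif(2 * 8), 2, 8)
  f1 <- ls_nmf(X, weights = rep(1, 24), k = 2, init = list(W = Wi, H = Hi),
               tol = 0, max_iter = 60)
  f3 <- ls_nmf(X, weights = rep(3, 24), k = 2, init = list(W = Wi, H = Hi),
               tol = 0, max_iter = 60)
  expect_lt(max(abs(f1$W - f3$W)), 1e-10)
  expect_equal(f3$objective_trace, 3 * f1$objective_trace, tolerance = 1e-10)
})

test_that("unequal survey weights change the fit in the weighted direction", {
  # two rows conflict; the heavily weighted one should be fit better
  X <- rbind(c(4, 0), c(0, 4))
  w_a <- c(10, 0.1)
  fit <- ls_nmf(X, weights = w_a, k = 1, seed = 1, n_restarts = 5)
  R <- X - fit$W %*% fit$H
  expect_lt(sum(R[1, ]^2), sum(R[2, ]^2))
})

test_that("normalisation moves scale into W and is idempotent", {
  fp <- structure(list(W = matrix(c(1, 2), 2, 1),
                       H = matrix(c(2, 2, 4), 1, 3),
                       k = 1, objective = 0, objective_trace = 0,
                       converged = TRUE, n_iter = 1, weights = c(1, 1)),
                  class = "ls_nmf_fit")
  nf <- normalize_factors(fp)
  expect_equal(unname(nf$H[1, ]), c(0.25, 0.25, 0.5))
  expect_equal(unname(nf$W[, 1]), c(8, 16))
  expect_equal(nf$W %*% nf$H, fp$W %*% fp$H, tolerance = 1e-12)
  expect_equal(normalize_factors(nf), nf)

  set.seed(24)
  fit <- ls_nmf(matrix(runif(60), 10, 6), k = 2, seed = 2, max_iter = 50)
  nf <- normalize_factors(fit)
  prod_diff <- max(abs(nf$W %*% nf$H - fit$W %*% fit$H))
  expect_lte(prod_diff, 1e-12 * max(fit$W %*% fit$H))

  fp$H[1, ] <- 0
  expect_error(normalize_factors(fp), "degenerate")
})

test_that("loading contributions apply the main-contributor cutoff", {
  fp <- structure(list(W = matrix(1, 2, 2),
                       H = rbind(c(0.5, 0.3, 0.2), c(0.024, 0.476, 0.5)),
                       k = 2, objective = 0, objective_trace = 0,
                       converged = TRUE, n_iter = 1, weights = c(1, 1)),
                  class = "ls_nmf_fit")
  colnames(fp$H) <- c("f1", "f2", "f3")
  rownames(fp$H) <- c("CS1", "CS2")
  ct <- loading_contributions(fp, cutoff = 0.025)
  expect_equal(ct$CS1$contribution_pct, c(50, 30, 20))
  expect_true(all(ct$CS1$main_contributor))
  # 2.4% is below the >= 2.5% rule
  f1row <- ct$CS2[ct$CS2$food_group == "f1", ]
  expect_false(f1row$main_contributor)
  expect_equal(sum(ct$CS2$contribution_pct), 100, tolerance = 1e-9)
})

test_that("factor matching recovers permutations and self-identity", {
  set.seed(25)
  H <- matrix(runif(4 * 12), 4, 12)
  m <- match_factors(H, H)
  expect_equal(m$permutation, 1:4)
  expect_equal(m$cosine, rep(1, 4), tolerance = 1e-12)
  perm <- c(3, 1, 4, 2)
  m2 <- match_factors(H[perm, ], H)
  expect_equal(m2$permutation, order(perm))
  expect_equal(m2$cosine, rep(1, 4), tolerance = 1e-12)
  expect_error(match_factors(H[1:3, ], H), "mismatch")
})

test_that("noiseless separable planted data is recovered almost exactly", {
  # disjoint dominant blocks make the factorisation unique up to
  # permutation/scale, so recovery is limited only by convergence
  set.seed(26)
  H0 <- matrix(0, 3, 30)
  for (j in 1:3) H0[j, (j - 1) * 10 + 1:10] <- rgamma(10, 4, 1)
  H0 <- H0 / rowSums(H0)
  W0 <- matrix(rgamma(200 * 3, 2, 1 / 100), 200, 3)
  X <- W0 %*% H0
  fit <- normalize_factors(ls_nmf(X, k = 3, seed = 3, n_restarts = 4,
                                  tol = 1e-10, max_iter = 6000))
  m <- match_factors(fit$H, H0)
  expect_gte(median(m$cosine), 0.999)
})

test_that("rank scan finds a small planted rank and improves with k", {
  votes <- vapply(1:6, function(s) {
    cfg <- sim_config(n_individuals = 250, n_food_groups = 30, n_cs = 3,
                      n_patterns = 3, noise_cv = 0.1, seed = s)
    tr <- generate_truth(cfg)
    X <- generate_consumption(tr, cfg)
    select_rank(X, k_range = 1:6, n_restarts = 2, seed = s, tol = 1e-5,
                max_iter = 400)$suggested_k
  }, numeric(1))
  expect_gte(sum(votes == 3), 4)   # majority of seeds

  cfg <- small_config(seed = 27)
  tr <- generate_truth(cfg)
  X <- generate_consumption(tr, cfg)
  rd <- select_rank(X, k_range = c(1, 5, 10), n_restarts = 2, seed = 1,
                    tol = 1e-5, max_iter = 300)
  obj <- rd$curve$objective
  expect_lte(obj[length(obj)], obj[1])   # fit improves with rank
})
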
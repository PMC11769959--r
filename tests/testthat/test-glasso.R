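test_that("empirical covariance of standardized data has unit diagonal", {
  d <- toy_data(p = 6L, seed = 13L)
  z <- zscore_normalize(d)
  S <- empirical_covariance(z)
  expect_lt(max(abs(diag(S$S) - 1)), 1e-10)
  expect_identical(S$S, t(S$S))

  # two perfectly correlated columns
  x <- rnorm(10)
  z2 <- list(values = cbind(x, 2 * x + 1), sd_type = "population")
  z2$values <- scale(z2$values) * sqrt(10 / 9)  # population standardization
  S2 <- empirical_covariance(z2)
  expect_equal(S2$S[1L, 2L], 1, tolerance = 1e-10)
})

test_that("empirical covariance equals the direct formula on a fixed matrix", {
  X <- matrix(c(1, 2, 0, 4, 3,
                0, 1, 1, 2, 2,
                5, 0, 2, 1, 0), 5, 3)
  z <- list(values = X, sd_type = "population")
  S <- empirical_covariance(z)$S
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(S - crossprod(Xc) / 5)), 1e-12)
})

test_that("closed-form solutions hold: diagonal, p = 2, and alpha = 0", {
  # diagonal S, alpha 0: inverse of the diagonal
  f0 <- graphical_lasso(matrix(c(2, 0, 0, 4), 2), 0)
  expect_equal(f0$theta, matrix(c(0.5, 0, 0, 0.25), 2), tolerance = 1e-8)

  # p = 2 soft-thresholding closed form
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  f <- graphical_lasso(S, 0.1, tol = 1e-8)
  expect_equal(f$W, matrix(c(1, 0.4, 0.4, 1), 2), tolerance = 1e-6)
  expect_equal(f$theta, (1 / 0.84) * matrix(c(1, -0.4, -0.4, 1), 2),
               tolerance = 1e-6)

  # all off-diagonals below alpha: theta diagonal with 1/S_ii
  S3 <- matrix(c(2, 0.05, -0.03,
                 0.05, 1, 0.08,
                 -0.03, 0.08, 4), 3)
  f3 <- graphical_lasso(S3, 0.1, tol = 1e-10)
  expect_equal(f3$theta, diag(1 / diag(S3)), tolerance = 1e-6)

  # alpha = 0 on a well-conditioned S returns its inverse
  S4 <- random_cov(4, seed = 1)
  expect_lt(max(abs(graphical_lasso(S4, 0)$theta - solve(S4))), 1e-8)
})

test_that("invalid inputs are rejected", {
  expect_error(graphical_lasso(matrix(c(1, 2, 2, 1), 2), 0.1),
               "positive semidefinite")
  expect_error(graphical_lasso(matrix(c(1, 1, 1, 1), 2), 0),
               "nonsingular")
  expect_error(graphical_lasso(random_cov(3, 2), -0.5), "alpha")
  expect_error(graphical_lasso(matrix(1:6, 2, 3), 0.1), "square")
})

test_that("estimates are symmetric, PD, and W inverts theta", {
  for (seed in 1:5) {
    S <- random_cov(6, seed, n = 40)
    f <- graphical_lasso(S, 0.1, tol = 1e-7)
    expect_identical(f$theta, t(f$theta))
    expect_identical(f$W, t(f$W))
    expect_gt(min(eigen(f$theta, symmetric = TRUE, only.values = TRUE)$values), 0)
    expect_lt(max(abs(f$W %*% f$theta - diag(6))), 1e-4)
    # support symmetry
    expect_identical(abs(f$theta) > 1e-8, t(abs(f$theta) > 1e-8))
  }
})

test_that("solver ascent objectives are monotone across sweeps", {
  for (seed in 1:5) {
    S <- random_cov(8, seed + 50, n = 12)  # n < p: needs several sweeps
    f <- graphical_lasso(S, 0.05, tol = 1e-10, max_iter = 100L)
    expect_gte(f$n_iter, 1L)
    if (length(f$dual_trace) > 1L) {
      expect_true(all(diff(f$dual_trace) >= -1e-9))
      expect_true(all(diff(f$primal_trace) >= -1e-9))
    }
  }
})

test_that("blockwise solutions match the projected-gradient dual oracle", {
  for (seed in 1:6) {
    p <- 2L + (seed %% 3L)
    S <- random_cov(p, seed * 7L)
    for (alpha in c(0.05, 0.1, 0.3)) {
      fit <- graphical_lasso(S, alpha, tol = 1e-9, max_iter = 500L)
      orc <- glasso_pg_oracle(S, alpha, gap_tol = 1e-8)
      expect_lt(max(abs(fit$theta - orc$theta)), 1e-3)
    }
  }
})

test_that("a penalty above max |S_ij| yields an edgeless network", {
  S <- random_cov(5, 3)
  amax <- max(abs(S[row(S) != col(S)]))
  f <- graphical_lasso(S, amax * 1.01, tol = 1e-8)
  net <- network_from_precision(f, paste0("m", 1:5))
  expect_equal(nrow(net$edges), 0L)
  expect_length(net$nodes, 0L)
})

test_that("network extraction reports partial correlations and prunes isolates", {
  # p = 2 closed form: single edge with partial correlation +0.4
  f <- graphical_lasso(matrix(c(1, 0.5, 0.5, 1), 2), 0.1, tol = 1e-8)
  net <- network_from_precision(f, c("a", "b"))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$partial_correlation, 0.4, tolerance = 1e-6)

  # 3-node chain: theta_13 = 0 -> exactly the two chain edges
  theta <- matrix(c(1.5, 0.4, 0,
                    0.4, 1.5, -0.3,
                    0, -0.3, 1.5), 3)
  est <- structure(list(theta = theta, W = solve(theta)),
                   class = "PrecisionEstimate")
  net3 <- network_from_precision(est, c("x", "y", "z"))
  expect_equal(nrow(net3$edges), 2L)
  expect_false(any(net3$edges$from == "x" & net3$edges$to == "z"))
  expect_equal(net3$edges$partial_correlation[1L], -0.4 / 1.5,
               tolerance = 1e-12)

  expect_error(network_from_precision(est, c("x", "y")), "3 names")
})

test_that("cross-validation is deterministic and honors explicit grids", {
  truth <- synthetic_truth(p = 8L, stages = c("A", "B"), density = 0.1,
                           seed = 31L)
  d <- generate_dataset(truth, n_rep = 15L, seed = 32L)
  z <- zscore_normalize(d)

  one <- cross_validate_alpha(z, seed = 5L, grid = 0.5)
  expect_equal(one$alpha_best, 0.5)

  cv1 <- cross_validate_alpha(z, seed = 5L)
  cv2 <- cross_validate_alpha(z, seed = 5L)
  expect_identical(cv1$alpha_best, cv2$alpha_best)
  expect_identical(cv1$cv_table, cv2$cv_table)

  expect_error(cross_validate_alpha(z, n_folds = 1L), "n_folds")
})

test_that("CV on planted-structure data picks an interior alpha", {
  truth <- synthetic_truth(p = 20L, stages = c("A", "B"), density = 0.08,
                           seed = 41L)
  d <- generate_dataset(truth, n_rep = 50L, seed = 42L)
  z <- zscore_normalize(d)
  cv <- cross_validate_alpha(z, seed = 7L)
  rng <- range(cv$cv_table$alpha)
  expect_gt(cv$alpha_best, rng[1L])
  expect_lt(cv$alpha_best, rng[2L])
})

test_that("support recovery at the planted-oracle penalty exceeds F1 0.7", {
  passes <- 0L
  for (seed in 1:10) {
    truth <- synthetic_truth(p = 30L, stages = c("A", "B"), density = 0.05,
                             seed = seed)
    d <- generate_dataset(truth, n_rep = 75L, seed = seed + 900L)
    S <- empirical_covariance(zscore_normalize(d))
    best <- 0
    for (alpha in exp(seq(log(0.05), log(0.4), length.out = 8L))) {
      f <- support_f1(graphical_lasso(S, alpha)$theta, truth$support)$f1
      best <- max(best, f)
    }
    passes <- passes + (best >= 0.7)
  }
  expect_gte(passes, 8L)
})
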
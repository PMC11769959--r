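norm_of <- function(values, stage_labels = rep("A", nrow(values))) {
  structure(list(values = values, stage_labels = stage_labels,
                 sample_ids = paste0("s", seq_len(nrow(values))),
                 metabolite_names = paste0("m", seq_len(ncol(values)))),
            class = "NormalizedMatrix")
}

test_that("PCA satisfies its algebraic invariants", {
  set.seed(11)
  X <- matrix(rnorm(20 * 6), 20, 6)
  res <- fit_pca(norm_of(X), 5L)
  G <- crossprod(res$loadings)
  expect_lt(max(abs(G - diag(5))), 1e-8)
  Xc <- sweep(X, 2, colMeans(X))
  expect_lt(max(abs(res$scores - Xc %*% res$loadings)), 1e-8)
  expect_true(all(diff(res$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(res$explained_variance_ratio), 1 + 1e-12)
  # total variance conservation over all min(n-1, p) components
  expect_equal(sum(res$explained_variance_all), sum(apply(X, 2, var)),
               tolerance = 1e-8)
})

test_that("PCA matches an independent eigendecomposition oracle", {
  X <- matrix(c(2, 0, 1,
                1, 3, 0,
                0, 1, 4,
                5, 2, 2), 4, 3, byrow = TRUE)
  res <- fit_pca(norm_of(X), 3L)
  Xc <- sweep(X, 2, colMeans(X))
  eig <- eigen(crossprod(Xc) / (nrow(X) - 1), symmetric = TRUE)
  for (j in 1:2) {  # third eigenvalue is ~0, direction ill-determined
    v <- eig$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v
    expect_lt(max(abs(res$loadings[, j] - v)), 1e-10)
    expect_equal(res$explained_variance[j], eig$values[j], tolerance = 1e-10)
  }
})

test_that("degenerate shapes behave: rank-1 data and 2-sample data", {
  set.seed(5)
  v <- rnorm(4)
  X <- outer(c(1, 2, 3, 5), v)  # rank-1 rows
  res <- fit_pca(norm_of(X), 1L)
  expect_equal(res$explained_variance_ratio[1L], 1.0, tolerance = 1e-12)

  X2 <- matrix(rnorm(2 * 5), 2, 5)
  res2 <- fit_pca(norm_of(X2), 1L)
  expect_equal(res2$scores[1L, 1L], -res2$scores[2L, 1L], tolerance = 1e-10)

  expect_error(fit_pca(norm_of(X2), 3L), "between 1 and 1")
})

test_that("permuting samples permutes scores and changes nothing else", {
  set.seed(6)
  X <- matrix(rnorm(12 * 4), 12, 4)
  res <- fit_pca(norm_of(X), 3L)
  perm <- sample(12)
  res2 <- fit_pca(norm_of(X[perm, ]), 3L)
  expect_equal(unname(res2$scores), unname(res$scores[perm, ]),
               tolerance = 1e-10)
  expect_equal(res2$loadings, res$loadings, tolerance = 1e-10)
  expect_equal(res2$explained_variance, res$explained_variance,
               tolerance = 1e-10)
})

test_that("pair PCA equals full PCA when the pair covers all samples", {
  truth <- synthetic_truth(p = 6L, stages = c("A", "B"), density = 0.2,
                           seed = 4L)
  d <- generate_dataset(truth, n_rep = 8L, seed = 5L)
  z <- zscore_normalize(d)
  full <- fit_pca(z, 4L)
  pair <- transition_pca(z, c("A", "B"), 4L)
  expect_equal(pair$loadings, full$loadings, tolerance = 1e-10)
  expect_equal(unname(pair$scores), unname(full$scores), tolerance = 1e-10)
  expect_error(transition_pca(z, c("A", "nope")), "fewer than 2 samples")
})

test_that("a dominant single-metabolite split dominates the first pair component", {
  # stages differ only in metabolite 5, whose between-stage split dwarfs the
  # remaining features' spread, so it owns the leading variance direction
  set.seed(9)
  stage <- rep(c("A", "B"), each = 15L)
  X <- matrix(rnorm(30 * 8, sd = 0.5), 30, 8)
  X[, 5L] <- ifelse(stage == "B", 2.5, -2.5) + rnorm(30, sd = 0.5)
  z <- structure(list(values = X, stage_labels = stage,
                      sample_ids = paste0("s", 1:30),
                      metabolite_names = paste0("met_0", 1:8)),
                 class = "NormalizedMatrix")
  res <- transition_pca(z, c("A", "B"), 3L)
  expect_gt(abs(res$loadings["met_05", 1L]), 0.9)
})

test_that("the discriminant selector finds the separating component and orients it", {
  set.seed(12)
  n <- 30
  stage <- rep(c("a", "b"), each = n / 2)
  # component 1 carries big stage-independent variance, component 2 the split
  X <- cbind(rnorm(n, sd = 10), ifelse(stage == "b", 1, -1) + rnorm(n, sd = 0.2),
             rnorm(n, sd = 0.1))
  res <- fit_pca(norm_of(X, stage), 3L)
  ts <- select_discriminant_component(res, stage, c("a", "b"))
  expect_equal(ts$component_index, 2L)
  expect_gte(mean(ts$oriented_scores[stage == "b"]),
             mean(ts$oriented_scores[stage == "a"]))

  # negating the data: the covariance (hence loadings) is unchanged, the
  # per-sample scores flip, orientation re-flips the component — so the
  # oriented sample scores are preserved while every feature association
  # swaps to the opposite stage (a metabolite high in b is now low in b)
  res_neg <- fit_pca(norm_of(-X, stage), 3L)
  ts_neg <- select_discriminant_component(res_neg, stage, c("a", "b"))
  expect_equal(ts_neg$oriented_scores, ts$oriented_scores, tolerance = 1e-10)
  nz <- ts$feature_score != 0
  expect_true(all(ts_neg$assigned_stage[nz] != ts$assigned_stage[nz]))
})

test_that("orientation holds for every transition of random datasets", {
  for (seed in 1:5) {
    truth <- synthetic_truth(p = 10L, density = 0.1, seed = seed)
    truth <- plant_markers(truth, 2L, c("met_01", "met_07"), shift = 1.5)
    d <- generate_dataset(truth, n_rep = 6L, seed = seed + 100L)
    z <- zscore_normalize(d)
    for (pair in truth$stages$transitions) {
      ts <- select_discriminant_component(transition_pca(z, pair))
      a <- z$stage_labels[z$stage_labels %in% pair] == pair[1L]
      expect_gte(mean(ts$oriented_scores[!a]), mean(ts$oriented_scores[a]))
      nz <- ts$feature_score != 0
      expect_true(all(!is.na(ts$assigned_stage[nz])))
      expect_true(all(ts$assigned_stage[nz] %in% pair))
    }
  }
})

test_that("planted stage-b markers score highest and are assigned to stage b", {
  truth <- synthetic_truth(p = 12L, stages = c("A", "B"), density = 0.05,
                           seed = 21L)
  mk <- c("met_02", "met_09")
  truth <- plant_markers(truth, c("A", "B"), mk, shift = 3)
  d <- generate_dataset(truth, n_rep = 40L, seed = 22L)
  ts <- select_discriminant_component(
    transition_pca(zscore_normalize(d), c("A", "B")))
  expect_identical(unname(ts$assigned_stage[mk]), c("B", "B"))
  top <- names(sort(abs(ts$feature_score), decreasing = TRUE))[1:2]
  expect_setequal(top, mk)
})
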
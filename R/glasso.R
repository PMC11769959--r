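#' Empirical covariance of standardized data
#'
#' `S = X'X / n` on the column-centered matrix (divisor n - 1 when the
#' normalization used sample standard deviations, so that standardized data
#' always yield a unit diagonal).
#'
#' @param norm a [zscore_normalize()] result, or any list with a numeric
#'   `values` matrix.
#' @return A `CovarianceEstimate`: `S` (p x p, symmetric PSD), `n_samples`.
#' @export
empirical_covariance <- function(norm) {
  X <- norm$values
  n <- nrow(X)
  if (n < 2L) stop("covariance needs at least 2 samples")
  Xc <- sweep(X, 2L, colMeans(X), "-")
  divisor <- if (identical(norm$sd_type, "sample")) n - 1L else n
  S <- crossprod(Xc) / divisor
  S <- (S + t(S)) / 2
  structure(list(S = S, n_samples = n), class = "CovarianceEstimate")
}

.check_cov_input <- function(S) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) stop("S must be a square matrix")
  if (max(abs(S - t(S))) > 1e-8 * max(abs(S), 1)) stop("S must be symmetric")
  ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    stop("S must be positive semidefinite (min eigenvalue ",
         format(min(ev)), ")")
  }
  ev
}

#' Graphical lasso: L1-penalized sparse precision estimation
#'
#' Maximizes the penalized Gaussian log-likelihood
#' `log det(Theta) - tr(S Theta) - alpha * sum_{i != j} |Theta_ij|`
#' by blockwise coordinate descent on the working covariance `W`: each
#' column subproblem is a lasso solved by cyclic coordinate descent
#' (implemented in compiled code). Iteration stops when the duality gap
#' falls below `tol` or after `max_iter` sweeps. By default only
#' off-diagonal entries are penalized, so the estimated covariance keeps the
#' empirical diagonal.
#'
#' @param S a [empirical_covariance()] result or a symmetric PSD matrix.
#' @param alpha L1 penalty, >= 0. `alpha = 0` requires a nonsingular `S` and
#'   returns its inverse.
#' @param tol duality-gap convergence tolerance (default 1e-4).
#' @param max_iter maximum number of outer sweeps (default 250).
#' @param penalize_diagonal also penalize diagonal entries (default FALSE).
#' @param warm optional previous `PrecisionEstimate` on the same problem
#'   shape used as a warm start (speeds up penalty paths).
#' @return A `PrecisionEstimate`: `theta` (sparse precision, symmetric PD),
#'   `W` (estimated covariance, `W %*% theta ~ I`), `alpha`, `n_iter`,
#'   `gap` (final duality gap), `converged`, and the per-sweep `dual_trace`
#'   (`log det W`, non-decreasing by construction) and `primal_trace`
#'   (penalized log-likelihood at `Theta`).
#' @export
graphical_lasso <- function(S, alpha, tol = 1e-4, max_iter = 250L,
                            penalize_diagonal = FALSE, warm = NULL) {
  if (inherits(S, "CovarianceEstimate")) S <- S$S
  ev <- .check_cov_input(S)
  if (alpha < 0) stop("alpha must be >= 0")
  p <- nrow(S)
  if (alpha == 0) {
    if (min(ev) < 1e-12 * max(ev)) {
      stop("alpha = 0 requires a nonsingular covariance matrix")
    }
    theta <- solve(S)
    theta <- (theta + t(theta)) / 2
    return(structure(list(theta = theta, W = S, alpha = 0, n_iter = 0L,
                          gap = 0, converged = TRUE,
                          dual_trace = numeric(0), primal_trace = numeric(0)),
                     class = "PrecisionEstimate"))
  }
  if (p == 1L) {
    d <- S[1L, 1L] + if (penalize_diagonal) alpha else 0
    return(structure(list(theta = matrix(1 / d), W = matrix(d), alpha = alpha,
                          n_iter = 1L, gap = 0, converged = TRUE,
                          dual_trace = log(d), primal_trace = -log(d) - 1),
                     class = "PrecisionEstimate"))
  }
  fit <- .glasso_cd(S, alpha, tol, as.integer(max_iter), penalize_diagonal,
                    if (!is.null(warm)) warm$W else NULL,
                    if (!is.null(warm)) warm$B else NULL)
  theta <- (fit$theta + t(fit$theta)) / 2
  W <- (fit$W + t(fit$W)) / 2
  dimnames(theta) <- dimnames(W) <- dimnames(S)
  structure(list(theta = theta, W = W, B = fit$B, alpha = alpha,
                 n_iter = fit$n_iter, gap = fit$gap,
                 converged = fit$converged,
                 dual_trace = fit$dual_trace,
                 primal_trace = fit$primal_trace),
            class = "PrecisionEstimate")
}

#' @export
print.PrecisionEstimate <- function(x, ...) {
  p <- nrow(x$theta)
  nz <- sum(abs(x$theta[upper.tri(x$theta)]) > 1e-8)
  cat(sprintf("PrecisionEstimate: p = %d, alpha = %g, %d nonzero off-diagonal pairs\n",
              p, x$alpha, nz))
  cat(sprintf("%d sweep(s), duality gap %.2e, converged: %s\n",
              x$n_iter, x$gap, x$converged))
  invisible(x)
}

.holdout_loglik <- function(theta, S_test) {
  d <- determinant(theta, logarithm = TRUE)
  as.numeric(d$modulus) - sum(S_test * theta)
}

#' Cross-validated penalty selection for the graphical lasso
#'
#' K-fold cross-validation on the held-out Gaussian log-likelihood
#' `log det(Theta) - tr(S_test Theta)`. The penalty grid is refined
#' iteratively: each round places `n_points` log-spaced values inside the
#' interval bracketing the current best (round 1 spans
#' `[alpha_max / 100, alpha_max]` with `alpha_max = max |S_ij|, i != j`).
#' Fold assignment is a seeded permutation and is recorded in the output.
#'
#' @param norm a [zscore_normalize()] result.
#' @param n_folds number of folds (default 5); each training split must keep
#'   at least 2 samples.
#' @param n_rounds,n_points grid refinement schedule (default 4 rounds of 4
#'   points).
#' @param tol,max_iter passed to [graphical_lasso()].
#' @param seed integer seed for the fold permutation.
#' @param grid optional explicit alpha grid; when supplied the refinement
#'   schedule is skipped and exactly these values are scored.
#' @return list with `alpha_best`, `cv_table` (data.frame: `alpha`,
#'   `mean_loglik`, `round`), `folds` (the fold assignment), `seed`.
#' @export
cross_validate_alpha <- function(norm, n_folds = 5L, n_rounds = 4L,
                                 n_points = 4L, tol = 1e-4, max_iter = 250L,
                                 seed = 1L, grid = NULL) {
  X <- norm$values
  n <- nrow(X)
  if (n_folds < 2L || n < n_folds) stop("need n_samples >= n_folds >= 2")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  folds <- sample(rep_len(seq_len(n_folds), n))
  for (f in seq_len(n_folds)) {
    if (sum(folds != f) < 2L) stop("fold ", f, " leaves < 2 training samples")
  }
  divisor_sample <- identical(norm$sd_type, "sample")
  cov_of <- function(rows, center) {
    Xc <- sweep(X[rows, , drop = FALSE], 2L, center, "-")
    d <- if (divisor_sample) max(sum(rows) - 1L, 1L) else sum(rows)
    crossprod(Xc) / d
  }
  score_alpha <- function(alpha) {
    ll <- numeric(n_folds)
    for (f in seq_len(n_folds)) {
      train <- folds != f
      center <- colMeans(X[train, , drop = FALSE])
      S_train <- cov_of(train, center)
      S_test <- cov_of(!train, center)
      fit <- graphical_lasso(S_train, alpha, tol = tol, max_iter = max_iter)
      ll[f] <- .holdout_loglik(fit$theta, S_test)
    }
    mean(ll)
  }

  if (!is.null(grid)) {
    ll <- vapply(grid, score_alpha, numeric(1))
    return(list(alpha_best = grid[which.max(ll)],
                cv_table = data.frame(alpha = grid, mean_loglik = ll,
                                      round = 1L),
                folds = folds, seed = seed))
  }

  S_full <- empirical_covariance(norm)$S
  amax <- max(abs(S_full[row(S_full) != col(S_full)]))
  if (!is.finite(amax) || amax <= 0) amax <- 1
  lo <- amax / 100
  hi <- amax
  table_alpha <- numeric(0)
  table_ll <- numeric(0)
  table_round <- integer(0)
  best_alpha <- NA_real_
  for (r in seq_len(n_rounds)) {
    grid <- exp(seq(log(hi), log(lo), length.out = n_points))
    grid <- setdiff(round(grid, 12), round(table_alpha, 12))
    for (a in grid) {
      table_alpha <- c(table_alpha, a)
      table_ll <- c(table_ll, score_alpha(a))
      table_round <- c(table_round, r)
    }
    ord <- order(table_alpha)
    alphas_sorted <- table_alpha[ord]
    ll_sorted <- table_ll[ord]
    b <- which.max(ll_sorted)
    best_alpha <- alphas_sorted[b]
    # refine between the neighbours of the incumbent, never beyond the
    # initial bracket: every alpha >= alpha_max gives the same diagonal fit
    lo <- if (b > 1L) alphas_sorted[b - 1L] else max(alphas_sorted[b] / 2,
                                                     amax / 100)
    hi <- if (b < length(alphas_sorted)) alphas_sorted[b + 1L] else amax
  }
  list(alpha_best = best_alpha,
       cv_table = data.frame(alpha = table_alpha, mean_loglik = table_ll,
                             round = table_round),
       folds = folds, seed = seed)
}

# save/restore the global RNG state so seeded internals do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Partial-correlation network from a precision estimate
#'
#' Edges connect metabolite pairs with `|theta_ij|` above `edge_threshold`;
#' the edge weight is the partial correlation
#' `-theta_ij / sqrt(theta_ii * theta_jj)` (positive weights are drawn
#' solid, negative dashed; magnitude maps to line thickness). Metabolites
#' left with no edges are dropped from the node list, mirroring
#' isolated-node pruning in the drawn network.
#'
#' @param est a [graphical_lasso()] result.
#' @param names metabolite names, length p.
#' @param edge_threshold minimum `|theta_ij|` for an edge (default 1e-8,
#'   i.e. numerical zero — the lasso already sparsifies).
#' @return A `SparseNetwork`: `nodes` (names with >= 1 edge, input order),
#'   `edges` (data.frame `from`, `to`, `partial_correlation` with
#'   `from < to` in input order), `p`, `all_names`.
#' @export
network_from_precision <- function(est, names, edge_threshold = 1e-8) {
  stopifnot(inherits(est, "PrecisionEstimate"))
  theta <- est$theta
  p <- nrow(theta)
  if (length(names) != p) {
    stop("expected ", p, " names, got ", length(names))
  }
  d <- sqrt(diag(theta))
  pc <- -theta / tcrossprod(d)
  idx <- which(upper.tri(theta) & abs(theta) > edge_threshold, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, 1L], idx[, 2L])
    idx <- idx[ord, , drop = FALSE]
    edges <- data.frame(from = names[idx[, 1L]],
                        to = names[idx[, 2L]],
                        partial_correlation = pc[idx],
                        stringsAsFactors = FALSE)
    nodes <- names[sort(unique(c(idx[, 1L], idx[, 2L])))]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        partial_correlation = numeric(),
                        stringsAsFactors = FALSE)
    nodes <- character()
  }
  structure(list(nodes = nodes, edges = edges, p = p, all_names = names),
            class = "SparseNetwork")
}

#' @export
print.SparseNetwork <- function(x, ...) {
  cat("SparseNetwork:", length(x$nodes), "connected nodes (of", x$p,
      "features ),", nrow(x$edges), "edges\n")
  invisible(x)
}
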
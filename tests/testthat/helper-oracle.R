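# Independent oracle for the penalized precision estimate: projected gradient
# ascent on the dual problem
#   maximize log det(S + Gamma)  s.t.  Gamma symmetric, diag(Gamma) = 0,
#                                      |Gamma_ij| <= alpha,
# with backtracking line search. Theta = (S + Gamma)^-1. Entirely separate
# from the blockwise coordinate-descent path it is used to check.
glasso_pg_oracle <- function(S, alpha, gap_tol = 1e-8, max_iter = 200000L) {
  p <- nrow(S)
  Gamma <- matrix(0, p, p)
  off <- row(S) != col(S)
  logdet <- function(W) {
    ch <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    2 * sum(log(diag(ch)))
  }
  project <- function(G) {
    G <- (G + t(G)) / 2
    G[G > alpha] <- alpha
    G[G < -alpha] <- -alpha
    diag(G) <- 0
    G
  }
  gap_of <- function(W) {
    theta <- solve(W)
    theta <- (theta + t(theta)) / 2
    sum(S * theta) - p + alpha * sum(abs(theta[off]))
  }
  obj <- logdet(S + Gamma)
  step <- 1
  for (it in seq_len(max_iter)) {
    W <- S + Gamma
    Grad <- solve(W)
    repeat {
      cand <- project(Gamma + step * Grad)
      cobj <- logdet(S + cand)
      if (cobj >= obj - 1e-14) break
      step <- step / 2
      if (step < 1e-14) break
    }
    moved <- max(abs(cand - Gamma))
    Gamma <- cand
    obj <- logdet(S + Gamma)
    step <- min(step * 2, 1)
    if (it %% 25L == 0L || moved < 1e-13) {
      if (gap_of(S + Gamma) < gap_tol) break
      if (moved < 1e-13) break
    }
  }
  W <- S + Gamma
  theta <- solve(W)
  theta <- (theta + t(theta)) / 2
  list(theta = theta, W = W, gap = gap_of(W))
}

# random correlation-like PSD matrix of size p (well-conditioned for small p)
random_cov <- function(p, seed, n = 50L) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  S <- crossprod(scale(X)) / n
  (S + t(S)) / 2
}

# small deterministic toy dataset: k stages x n_rep replicates, p metabolites
toy_data <- function(k = 5L, n_rep = 3L, p = 5L, seed = 1L) {
  set.seed(seed)
  stages <- paste0("S", seq_len(k))
  vals <- matrix(abs(rnorm(k * n_rep * p, mean = 10, sd = 2)), k * n_rep, p)
  concentration_matrix(vals,
                       stage_labels = rep(stages, each = n_rep),
                       replicate_ids = rep(seq_len(n_rep), times = k),
                       metabolite_names = paste0("m", seq_len(p)))
}

toy_stages <- function(k = 5L) stage_sequence(paste0("S", seq_len(k)))
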
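#' Generate a planted sparse precision matrix
#'
#' Erdős–Rényi support with off-diagonal magnitudes uniform in [0.1, 0.4]
#' and random sign; the diagonal is set to the absolute row sum plus 0.5,
#' which makes the matrix strictly diagonally dominant and hence positive
#' definite (Gershgorin bound: minimum eigenvalue >= 0.5).
#'
#' @param p number of features (>= 2).
#' @param density edge probability in (0, 1).
#' @param seed integer seed; the draw is deterministic per seed.
#' @return list with `theta_true` (p x p precision) and `support`
#'   (data.frame `i`, `j` with `i < j` of planted edges).
#' @export
generate_precision <- function(p, density, seed = 1L) {
  stopifnot(p >= 2L, density > 0, density < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  theta <- matrix(0, p, p)
  ut <- which(upper.tri(theta))
  present <- rbinom(length(ut), 1L, density) == 1L
  vals <- runif(sum(present), 0.1, 0.4) *
    sample(c(-1, 1), sum(present), replace = TRUE)
  theta[ut[present]] <- vals
  theta <- theta + t(theta)
  diag(theta) <- rowSums(abs(theta)) + 0.5
  idx <- which(upper.tri(theta) & theta != 0, arr.ind = TRUE)
  support <- data.frame(i = idx[, 1L], j = idx[, 2L])
  support <- support[order(support$i, support$j), , drop = FALSE]
  rownames(support) <- NULL
  list(theta_true = theta, support = support)
}

#' Construct a synthetic ground truth
#'
#' Holds a planted precision matrix, per-stage mean shifts (in units of each
#' feature's marginal standard deviation) and the planted marker sets used
#' to grade marker recovery. Mean shifts start at zero; use
#' [plant_markers()] to add them.
#'
#' @param p number of features.
#' @param stages a [stage_sequence()] or character vector of stage names
#'   (default: the five-stage neural differentiation sequence).
#' @param density planted edge probability.
#' @param seed integer seed.
#' @return A `SyntheticTruth`: `theta_true`, `support`, `stage_means`
#'   (k x p, standardized units), `marker_sets` (named list per transition),
#'   `stages`, `metabolite_names`, `seed`.
#' @export
synthetic_truth <- function(p, stages = c("hESC", "EB", "Rosette", "hNPC",
                                          "Neuron"),
                            density = 0.05, seed = 1L) {
  if (!inherits(stages, "StageSequence")) stages <- stage_sequence(stages)
  prec <- generate_precision(p, density, seed)
  k <- length(stages$stages)
  mets <- sprintf("met_%02d", seq_len(p))
  structure(list(theta_true = prec$theta_true,
                 support = prec$support,
                 stage_means = matrix(0, k, p,
                                      dimnames = list(stages$stages, mets)),
                 marker_sets = list(),
                 stages = stages,
                 metabolite_names = mets,
                 seed = seed),
            class = "SyntheticTruth")
}

#' Plant stage markers into a synthetic truth
#'
#' Adds `shift` (in feature-sd units) to the marker features' means at stage
#' b of the transition and every later stage — a persistent step profile,
#' the kind of change a template like `"1-1-2-2-2"` describes. A pulse
#' profile (stage b only) is available via `profile = "pulse"`.
#'
#' @param truth a [synthetic_truth()].
#' @param transition character pair `c(stage_a, stage_b)` or the index of a
#'   consecutive transition.
#' @param markers metabolite names (from `truth$metabolite_names`).
#' @param shift standardized mean shift.
#' @param profile `"step"` (default) or `"pulse"`.
#' @return the updated `SyntheticTruth` with the marker set recorded.
#' @export
plant_markers <- function(truth, transition, markers, shift,
                          profile = c("step", "pulse")) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  profile <- match.arg(profile)
  if (is.numeric(transition)) transition <- truth$stages$transitions[[transition]]
  transition <- as.character(transition)
  ok <- any(vapply(truth$stages$transitions, identical, logical(1),
                   y = transition))
  if (!ok) stop("(", paste(transition, collapse = ", "),
                ") is not a consecutive transition of the stage sequence")
  bad <- setdiff(markers, truth$metabolite_names)
  if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
  b <- match(transition[2L], truth$stages$stages)
  rows <- if (profile == "step") b:length(truth$stages$stages) else b
  truth$stage_means[rows, markers] <- truth$stage_means[rows, markers] + shift
  truth$marker_sets[[paste(transition, collapse = "->")]] <- markers
  truth
}

#' Draw a synthetic longitudinal dataset from a planted truth
#'
#' For each stage, `n_rep` samples from a multivariate Gaussian with
#' covariance `solve(theta_true)` and mean `stage_means[s, ] * sd`, where
#' `sd` is each feature's marginal standard deviation (so planted shifts are
#' in standardized units). The raw Gaussian draw is the default since the
#' pipeline standardizes anyway; `positivity = "exp"` exponentiates and
#' `"shift"` translates to the positive orthant for workflows that insist on
#' non-negative concentrations.
#'
#' @param truth a [synthetic_truth()].
#' @param n_rep replicates per stage (>= 2).
#' @param seed integer seed.
#' @param positivity `"none"` (default), `"exp"` or `"shift"`.
#' @return a [concentration_matrix()] with stage and replicate labels.
#' @export
generate_dataset <- function(truth, n_rep, seed = 1L,
                             positivity = c("none", "exp", "shift")) {
  stopifnot(inherits(truth, "SyntheticTruth"), n_rep >= 2L)
  positivity <- match.arg(positivity)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Sigma <- solve(truth$theta_true)
  Sigma <- (Sigma + t(Sigma)) / 2
  R <- chol(Sigma)
  sds <- sqrt(diag(Sigma))
  k <- length(truth$stages$stages)
  p <- ncol(Sigma)
  X <- matrix(NA_real_, k * n_rep, p)
  stage_labels <- character(k * n_rep)
  replicate_ids <- character(k * n_rep)
  for (s in seq_len(k)) {
    Z <- matrix(rnorm(n_rep * p), n_rep, p)
    rows <- (s - 1L) * n_rep + seq_len(n_rep)
    X[rows, ] <- Z %*% R +
      matrix(truth$stage_means[s, ] * sds, n_rep, p, byrow = TRUE)
    stage_labels[rows] <- truth$stages$stages[s]
    replicate_ids[rows] <- as.character(seq_len(n_rep))
  }
  if (positivity == "exp") X <- exp(X) else
    if (positivity == "shift") X <- X - min(X) + 1
  concentration_matrix(X, stage_labels, replicate_ids,
                       sample_ids = paste(stage_labels, replicate_ids, sep = "_"),
                       metabolite_names = truth$metabolite_names,
                       stages = truth$stages)
}

#' Round-robin class annotation for synthetic metabolites
#'
#' Assigns each metabolite one of `classes` cyclically — a stand-in for a
#' curated compound-class table when exercising composition summaries on
#' synthetic data.
#'
#' @param metabolite_names character vector.
#' @param classes class labels (default: eight generic compound classes).
#' @return an [annotation_table()].
#' @export
synthetic_annotation <- function(metabolite_names,
                                 classes = c("amino acid", "bioenergetics",
                                             "peptide", "carbohydrate",
                                             "nucleotide", "organic acid",
                                             "amine", "lipid")) {
  annotation_table(metabolite_names,
                   rep_len(classes, length(metabolite_names)))
}

#' Edge-set F1 between an estimated and a planted precision support
#'
#' Precision/recall/F1 of the estimated off-diagonal support against the
#' planted one — the structure-recovery score used to validate the solver on
#' synthetic data.
#'
#' @param theta_hat estimated precision matrix.
#' @param support planted support (data.frame `i`, `j`), as produced by
#'   [generate_precision()].
#' @param threshold `|theta_ij|` above which an estimated edge counts.
#' @return list with `precision`, `recall`, `f1`, `n_estimated`, `n_true`.
#' @export
support_f1 <- function(theta_hat, support, threshold = 1e-8) {
  p <- nrow(theta_hat)
  est <- which(upper.tri(theta_hat) & abs(theta_hat) > threshold)
  true <- (support$j - 1L) * p + support$i
  tp <- length(intersect(est, true))
  prec <- if (length(est)) tp / length(est) else if (!length(true)) 1 else 0
  rec <- if (length(true)) tp / length(true) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1,
       n_estimated = length(est), n_true = length(true))
}
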
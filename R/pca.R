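#' Principal component analysis with a deterministic sign convention
#'
#' Thin SVD of the column-centered data. Each loading column is flipped so
#' that its largest-absolute entry is positive, making the output
#' deterministic across numerical backends. Explained variances use the
#' sample convention (divisor n - 1), so they sum to the total column
#' variance of the input.
#'
#' @param norm a [zscore_normalize()] result (or any object with a numeric
#'   `values` matrix and `metabolite_names`).
#' @param n_components number of components to keep; at most
#'   `min(n_samples - 1, n_metabolites)`.
#' @return A `PCAResult`: `loadings` (p x k, orthonormal columns), `scores`
#'   (n x k, equal to the centered data times the loadings),
#'   `explained_variance`, `explained_variance_ratio` (non-increasing, sums
#'   to <= 1), `n_components`, `center` (the column means removed), plus the
#'   sample metadata of the input when present.
#' @export
fit_pca <- function(norm, n_components = NULL) {
  X <- norm$values
  n <- nrow(X)
  p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (is.null(n_components)) n_components <- min(10L, kmax)
  if (n_components < 1L || n_components > kmax) {
    stop("n_components must be between 1 and ", kmax,
         " (min(n_samples - 1, n_metabolites))")
  }
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center, "-")
  sv <- svd(Xc, nu = 0, nv = kmax)
  ev_all <- sv$d[seq_len(kmax)]^2 / (n - 1L)
  total_var <- sum(ev_all)
  loadings <- sv$v[, seq_len(n_components), drop = FALSE]
  # sign convention: largest-|entry| of each loading column is positive
  for (j in seq_len(n_components)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) loadings[, j] <- -loadings[, j]
  }
  scores <- Xc %*% loadings
  rownames(loadings) <- norm$metabolite_names
  colnames(loadings) <- paste0("PC", seq_len(n_components))
  rownames(scores) <- rownames(X)
  colnames(scores) <- colnames(loadings)
  structure(list(loadings = loadings,
                 scores = scores,
                 explained_variance = ev_all[seq_len(n_components)],
                 explained_variance_ratio =
                   if (total_var > 0) ev_all[seq_len(n_components)] / total_var
                   else rep(0, n_components),
                 explained_variance_all = ev_all,
                 n_components = n_components,
                 center = center,
                 sample_ids = norm$sample_ids,
                 stage_labels = norm$stage_labels),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", x$n_components, "components over",
      nrow(x$scores), "samples x", nrow(x$loadings), "features\n")
  cat("explained variance ratio:",
      paste(sprintf("%.3f", x$explained_variance_ratio), collapse = " "), "\n")
  invisible(x)
}

#' PCA restricted to one stage pair
#'
#' Subsets the samples to the two stages of a transition and re-centers on
#' the subset. By default the global standardization is kept (a single
#' normalized dataset feeds all pairs); `rescale = TRUE` re-standardizes
#' within the pair instead.
#'
#' @param norm a [zscore_normalize()] result.
#' @param pair character pair `c(stage_a, stage_b)`; both stages need at
#'   least 2 samples.
#' @param n_components passed to [fit_pca()] (default: all admissible, up to
#'   10).
#' @param rescale re-standardize columns within the pair subset.
#' @return A `PCAResult` for the pair's samples, with `pair` attached.
#' @export
transition_pca <- function(norm, pair, n_components = NULL, rescale = FALSE) {
  stopifnot(inherits(norm, "NormalizedMatrix"), length(pair) == 2L)
  rows <- norm$stage_labels %in% pair
  for (s in pair) {
    if (sum(norm$stage_labels == s) < 2L) {
      stop("stage '", s, "' has fewer than 2 samples")
    }
  }
  sub <- norm
  sub$values <- norm$values[rows, , drop = FALSE]
  sub$sample_ids <- norm$sample_ids[rows]
  sub$stage_labels <- norm$stage_labels[rows]
  sub$replicate_ids <- norm$replicate_ids[rows]
  if (rescale) {
    cm <- concentration_matrix(sub$values, sub$stage_labels, sub$replicate_ids,
                               sample_ids = sub$sample_ids,
                               metabolite_names = sub$metabolite_names)
    sub <- zscore_normalize(cm, sd_type = norm$sd_type)
  }
  res <- fit_pca(sub, n_components)
  res$pair <- pair
  res
}

#' Select the stage-discriminating component of a pair PCA
#'
#' For each component the standardized group separation
#' `|mean(score | b) - mean(score | a)| / pooled within-stage sd` is
#' computed; the maximizing component is selected (ties fall back to the
#' lowest index) and oriented so that stage b's mean score is >= stage a's.
#' The oriented loadings are the per-metabolite feature scores: a positive
#' score associates the metabolite with stage b, a negative one with
#' stage a.
#'
#' @param result a [transition_pca()] (or [fit_pca()]) result whose samples
#'   span exactly two stages.
#' @param pair_labels per-sample stage labels; defaults to the labels stored
#'   in `result`.
#' @param pair the ordered pair `c(stage_a, stage_b)`; defaults to the pair
#'   stored in `result`.
#' @return A `TransitionScores`: `pair`, `component_index`, `feature_score`
#'   (signed oriented loadings), `assigned_stage` (per metabolite, `NA` for
#'   exactly-zero scores), `separation` (the selected component's
#'   standardized mean difference), `oriented_scores` (per-sample scores on
#'   the selected, oriented component).
#' @export
select_discriminant_component <- function(result, pair_labels = NULL,
                                          pair = NULL) {
  stopifnot(inherits(result, "PCAResult"))
  if (is.null(pair_labels)) pair_labels <- result$stage_labels
  if (is.null(pair)) pair <- result$pair
  if (is.null(pair_labels) || is.null(pair)) {
    stop("pair_labels and pair are required when not stored in the PCA result")
  }
  present <- unique(pair_labels)
  if (length(present) != 2L || !setequal(present, pair)) {
    stop("exactly the two stages ", paste(pair, collapse = ", "),
         " must be present")
  }
  a <- pair_labels == pair[1L]
  b <- pair_labels == pair[2L]
  na <- sum(a); nb <- sum(b)
  sep <- vapply(seq_len(result$n_components), function(j) {
    sc <- result$scores[, j]
    ma <- mean(sc[a]); mb <- mean(sc[b])
    va <- if (na > 1L) var(sc[a]) else 0
    vb <- if (nb > 1L) var(sc[b]) else 0
    pooled <- sqrt(((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L))
    d <- abs(mb - ma)
    if (pooled > 0) d / pooled else if (d > 0) Inf else 0
  }, numeric(1))
  if (all(sep == 0 | is.nan(sep))) {
    stop("degenerate data: zero between-stage separation on every component")
  }
  k <- which.max(sep)  # ties -> lowest index
  sc <- result$scores[, k]
  load <- result$loadings[, k]
  if (mean(sc[b]) < mean(sc[a])) {  # orient: stage b scores on top
    sc <- -sc
    load <- -load
  }
  assigned <- ifelse(load > 0, pair[2L], ifelse(load < 0, pair[1L], NA_character_))
  names(assigned) <- names(load)
  structure(list(pair = pair,
                 component_index = k,
                 feature_score = load,
                 assigned_stage = assigned,
                 separation = sep[k],
                 separation_all = sep,
                 oriented_scores = sc),
            class = "TransitionScores")
}

#' @export
print.TransitionScores <- function(x, ...) {
  cat("TransitionScores:", paste(x$pair, collapse = " -> "),
      sprintf("(component %d, separation %.2f)\n", x$component_index,
              x$separation))
  invisible(x)
}
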
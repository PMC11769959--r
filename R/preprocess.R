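#' Mean/standard-deviation normalize a concentration matrix
#'
#' Column-standardizes the concentrations: every metabolite gets mean 0 and
#' standard deviation 1 over all samples. This single global normalization is
#' computed once and reused by the full-dataset PCA, the network inference
#' and (by default) the per-transition analyses, so scores and deltas from
#' different transitions live on one common scale.
#'
#' @param data a [concentration_matrix()].
#' @param sd_type `"population"` (divisor n, default) or `"sample"`
#'   (divisor n - 1).
#' @return A `NormalizedMatrix`: list with `values` (standardized matrix),
#'   `feature_means`, `feature_sds`, `constant_features` (names of columns
#'   with zero variance, which are set to all-zero rather than NaN),
#'   `sd_type`, and the sample metadata carried over from `data`
#'   (`sample_ids`, `stage_labels`, `replicate_ids`, `metabolite_names`).
#' @export
zscore_normalize <- function(data, sd_type = c("population", "sample")) {
  stopifnot(inherits(data, "ConcentrationMatrix"))
  sd_type <- match.arg(sd_type)
  X <- data$values
  n <- nrow(X)
  if (n < 2L) stop("normalization needs at least 2 samples")
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu, "-")
  divisor <- if (sd_type == "population") n else n - 1L
  sds <- sqrt(colSums(Xc^2) / divisor)
  const <- sds <= .Machine$double.eps * max(abs(X), 1)
  sds_safe <- ifelse(const, 1, sds)
  Z <- sweep(Xc, 2L, sds_safe, "/")
  Z[, const] <- 0
  structure(list(values = Z,
                 feature_means = mu,
                 feature_sds = sds,
                 constant_features = data$metabolite_names[const],
                 sd_type = sd_type,
                 sample_ids = data$sample_ids,
                 stage_labels = data$stage_labels,
                 replicate_ids = data$replicate_ids,
                 metabolite_names = data$metabolite_names),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat("NormalizedMatrix:", nrow(x$values), "samples x", ncol(x$values),
      "metabolites (", x$sd_type, "sd )\n")
  if (length(x$constant_features)) {
    cat("constant features set to zero:",
        paste(x$constant_features, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-stage mean profile matrix
#'
#' @param norm a [zscore_normalize()] result.
#' @param stages a [stage_sequence()]; every stage must have at least one
#'   sample.
#' @return stages x metabolites matrix of arithmetic means of the normalized
#'   values.
#' @export
stage_means <- function(norm, stages) {
  stopifnot(inherits(norm, "NormalizedMatrix"), inherits(stages, "StageSequence"))
  out <- matrix(NA_real_, length(stages$stages), ncol(norm$values),
                dimnames = list(stages$stages, norm$metabolite_names))
  for (s in stages$stages) {
    rows <- norm$stage_labels == s
    if (!any(rows)) stop("stage '", s, "' has no samples")
    out[s, ] <- colMeans(norm$values[rows, , drop = FALSE])
  }
  out
}

#' Signed per-metabolite concentration change over a transition
#'
#' `delta(m) = mean_b(m) - mean_a(m)` on the normalized scale. The network
#' overlay consumes `|delta|` as node size and `sign(delta)` as direction.
#'
#' @param means a [stage_means()] matrix.
#' @param pair character pair `c(stage_a, stage_b)`.
#' @return named numeric vector of signed deltas.
#' @export
transition_delta <- function(means, pair) {
  stopifnot(length(pair) == 2L)
  bad <- setdiff(pair, rownames(means))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  means[pair[2L], ] - means[pair[1L], ]
}
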
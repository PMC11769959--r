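#' Parse a dash-separated concentration pattern template
#'
#' A template assigns one expected relative concentration level per stage,
#' written as numbers separated by `-` (e.g. `"1-2-3-4-5"` for a linear
#' increase across five stages, `"2-1-1-1-1"` for elevation only in the
#' first stage). Unicode dashes are tolerated.
#'
#' @param spec the template string; must split into exactly
#'   `length(stages$stages)` numeric tokens, not all equal.
#' @param stages a [stage_sequence()].
#' @return A `PatternTemplate`: `levels` (numeric, named by stage),
#'   `stages`.
#' @export
parse_template <- function(spec, stages) {
  stopifnot(inherits(stages, "StageSequence"))
  norm_spec <- gsub("[‐‑‒–—]", "-", spec)
  tokens <- strsplit(norm_spec, "-", fixed = TRUE)[[1L]]
  tokens <- tokens[nzchar(tokens)]
  k <- length(stages$stages)
  if (length(tokens) != k) {
    stop("template '", spec, "' has ", length(tokens),
         " levels but the stage sequence has ", k)
  }
  levels <- suppressWarnings(as.numeric(tokens))
  if (anyNA(levels)) stop("non-numeric template token: ",
                          tokens[which(is.na(levels))[1L]])
  if (length(unique(levels)) == 1L) {
    stop("constant template carries no pattern")
  }
  structure(list(levels = setNames(levels, stages$stages), stages = stages),
            class = "PatternTemplate")
}

#' Template-pattern correlation screen across ordered stages
#'
#' For every metabolite, the Pearson (or Spearman) correlation between its
#' values and the template level of each sample's stage; the two-sided
#' p-value comes from the t distribution with n - 2 degrees of freedom.
#' By default the template level is assigned per sample, so replicate
#' variance penalizes noisy matches; `mode = "stage_means"` correlates the
#' per-stage mean profile with the template instead.
#'
#' @param data a [concentration_matrix()].
#' @param template a [parse_template()] result.
#' @param mode `"samples"` (default) or `"stage_means"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param fdr add a Benjamini-Hochberg adjusted p-value column.
#' @return A `PatternResult` data.frame: `metabolite`, `r`, `p_value`,
#'   `sign_class` (`"positive"`/`"negative"`/`"none"`), `constant` (flag for
#'   zero-variance metabolites, reported as r = 0, p = 1), optionally
#'   `p_adjusted`. Rows follow the input metabolite order.
#' @export
pattern_hunter <- function(data, template, mode = c("samples", "stage_means"),
                           method = c("pearson", "spearman"), fdr = FALSE) {
  stopifnot(inherits(data, "ConcentrationMatrix"),
            inherits(template, "PatternTemplate"))
  mode <- match.arg(mode)
  method <- match.arg(method)
  stages <- template$stages
  bad <- setdiff(unique(data$stage_labels), stages$stages)
  if (length(bad)) stop("stage label(s) not in template's sequence: ",
                        paste(bad, collapse = ", "))
  for (s in stages$stages) {
    if (!any(data$stage_labels == s)) stop("stage '", s, "' has no samples")
  }
  if (mode == "samples") {
    x <- unname(template$levels[data$stage_labels])
    Y <- data$values
  } else {
    x <- unname(template$levels)
    Y <- vapply(stages$stages, function(s) {
      colMeans(data$values[data$stage_labels == s, , drop = FALSE])
    }, numeric(ncol(data$values)))
    Y <- t(Y)
  }
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations for the screen")
  res <- lapply(seq_len(ncol(Y)), function(j) {
    y <- Y[, j]
    if (sd(y) == 0) return(c(r = 0, p = 1, const = 1))
    r <- cor(x, y, method = method)
    tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = n - 2)
    c(r = r, p = max(p, .Machine$double.xmin), const = 0)
  })
  res <- do.call(rbind, res)
  out <- data.frame(metabolite = data$metabolite_names,
                    r = res[, "r"],
                    p_value = res[, "p"],
                    sign_class = ifelse(res[, "r"] > 0, "positive",
                                        ifelse(res[, "r"] < 0, "negative", "none")),
                    constant = res[, "const"] == 1,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (fdr) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  structure(out, class = c("PatternResult", "data.frame"))
}

#' All-pairs metabolite correlation matrix
#'
#' Pearson correlations between every pair of metabolites over all samples.
#' Constant metabolites get zero off-diagonal entries (unit diagonal) and
#' are listed in the `"constant_features"` attribute.
#'
#' @param norm a [zscore_normalize()] result (or a `ConcentrationMatrix`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return symmetric p x p matrix with unit diagonal, entries in [-1, 1].
#' @export
correlation_matrix <- function(norm, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- norm$values
  if (nrow(X) < 3L) stop("need at least 3 samples")
  sds <- apply(X, 2L, sd)
  const <- sds == 0
  C <- suppressWarnings(cor(X, method = method))
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 1
  C <- (C + t(C)) / 2
  diag(C) <- 1
  attr(C, "constant_features") <- colnames(X)[const]
  C
}
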
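#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Defaults follow
#' the published analysis settings: 10 PCA components on the globally
#' standardized data, cross-validated penalty for the full-data network,
#' fixed `alpha = 0.9` for the small per-transition fits (truncated pair
#' datasets are unstable under cross-validation), 250-sweep solver cap.
#'
#' @param n_components PCA components for the full-data and pair fits.
#' @param cv_folds,cv_rounds,cv_points cross-validation schedule for the
#'   full-data penalty (see [cross_validate_alpha()]).
#' @param transition_alpha fixed graphical-lasso penalty for pair networks.
#' @param edge_threshold minimum `|theta_ij|` for a drawn edge.
#' @param tol,max_iter solver settings (see [graphical_lasso()]).
#' @param sd_type standardization convention (see [zscore_normalize()]).
#' @param pair_rescale re-standardize within each pair instead of reusing
#'   the global normalization.
#' @param allow_nonconsecutive permit transition analysis of non-adjacent
#'   stage pairs.
#' @param restrict_to_background keep only transition edges also present in
#'   the background network.
#' @param seed integer seed for all randomized steps (CV fold assignment,
#'   layouts).
#' @return a named list of class `stagenet_config`.
#' @export
stagenet_config <- function(n_components = 10L,
                            cv_folds = 5L, cv_rounds = 4L, cv_points = 4L,
                            transition_alpha = 0.9,
                            edge_threshold = 1e-8,
                            tol = 1e-4, max_iter = 250L,
                            sd_type = c("population", "sample"),
                            pair_rescale = FALSE,
                            allow_nonconsecutive = FALSE,
                            restrict_to_background = FALSE,
                            seed = 1L) {
  structure(list(n_components = as.integer(n_components),
                 cv_folds = as.integer(cv_folds),
                 cv_rounds = as.integer(cv_rounds),
                 cv_points = as.integer(cv_points),
                 transition_alpha = transition_alpha,
                 edge_threshold = edge_threshold,
                 tol = tol, max_iter = as.integer(max_iter),
                 sd_type = match.arg(sd_type),
                 pair_rescale = isTRUE(pair_rescale),
                 allow_nonconsecutive = isTRUE(allow_nonconsecutive),
                 restrict_to_background = isTRUE(restrict_to_background),
                 seed = as.integer(seed)),
            class = "stagenet_config")
}

#' Full-dataset analysis: global PCA and background network
#'
#' Runs the stage-agnostic half of the pipeline: standardize, fit the
#' full-data PCA, select the graphical-lasso penalty by cross-validation on
#' the held-out log-likelihood, and extract the background
#' partial-correlation network that all transition overlays share.
#'
#' @param data a [concentration_matrix()].
#' @param stages a [stage_sequence()] covering the data's stage labels.
#' @param config a [stagenet_config()].
#' @return A `stagenet_fit`: `full_network` ([network_from_precision()]),
#'   `pca_all`, `precision`, `cv` (the cross-validation record), `norm`
#'   (the global normalization), `means` (stage x metabolite normalized
#'   means), `stages`, `config`.
#' @export
stagenet_full <- function(data, stages, config = stagenet_config()) {
  stopifnot(inherits(data, "ConcentrationMatrix"),
            inherits(stages, "StageSequence"))
  bad <- setdiff(unique(data$stage_labels), stages$stages)
  if (length(bad)) stop("stage label(s) not in sequence: ",
                        paste(bad, collapse = ", "))
  norm <- zscore_normalize(data, sd_type = config$sd_type)
  kmax <- min(nrow(norm$values) - 1L, ncol(norm$values))
  pca_all <- fit_pca(norm, min(config$n_components, kmax))
  cv <- cross_validate_alpha(norm, n_folds = config$cv_folds,
                             n_rounds = config$cv_rounds,
                             n_points = config$cv_points,
                             tol = config$tol, max_iter = config$max_iter,
                             seed = config$seed)
  S <- empirical_covariance(norm)
  precision <- graphical_lasso(S, cv$alpha_best, tol = config$tol,
                               max_iter = config$max_iter)
  full_network <- network_from_precision(precision, norm$metabolite_names,
                                         config$edge_threshold)
  structure(list(full_network = full_network,
                 pca_all = pca_all,
                 precision = precision,
                 cv = cv,
                 norm = norm,
                 means = stage_means(norm, stages),
                 stages = stages,
                 config = config),
            class = "stagenet_fit")
}

#' @export
print.stagenet_fit <- function(x, ...) {
  cat("stagenet fit over", length(x$stages$stages), "stages,",
      ncol(x$norm$values), "metabolites\n")
  cat(sprintf("background network: alpha = %.4g (CV), %d nodes, %d edges\n",
              x$precision$alpha, length(x$full_network$nodes),
              nrow(x$full_network$edges)))
  invisible(x)
}

#' Annotated network for one stage transition
#'
#' The overlay step: samples are subset to the pair, a pair PCA is fit and
#' its discriminating component selected, a pair-specific graphical lasso is
#' fit at the configured fixed penalty, and per-metabolite overlay
#' attributes are assembled against the shared background network. Node
#' color in a rendering encodes `assigned_stage`, color intensity the
#' max-normalized `score_intensity`, node size the concentration change
#' `delta_magnitude` over the transition.
#'
#' @param data a [concentration_matrix()].
#' @param pair character pair `c(stage_a, stage_b)`; must be a consecutive
#'   transition of `stages` unless `config$allow_nonconsecutive`.
#' @param background the `full_network` of a [stagenet_full()] fit.
#' @param config a [stagenet_config()].
#' @param fit optional `stagenet_fit`; when supplied its normalization and
#'   stage means are reused (recommended — guarantees one common scale).
#' @param stages a [stage_sequence()]; required when `fit` is missing.
#' @return An `AnnotatedNetwork`: `background_edges`, `transition_edges`,
#'   `node_attrs` (data.frame over all metabolites: `metabolite`,
#'   `assigned_stage`, `feature_score`, `score_intensity` in [0,1],
#'   `delta`, `delta_magnitude`, `delta_sign`), `pair`, `provenance`.
#' @export
stagenet_transition <- function(data, pair, background,
                                config = stagenet_config(), fit = NULL,
                                stages = NULL) {
  stopifnot(length(pair) == 2L)
  if (!is.null(fit)) stages <- fit$stages
  if (is.null(stages)) stop("supply either 'fit' or 'stages'")
  consecutive <- any(vapply(stages$transitions, identical,
                            logical(1), y = as.character(pair)))
  if (!consecutive && !config$allow_nonconsecutive) {
    stop("(", paste(pair, collapse = ", "), ") is not a consecutive ",
         "transition; set allow_nonconsecutive in the config to analyze it")
  }
  norm <- if (!is.null(fit)) fit$norm else
    zscore_normalize(data, sd_type = config$sd_type)
  means <- if (!is.null(fit)) fit$means else stage_means(norm, stages)

  tpca <- transition_pca(norm, pair,
                         n_components = min(config$n_components,
                                            sum(norm$stage_labels %in% pair) - 1L,
                                            ncol(norm$values)),
                         rescale = config$pair_rescale)
  ts <- select_discriminant_component(tpca)

  rows <- norm$stage_labels %in% pair
  sub <- list(values = norm$values[rows, , drop = FALSE], sd_type = norm$sd_type)
  S_pair <- empirical_covariance(sub)
  est <- graphical_lasso(S_pair, config$transition_alpha, tol = config$tol,
                         max_iter = config$max_iter)
  net <- network_from_precision(est, norm$metabolite_names,
                                config$edge_threshold)
  transition_edges <- net$edges
  if (config$restrict_to_background && nrow(transition_edges)) {
    key <- function(e) paste(e$from, e$to, sep = "\r")
    transition_edges <-
      transition_edges[key(transition_edges) %in% key(background$edges), ,
                       drop = FALSE]
    rownames(transition_edges) <- NULL
  }

  delta <- transition_delta(means, pair)
  fs <- ts$feature_score
  mx <- max(abs(fs))
  intensity <- if (mx > 0) abs(fs) / mx else rep(0, length(fs))
  node_attrs <- data.frame(metabolite = norm$metabolite_names,
                           assigned_stage = unname(ts$assigned_stage),
                           feature_score = unname(fs),
                           score_intensity = unname(intensity),
                           delta = unname(delta),
                           delta_magnitude = abs(unname(delta)),
                           delta_sign = sign(unname(delta)),
                           stringsAsFactors = FALSE)
  flag_empty <- length(intersect(net$nodes, background$nodes)) == 0L
  structure(list(background_edges = background$edges,
                 background_nodes = background$nodes,
                 transition_edges = transition_edges,
                 transition_nodes = net$nodes,
                 node_attrs = node_attrs,
                 pair = as.character(pair),
                 no_background_overlap = flag_empty,
                 provenance = list(alpha = config$transition_alpha,
                                   component_index = ts$component_index,
                                   separation = ts$separation,
                                   pair_rescale = config$pair_rescale,
                                   sd_type = norm$sd_type,
                                   edge_threshold = config$edge_threshold)),
            class = "AnnotatedNetwork")
}

#' @export
print.AnnotatedNetwork <- function(x, ...) {
  cat("AnnotatedNetwork:", paste(x$pair, collapse = " -> "), "\n")
  cat(sprintf("  transition edges: %d | background edges: %d | component %d\n",
              nrow(x$transition_edges), nrow(x$background_edges),
              x$provenance$component_index))
  invisible(x)
}

#' Run every consecutive transition against one shared background
#'
#' The headline pipeline: one [stagenet_full()] fit, then one
#' [stagenet_transition()] overlay per consecutive stage pair, all sharing
#' the same background network and global normalization.
#'
#' @inheritParams stagenet_full
#' @return list with `fit` (the `stagenet_fit`) and `transitions` (one
#'   `AnnotatedNetwork` per consecutive pair; `length(stages) - 1` in
#'   total), class `stagenet_run`.
#' @export
run_all_transitions <- function(data, stages, config = stagenet_config()) {
  fit <- stagenet_full(data, stages, config)
  transitions <- lapply(stages$transitions, function(pair) {
    stagenet_transition(data, pair, fit$full_network, config, fit = fit)
  })
  names(transitions) <- vapply(stages$transitions, paste, character(1),
                               collapse = "->")
  structure(list(fit = fit, transitions = transitions),
            class = "stagenet_run")
}

#' @export
print.stagenet_run <- function(x, ...) {
  print(x$fit)
  cat("transitions:", paste(names(x$transitions), collapse = ", "), "\n")
  invisible(x)
}
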
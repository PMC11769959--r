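#' Convert an annotated network to an igraph object
#'
#' Background and transition edges become one graph with a `layer` edge
#' attribute (`"background"` / `"transition"`); every metabolite that is an
#' endpoint of any edge (plus, optionally, all annotated metabolites)
#' becomes a node carrying the overlay attributes.
#'
#' @param net an `AnnotatedNetwork` from [stagenet_transition()].
#' @param include_isolated also include metabolites without any edge.
#' @return an [igraph::graph_from_data_frame()] graph.
#' @export
as_igraph <- function(net, include_isolated = FALSE) {
  stopifnot(inherits(net, "AnnotatedNetwork"))
  bg <- net$background_edges
  tr <- net$transition_edges
  edges <- rbind(
    if (nrow(bg)) cbind(bg, layer = "background"),
    if (nrow(tr)) cbind(tr, layer = "transition"))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        partial_correlation = numeric(), layer = character())
  }
  attrs <- net$node_attrs
  used <- unique(c(edges$from, edges$to))
  verts <- if (include_isolated) attrs else
    attrs[attrs$metabolite %in% used, , drop = FALSE]
  # endpoints must exist even if attrs were subset upstream
  missing <- setdiff(used, verts$metabolite)
  if (length(missing)) {
    pad <- verts[0, , drop = FALSE][seq_along(missing), , drop = FALSE]
    pad$metabolite <- missing
    verts <- rbind(verts, pad)
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Export an annotated network as GraphML
#'
#' Node attributes: `assigned_stage`, `feature_score`, `score_intensity`,
#' `delta`, `delta_magnitude`, `delta_sign`. Edge attributes:
#' `partial_correlation`, `layer`.
#'
#' @param net an `AnnotatedNetwork`.
#' @param path output file.
#' @param include_isolated include edge-less metabolites as nodes.
#' @return `path`, invisibly.
#' @export
export_network_graphml <- function(net, path, include_isolated = FALSE) {
  g <- as_igraph(net, include_isolated = include_isolated)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export node and edge tables of an annotated network as CSV
#'
#' Flat machine-readable companions to any rendering: everything encoded in
#' a figure (size, intensity, color, line style) is derivable from these
#' tables.
#'
#' @param net an `AnnotatedNetwork`.
#' @param node_path,edge_path output CSV files (either may be `NULL` to
#'   skip).
#' @return named list of the written paths, invisibly.
#' @export
export_network_tables <- function(net, node_path = NULL, edge_path = NULL) {
  stopifnot(inherits(net, "AnnotatedNetwork"))
  if (!is.null(node_path)) {
    write.csv(net$node_attrs, node_path, row.names = FALSE)
  }
  if (!is.null(edge_path)) {
    bg <- net$background_edges
    tr <- net$transition_edges
    edges <- rbind(
      if (nrow(bg)) cbind(bg, layer = "background"),
      if (nrow(tr)) cbind(tr, layer = "transition"))
    if (is.null(edges)) {
      edges <- data.frame(from = character(), to = character(),
                          partial_correlation = numeric(), layer = character())
    }
    write.csv(edges, edge_path, row.names = FALSE)
  }
  invisible(list(nodes = node_path, edges = edge_path))
}

#' Serialize a run's provenance to JSON
#'
#' Records the settings that determine the outputs (alphas, component
#' choices, normalization statistics, seeds), sufficient to reproduce a run.
#'
#' @param run a [run_all_transitions()] result.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
export_provenance <- function(run, path) {
  stopifnot(inherits(run, "stagenet_run"))
  prov <- list(
    package_version = as.character(utils::packageVersion("stagenet")),
    stages = run$fit$stages$stages,
    config = unclass(run$fit$config),
    cv_alpha = run$fit$cv$alpha_best,
    cv_seed = run$fit$cv$seed,
    solver = list(n_iter = run$fit$precision$n_iter,
                  gap = run$fit$precision$gap,
                  converged = run$fit$precision$converged),
    normalization = list(sd_type = run$fit$norm$sd_type,
                         feature_means = unname(run$fit$norm$feature_means),
                         feature_sds = unname(run$fit$norm$feature_sds),
                         constant_features = run$fit$norm$constant_features),
    transitions = lapply(run$transitions, function(tr) tr$provenance))
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
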
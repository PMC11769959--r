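#' Rendering settings for network figures
#'
#' @param layout_seed seed for the force-directed layout.
#' @param palette named stage -> color map; defaults to a fixed ordered
#'   palette over the run's stages.
#' @param size_range node sizes (plot units) that the smallest/largest
#'   concentration change map to.
#' @param background_color color of the background layer (neutral grey).
#' @param width_range line widths for the weakest/strongest edge.
#' @return list of class `render_spec`.
#' @export
render_spec <- function(layout_seed = 42L, palette = NULL,
                        size_range = c(4, 14), background_color = "grey80",
                        width_range = c(0.5, 3)) {
  structure(list(layout_seed = as.integer(layout_seed), palette = palette,
                 size_range = size_range,
                 background_color = background_color,
                 width_range = width_range),
            class = "render_spec")
}

.default_palette <- function(stages) {
  cols <- c("#E64B35", "#4DBBD5", "#00A087", "#3C5488", "#F39B7F",
            "#8491B4", "#91D1C2", "#DC0000")
  setNames(rep_len(cols, length(stages)), stages)
}

#' Seeded force-directed layout on the background graph
#'
#' Computes one set of node coordinates from the background edges so that
#' every transition panel of a run shares the same frame. Deterministic for
#' a fixed seed.
#'
#' @param net an `AnnotatedNetwork` (any transition of the run — the
#'   background is shared) or a `SparseNetwork`.
#' @param layout_seed integer seed.
#' @return data.frame `metabolite`, `x`, `y`.
#' @export
network_layout <- function(net, layout_seed = 42L) {
  if (inherits(net, "AnnotatedNetwork")) {
    edges <- net$background_edges
    nodes <- union(net$node_attrs$metabolite,
                   unique(c(edges$from, edges$to,
                            net$transition_edges$from,
                            net$transition_edges$to)))
  } else {
    edges <- net$edges
    nodes <- net$all_names
  }
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = data.frame(name = nodes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(layout_seed)
  xy <- igraph::layout_with_fr(g)
  data.frame(metabolite = nodes, x = xy[, 1L], y = xy[, 2L],
             stringsAsFactors = FALSE)
}

.edge_style_table <- function(edges, width_range) {
  if (!nrow(edges)) {
    return(data.frame(from = character(), to = character(),
                      partial_correlation = numeric(), layer = character(),
                      linetype = character(), width = numeric()))
  }
  mx <- max(abs(edges$partial_correlation))
  w <- if (mx > 0) {
    width_range[1L] + (width_range[2L] - width_range[1L]) *
      abs(edges$partial_correlation) / mx
  } else rep(width_range[1L], nrow(edges))
  cbind(edges,
        linetype = ifelse(edges$partial_correlation >= 0, "solid", "dashed"),
        width = w)
}

#' Render a transition network over its grey background
#'
#' Draws the shared background network in neutral grey underneath the
#' colored transition layer: node color encodes the assigned stage, color
#' intensity the max-normalized loading score, node size the magnitude of
#' the concentration change, solid/dashed edges positive/negative partial
#' correlations with thickness proportional to strength. Everything shown is
#' also written to machine-readable tables (coordinates and edge styles).
#'
#' @param net an `AnnotatedNetwork`.
#' @param spec a [render_spec()].
#' @param file output image (`.png`); `NULL` skips the image and returns
#'   the tables only.
#' @param layout a precomputed [network_layout()] table to reuse across
#'   panels; computed from the background when `NULL`.
#' @return list with `coordinates` (node positions and visual attributes)
#'   and `edge_style` (per-edge linetype/width), invisibly when plotting.
#' @export
render_network <- function(net, spec = render_spec(), file = NULL,
                           layout = NULL) {
  stopifnot(inherits(net, "AnnotatedNetwork"))
  if (is.null(layout)) layout <- network_layout(net, spec$layout_seed)
  attrs <- net$node_attrs
  coords <- merge(layout, attrs, by = "metabolite", all.x = TRUE, sort = FALSE)
  coords <- coords[order(match(coords$metabolite, layout$metabolite)), ]
  rownames(coords) <- NULL
  dm <- coords$delta_magnitude
  dm[is.na(dm)] <- 0
  mx <- max(dm)
  coords$size <- spec$size_range[1L] +
    (spec$size_range[2L] - spec$size_range[1L]) * (if (mx > 0) dm / mx else 0)
  palette <- spec$palette
  if (is.null(palette)) palette <- .default_palette(unique(net$pair))
  coords$color <- unname(palette[coords$assigned_stage])
  bg <- .edge_style_table(
    if (nrow(net$background_edges))
      cbind(net$background_edges, layer = "background")
    else cbind(net$background_edges,
               layer = character(0)), spec$width_range)
  tr <- .edge_style_table(
    if (nrow(net$transition_edges))
      cbind(net$transition_edges, layer = "transition")
    else cbind(net$transition_edges,
               layer = character(0)), spec$width_range)
  edge_style <- rbind(bg, tr)

  if (!is.null(file)) {
    if (!nrow(coords)) warning("empty network: rendering an empty canvas")
    grDevices::png(file, width = 1200, height = 1200, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    plot(coords$x, coords$y, type = "n", axes = FALSE, xlab = "", ylab = "",
         main = paste(net$pair, collapse = " → "))
    draw_edges <- function(tab, col) {
      if (!nrow(tab)) return(invisible())
      i <- match(tab$from, coords$metabolite)
      j <- match(tab$to, coords$metabolite)
      segments(coords$x[i], coords$y[i], coords$x[j], coords$y[j],
               col = col, lwd = tab$width,
               lty = ifelse(tab$linetype == "solid", 1L, 2L))
    }
    draw_edges(bg, spec$background_color)
    draw_edges(tr, "grey30")
    intensity <- coords$score_intensity
    intensity[is.na(intensity)] <- 0
    node_col <- ifelse(is.na(coords$color), spec$background_color,
                       coords$color)
    pt_col <- vapply(seq_len(nrow(coords)), function(i) {
      grDevices::adjustcolor(node_col[i], alpha.f = 0.25 + 0.75 * intensity[i])
    }, character(1))
    points(coords$x, coords$y, pch = 21, bg = pt_col,
           cex = coords$size / 5, col = "grey40")
  }
  invisible(list(coordinates = coords, edge_style = edge_style))
}

#' Heatmap of normalized abundance with clustered metabolites
#'
#' Samples are grouped by stage in sequence order; metabolites are ordered
#' by average-linkage hierarchical clustering on Euclidean distance, and the
#' leaf order is returned (and optionally written) so the figure is fully
#' reproducible from the table.
#'
#' @param norm a [zscore_normalize()] result.
#' @param stages a [stage_sequence()].
#' @param file optional `.png` output.
#' @param csv optional path for the ordered matrix as CSV.
#' @return list with `matrix` (ordered samples x metabolites),
#'   `leaf_order` (metabolite order), `sample_order`, invisibly.
#' @export
render_heatmap <- function(norm, stages, file = NULL, csv = NULL) {
  stopifnot(inherits(norm, "NormalizedMatrix"),
            inherits(stages, "StageSequence"))
  hc <- hclust(dist(t(norm$values)), method = "average")
  leaf_order <- norm$metabolite_names[hc$order]
  sample_order <- order(match(norm$stage_labels, stages$stages))
  M <- norm$values[sample_order, hc$order, drop = FALSE]
  if (!is.null(csv)) {
    write.csv(data.frame(sample = norm$sample_ids[sample_order],
                         stage = norm$stage_labels[sample_order],
                         M, check.names = FALSE),
              csv, row.names = FALSE)
  }
  if (!is.null(file)) {
    grDevices::png(file, width = 1200, height = 900, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    image(seq_len(ncol(M)), seq_len(nrow(M)), t(M),
          col = grDevices::hcl.colors(64, "Blue-Red 3"),
          xlab = "metabolites (clustered)", ylab = "samples (by stage)",
          axes = FALSE, main = "normalized abundance")
    axis(2, at = seq_len(nrow(M)), labels = norm$sample_ids[sample_order],
         las = 2, cex.axis = 0.5)
  }
  invisible(list(matrix = M, leaf_order = leaf_order,
                 sample_order = sample_order, hclust = hc))
}

#' Export 3-D PCA coordinates of the full dataset
#'
#' The first three components of the full-data PCA, as plain coordinates
#' (one row per sample with its stage), plus an optional static 2-panel
#' projection image.
#'
#' @param pca a [fit_pca()] result with >= 3 components.
#' @param csv optional output CSV.
#' @param file optional `.png` with the PC1/PC2 and PC1/PC3 projections.
#' @return the coordinates data.frame, invisibly.
#' @export
pca_scatter3 <- function(pca, csv = NULL, file = NULL) {
  stopifnot(inherits(pca, "PCAResult"))
  if (pca$n_components < 3L) stop("need at least 3 components")
  df <- data.frame(sample = rownames(pca$scores),
                   stage = pca$stage_labels,
                   PC1 = pca$scores[, 1L], PC2 = pca$scores[, 2L],
                   PC3 = pca$scores[, 3L], stringsAsFactors = FALSE)
  if (!is.null(csv)) write.csv(df, csv, row.names = FALSE)
  if (!is.null(file)) {
    pal <- .default_palette(unique(df$stage))
    grDevices::png(file, width = 1400, height = 700, res = 150)
    on.exit(grDevices::dev.off(), add = TRUE)
    op <- par(mfrow = c(1, 2))
    on.exit(par(op), add = TRUE)
    plot(df$PC1, df$PC2, col = pal[df$stage], pch = 19,
         xlab = "PC1", ylab = "PC2")
    plot(df$PC1, df$PC3, col = pal[df$stage], pch = 19,
         xlab = "PC1", ylab = "PC3")
  }
  invisible(df)
}
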
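# Static visualizations: circular hierarchy ("circle tree"), aberration
# tree, composition radar and marker dot plots. All renderers consume the
# module output tables and return ggplot objects; writing to file is
# optional.

save_plot_maybe <- function(p, file, width, height) {
  if (!is.null(file)) {
    ggplot2::ggsave(file, plot = p, width = width, height = height,
                    device = if (grepl("\\.pdf$", file)) grDevices::pdf)
  }
  p
}

#' Circular hierarchy plot of an atlas
#'
#' Cell types sit on an inner circle at angles taken from the radial tree
#' layout; their subclusters are fanned around the outer rim and linked to
#' their type by gray spokes. Tree edges are drawn solid or dashed according
#' to their kind. When an aberration profile is supplied, node sizes encode
#' the relative ratio.
#'
#' @param atlas A `ReferenceAtlas`.
#' @param aberration Optional `AberrationProfile`.
#' @param file Optional output path (pdf/png).
#' @param width,height Device size in inches.
#' @return A ggplot object.
#' @export
plot_circle_tree <- function(atlas, aberration = NULL, file = NULL,
                             width = 7, height = 7) {
  stopifnot(inherits(atlas, "ReferenceAtlas"))
  ab <- aberration %||%
    structure(list(ratio = setNames(rep(1, nrow(atlas$tree$nodes)),
                                    atlas$tree$nodes$name),
                   epsilon = 0, flags = NULL), class = "AberrationProfile")
  lay <- tree_layout(ab, atlas$tree)
  nd <- lay$nodes
  maxd <- max(nd$depth)
  r_type <- 0.25 + 0.55 * nd$depth / max(maxd, 1)
  nd$px <- r_type * cos(nd$angle); nd$py <- r_type * sin(nd$angle)
  sc <- data.frame(subcluster = names(atlas$subcluster_map),
                   cell_type = unname(atlas$subcluster_map),
                   stringsAsFactors = FALSE)
  ord <- tree_preorder(atlas$tree)
  sc <- sc[order(match(sc$cell_type, ord), sc$subcluster), , drop = FALSE]
  sc$angle <- seq(0, 2 * pi, length.out = nrow(sc) + 1L)[seq_len(nrow(sc))]
  sc$px <- cos(sc$angle); sc$py <- sin(sc$angle)
  idx <- match(sc$cell_type, nd$node)
  spokes <- data.frame(x = sc$px, y = sc$py, xend = nd$px[idx],
                       yend = nd$py[idx])
  eidx_p <- match(lay$edges$parent, nd$node)
  eidx_c <- match(lay$edges$child, nd$node)
  ed <- data.frame(x = nd$px[eidx_p], y = nd$py[eidx_p],
                   xend = nd$px[eidx_c], yend = nd$py[eidx_c],
                   kind = lay$edges$kind)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = spokes,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          color = "gray80", linewidth = 0.2) +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$kind),
                          color = "gray30") +
    ggplot2::geom_point(data = sc,
                        ggplot2::aes(x = .data$px, y = .data$py,
                                     color = .data$cell_type), size = 1) +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$px, y = .data$py,
                                     color = .data$node,
                                     size = .data$node_radius)) +
    ggplot2::scale_linetype_manual(values = c(solid = "solid",
                                              dashed = "dashed")) +
    ggplot2::scale_size_identity() +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::guides(color = "none") -> p
  save_plot_maybe(p, file, width, height)
}

#' Aberration tree plot
#'
#' Renders the node/edge tables from [tree_layout()]: node size encodes the
#' relative ratio (log-scaled radius), edge thickness the lineage cell
#' fraction, and linetype the edge kind.
#'
#' @param layout Output of [tree_layout()].
#' @param file,width,height See [plot_circle_tree()].
#' @return A ggplot object.
#' @export
plot_tree <- function(layout, file = NULL, width = 7, height = 7) {
  nd <- layout$nodes
  nd$flag[is.na(nd$flag)] <- "normal"
  idx_p <- match(layout$edges$parent, nd$node)
  idx_c <- match(layout$edges$child, nd$node)
  ed <- data.frame(x = nd$x[idx_p], y = nd$y[idx_p],
                   xend = nd$x[idx_c], yend = nd$y[idx_c],
                   kind = layout$edges$kind, width = layout$edges$width)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$kind,
                                       linewidth = .data$width),
                          color = "gray40") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$node_radius,
                                     color = .data$flag)) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$node),
                       size = 2.5, vjust = -1.2) +
    ggplot2::scale_size_identity() +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2)) +
    ggplot2::scale_linetype_manual(values = c(solid = "solid",
                                              dashed = "dashed")) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() -> p
  save_plot_maybe(p, file, width, height)
}

#' Radar plot of composition ratios
#'
#' One closed polyline per profile column of a [radar_table()].
#'
#' @param radar Output of [radar_table()].
#' @param file,width,height See [plot_circle_tree()].
#' @return A ggplot object.
#' @export
plot_radar <- function(radar, file = NULL, width = 7, height = 7) {
  profs <- setdiff(names(radar), "cell_type")
  long <- do.call(rbind, lapply(profs, function(p)
    data.frame(cell_type = radar$cell_type, profile = p,
               ratio = radar[[p]], stringsAsFactors = FALSE)))
  long$cell_type <- factor(long$cell_type, levels = radar$cell_type)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cell_type, y = .data$ratio,
                                     group = .data$profile,
                                     color = .data$profile)) +
    ggplot2::geom_polygon(fill = NA) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_polar() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = "relative ratio") -> p
  save_plot_maybe(p, file, width, height)
}

#' Marker dot plot
#'
#' Dot size encodes the fraction of cells expressing the gene within each
#' cluster; color encodes the mean log-normalized expression.
#'
#' @param norm A `NormMatrix`.
#' @param labels A `ClusterLabels` object.
#' @param genes Genes to display.
#' @param file,width,height See [plot_circle_tree()].
#' @return A ggplot object.
#' @export
plot_marker_dot <- function(norm, labels, genes, file = NULL,
                            width = 7, height = 5) {
  missing <- setdiff(genes, colnames(norm$values))
  if (length(missing))
    stopf("genes absent from matrix: %s", paste(head(missing, 5), collapse = ", "))
  v <- norm$values[labels$cell_ids, genes, drop = FALSE]
  rows <- list()
  for (cl in sort(unique(labels$labels))) {
    vi <- v[labels$labels == cl, , drop = FALSE]
    rows[[cl]] <- data.frame(cluster = cl, gene = genes,
                             pct = Matrix::colMeans(vi > 0),
                             mean_expr = Matrix::colMeans(vi),
                             stringsAsFactors = FALSE, row.names = NULL)
  }
  long <- do.call(rbind, rows)
  long$gene <- factor(long$gene, levels = genes)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$gene, y = .data$cluster,
                                     size = .data$pct,
                                     color = .data$mean_expr)) +
    ggplot2::geom_point() +
    ggplot2::scale_size_area(max_size = 5) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5)) -> p
  save_plot_maybe(p, file, width, height)
}

#' Dispatch plot rendering by kind
#'
#' @param kind One of `"circle_tree"`, `"tree"`, `"radar"`, `"marker_dot"`.
#' @param data A list of the inputs the corresponding `plot_*` function
#'   expects (e.g. `list(atlas = atlas)` for `circle_tree`).
#' @param file Optional output path.
#' @param ... Forwarded to the renderer.
#' @return A ggplot object.
#' @export
render_plots <- function(kind = c("circle_tree", "tree", "radar",
                                  "marker_dot"),
                         data, file = NULL, ...) {
  kind <- match.arg(kind)
  switch(kind,
         circle_tree = plot_circle_tree(data$atlas, data$aberration,
                                        file = file, ...),
         tree = plot_tree(data$layout, file = file, ...),
         radar = plot_radar(data$radar, file = file, ...),
         marker_dot = plot_marker_dot(data$norm, data$labels, data$genes,
                                      file = file, ...))
}
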
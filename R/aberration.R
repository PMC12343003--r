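# Lineage-aberration inference: relative cell-type ratios against the
# normal reference, proliferation/suppression flags on the hierarchy tree,
# the initiating site, and the tree/radar tables behind the plots.

as_fractions <- function(x) {
  if (inherits(x, "CompositionProfile")) x$fractions
  else if (is.numeric(x) && !is.null(names(x))) x
  else stopf("expected a CompositionProfile or a named numeric vector")
}

#' Relative cell-type ratios of a query composition against the normal one
#'
#' `ratio(t) = (q(t) + epsilon) / (p(t) + epsilon)` over the union of cell
#' types; types missing from either profile count as 0. The additive
#' `epsilon` guards against zero denominators and is recorded in the result.
#' A ratio > 1 indicates proliferation of the lineage relative to normal
#' hematopoiesis, a ratio < 1 suppression.
#'
#' @param query,normal Composition profiles ([composition_profile()] or
#'   named fraction vectors).
#' @param epsilon Additive smoothing (default 1e-4).
#' @return An `AberrationProfile` with the `ratio` field filled.
#' @export
relative_ratio <- function(query, normal, epsilon = 1e-4) {
  q <- as_fractions(query); p <- as_fractions(normal)
  types <- union(names(q), names(p))
  qv <- setNames(rep(0, length(types)), types); qv[names(q)] <- q
  pv <- setNames(rep(0, length(types)), types); pv[names(p)] <- p
  structure(list(ratio = (qv + epsilon) / (pv + epsilon),
                 epsilon = epsilon, flags = NULL, initiating_sites = NULL,
                 threshold = NULL),
            class = "AberrationProfile")
}

#' @export
print.AberrationProfile <- function(x, ...) {
  cat(sprintf("AberrationProfile: %d cell types (epsilon = %g)\n",
              length(x$ratio), x$epsilon))
  if (!is.null(x$flags)) {
    n <- table(x$flags)
    cat(sprintf("  flags: %s\n",
                paste(sprintf("%s=%d", names(n), n), collapse = ", ")))
    cat(sprintf("  initiating sites: %s\n",
                paste(x$initiating_sites, collapse = ", ")))
  }
  invisible(x)
}

#' Flag aberrant lineages on the tree and locate the initiating site
#'
#' A node is flagged `proliferation` when its relative ratio exceeds
#' `threshold`, `suppression` when it falls below `1/threshold`, otherwise
#' `normal`. Initiating sites are proliferation-flagged nodes none of whose
#' ancestors along solid edges is itself proliferation-flagged; dashed
#' (recruitment) edges never propagate initiation. Tree nodes without a
#' ratio default to 1.0 (reported via message).
#'
#' @param aberration An `AberrationProfile` from [relative_ratio()].
#' @param tree A `HierarchyTree`.
#' @param threshold Fold-change threshold (default 1.25).
#' @return The profile with `flags`, `initiating_sites` and `threshold`
#'   filled.
#' @export
flag_aberrations <- function(aberration, tree, threshold = 1.25) {
  stopifnot(inherits(aberration, "AberrationProfile"),
            inherits(tree, "HierarchyTree"))
  nodes <- tree$nodes$name
  ratio <- setNames(rep(1.0, length(nodes)), nodes)
  known <- intersect(names(aberration$ratio), nodes)
  ratio[known] <- aberration$ratio[known]
  absent <- setdiff(nodes, names(aberration$ratio))
  if (length(absent))
    message(sprintf("ratio missing for %d tree node(s); defaulted to 1.0 (%s)",
                    length(absent), paste(head(absent, 5), collapse = ", ")))
  flags <- ifelse(ratio > threshold, "proliferation",
                  ifelse(ratio < 1 / threshold, "suppression", "normal"))
  prolif <- names(flags)[flags == "proliferation"]
  init <- prolif[vapply(prolif, function(nd) {
    !any(flags[solid_ancestors(tree, nd)] == "proliferation")
  }, logical(1))]
  aberration$ratio <- ratio
  aberration$flags <- flags
  aberration$initiating_sites <- unname(init)
  aberration$threshold <- threshold
  aberration
}

#' Deterministic radial layout of the aberration tree
#'
#' Places the root at the origin and each node at a radius equal to its
#' depth, with leaves spread over equal angles in configuration order and
#' internal nodes at the mean angle of their children. The drawn node radius
#' is the relative ratio on a log scale, `1 + log2(ratio)/2`, clamped to
#' `[0.25, 4]` (a ratio of 1 maps to the unit radius). Edge widths are
#' proportional to the query cell fraction of the child's subtree.
#'
#' @param aberration A flagged `AberrationProfile` (or one from
#'   [relative_ratio()]).
#' @param tree A `HierarchyTree`.
#' @param composition Optional query `CompositionProfile` used for edge
#'   widths; defaults to equal weight per type.
#' @return A list with `nodes` (node, x, y, depth, angle, ratio,
#'   node_radius, flag) and `edges` (parent, child, kind, width) data frames.
#' @export
tree_layout <- function(aberration, tree, composition = NULL) {
  stopifnot(inherits(tree, "HierarchyTree"))
  nodes <- tree$nodes$name
  ratio <- setNames(rep(1.0, length(nodes)), nodes)
  known <- intersect(names(aberration$ratio), nodes)
  ratio[known] <- aberration$ratio[known]
  flags <- if (!is.null(aberration$flags)) aberration$flags[nodes]
           else setNames(rep(NA_character_, length(nodes)), nodes)

  kids <- split(tree$edges$child, tree$edges$parent)
  depth <- setNames(rep(0L, length(nodes)), nodes)
  order_pre <- tree_preorder(tree)
  parent <- tree_parent(tree)
  for (nd in order_pre)
    if (nd %in% names(parent)) depth[nd] <- depth[[parent[[nd]]]] + 1L
  leaves <- nodes[!(nodes %in% tree$edges$parent)]
  leaves <- order_pre[order_pre %in% leaves]          # config order
  angle <- setNames(rep(NA_real_, length(nodes)), nodes)
  angle[leaves] <- seq(0, 2 * pi, length.out = length(leaves) + 1L)[seq_along(leaves)]
  for (nd in rev(order_pre))
    if (is.na(angle[[nd]])) angle[nd] <- mean(angle[kids[[nd]]])

  frac <- setNames(rep(1 / length(nodes), length(nodes)), nodes)
  if (!is.null(composition)) {
    cf <- as_fractions(composition)
    frac[] <- 0
    frac[intersect(names(cf), nodes)] <- cf[intersect(names(cf), nodes)]
  }
  subtree_frac <- setNames(rep(0, length(nodes)), nodes)
  for (nd in rev(order_pre))
    subtree_frac[nd] <- frac[[nd]] + sum(subtree_frac[kids[[nd]]])

  node_radius <- clamp(1 + log2(ratio) / 2, 0.25, 4)
  nd_tab <- data.frame(node = nodes,
                       x = depth[nodes] * cos(angle[nodes]),
                       y = depth[nodes] * sin(angle[nodes]),
                       depth = depth[nodes], angle = angle[nodes],
                       ratio = ratio[nodes],
                       node_radius = node_radius[nodes],
                       flag = unname(flags),
                       stringsAsFactors = FALSE, row.names = NULL)
  ed_tab <- data.frame(parent = tree$edges$parent, child = tree$edges$child,
                       kind = tree$edges$kind,
                       width = unname(subtree_frac[tree$edges$child]),
                       stringsAsFactors = FALSE, row.names = NULL)
  list(nodes = nd_tab, edges = ed_tab)
}

#' Radar table of composition ratios
#'
#' One column per query profile, one row per cell type (ordered by tree
#' preorder when a tree is supplied, alphabetically otherwise), holding the
#' relative ratio of each profile against the normal composition.
#'
#' @param profiles List of composition profiles (named list names the
#'   columns).
#' @param normal Normal composition profile.
#' @param tree Optional `HierarchyTree` fixing the row order.
#' @param epsilon Smoothing forwarded to [relative_ratio()].
#' @return Data frame, cell types x profiles.
#' @export
radar_table <- function(profiles, normal, tree = NULL, epsilon = 1e-4) {
  if (inherits(profiles, "CompositionProfile")) profiles <- list(profiles)
  ratios <- lapply(profiles, function(p) relative_ratio(p, normal, epsilon)$ratio)
  types <- sort(unique(unlist(lapply(ratios, names))))
  if (!is.null(tree)) {
    ord <- tree_preorder(tree)
    types <- c(intersect(ord, types), setdiff(types, ord))
  }
  out <- data.frame(cell_type = types, stringsAsFactors = FALSE)
  nms <- names(profiles) %||% paste0("profile", seq_along(profiles))
  if (is.null(names(profiles)) || any(!nzchar(nms)))
    nms <- paste0("profile", seq_along(profiles))
  for (i in seq_along(ratios)) {
    v <- setNames(rep(1.0, length(types)), types)
    v[intersect(names(ratios[[i]]), types)] <-
      ratios[[i]][intersect(names(ratios[[i]]), types)]
    out[[nms[i]]] <- unname(v)
  }
  out
}
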
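# The curated hematopoietic differentiation tree: cell types arranged under
# a single root (HSC/MPP by convention), with solid edges for continuous
# intramedullary differentiation and dashed edges for mature cells recruited
# from outside the bone marrow (T/NK cells, some memory B cells).

LINEAGE_CLASSES <- c("HSPC", "myeloid", "B", "TNK")

#' Construct and validate a hematopoietic hierarchy tree
#'
#' @param nodes Data frame with columns `name`, `population` (level-2
#'   population), `lineage_class` (one of HSPC, myeloid, B, TNK).
#' @param edges Data frame with columns `parent`, `child`, `kind`
#'   (`"solid"` or `"dashed"`).
#' @param root Root node name; defaults to the unique node without a parent.
#' @return A validated `HierarchyTree`.
#' @details Validation rejects duplicate nodes, unknown edge endpoints,
#'   multiple parents, cycles/disconnected nodes, multiple roots, and dashed
#'   edges pointing into anything other than a T/NK-class or memory-B node.
#' @export
hierarchy_tree <- function(nodes, edges, root = NULL) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "population", "lineage_class") %in% names(nodes)),
            all(c("parent", "child", "kind") %in% names(edges)))
  if (anyDuplicated(nodes$name))
    stopf("duplicate node names: %s",
          paste(unique(nodes$name[duplicated(nodes$name)]), collapse = ", "))
  bad_class <- setdiff(unique(nodes$lineage_class), LINEAGE_CLASSES)
  if (length(bad_class))
    stopf("unknown lineage_class: %s", paste(bad_class, collapse = ", "))
  bad_kind <- setdiff(unique(edges$kind), c("solid", "dashed"))
  if (length(bad_kind))
    stopf("edge kind must be solid or dashed (got: %s)",
          paste(bad_kind, collapse = ", "))
  unknown <- setdiff(unique(c(edges$parent, edges$child)), nodes$name)
  if (length(unknown))
    stopf("edges reference unknown nodes: %s", paste(unknown, collapse = ", "))
  if (anyDuplicated(edges$child))
    stopf("nodes with multiple parents: %s",
          paste(unique(edges$child[duplicated(edges$child)]), collapse = ", "))
  rootless <- setdiff(nodes$name, edges$child)
  if (length(rootless) != 1)
    stopf("tree must have exactly one root (found: %s)",
          paste(rootless, collapse = ", "))
  if (!is.null(root) && root != rootless)
    stopf("declared root '%s' does not match the parentless node '%s'",
          root, rootless)
  root <- rootless
  # reachability from root == acyclic + connected given single-parent edges
  reach <- root
  repeat {
    nxt <- edges$child[edges$parent %in% reach & !(edges$child %in% reach)]
    if (!length(nxt)) break
    reach <- c(reach, nxt)
  }
  stranded <- setdiff(nodes$name, reach)
  if (length(stranded))
    stopf("nodes unreachable from root (cycle or disconnected): %s",
          paste(stranded, collapse = ", "))
  cls <- setNames(nodes$lineage_class, nodes$name)
  dashed <- edges[edges$kind == "dashed", , drop = FALSE]
  bad <- dashed$child[!(cls[dashed$child] == "TNK" |
                          grepl("memory[ _-]?b", tolower(dashed$child)))]
  if (length(bad))
    stopf("dashed edges may only point into T/NK or memory-B nodes (bad: %s)",
          paste(bad, collapse = ", "))
  structure(list(nodes = nodes, edges = edges, root = root),
            class = "HierarchyTree")
}

#' @export
print.HierarchyTree <- function(x, ...) {
  cat(sprintf("HierarchyTree: %d cell types, %d edges, root '%s'\n",
              nrow(x$nodes), nrow(x$edges), x$root))
  invisible(x)
}

tree_parent <- function(tree) {
  setNames(tree$edges$parent, tree$edges$child)
}

tree_edge_kind <- function(tree) {
  setNames(tree$edges$kind, tree$edges$child)
}

tree_lineage_class <- function(tree) {
  setNames(tree$nodes$lineage_class, tree$nodes$name)
}

# Depth-first preorder with children in edge (config) order.
tree_preorder <- function(tree) {
  kids <- split(tree$edges$child, tree$edges$parent)
  out <- character(0)
  walk <- function(node) {
    out <<- c(out, node)
    for (ch in kids[[node]]) walk(ch)
  }
  walk(tree$root)
  out
}

# Ancestors of `node` reachable by walking solid edges upward only; a dashed
# edge breaks the chain (recruited cells do not inherit initiation).
solid_ancestors <- function(tree, node) {
  parent <- tree_parent(tree)
  kind <- tree_edge_kind(tree)
  out <- character(0)
  cur <- node
  while (cur %in% names(parent)) {
    if (kind[[cur]] != "solid") break
    cur <- parent[[cur]]
    out <- c(out, cur)
  }
  out
}

#' Miniature 11-type hematopoietic tree
#'
#' Default tree used by the synthetic cohort generator: a reduced bone-marrow
#' hierarchy with the myeloid arm (CMP, GMP, GMP-Mono, CD14 Mono, MEP, Ery),
#' the B arm (CLP, pre-pro-B, pre-B) and a recruited (dashed) T/NK node, all
#' rooted at HSC/MPP.
#'
#' @return A `HierarchyTree`.
#' @export
miniature_tree <- function() {
  nodes <- data.frame(
    name = c("HSC/MPP", "CMP", "GMP", "GMP-Mono", "CD14 Mono",
             "MEP", "Ery", "CLP", "pre-pro-B", "pre-B", "T/NK"),
    population = c("HSPCs", "HSPCs", "HSPCs", "Monocytes", "Monocytes",
                   "HSPCs", "Erythrocytes", "HSPCs", "B cells", "B cells",
                   "T/NK cells"),
    lineage_class = c("HSPC", "HSPC", "HSPC", "myeloid", "myeloid",
                      "HSPC", "myeloid", "HSPC", "B", "B", "TNK"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    parent = c("HSC/MPP", "CMP", "GMP", "GMP-Mono", "CMP", "MEP",
               "HSC/MPP", "CLP", "pre-pro-B", "CLP"),
    child = c("CMP", "GMP", "GMP-Mono", "CD14 Mono", "MEP", "Ery",
              "CLP", "pre-pro-B", "pre-B", "T/NK"),
    kind = c(rep("solid", 9), "dashed"),
    stringsAsFactors = FALSE)
  hierarchy_tree(nodes, edges)
}

#' Full 38-type bone-marrow hierarchy
#'
#' Loads the curated 38-cell-type tree shipped with the package
#' (`inst/extdata/tree_bmmc38.tsv`): HSC/MPP at the root, solid edges along
#' the monocyte, dendritic-cell, megakaryocyte/erythroid and B arms, and
#' dashed edges into recruited T/NK and memory-B populations.
#'
#' @return A `HierarchyTree`.
#' @export
bmmc_tree <- function() {
  read_tree_config(system.file("extdata", "tree_bmmc38.tsv",
                               package = "hematree", mustWork = TRUE))
}

#' Read / write a tree configuration file
#'
#' The config is a TSV with one record per line: `node <name> <population>
#' <lineage_class>` or `edge <parent> <child> <solid|dashed>`. Lines starting
#' with `#` are comments.
#'
#' @param path File path.
#' @return `read_tree_config()` returns a `HierarchyTree`;
#'   `write_tree_config()` returns `path` invisibly.
#' @export
read_tree_config <- function(path) {
  if (!file.exists(path)) stopf("tree config not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  kind <- vapply(parts, `[[`, "", 1L)
  bad <- setdiff(unique(kind), c("node", "edge"))
  if (length(bad)) stopf("unknown record type in tree config: %s",
                         paste(bad, collapse = ", "))
  nd <- parts[kind == "node"]
  ed <- parts[kind == "edge"]
  nodes <- data.frame(name = vapply(nd, `[[`, "", 2L),
                      population = vapply(nd, `[[`, "", 3L),
                      lineage_class = vapply(nd, `[[`, "", 4L),
                      stringsAsFactors = FALSE)
  edges <- data.frame(parent = vapply(ed, `[[`, "", 2L),
                      child = vapply(ed, `[[`, "", 3L),
                      kind = vapply(ed, `[[`, "", 4L),
                      stringsAsFactors = FALSE)
  hierarchy_tree(nodes, edges)
}

#' @rdname read_tree_config
#' @param tree A `HierarchyTree`.
#' @export
write_tree_config <- function(tree, path) {
  stopifnot(inherits(tree, "HierarchyTree"))
  nd <- sprintf("node\t%s\t%s\t%s", tree$nodes$name, tree$nodes$population,
                tree$nodes$lineage_class)
  ed <- sprintf("edge\t%s\t%s\t%s", tree$edges$parent, tree$edges$child,
                tree$edges$kind)
  writeLines(c("# hematree hierarchy config", nd, ed), path)
  invisible(path)
}
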
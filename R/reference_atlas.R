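# Assembly, serialization and evaluation of the hierarchy-based reference:
# subcluster centroid matrix B, the HSC/MPP (root) centroid matrix C, the
# subcluster -> cell-type map, the normal composition, and the tree.

ATLAS_VERSION <- "hematree-atlas-1"

#' Mean expression profiles per subcluster
#'
#' Row `s` is the arithmetic mean of the log-normalized profiles of the
#' member cells of subcluster `s`. Rows are ordered lexicographically by
#' label.
#'
#' @param norm A `NormMatrix`.
#' @param labels A `ClusterLabels` object (level 4 subclusters).
#' @return Dense matrix, subclusters x genes.
#' @export
centroid_profiles <- function(norm, labels) {
  stopifnot(inherits(norm, "NormMatrix"), inherits(labels, "ClusterLabels"))
  missing <- setdiff(labels$cell_ids, rownames(norm$values))
  if (length(missing))
    stopf("cells absent from matrix: %s", paste(head(missing, 5), collapse = ", "))
  if (!length(labels$cell_ids)) stopf("empty label set")
  v <- norm$values[labels$cell_ids, , drop = FALSE]
  f <- factor(labels$labels, levels = sort(unique(labels$labels)))
  ind <- Matrix::sparseMatrix(i = as.integer(f), j = seq_along(f), x = 1,
                              dims = c(nlevels(f), length(f)),
                              dimnames = list(levels(f), NULL))
  cent <- as.matrix((ind %*% v) / as.vector(table(f)))
  colnames(cent) <- colnames(v)
  cent
}

#' Assemble the reference atlas
#'
#' Combines level-4 subcluster centroids (restricted to the highly variable
#' gene set), the subcluster -> cell-type annotation, the cell-count-weighted
#' normal composition, the root-type centroid matrix C, and the curated tree.
#'
#' @param norm A `NormMatrix` of the reference cells.
#' @param labels4 Level-4 `ClusterLabels`.
#' @param annotations Data frame with columns `subcluster`, `cell_type`
#'   covering every subcluster; all cell types must be tree nodes and the
#'   root type must be present.
#' @param tree A `HierarchyTree`.
#' @param hvg Character vector of gene ids defining the similarity gene
#'   space (columns of B).
#' @return A `ReferenceAtlas`.
#' @export
build_reference <- function(norm, labels4, annotations, tree, hvg) {
  stopifnot(inherits(tree, "HierarchyTree"))
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  stopifnot(all(c("subcluster", "cell_type") %in% names(annotations)))
  cent <- centroid_profiles(norm, labels4)
  uncovered <- setdiff(rownames(cent), annotations$subcluster)
  if (length(uncovered))
    stopf("subclusters without annotation: %s",
          paste(head(uncovered, 5), collapse = ", "))
  offenders <- setdiff(unique(annotations$cell_type), tree$nodes$name)
  if (length(offenders))
    stopf("annotations name unknown tree nodes: %s",
          paste(offenders, collapse = ", "))
  map <- setNames(annotations$cell_type, annotations$subcluster)
  map <- map[rownames(cent)]
  if (!any(map == tree$root))
    stopf("no subcluster annotated to the root type '%s'", tree$root)
  missing_hvg <- setdiff(hvg, colnames(cent))
  if (length(missing_hvg))
    stopf("hvg genes absent from matrix: %s",
          paste(head(missing_hvg, 5), collapse = ", "))
  B <- cent[, hvg, drop = FALSE]
  sizes <- table(factor(labels4$labels, levels = rownames(cent)))
  type_counts <- tapply(as.vector(sizes), map, sum)
  composition <- as.vector(type_counts) / sum(type_counts)
  names(composition) <- names(type_counts)
  C <- B[map == tree$root, , drop = FALSE]
  structure(list(B = B, C = C, subcluster_map = map,
                 normal_composition = composition, hvg = hvg, tree = tree,
                 subcluster_sizes = setNames(as.vector(sizes), rownames(cent)),
                 version = ATLAS_VERSION),
            class = "ReferenceAtlas")
}

#' @export
print.ReferenceAtlas <- function(x, ...) {
  cat(sprintf("ReferenceAtlas: %d subclusters, %d cell types, %d genes\n",
              nrow(x$B), length(unique(x$subcluster_map)), ncol(x$B)))
  invisible(x)
}

#' Robustness of centroids under downsampling
#'
#' For each fraction and replicate, cells are subsampled without replacement
#' within every subcluster, centroids are recomputed on the atlas gene
#' space, and the per-subcluster Pearson correlation against the full
#' centroid is averaged. Subclusters downsampled to zero cells are skipped
#' and counted in the output.
#'
#' @param atlas A `ReferenceAtlas`.
#' @param norm The full `NormMatrix` the atlas was built from.
#' @param labels4 The level-4 `ClusterLabels` used for the atlas.
#' @param fractions Numeric vector of fractions in (0, 1].
#' @param n_rep Replicates per fraction.
#' @param seed RNG seed.
#' @return Data frame (fraction, replicate, mean_r, n_skipped).
#' @export
robustness_downsample <- function(atlas, norm, labels4,
                                  fractions = c(0.1, 0.25, 0.5, 0.75, 0.9),
                                  n_rep = 3L, seed = 0L) {
  stopifnot(inherits(atlas, "ReferenceAtlas"))
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must lie in (0, 1]")
  cells_by_sc <- split(labels4$cell_ids, labels4$labels)
  v <- norm$values[, atlas$hvg, drop = FALSE]
  local_seed(seed, {
    rows <- list()
    for (f in fractions) {
      for (r in seq_len(n_rep)) {
        rs <- numeric(0); skipped <- 0L
        for (sc in rownames(atlas$B)) {
          cells <- cells_by_sc[[sc]]
          m <- round(f * length(cells))
          if (m == 0) { skipped <- skipped + 1L; next }
          sub <- if (m == length(cells)) cells else sample(cells, m)
          cen <- Matrix::colMeans(v[sub, , drop = FALSE])
          rs <- c(rs, stats::cor(cen, atlas$B[sc, ]))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(fraction = f, replicate = r, mean_r = mean(rs),
                     n_skipped = skipped)
      }
    }
    do.call(rbind, rows)
  })
}

write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_matrix_tsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Save / load a reference atlas bundle
#'
#' The bundle is a directory of plain-text files (B and C as TSV matrices,
#' map and composition as TSV tables, the tree as a config file, plus a
#' version tag) so it is portable across languages.
#'
#' @param atlas A `ReferenceAtlas`.
#' @param path Bundle directory.
#' @return `save_atlas()` returns `path` invisibly; `load_atlas()` returns
#'   the `ReferenceAtlas`.
#' @export
save_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "ReferenceAtlas"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  writeLines(atlas$version, file.path(path, "version.txt"))
  write_matrix_tsv(format(atlas$B, digits = 17, trim = TRUE, scientific = TRUE),
                   file.path(path, "B.tsv"))
  write_matrix_tsv(format(atlas$C, digits = 17, trim = TRUE, scientific = TRUE),
                   file.path(path, "C.tsv"))
  write.table(data.frame(subcluster = names(atlas$subcluster_map),
                         cell_type = unname(atlas$subcluster_map),
                         n_cells = unname(atlas$subcluster_sizes)),
              file.path(path, "subcluster_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_type = names(atlas$normal_composition),
                         fraction = unname(atlas$normal_composition)),
              file.path(path, "composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(atlas$hvg, file.path(path, "hvg.txt"))
  write_tree_config(atlas$tree, file.path(path, "tree.tsv"))
  invisible(path)
}

#' @rdname save_atlas
#' @export
load_atlas <- function(path) {
  vf <- file.path(path, "version.txt")
  if (!file.exists(vf)) stopf("not an atlas bundle (missing version.txt): %s", path)
  ver <- readLines(vf, n = 1L)
  if (ver != ATLAS_VERSION)
    stopf("atlas version mismatch: found '%s', expected '%s'", ver, ATLAS_VERSION)
  if (!file.exists(file.path(path, "C.tsv")))
    stopf("invalid atlas bundle: missing HSC/MPP matrix (C.tsv)")
  B <- read_matrix_tsv(file.path(path, "B.tsv"))
  storage.mode(B) <- "double"
  C <- read_matrix_tsv(file.path(path, "C.tsv"))
  storage.mode(C) <- "double"
  mp <- read.delim(file.path(path, "subcluster_map.tsv"),
                   stringsAsFactors = FALSE)
  comp <- read.delim(file.path(path, "composition.tsv"),
                     stringsAsFactors = FALSE)
  structure(list(B = B, C = C,
                 subcluster_map = setNames(mp$cell_type, mp$subcluster),
                 normal_composition = setNames(comp$fraction, comp$cell_type),
                 hvg = readLines(file.path(path, "hvg.txt")),
                 tree = read_tree_config(file.path(path, "tree.tsv")),
                 subcluster_sizes = setNames(mp$n_cells, mp$subcluster),
                 version = ver),
            class = "ReferenceAtlas")
}
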
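# High-level pipeline entry points composing the modules end-to-end:
# reference construction, query annotation, aberration inference, and bulk
# deconvolution. These are the package's user-facing workflow surface.

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[hematree] ", fmt), ...))
}

#' Build a reference atlas from a count matrix
#'
#' Runs QC, log-normalization, highly-variable-gene selection, PCA, per-type
#' max-min k-means subclustering and atlas assembly, then optionally saves
#' the atlas bundle.
#'
#' @param counts A [count_matrix()] of normal bone-marrow cells.
#' @param cell_types Named character vector (cell id -> cell type); every
#'   type must be a node of `tree`. Cells without a label are dropped.
#' @param tree A `HierarchyTree`.
#' @param qc [qc_params()] applied before anything else.
#' @param n_hvg Number of highly variable genes (default 3000, clamped to
#'   the available genes).
#' @param d PCA dimensions (default 30).
#' @param target_median Target median subcluster size (default 100).
#' @param seed Seed recorded in the subcluster parameters.
#' @param out_dir Optional directory for [save_atlas()].
#' @param verbose Log stage progress (default TRUE).
#' @return List with `atlas`, `norm`, `embedding`, `labels4`, `qc_report`.
#' @export
run_build_ref <- function(counts, cell_types, tree, qc = qc_params(),
                          n_hvg = 3000L, d = 30L, target_median = 100L,
                          seed = 0L, out_dir = NULL, verbose = TRUE) {
  t0 <- Sys.time()
  qcres <- qc_filter(counts, qc)
  log_stage(verbose, "qc: %d/%d cells retained",
            nrow(qcres$counts$counts), nrow(counts$counts))
  cells <- intersect(cell_ids(qcres$counts), names(cell_types))
  if (!length(cells)) stopf("no QC-passing cells carry a cell_types label")
  norm <- lognormalize(qcres$counts)
  hvg <- suppressWarnings(select_hvg(norm, n_top = n_hvg))
  emb <- embed_pca(norm, hvg, d = d)
  log_stage(verbose, "normalized %d cells, %d HVGs, %d PCs",
            nrow(norm$values), length(hvg), emb$d)
  types <- cell_types[cells]
  offenders <- setdiff(unique(types), tree$nodes$name)
  if (length(offenders))
    stopf("cell_types name unknown tree nodes: %s",
          paste(offenders, collapse = ", "))
  params <- subcluster_params(target_median = target_median, seed = seed)
  all_ids <- character(0); all_labs <- character(0)
  for (t in sort(unique(types))) {
    sub <- cells[types == t]
    lab <- suppressWarnings(
      maxmin_kmeans(emb, sub, params, label_prefix = paste0(t, "|")))
    all_ids <- c(all_ids, lab$cell_ids)
    all_labs <- c(all_labs, lab$labels)
  }
  labels4 <- cluster_labels(all_ids, all_labs, 4L)
  ann <- data.frame(subcluster = sort(unique(all_labs)),
                    stringsAsFactors = FALSE)
  ann$cell_type <- sub("\\|.*$", "", ann$subcluster)
  atlas <- build_reference(norm, labels4, ann, tree, hvg)
  log_stage(verbose, "atlas: %d subclusters over %d cell types (%.1fs)",
            nrow(atlas$B), length(unique(atlas$subcluster_map)),
            as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) save_atlas(atlas, out_dir)
  list(atlas = atlas, norm = norm, embedding = emb, labels4 = labels4,
       qc_report = qcres$report)
}

#' Annotate a query sample against a reference atlas
#'
#' Runs the standard query workflow (QC, normalization, HVG + PCA, graph
#' clustering, max-min k-means subclustering within each graph cluster),
#' scores every query subcluster with the LIKE score and estimates the
#' sample composition.
#'
#' @param counts Query [count_matrix()].
#' @param atlas A `ReferenceAtlas`.
#' @param qc [qc_params()].
#' @param n_hvg,d,k_neighbors,resolution Query preprocessing parameters.
#' @param target_median Target median subcluster size (default 100).
#' @param mode Theta definition, see [hsc_sin_theta()].
#' @param declared_lineage Forwarded to [like_score_matrix()]; declared
#'   T-lineage queries are refused.
#' @param seed Clustering seed.
#' @param verbose Log stage progress.
#' @return List with `like` (`LikeResult`), `composition`
#'   (`CompositionProfile`), `labels4`, `qc_report`.
#' @export
run_annotate <- function(counts, atlas, qc = qc_params(), n_hvg = 3000L,
                         d = 30L, k_neighbors = 20L, resolution = 1,
                         target_median = 100L, mode = "query_vs_root",
                         declared_lineage = NULL, seed = 0L, verbose = TRUE) {
  if (!is.null(declared_lineage) &&
      toupper(declared_lineage) %in% c("T", "TNK", "T-ALL", "TALL"))
    stopf(paste("query declared T-lineage: T-cell development is",
                "extramedullary and the LIKE score is undefined for it"))
  if (!nrow(counts$counts)) stopf("empty query matrix")
  qcres <- qc_filter(counts, qc)
  log_stage(verbose, "qc: %d/%d cells retained",
            nrow(qcres$counts$counts), nrow(counts$counts))
  norm <- lognormalize(qcres$counts)
  hvg <- suppressWarnings(select_hvg(norm, n_top = n_hvg))
  emb <- embed_pca(norm, hvg, d = d)
  cl1 <- graph_cluster(emb, resolution = resolution,
                       k_neighbors = k_neighbors, seed = seed)
  params <- subcluster_params(target_median = target_median, seed = seed)
  all_ids <- character(0); all_labs <- character(0)
  for (cl in sort(unique(cl1$labels))) {
    sub <- cl1$cell_ids[cl1$labels == cl]
    lab <- suppressWarnings(
      maxmin_kmeans(emb, sub, params, label_prefix = paste0(cl, "|")))
    all_ids <- c(all_ids, lab$cell_ids)
    all_labs <- c(all_labs, lab$labels)
  }
  labels4 <- cluster_labels(all_ids, all_labs, 4L)
  cent <- centroid_profiles(norm, labels4)
  sizes <- table(labels4$labels)
  query <- query_profiles(cent, setNames(as.integer(sizes), names(sizes)))
  like <- like_score_matrix(query, atlas, mode = mode)
  comp <- estimate_composition(like)
  log_stage(verbose, "annotated %d subclusters (%d cells)",
            nrow(like$table), comp$total_cells)
  list(like = like, composition = comp, labels4 = labels4,
       qc_report = qcres$report)
}

#' Infer lineage aberrations of a query composition
#'
#' @param composition Query `CompositionProfile` (e.g. from
#'   [run_annotate()]).
#' @param atlas A `ReferenceAtlas` supplying the normal composition and the
#'   tree.
#' @param threshold Fold-change threshold for flags (default 1.25).
#' @param epsilon Smoothing for [relative_ratio()].
#' @return List with `aberration` (flagged `AberrationProfile`) and
#'   `layout` (node/edge tables for plotting).
#' @export
run_aberration <- function(composition, atlas, threshold = 1.25,
                           epsilon = 1e-4) {
  ab <- relative_ratio(composition, atlas$normal_composition, epsilon)
  ab <- flag_aberrations(ab, atlas$tree, threshold)
  list(aberration = ab,
       layout = tree_layout(ab, atlas$tree, composition = composition))
}

#' Train the per-cell-type LASSO score models of an atlas
#'
#' @param atlas A `ReferenceAtlas`.
#' @param folds CV folds (default 10).
#' @param seed Fold-assignment seed.
#' @param ... Forwarded to [train_models()].
#' @return A `LassoModelSet`.
#' @export
run_deconv_train <- function(atlas, folds = 10L, seed = 0L, ...) {
  train_models(atlas$B, atlas$subcluster_map, folds = folds, seed = seed, ...)
}

#' Log-normalize a bulk expression matrix
#'
#' Column-wise counts-per-`scale_factor` followed by `log1p`, putting bulk
#' profiles on the same scale as the reference centroids.
#'
#' @param bulk Matrix (genes x samples) of counts or TPM-like values.
#' @param scale_factor Target library size (default 1e4).
#' @return Matrix of the same shape.
#' @export
bulk_lognormalize <- function(bulk, scale_factor = 1e4) {
  bulk <- as.matrix(bulk)
  totals <- colSums(bulk)
  if (any(totals == 0)) stopf("bulk samples with zero total expression")
  log1p(sweep(bulk, 2, totals, "/") * scale_factor)
}

#' Score bulk samples and call aberrant cell types
#'
#' @param bulk Matrix (genes x samples); log-normalized internally unless
#'   `normalize = "none"`.
#' @param models A `LassoModelSet` from [run_deconv_train()].
#' @param normal_ids Optional normal-panel sample ids; when given, scores
#'   are normalized and aberrant calls made.
#' @param fold_change Call threshold (default 1.25).
#' @param normalize `"log_cpm"` (default) or `"none"`.
#' @return A `ScoreTable`.
#' @export
run_deconv_score <- function(bulk, models, normal_ids = NULL,
                             fold_change = 1.25,
                             normalize = c("log_cpm", "none")) {
  normalize <- match.arg(normalize)
  expr <- if (normalize == "log_cpm") bulk_lognormalize(bulk) else as.matrix(bulk)
  scores <- score_samples(expr, models)
  if (!is.null(normal_ids)) {
    scores <- normalize_scores(scores, normal_ids)
    scores <- call_aberrant(scores, fold_change)
  }
  scores
}

#' Write a LIKE result, composition or aberration profile to TSV
#'
#' @param x A `LikeResult`, `CompositionProfile`, `AberrationProfile` or
#'   marker data frame.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_result_tsv <- function(x, path) {
  tab <- if (inherits(x, "LikeResult")) x$table
  else if (inherits(x, "CompositionProfile"))
    data.frame(cell_type = names(x$fractions), fraction = unname(x$fractions))
  else if (inherits(x, "AberrationProfile"))
    data.frame(cell_type = names(x$ratio), ratio = unname(x$ratio),
               flag = if (is.null(x$flags)) NA_character_ else unname(x$flags))
  else as.data.frame(x)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
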
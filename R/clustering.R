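# Graph-based clustering into major populations, max-min seeded k-means
# subclustering toward a target median subcluster size, and one-vs-rest
# Wilcoxon marker detection.

#' Cluster label container
#'
#' @param cell_ids Character vector of cell ids.
#' @param labels Character vector, one label per cell.
#' @param level Integer hierarchy level (1 = lineages ... 4 = subclusters).
#' @return A `ClusterLabels` object.
#' @export
cluster_labels <- function(cell_ids, labels, level) {
  if (length(cell_ids) != length(labels))
    stopf("labels length (%d) != cells (%d)", length(labels), length(cell_ids))
  structure(list(cell_ids = as.character(cell_ids),
                 labels = as.character(labels),
                 level = as.integer(level)),
            class = "ClusterLabels")
}

#' @export
print.ClusterLabels <- function(x, ...) {
  cat(sprintf("ClusterLabels (level %d): %d cells, %d clusters\n",
              x$level, length(x$cell_ids), length(unique(x$labels))))
  invisible(x)
}

# Exact k-nearest-neighbour indices by blocked brute force (euclidean).
knn_indices <- function(coords, k, block = 1024L) {
  n <- nrow(coords)
  sq <- rowSums(coords^2)
  out <- matrix(NA_integer_, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(coords[idx, , drop = FALSE], coords)
    for (r in seq_along(idx)) {
      o <- order(d2[r, ], seq_len(n))   # deterministic tie-break by index
      o <- o[o != idx[r]]
      out[idx[r], ] <- o[seq_len(k)]
    }
  }
  out
}

#' Graph-based clustering (Louvain on a shared-nearest-neighbor graph)
#'
#' Builds an exact k-nearest-neighbor graph on the embedding, weights edges
#' by the Jaccard overlap of neighborhoods (pruning weights below `prune`),
#' and partitions it with the Louvain modularity algorithm. Labels are
#' `"C0"`, `"C1"`, ... ordered by descending cluster size.
#'
#' @param embedding An `Embedding` from [embed_pca()] (or any list with a
#'   `coords` matrix).
#' @param resolution Louvain resolution (default 1).
#' @param k_neighbors Neighborhood size (default 20).
#' @param seed RNG seed for the community search (default 0).
#' @param prune Jaccard pruning threshold (default 1/15).
#' @return A `ClusterLabels` object at level 1.
#' @export
graph_cluster <- function(embedding, resolution = 1, k_neighbors = 20L,
                          seed = 0L, prune = 1 / 15) {
  coords <- embedding$coords
  n <- nrow(coords)
  if (n < k_neighbors + 1L)
    stopf("need at least k_neighbors + 1 = %d cells (got %d); use a smaller k",
          k_neighbors + 1L, n)
  nn <- knn_indices(coords, k_neighbors)
  # neighbourhood incidence including self
  adj <- Matrix::sparseMatrix(i = rep(seq_len(n), k_neighbors + 1L),
                              j = c(as.vector(nn), seq_len(n)),
                              x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(adj)
  shared <- methods::as(shared, "CsparseMatrix")
  ksz <- k_neighbors + 1L
  shared@x <- shared@x / (2 * ksz - shared@x)   # jaccard
  shared@x[shared@x < prune] <- 0
  shared <- Matrix::drop0(shared)
  g <- igraph::graph_from_adjacency_matrix(shared, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  comm <- local_seed(seed, igraph::cluster_louvain(
    g, weights = igraph::E(g)$weight, resolution = resolution))
  mem <- igraph::membership(comm)
  sizes <- sort(table(mem), decreasing = TRUE)
  relabel <- setNames(paste0("C", seq_along(sizes) - 1L), names(sizes))
  cluster_labels(rownames(coords), unname(relabel[as.character(mem)]), 1L)
}

#' Number of subclusters for a target median size
#'
#' `k = max(1, floor(n_cells / target_median + 0.5))` (half rounds up).
#'
#' @param n_cells Number of cells.
#' @param target_median Desired median cells per subcluster (default 100).
#' @return Integer k.
#' @export
choose_k <- function(n_cells, target_median = 100L) {
  stopifnot(n_cells >= 1, target_median >= 1)
  max(1L, as.integer(floor(n_cells / target_median + 0.5)))
}

#' Subclustering parameters
#'
#' @param target_median Desired median cells per subcluster (default 100).
#' @param max_iter Maximum Lloyd iterations (default 100).
#' @param seed RNG seed recorded for provenance (the algorithm itself is
#'   deterministic).
#' @param tol Convergence tolerance on the within-cluster sum of squares.
#' @return A `SubclusterParams` list.
#' @export
subcluster_params <- function(target_median = 100L, max_iter = 100L,
                              seed = 0L, tol = 1e-6) {
  stopifnot(target_median >= 1)
  structure(list(target_median = as.integer(target_median),
                 max_iter = as.integer(max_iter),
                 seed = as.integer(seed), tol = tol),
            class = "SubclusterParams")
}

#' Max-min seeded k-means subclustering
#'
#' Generates metacell-like subclusters of a target median size. k is set by
#' [choose_k()]; seeding is farthest-first: the first seed is the cell
#' nearest the subset centroid, and each following seed maximizes its minimum
#' euclidean distance to the seeds already chosen (ties broken by cell id).
#' Lloyd iterations then run to an assignment fixpoint (or `max_iter`). The
#' procedure is fully deterministic given the input.
#'
#' @param embedding An `Embedding`.
#' @param cells Optional subset of cell ids (default: all cells).
#' @param params A [subcluster_params()] object.
#' @param label_prefix Prefix for subcluster labels, used to nest level-4
#'   labels under their parent cell type.
#' @return A `ClusterLabels` object at level 4 with a `wss_trace` attribute
#'   (within-cluster sum of squares per Lloyd iteration).
#' @export
maxmin_kmeans <- function(embedding, cells = NULL,
                          params = subcluster_params(),
                          label_prefix = "") {
  coords <- embedding$coords
  if (!is.null(cells)) {
    missing <- setdiff(cells, rownames(coords))
    if (length(missing))
      stopf("cells absent from embedding: %s",
            paste(head(missing, 5), collapse = ", "))
    coords <- coords[cells, , drop = FALSE]
  }
  n <- nrow(coords)
  if (n == 0) stopf("empty cell subset")
  ids <- rownames(coords)
  k <- choose_k(n, params$target_median)
  if (k > n) {
    warnf("k (%d) exceeds number of cells (%d); clamped", k, n)
    k <- n
  }

  # farthest-first (max-min) seeding
  ctr <- colMeans(coords)
  d0 <- rowSums(sweep(coords, 2, ctr, "-")^2)
  seeds <- integer(k)
  seeds[1] <- order(d0, ids)[1]
  if (k > 1) {
    mind <- rowSums(sweep(coords, 2, coords[seeds[1], ], "-")^2)
    for (j in 2:k) {
      seeds[j] <- order(-mind, ids)[1]
      if (j < k) {
        dj <- rowSums(sweep(coords, 2, coords[seeds[j], ], "-")^2)
        mind <- pmin(mind, dj)
      }
    }
  }
  centers <- coords[seeds, , drop = FALSE]

  assign_nearest <- function(centers) {
    d2 <- outer(rowSums(coords^2), rowSums(centers^2), "+") -
      2 * tcrossprod(coords, centers)
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_nearest(centers)
  wss_trace <- numeric(0)
  for (iter in seq_len(params$max_iter)) {
    for (j in seq_len(k)) {           # keep every subcluster nonempty
      if (!any(lab == j)) {
        cd <- rowSums((coords - centers[lab, , drop = FALSE])^2)
        lab[which.max(cd)] <- j
      }
    }
    centers <- rowsum(coords, lab) / as.vector(table(lab))
    wss <- sum(rowSums((coords - centers[lab, , drop = FALSE])^2))
    wss_trace <- c(wss_trace, wss)
    new_lab <- assign_nearest(centers)
    if (all(new_lab == lab)) break
    if (length(wss_trace) > 1 &&
        abs(diff(tail(wss_trace, 2))) < params$tol * wss) {
      lab <- new_lab
      break
    }
    lab <- new_lab
  }
  fmt <- paste0(label_prefix, "s%0", nchar(as.character(k)), "d")
  out <- cluster_labels(ids, sprintf(fmt, lab), 4L)
  attr(out, "wss_trace") <- wss_trace
  out
}

# Wilcoxon rank-sum (normal approximation with tie correction), vectorized
# over the columns of a dense matrix; `in_mask` marks group 1.
rank_sum_test <- function(vals, in_mask) {
  n1 <- sum(in_mask); n2 <- sum(!in_mask); n <- n1 + n2
  apply(vals, 2, function(x) {
    r <- rank(x)
    u <- sum(r[in_mask]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tiecor <- sum(ties^3 - ties) / (n * (n - 1))
    sg2 <- n1 * n2 / 12 * ((n + 1) - tiecor)
    if (sg2 <= 0) return(1)
    z <- (u - n1 * n2 / 2) / sqrt(sg2)
    min(1, 2 * stats::pnorm(-abs(z)))
  })
}

#' One-vs-rest marker detection
#'
#' For every cluster, tests each candidate gene with a Wilcoxon rank-sum test
#' (normal approximation with tie correction) against all other cells. The
#' log2 fold change is computed on `expm1`-scale means with a pseudocount of
#' 1. P values are Benjamini-Hochberg adjusted within each cluster across the
#' genes tested for it. Only rows with `log2_fold_change > lfc_min`,
#' `pct_in > pct_min` and `p_adjusted < alpha` are retained.
#'
#' @param norm A `NormMatrix`.
#' @param labels A `ClusterLabels` object (>= 2 clusters; clusters with fewer
#'   than 3 cells are skipped with a warning).
#' @param lfc_min Minimum log2 fold change (default 0.25).
#' @param pct_min Minimum in-cluster detection fraction (default 0.1).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Data frame with columns gene, cluster, log2_fold_change, pct_in,
#'   pct_out, p_value, p_adjusted.
#' @export
find_markers <- function(norm, labels, lfc_min = 0.25, pct_min = 0.1,
                         alpha = 0.05) {
  stopifnot(inherits(norm, "NormMatrix"), inherits(labels, "ClusterLabels"))
  v <- norm$values[labels$cell_ids, , drop = FALSE]
  labs <- labels$labels
  uniq <- sort(unique(labs))
  if (length(uniq) < 2) stopf("need at least 2 clusters")
  res <- list()
  for (cl in uniq) {
    in_mask <- labs == cl
    if (sum(in_mask) < 3) {
      warnf("cluster '%s' has < 3 cells; skipped", cl)
      next
    }
    vi <- v[in_mask, , drop = FALSE]
    vo <- v[!in_mask, , drop = FALSE]
    pct_in <- Matrix::colMeans(vi > 0)
    pct_out <- Matrix::colMeans(vo > 0)
    mi <- Matrix::colMeans(expm1(vi))
    mo <- Matrix::colMeans(expm1(vo))
    lfc <- log2((mi + 1) / (mo + 1))
    cand <- which(pct_in > pct_min & lfc > lfc_min)
    if (!length(cand)) next
    p <- rank_sum_test(as.matrix(v[, cand, drop = FALSE]), in_mask)
    padj <- stats::p.adjust(p, method = "BH")
    keep <- padj < alpha
    if (!any(keep)) next
    res[[cl]] <- data.frame(gene = colnames(v)[cand][keep],
                            cluster = cl,
                            log2_fold_change = lfc[cand][keep],
                            pct_in = pct_in[cand][keep],
                            pct_out = pct_out[cand][keep],
                            p_value = p[keep],
                            p_adjusted = padj[keep],
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(res))
    return(data.frame(gene = character(), cluster = character(),
                      log2_fold_change = numeric(), pct_in = numeric(),
                      pct_out = numeric(), p_value = numeric(),
                      p_adjusted = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$cluster, -out$log2_fold_change, out$gene), , drop = FALSE]
}
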
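# Reading, quality control, normalization, feature selection and PCA for
# single-cell count matrices. Cells are rows internally; 10x-style input
# (genes x cells) is transposed at read time.

#' Construct a single-cell count matrix
#'
#' Thin container holding a sparse cells x genes matrix of non-negative
#' integer counts together with optional per-cell donor labels and doublet
#' flags. Cell and gene identifiers must be unique.
#'
#' @param counts Matrix-like object (cells x genes) coercible to a sparse
#'   `dgCMatrix`, with rownames (cell ids) and colnames (gene ids).
#' @param donor_labels Optional character vector, one donor label per cell.
#' @param doublet_flags Optional logical vector, one flag per cell; `TRUE`
#'   marks a cell called as a doublet by an external tool.
#' @return An object of class `CountMatrix`.
#' @export
count_matrix <- function(counts, donor_labels = NULL, doublet_flags = NULL) {
  m <- methods::as(methods::as(methods::as(counts, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  dn <- dimnames(m)
  if (is.null(dn[[1]]) && nrow(m) == 0) dn[[1]] <- character(0)
  if (is.null(dn[[2]]) && ncol(m) == 0) dn[[2]] <- character(0)
  if (is.null(dn[[1]]) || is.null(dn[[2]]))
    stopf("counts must carry cell ids (rownames) and gene ids (colnames)")
  dimnames(m) <- dn
  if (anyDuplicated(rownames(m))) stopf("duplicate cell identifiers")
  if (anyDuplicated(colnames(m))) stopf("duplicate gene identifiers")
  if (any(m@x < 0)) stopf("counts must be non-negative")
  if (!is.null(donor_labels) && length(donor_labels) != nrow(m))
    stopf("donor_labels length (%d) != number of cells (%d)",
          length(donor_labels), nrow(m))
  if (!is.null(doublet_flags) && length(doublet_flags) != nrow(m))
    stopf("doublet_flags length (%d) != number of cells (%d)",
          length(doublet_flags), nrow(m))
  structure(list(counts = m,
                 donor_labels = donor_labels,
                 doublet_flags = if (is.null(doublet_flags)) NULL
                                 else as.logical(doublet_flags)),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
`[.CountMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  ii <- if (is.character(i)) match(i, rownames(x$counts)) else
    seq_len(nrow(x$counts))[i]
  if (anyNA(ii)) stopf("unknown cell ids in subset")
  count_matrix(x$counts[ii, j, drop = FALSE],
               donor_labels = x$donor_labels[ii],
               doublet_flags = x$doublet_flags[ii])
}

#' Cell and gene identifiers
#' @param x A `CountMatrix` or `NormMatrix`.
#' @return Character vector of ids.
#' @export
cell_ids <- function(x) rownames(if (inherits(x, "NormMatrix")) x$values else x$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(x) colnames(if (inherits(x, "NormMatrix")) x$values else x$counts)

find_first <- function(dir, candidates) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  NULL
}

read_table_cols <- function(path) {
  # plain or gzipped TSV without header (read.delim decompresses .gz itself)
  read.delim(path, header = FALSE, stringsAsFactors = FALSE)
}

#' Read a single-cell count matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet directory (`matrix.mtx` plus
#' gene/feature and barcode tables, plain or gzipped) and a dense TSV with a
#' header row of gene ids and a first column of cell ids. Cells are returned
#' as rows regardless of the on-disk orientation. Duplicated gene symbols are
#' disambiguated by suffixing (`ACTB`, `ACTB.1`, ...).
#'
#' @param path Directory (for `mtx_dir`) or file (for `dense_tsv`).
#' @param format One of `"mtx_dir"`, `"dense_tsv"`.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path, format = c("mtx_dir", "dense_tsv")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    if (!dir.exists(path)) stopf("input directory not found: %s", path)
    mtx <- find_first(path, c("matrix.mtx", "matrix.mtx.gz"))
    if (is.null(mtx)) stopf("missing Matrix Market file: %s",
                            file.path(path, "matrix.mtx[.gz]"))
    feats <- find_first(path, c("features.tsv", "features.tsv.gz",
                                "genes.tsv", "genes.tsv.gz"))
    if (is.null(feats)) stopf("missing gene table: %s",
                              file.path(path, "features.tsv[.gz]"))
    bcs <- find_first(path, c("barcodes.tsv", "barcodes.tsv.gz"))
    if (is.null(bcs)) stopf("missing barcode table: %s",
                            file.path(path, "barcodes.tsv[.gz]"))
    m <- Matrix::readMM(mtx)
    ft <- read_table_cols(feats)
    bc <- read_table_cols(bcs)
    genes <- if (ncol(ft) >= 2) as.character(ft[[2]]) else as.character(ft[[1]])
    cells <- as.character(bc[[1]])
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      stopf("matrix is %d x %d but gene/barcode tables list %d genes and %d cells",
            nrow(m), ncol(m), length(genes), length(cells))
    m <- Matrix::t(m)              # on-disk genes x cells -> cells x genes
    dimnames(m) <- list(cells, make.unique(genes))
    count_matrix(m)
  } else {
    if (!file.exists(path)) stopf("input file not found: %s", path)
    first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
    tab <- read.delim(path, header = FALSE, skip = 1L,
                      stringsAsFactors = FALSE)
    # header may or may not carry a label over the cell-id column
    genes <- if (length(first) == ncol(tab)) first[-1] else first
    cells <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (ncol(m) != length(genes))
      stopf("header lists %d genes but rows carry %d values",
            length(genes), ncol(m))
    dimnames(m) <- list(cells, make.unique(genes))
    count_matrix(m)
  }
}

#' Quality-control parameters
#'
#' Defaults follow the standard droplet scRNA-seq filters: cells are removed
#' when they express fewer than `min_genes` genes, carry fewer than
#' `min_counts` or more than `max_counts` unique counts, exceed
#' `max_mito_fraction` mitochondrial content, or are flagged as doublets.
#'
#' @param min_genes Minimum number of expressed genes (default 300).
#' @param min_counts Minimum total counts (default 500).
#' @param max_counts Maximum total counts (default 30000).
#' @param max_mito_fraction Maximum mitochondrial fraction (default 0.10).
#' @param mito_prefix Gene-id prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @param drop_doublets Remove cells flagged as doublets (default `TRUE`).
#' @return A `QCParams` list.
#' @export
qc_params <- function(min_genes = 300L, min_counts = 500L,
                      max_counts = 30000L, max_mito_fraction = 0.10,
                      mito_prefix = "MT-", drop_doublets = TRUE) {
  if (min_counts >= max_counts) stopf("min_counts must be < max_counts")
  if (max_mito_fraction < 0 || max_mito_fraction > 1)
    stopf("max_mito_fraction must lie in [0, 1]")
  structure(list(min_genes = as.integer(min_genes),
                 min_counts = as.integer(min_counts),
                 max_counts = as.integer(max_counts),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix,
                 drop_doublets = isTRUE(drop_doublets)),
            class = "QCParams")
}

#' Filter low-quality cells
#'
#' Applies the four per-cell rules of [qc_params()] in a fixed order
#' (min_genes, min_counts, max_counts, max_mito, doublet) and reports, for
#' every removed cell, the first rule it failed. The gene set is unchanged.
#' If no gene id carries the mitochondrial prefix the mito rule is skipped
#' with a warning and the skip is recorded in the report's
#' `mito_rule_skipped` attribute.
#'
#' @param x A [count_matrix()].
#' @param params A [qc_params()] object.
#' @return A list with `counts` (filtered `CountMatrix`) and `report`
#'   (per-cell data frame: id, stats, pass flag, first failing reason).
#' @export
qc_filter <- function(x, params = qc_params()) {
  stopifnot(inherits(x, "CountMatrix"))
  m <- x$counts
  n_genes <- Matrix::rowSums(m > 0)
  totals <- Matrix::rowSums(m)
  mito <- startsWith(colnames(m), params$mito_prefix)
  mito_skipped <- !any(mito)
  if (mito_skipped) {
    warnf("no gene ids start with '%s'; mitochondrial rule skipped",
          params$mito_prefix)
    mito_frac <- rep(0, nrow(m))
  } else {
    mito_frac <- Matrix::rowSums(m[, mito, drop = FALSE]) / pmax(totals, 1)
  }
  doublet <- if (params$drop_doublets && !is.null(x$doublet_flags))
    x$doublet_flags else rep(FALSE, nrow(m))

  reason <- rep(NA_character_, nrow(m))
  rule <- function(fail, name) ifelse(is.na(reason) & fail, name, reason)
  reason <- rule(n_genes < params$min_genes, "min_genes")
  reason <- rule(totals < params$min_counts, "min_counts")
  reason <- rule(totals > params$max_counts, "max_counts")
  if (!mito_skipped)
    reason <- rule(mito_frac > params$max_mito_fraction, "max_mito")
  reason <- rule(doublet, "doublet")

  keep <- is.na(reason)
  report <- data.frame(cell_id = rownames(m),
                       n_genes = as.integer(n_genes),
                       n_counts = as.numeric(totals),
                       mito_fraction = mito_frac,
                       doublet = doublet,
                       pass = keep,
                       reason = ifelse(keep, "", reason),
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(report, "mito_rule_skipped") <- mito_skipped
  out <- count_matrix(m[keep, , drop = FALSE],
                      donor_labels = x$donor_labels[keep],
                      doublet_flags = x$doublet_flags[keep])
  list(counts = out, report = report)
}

#' Log-normalize counts
#'
#' Library-size normalization followed by `log1p`:
#' `value(c, g) = log1p(count(c, g) / total(c) * scale_factor)`.
#'
#' @param x A [count_matrix()]; every cell must have total count > 0.
#' @param scale_factor Counts-per-`scale_factor` target (default 1e4).
#' @return A `NormMatrix` (sparse cells x genes log-normalized values).
#' @export
lognormalize <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "CountMatrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0))
    stopf("cells with zero total counts present; run qc_filter first")
  v <- Matrix::Diagonal(x = scale_factor / totals) %*% x$counts
  v <- methods::as(v, "CsparseMatrix")
  v@x <- log1p(v@x)
  dimnames(v) <- dimnames(x$counts)
  structure(list(values = v, scale_factor = scale_factor),
            class = "NormMatrix")
}

#' @export
print.NormMatrix <- function(x, ...) {
  cat(sprintf("NormMatrix: %d cells x %d genes (scale factor %g)\n",
              nrow(x$values), ncol(x$values), x$scale_factor))
  invisible(x)
}

#' @export
dim.NormMatrix <- function(x) dim(x$values)

gene_mean_var <- function(v) {
  n <- nrow(v)
  mu <- Matrix::colMeans(v)
  ex2 <- Matrix::colMeans(v^2)
  varg <- (ex2 - mu^2) * n / max(n - 1, 1)
  list(mean = mu, var = pmax(varg, 0))
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion (variance / mean of the log-normalized values)
#' standardized within mean-abundance bins, and returns the top `n_top`
#' gene ids. Deterministic; ties are broken by gene id. Genes with zero
#' variance are never selected.
#'
#' @param norm A `NormMatrix` from [lognormalize()].
#' @param n_top Number of genes to keep (default 3000); clamped with a
#'   warning when fewer variable genes are available.
#' @param n_bins Number of equal-frequency mean bins (default 20).
#' @return Character vector of gene ids, ranked most variable first.
#' @export
select_hvg <- function(norm, n_top = 3000L, n_bins = 20L) {
  stopifnot(inherits(norm, "NormMatrix"))
  mv <- gene_mean_var(norm$values)
  # guard against floating-point residue on genuinely constant genes
  ok <- mv$var > 1e-10 * (1 + mv$mean^2) & mv$mean > 0
  if (!any(ok)) stopf("no variable genes in the matrix")
  ids <- colnames(norm$values)[ok]
  mu <- mv$mean[ok]
  disp <- mv$var[ok] / mu
  br <- unique(quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  z <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  if (n_top > length(ids)) {
    warnf("n_top (%d) exceeds available variable genes (%d); clamped",
          n_top, length(ids))
    n_top <- length(ids)
  }
  ids[order(-z, ids)][seq_len(n_top)]
}

#' Principal-component embedding
#'
#' Standardizes the selected genes (zero mean, unit variance, values clipped
#' at +/-10) and computes the leading principal components via an
#' eigendecomposition of the gene-gene covariance. The sign of each component
#' is fixed so its largest-magnitude gene loading is positive.
#'
#' @param norm A `NormMatrix`.
#' @param genes Gene ids to use (typically from [select_hvg()]).
#' @param d Number of dimensions (default 30); clamped with a warning when it
#'   exceeds `min(cells, genes)`.
#' @param clip Absolute clip applied to standardized values (default 10).
#' @return An `Embedding`: list with `coords` (cells x d), `explained_variance`
#'   (non-increasing), `d`.
#' @export
embed_pca <- function(norm, genes, d = 30L, clip = 10) {
  stopifnot(inherits(norm, "NormMatrix"))
  missing <- setdiff(genes, colnames(norm$values))
  if (length(missing))
    stopf("genes absent from matrix: %s", paste(head(missing, 5), collapse = ", "))
  x <- as.matrix(norm$values[, genes, drop = FALSE])
  mu <- colMeans(x)
  sdv <- apply(x, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x <- clamp(sweep(sweep(x, 2, mu, "-"), 2, sdv, "/"), -clip, clip)
  n <- nrow(x)
  maxd <- min(n, ncol(x))
  if (d > maxd) {
    warnf("d (%d) exceeds min(cells, genes) = %d; clamped", d, maxd)
    d <- maxd
  }
  cv <- crossprod(x) / max(n - 1, 1)
  ed <- eigen(cv, symmetric = TRUE)
  v <- ed$vectors[, seq_len(d), drop = FALSE]
  for (k in seq_len(d)) {
    j <- which.max(abs(v[, k]))
    if (v[j, k] < 0) v[, k] <- -v[, k]
  }
  coords <- x %*% v
  rownames(coords) <- rownames(norm$values)
  colnames(coords) <- paste0("PC", seq_len(d))
  ev <- pmax(ed$values[seq_len(d)], 0)
  structure(list(coords = coords, explained_variance = ev, d = d,
                 total_variance = sum(pmax(ed$values, 0))),
            class = "Embedding")
}

#' @export
print.Embedding <- function(x, ...) {
  cat(sprintf("Embedding: %d cells x %d dimensions\n", nrow(x$coords), x$d))
  invisible(x)
}
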
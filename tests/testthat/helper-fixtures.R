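# Shared fixtures, built lazily once per test run.

.fx <- new.env(parent = emptyenv())

# Multi-donor reference cohort at the generator's default study conditions.
fx_cohort <- function() {
  if (is.null(.fx$cohort)) {
    cfg <- synthetic_config(seed = 42)
    .fx$cohort <- simulate_reference_cohort(cfg)
  }
  .fx$cohort
}

# Atlas built from the cohort above.
fx_atlas <- function() {
  if (is.null(.fx$atlas)) {
    co <- fx_cohort()
    .fx$atlas <- run_build_ref(co$counts, co$truth$cell_types,
                               co$truth$config$tree, n_hvg = 1500,
                               verbose = FALSE)
  }
  .fx$atlas
}

# NormMatrix straight from a dense value matrix (bypasses count generation).
make_norm <- function(values, scale_factor = 1e4) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("c%03d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("g%03d", seq_len(ncol(values)))
  v <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  structure(list(values = v, scale_factor = scale_factor),
            class = "NormMatrix")
}

# CountMatrix from a dense matrix with auto ids.
make_counts <- function(m, cells = NULL, genes = NULL, ...) {
  rownames(m) <- cells %||% sprintf("c%02d", seq_len(nrow(m)))
  colnames(m) <- genes %||% sprintf("g%02d", seq_len(ncol(m)))
  count_matrix(m, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Five-cell QC toy: one failure per rule plus one passing cell.
# Gene space: 600 genes incl. one mitochondrial gene.
qc_toy <- function() {
  n_genes <- 600
  genes <- c(sprintf("g%03d", seq_len(n_genes - 1)), "MT-1")
  m <- matrix(0, 5, n_genes, dimnames = list(
    c("few_genes", "few_counts", "many_counts", "mito_high", "ok"), genes))
  m["few_genes", 1:299] <- 2              # 299 genes expressed, 598 counts
  m["few_counts", 1:400] <- 1             # 400 genes, 400 counts (< 500)
  m["many_counts", 1:500] <- 70           # 35000 counts (> 30000)
  m["mito_high", 1:400] <- 2              # 800 + 100 mito = 11% mito
  m["mito_high", "MT-1"] <- 100
  m["ok", 1:400] <- 3                     # 400 genes, 1200 counts, 0% mito
  count_matrix(m, doublet_flags = c(FALSE, FALSE, FALSE, FALSE, FALSE))
}

# Marker-threshold fixture: NormMatrix with genes engineered to sit exactly
# at the log2FC 0.24/0.26 and pct 0.09/0.11 decision boundaries.
threshold_marker_fixture <- function() {
  n_in <- 100; n_out <- 100
  v <- matrix(0, n_in + n_out, 5,
              dimnames = list(sprintf("c%03d", seq_len(n_in + n_out)),
                              c("lfc_low", "lfc_high", "pct_low", "pct_high",
                                "flat")))
  in_cells <- seq_len(n_in)
  v[in_cells, "lfc_low"] <- log1p(2^0.24 - 1)   # expm1-mean fold 2^0.24
  v[in_cells, "lfc_high"] <- log1p(2^0.26 - 1)
  v[in_cells[1:9], "pct_low"] <- log1p(5)       # pct_in = 0.09
  v[in_cells[1:11], "pct_high"] <- log1p(5)     # pct_in = 0.11
  v[, "flat"] <- log1p(1)                       # identical in and out
  labels <- cluster_labels(rownames(v),
                           rep(c("in", "out"), c(n_in, n_out)), 1L)
  list(norm = make_norm(v), labels = labels)
}
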
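# Bulk RNA-seq scoring: one LASSO model per cell type trained on subcluster
# centroids (0/1 membership response, squared-error loss, 10-fold CV for
# lambda), raw sample scores, normalization against a normal panel, and
# aberrant-call thresholds at fold change 1.25.

lambda_grid <- function(x, y, n = 100L, min_ratio = 1e-4) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / nrow(x)
  lmax <- max(lmax, 1e-8)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n))
}

# Stratified fold assignment: members and non-members are shuffled
# independently and dealt round-robin across folds.
stratified_folds <- function(y, folds, seed) {
  local_seed(seed, {
    id <- integer(length(y))
    for (g in unique(y)) {
      i <- sample(which(y == g))
      id[i] <- rep_len(seq_len(folds), length(i))
    }
    id
  })
}

#' Train per-cell-type LASSO models on subcluster centroids
#'
#' For every cell type `t` the response is 1 for subclusters annotated to
#' `t` and 0 otherwise; predictors are the gene-standardized centroid
#' profiles. An L1-penalized least-squares path is fitted over a 100-point
#' log-spaced lambda grid and the optimal lambda minimizes the mean
#' cross-validation error over `folds` membership-stratified folds.
#' Standardization parameters are frozen into the model set for scoring.
#' Cell types with fewer than 2 member or 2 non-member subclusters are
#' skipped with a warning.
#'
#' @param B Subcluster centroid matrix (subclusters x genes), e.g.
#'   `atlas$B`.
#' @param subcluster_map Named character vector, subcluster -> cell type.
#' @param folds Number of CV folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param family `"gaussian"` (default, squared-error loss) or
#'   `"binomial"` for a logistic variant.
#' @param lambda_rule `"min"` (default; lambda at minimum mean CV error) or
#'   `"1se"` (largest lambda within one standard error of the minimum).
#' @return A `LassoModelSet`.
#' @export
train_models <- function(B, subcluster_map, folds = 10L, seed = 0L,
                         family = c("gaussian", "binomial"),
                         lambda_rule = c("min", "1se")) {
  family <- match.arg(family)
  lambda_rule <- match.arg(lambda_rule)
  B <- as.matrix(B)
  if (nrow(B) < folds)
    stopf("need at least %d subclusters for %d-fold CV (got %d)",
          folds, folds, nrow(B))
  map <- subcluster_map[rownames(B)]
  if (anyNA(map)) stopf("subcluster_map does not cover all rows of B")
  mu <- colMeans(B)
  sdv <- apply(B, 2, stats::sd)
  sdv[sdv == 0] <- 1
  X <- sweep(sweep(B, 2, mu, "-"), 2, sdv, "/")
  models <- list()
  for (ct in sort(unique(map))) {
    y <- as.numeric(map == ct)
    if (sum(y) < 2 || sum(1 - y) < 2) {
      warnf("cell type '%s' has < 2 member or non-member subclusters; skipped", ct)
      next
    }
    grid <- lambda_grid(X, y)
    foldid <- stratified_folds(y, folds, seed)
    cv <- glmnet::cv.glmnet(X, y, alpha = 1, lambda = grid, foldid = foldid,
                            family = family, standardize = FALSE)
    lam <- if (lambda_rule == "min") cv$lambda.min else cv$lambda.1se
    cf <- as.matrix(stats::coef(cv, s = lam))
    w <- cf[-1, 1]
    models[[ct]] <- list(coefficients = w[w != 0],
                         intercept = cf[1, 1],
                         lambda_opt = lam,
                         cv_table = data.frame(lambda = cv$lambda,
                                               cvm = cv$cvm, cvsd = cv$cvsd),
                         nzero = as.vector(cv$nzero))
  }
  if (!length(models)) stopf("no trainable cell types")
  structure(list(models = models, gene_mean = mu, gene_sd = sdv,
                 genes = colnames(B), folds = as.integer(folds),
                 seed = as.integer(seed), family = family,
                 lambda_rule = lambda_rule),
            class = "LassoModelSet")
}

#' @export
print.LassoModelSet <- function(x, ...) {
  nz <- vapply(x$models, function(m) length(m$coefficients), integer(1))
  cat(sprintf("LassoModelSet: %d cell types (%s, %d-fold CV), %d-%d nonzero coefficients\n",
              length(x$models), x$family, x$folds, min(nz), max(nz)))
  invisible(x)
}

#' Score bulk samples with the per-cell-type models
#'
#' `raw_score(sample, t) = intercept_t + sum_g coef_t(g) * z(g, sample)`
#' where `z` standardizes the bulk expression with the gene means and
#' standard deviations frozen at training time. Genes absent from the bulk
#' matrix contribute 0; a per-type warning is raised when fewer than half of
#' a model's nonzero-coefficient genes are present.
#'
#' @param expr Bulk expression matrix (genes x samples) on the same scale as
#'   the training centroids (log-normalized).
#' @param models A `LassoModelSet`.
#' @return A `ScoreTable` with the `raw` matrix (samples x cell types).
#' @export
score_samples <- function(expr, models) {
  stopifnot(inherits(models, "LassoModelSet"))
  expr <- as.matrix(expr)
  if (is.null(rownames(expr))) stopf("expr must carry gene ids as rownames")
  shared <- intersect(models$genes, rownames(expr))
  if (!length(shared)) stopf("no genes shared between bulk matrix and models")
  z <- sweep(sweep(expr[shared, , drop = FALSE], 1, models$gene_mean[shared], "-"),
             1, models$gene_sd[shared], "/")
  raw <- matrix(0, ncol(expr), length(models$models),
                dimnames = list(colnames(expr), names(models$models)))
  for (ct in names(models$models)) {
    m <- models$models[[ct]]
    gs <- names(m$coefficients)
    present <- intersect(gs, shared)
    if (length(gs) && length(present) < 0.5 * length(gs))
      warnf("cell type '%s': only %d of %d model genes present in bulk matrix",
            ct, length(present), length(gs))
    raw[, ct] <- m$intercept +
      if (length(present)) as.vector(crossprod(z[present, , drop = FALSE],
                                               m$coefficients[present])) else 0
  }
  structure(list(raw = raw, normalized = NULL, z_score = NULL,
                 calls = NULL, normal_ids = NULL),
            class = "ScoreTable")
}

#' @export
print.ScoreTable <- function(x, ...) {
  cat(sprintf("ScoreTable: %d samples x %d cell types%s%s\n",
              nrow(x$raw), ncol(x$raw),
              if (!is.null(x$normalized)) ", normalized" else "",
              if (!is.null(x$calls)) ", called" else ""))
  invisible(x)
}

#' Normalize scores against a normal panel
#'
#' Per cell type, the normalized score subtracts the mean raw score of the
#' designated normal samples (so the normal panel averages 0), and the
#' z-score standardizes raw scores across all samples.
#'
#' @param scores A `ScoreTable` from [score_samples()].
#' @param normal_ids Sample ids of the normal panel (>= 2, all present).
#' @return The `ScoreTable` with `normalized` and `z_score` filled.
#' @export
normalize_scores <- function(scores, normal_ids) {
  stopifnot(inherits(scores, "ScoreTable"))
  missing <- setdiff(normal_ids, rownames(scores$raw))
  if (length(missing))
    stopf("normal ids absent from score table: %s",
          paste(missing, collapse = ", "))
  if (length(normal_ids) < 2) stopf("need at least 2 normal samples")
  nmean <- colMeans(scores$raw[normal_ids, , drop = FALSE])
  scores$normalized <- sweep(scores$raw, 2, nmean, "-")
  sdv <- apply(scores$raw, 2, stats::sd)
  sdv[sdv == 0] <- 1
  scores$z_score <- sweep(sweep(scores$raw, 2, colMeans(scores$raw), "-"),
                          2, sdv, "/")
  scores$normal_ids <- normal_ids
  scores
}

#' Call aberrant cell types by fold change against the normal panel
#'
#' Scores are shifted per cell type so the normal-panel minimum maps to 1
#' (a positive scale on which fold changes are meaningful); a sample is
#' `aberrant_high` for a type when its shifted score exceeds
#' `fold_change` times the shifted normal mean, `aberrant_low` below
#' `1/fold_change` times it, otherwise `normal`. Types whose normal panel
#' has no spread are suppressed with a warning.
#'
#' @param scores A normalized `ScoreTable` (run [normalize_scores()] first).
#' @param fold_change Fold-change threshold (default 1.25).
#' @return The `ScoreTable` with a `calls` character matrix filled.
#' @export
call_aberrant <- function(scores, fold_change = 1.25) {
  stopifnot(inherits(scores, "ScoreTable"))
  if (is.null(scores$normal_ids))
    stopf("normalized scores absent; run normalize_scores first")
  raw <- scores$raw
  calls <- matrix("normal", nrow(raw), ncol(raw), dimnames = dimnames(raw))
  fc <- matrix(NA_real_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (ct in colnames(raw)) {
    nv <- raw[scores$normal_ids, ct]
    if (stats::sd(nv) == 0) {
      warnf("cell type '%s': degenerate normal spread; calls suppressed", ct)
      calls[, ct] <- NA_character_
      next
    }
    shifted <- raw[, ct] - min(nv) + 1
    nmean <- mean(shifted[scores$normal_ids])
    fc[, ct] <- shifted / nmean
    calls[fc[, ct] > fold_change, ct] <- "aberrant_high"
    calls[fc[, ct] < 1 / fold_change, ct] <- "aberrant_low"
  }
  scores$calls <- calls
  scores$fold_change <- fc
  scores$fold_change_threshold <- fold_change
  scores
}

#' Quantile-normalize bulk samples onto a reference distribution
#'
#' Maps every query column onto the pooled reference distribution (the mean
#' of the sorted reference columns over the shared gene set), interpolating
#' at tied ranks. Deterministic and invariant to sample order.
#'
#' @param bulk Query matrix (genes x samples).
#' @param reference_bulk Reference matrix (genes x samples) sharing at least
#'   100 gene ids with `bulk`.
#' @return Matrix of the same shape as `bulk` restricted to the shared
#'   genes.
#' @export
normalize_between <- function(bulk, reference_bulk) {
  bulk <- as.matrix(bulk); reference_bulk <- as.matrix(reference_bulk)
  shared <- intersect(rownames(bulk), rownames(reference_bulk))
  if (length(shared) < 100)
    stopf("need >= 100 shared genes (got %d)", length(shared))
  q <- bulk[shared, , drop = FALSE]
  r <- reference_bulk[shared, , drop = FALSE]
  target <- rowMeans(apply(r, 2, sort))
  n <- length(target)
  out <- apply(q, 2, function(x) {
    stats::approx(seq_len(n), target,
                  xout = rank(x, ties.method = "average"))$y
  })
  dimnames(out) <- dimnames(q)
  out
}
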
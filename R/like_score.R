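# Cosine similarity/distance, the sin(theta) adjustment against the HSC/MPP
# root, the LIKE score with its T/NK bypass, argmax cell-type assignment and
# per-sample composition estimates.
#
# For every query subcluster profile a and reference subcluster profile b,
#   sim(a, b) = a.b / (|a||b|),   d(a, b) = 1 - sim(a, b)
#   like(a, b) = sim(a, b) * sin(theta)   for non-T/NK reference rows
#   like(a, b) = sim(a, b)                for T/NK reference rows
# where theta is the angle of the query relative to the HSC/MPP root
# (see hsc_sin_theta for the two supported definitions).

#' Query subcluster profiles
#'
#' @param A Matrix of query subcluster centroids (subclusters x genes) with
#'   dimnames.
#' @param member_counts Integer vector, cells per subcluster (named or in
#'   row order); all >= 1.
#' @return A `QueryProfiles` object.
#' @export
query_profiles <- function(A, member_counts) {
  A <- as.matrix(A)
  if (is.null(rownames(A)) || is.null(colnames(A)))
    stopf("A must carry subcluster (row) and gene (column) names")
  if (!is.null(names(member_counts)))
    member_counts <- member_counts[rownames(A)]
  if (length(member_counts) != nrow(A))
    stopf("member_counts length (%d) != subclusters (%d)",
          length(member_counts), nrow(A))
  if (any(member_counts < 1)) stopf("member_counts must be >= 1")
  structure(list(A = A,
                 member_counts = setNames(as.integer(member_counts),
                                          rownames(A))),
            class = "QueryProfiles")
}

#' Cosine similarity and distance between expression profiles
#'
#' `cosine_similarity(a, b)` is the dot product of the two profiles divided
#' by the product of their magnitudes; for non-negative profiles it lies in
#' `[0, 1]`. `cosine_distance(a, b) = 1 - cosine_similarity(a, b)`.
#'
#' @param a,b Numeric vectors of equal length; neither may be all-zero.
#' @return A scalar in `[-1, 1]` (in `[0, 1]` for non-negative profiles).
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b))
    stopf("profile lengths differ (%d vs %d)", length(a), length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stopf("undefined similarity for zero profile")
  sum(a * b) / (na * nb)
}

#' @rdname cosine_similarity
#' @export
cosine_distance <- function(a, b) 1 - cosine_similarity(a, b)

#' Angle of a query profile relative to the HSC/MPP root
#'
#' In `query_vs_root` mode (the default) `cos(theta)` is the cosine
#' similarity between the query profile and the mean HSC/MPP centroid, and
#' `sin(theta) = sqrt(1 - cos(theta)^2)`. In `axis_offset` mode theta is the
#' angle between the root-centered query (`a - c_bar`) and the root-centered
#' reference row (`b - c_bar`); a query coinciding with the root mean has
#' `sin(theta)` defined as 0 with a warning.
#'
#' @param a Query profile vector.
#' @param C HSC/MPP centroid matrix (rows = root subclusters).
#' @param mode `"query_vs_root"` or `"axis_offset"`.
#' @param b Reference profile vector (required for `axis_offset`).
#' @return List with `cos_theta`, `sin_theta`, `mode`.
#' @export
hsc_sin_theta <- function(a, C, mode = c("query_vs_root", "axis_offset"),
                          b = NULL) {
  mode <- match.arg(mode)
  C <- as.matrix(C)
  if (nrow(C) == 0) stopf("empty HSC/MPP matrix")
  cbar <- colMeans(C)
  if (mode == "query_vs_root") {
    ct <- clamp(cosine_similarity(a, cbar), -1, 1)
  } else {
    if (is.null(b)) stopf("axis_offset mode requires a reference profile b")
    ar <- a - cbar; br <- b - cbar
    if (sqrt(sum(ar^2)) < 1e-12 * sqrt(sum(cbar^2))) {
      warnf("query coincides with the HSC/MPP mean; sin(theta) set to 0")
      return(list(cos_theta = 1, sin_theta = 0, mode = mode))
    }
    ct <- clamp(cosine_similarity(ar, br), -1, 1)
  }
  list(cos_theta = ct, sin_theta = sqrt(max(0, 1 - ct^2)), mode = mode)
}

#' LIKE scores of query subclusters against a reference atlas
#'
#' Restricts query and reference to their shared gene space (which must
#' cover at least half of the atlas HVGs), computes cosine similarities of
#' every query subcluster centroid to every reference subcluster centroid,
#' and scores each pair with `sim * sin(theta)`, where theta positions the
#' query relative to the HSC/MPP root. The T/NK lineage is recruited from
#' outside the bone marrow, so the root adjustment does not apply to it:
#' a query whose nearest reference row (by raw similarity) is T/NK keeps
#' the raw similarity as its score on T/NK rows. Because `sin(theta)` is a
#' common per-query factor, the maximizing reference row is the raw-sim
#' maximizer; each query is assigned the cell type of that row, suffixed
#' `"-like"`. Ties are broken by higher raw similarity, then lexicographic
#' reference row id.
#'
#' @param query A [query_profiles()] object.
#' @param atlas A `ReferenceAtlas`.
#' @param mode Theta definition, see [hsc_sin_theta()].
#' @param declared_lineage Optional query lineage declaration; `"T"` /
#'   `"T-ALL"` queries are refused because T-cell development is
#'   extramedullary and the score is undefined for them.
#' @return A `LikeResult`: per-subcluster assignment table plus the full
#'   `sim` and `like` matrices.
#' @export
like_score_matrix <- function(query, atlas,
                              mode = c("query_vs_root", "axis_offset"),
                              declared_lineage = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "QueryProfiles"), inherits(atlas, "ReferenceAtlas"))
  if (!is.null(declared_lineage) &&
      toupper(declared_lineage) %in% c("T", "TNK", "T-ALL", "TALL"))
    stopf(paste("query declared T-lineage: T-cell development is",
                "extramedullary and the LIKE score is undefined for it"))
  genes <- intersect(colnames(query$A), atlas$hvg)
  if (!length(genes)) stopf("no genes shared between query and atlas")
  if (length(genes) < 0.5 * length(atlas$hvg))
    stopf("query covers only %d of %d atlas genes (< 50%%)",
          length(genes), length(atlas$hvg))
  A <- query$A[, genes, drop = FALSE]
  B <- atlas$B[, genes, drop = FALSE]
  C <- atlas$C[, genes, drop = FALSE]
  cbar <- colMeans(C)
  sim <- row_unit(A, "query profile") %*% t(row_unit(B, "reference profile"))
  cls <- tree_lineage_class(atlas$tree)
  ref_types <- atlas$subcluster_map[rownames(B)]
  tnk <- cls[ref_types] == "TNK"

  nq <- nrow(A)
  ref_ids <- rownames(B)
  # counterpart determination on raw similarity (ties: lexicographic row id)
  best_idx <- integer(nq)
  for (i in seq_len(nq)) {
    mx <- max(sim[i, ])
    cand <- which(sim[i, ] >= mx - 1e-15)
    if (length(cand) > 1) cand <- cand[order(ref_ids[cand])]
    best_idx[i] <- cand[1]
  }
  tnk_query <- tnk[best_idx]

  like <- sim
  cos_theta <- sin_theta <- numeric(nq)
  if (mode == "query_vs_root") {
    for (i in seq_len(nq)) {
      th <- hsc_sin_theta(A[i, ], C, mode = "query_vs_root")
      cos_theta[i] <- th$cos_theta; sin_theta[i] <- th$sin_theta
      adj <- if (tnk_query[i]) !tnk else rep(TRUE, length(tnk))
      like[i, adj] <- sim[i, adj] * th$sin_theta
    }
  } else {
    for (i in seq_len(nq)) {
      ar <- A[i, ] - cbar
      if (sqrt(sum(ar^2)) < 1e-12 * sqrt(sum(cbar^2))) {
        warnf("query '%s' coincides with the HSC/MPP mean; sin(theta) = 0",
              rownames(A)[i])
        st <- rep(0, ncol(sim)); ct <- rep(1, ncol(sim))
      } else {
        Br <- sweep(B, 2, cbar, "-")
        nb <- sqrt(rowSums(Br^2))
        ct <- clamp(as.vector(Br %*% ar) / (sqrt(sum(ar^2)) * pmax(nb, 1e-300)),
                    -1, 1)
        st <- sqrt(pmax(0, 1 - ct^2))
      }
      adj <- if (tnk_query[i]) !tnk else rep(TRUE, length(tnk))
      like[i, adj] <- sim[i, adj] * st[adj]
      cos_theta[i] <- ct[best_idx[i]]; sin_theta[i] <- st[best_idx[i]]
    }
  }

  best <- character(nq); best_score <- numeric(nq)
  for (i in seq_len(nq)) {
    mx <- max(like[i, ])
    cand <- which(like[i, ] >= mx - 1e-15)
    if (length(cand) > 1) {
      cand <- cand[order(-sim[i, cand], ref_ids[cand])]
    }
    best[i] <- ref_ids[cand[1]]
    best_score[i] <- like[i, cand[1]]
  }
  tab <- data.frame(subcluster = rownames(A),
                    assigned_type = paste0(unname(ref_types[best]), "-like"),
                    ref_type = unname(ref_types[best]),
                    best_subcluster = best,
                    best_score = best_score,
                    cos_theta = cos_theta,
                    sin_theta = sin_theta,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, sim = sim, like = like, mode = mode,
                 member_counts = query$member_counts,
                 n_genes_used = length(genes)),
            class = "LikeResult")
}

#' @export
print.LikeResult <- function(x, ...) {
  cat(sprintf("LikeResult (%s): %d query subclusters vs %d reference rows\n",
              x$mode, nrow(x$table), ncol(x$sim)))
  print(head(x$table))
  invisible(x)
}

#' Composition profile container
#'
#' @param fractions Named numeric vector of cell-type fractions (sums to 1).
#' @param total_cells Total number of cells behind the estimate.
#' @return A `CompositionProfile`.
#' @export
composition_profile <- function(fractions, total_cells = NA_integer_) {
  if (any(fractions < 0)) stopf("fractions must be non-negative")
  s <- sum(fractions)
  if (abs(s - 1) > 1e-9) stopf("fractions must sum to 1 (got %.12f)", s)
  structure(list(fractions = fractions,
                 total_cells = as.integer(total_cells)),
            class = "CompositionProfile")
}

#' Estimate cellular composition from LIKE assignments
#'
#' `fraction(t)` is the number of query cells in subclusters assigned to
#' reference cell type `t` divided by the total number of query cells.
#' Fractions are keyed by the reference cell-type name (without the
#' `"-like"` suffix) so they can be compared with the normal composition.
#'
#' @param result A `LikeResult`.
#' @return A [composition_profile()].
#' @export
estimate_composition <- function(result) {
  stopifnot(inherits(result, "LikeResult"))
  counts <- result$member_counts[result$table$subcluster]
  agg <- tapply(as.numeric(counts), result$table$ref_type, sum)
  fr <- as.vector(agg) / sum(agg)
  names(fr) <- names(agg)
  composition_profile(fr, sum(counts))
}
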
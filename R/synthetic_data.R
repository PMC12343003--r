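# Synthetic cohorts with known truth: cell types arranged on a
# differentiation tree (disjoint marker blocks, smooth expression gradients
# along solid edges), negative-binomial counts with lognormal library sizes,
# mild multiplicative donor batch shifts, leukemic samples with one expanded
# blast population, and pseudobulk mixtures with known proportions.

#' Configuration of the synthetic cohort generator
#'
#' The defaults define the study conditions under which the package is
#' exercised: the miniature 11-type tree, 25 disjoint marker genes per type
#' boosted by 2 log2 units, moderate negative-binomial overdispersion,
#' lognormal library sizes around 2500 counts, a 30% blend of the parent
#' profile along solid edges, and 4 donors with mild batch noise.
#'
#' @param tree A `HierarchyTree` (default [miniature_tree()]).
#' @param n_cells_per_type Cells per type (scalar or named vector); ignored
#'   when `composition` is given.
#' @param composition Optional named fractions; cell types are then drawn
#'   multinomially for `n_cells_total` cells.
#' @param n_cells_total Total cells when `composition` is given.
#' @param n_genes Number of genes (default 2000; the last 10 are named with
#'   the `MT-` prefix so QC sees mitochondrial genes).
#' @param n_markers Markers per type (default 25), disjoint across types.
#' @param marker_lfc Marker boost in log2 units (default 2.0).
#' @param type_sigma Lognormal sigma of the genome-wide type-specific
#'   expression program (default 0.8). Real cell types differ across
#'   thousands of genes, not only in their markers; this term decorrelates
#'   type profiles accordingly. Marker genes are exempted so their
#'   fold-change guarantee is exact.
#' @param nb_dispersion Negative-binomial dispersion (default 0.1; the
#'   per-gene size parameter is jittered around `1/nb_dispersion`).
#' @param libsize_meanlog,libsize_sdlog Lognormal library-size parameters
#'   (defaults `log(2500)` and 0.35).
#' @param gradient_weight Blend of the parent mean into each child along
#'   solid edges, in `[0, 1]` (default 0.3).
#' @param n_donors Number of donors (default 4).
#' @param batch_sigma Lognormal sigma of per-donor per-gene batch factors
#'   (default 0.08).
#' @param seed RNG seed; generators are pure functions of (config, seed).
#' @return A `SyntheticConfig`.
#' @export
synthetic_config <- function(tree = miniature_tree(),
                             n_cells_per_type = 500L,
                             composition = NULL,
                             n_cells_total = NULL,
                             n_genes = 2000L,
                             n_markers = 25L,
                             marker_lfc = 2.0,
                             type_sigma = 0.8,
                             nb_dispersion = 0.1,
                             libsize_meanlog = log(2500),
                             libsize_sdlog = 0.35,
                             gradient_weight = 0.3,
                             n_donors = 4L,
                             batch_sigma = 0.08,
                             seed = 1L) {
  stopifnot(inherits(tree, "HierarchyTree"))
  types <- tree$nodes$name
  if (n_markers * length(types) > n_genes)
    stopf("marker demand (%d types x %d markers) exceeds n_genes (%d)",
          length(types), n_markers, n_genes)
  if (gradient_weight < 0 || gradient_weight > 1)
    stopf("gradient_weight must lie in [0, 1]")
  if (!is.null(composition)) {
    if (is.null(n_cells_total)) stopf("composition requires n_cells_total")
    if (abs(sum(composition) - 1) > 1e-9) stopf("composition must sum to 1")
    bad <- setdiff(names(composition), types)
    if (length(bad)) stopf("composition names unknown types: %s",
                           paste(bad, collapse = ", "))
  }
  if (length(n_cells_per_type) > 1) {
    bad <- setdiff(names(n_cells_per_type), types)
    if (length(bad)) stopf("n_cells_per_type names unknown types: %s",
                           paste(bad, collapse = ", "))
  }
  structure(list(tree = tree, n_cells_per_type = n_cells_per_type,
                 composition = composition, n_cells_total = n_cells_total,
                 n_genes = as.integer(n_genes),
                 n_markers = as.integer(n_markers),
                 marker_lfc = marker_lfc, type_sigma = type_sigma,
                 nb_dispersion = nb_dispersion,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 gradient_weight = gradient_weight,
                 n_donors = as.integer(n_donors),
                 batch_sigma = batch_sigma, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

synthetic_gene_ids <- function(n_genes) {
  n_mt <- if (n_genes >= 50) 10L else 0L
  c(sprintf("gene%04d", seq_len(n_genes - n_mt)),
    if (n_mt > 0) paste0("MT-", seq_len(n_mt)))
}

# Deterministic expression model: baseline lognormal means, disjoint marker
# blocks, gradient blending along solid edges, per-gene NB size parameters.
synthetic_model <- function(config) {
  local_seed(config$seed, {
    genes <- synthetic_gene_ids(config$n_genes)
    types <- config$tree$nodes$name
    baseline <- stats::rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
    names(baseline) <- genes
    non_mt <- genes[!startsWith(genes, "MT-")]
    pool <- sample(non_mt, config$n_markers * length(types))
    markers <- split(pool, rep(types, each = config$n_markers))[types]
    # genome-wide type program (markers exempted), then marker boosts
    program <- matrix(stats::rlnorm(length(types) * config$n_genes,
                                    0, config$type_sigma),
                      nrow = length(types),
                      dimnames = list(types, genes))
    program[, pool] <- 1
    raw <- matrix(rep(baseline, length(types)), nrow = length(types),
                  byrow = TRUE, dimnames = list(types, genes)) * program
    for (t in types)
      raw[t, markers[[t]]] <- raw[t, markers[[t]]] * 2^config$marker_lfc
    # blend parent means into children along solid edges (BFS from root)
    blended <- raw
    kind <- tree_edge_kind(config$tree)
    parent <- tree_parent(config$tree)
    for (nd in tree_preorder(config$tree)) {
      if (nd %in% names(parent) && kind[[nd]] == "solid") {
        w <- config$gradient_weight
        blended[nd, ] <- (1 - w) * raw[nd, ] + w * blended[parent[[nd]], ]
      }
    }
    props <- blended / rowSums(blended)
    size_g <- (1 / config$nb_dispersion) * 2^stats::runif(config$n_genes, -1, 1)
    list(genes = genes, type_props = props, markers = markers,
         size_g = size_g)
  })
}

# Per-cell type assignment: deterministic counts per type, or a multinomial
# draw when a composition is configured.
draw_cell_types <- function(config) {
  types <- config$tree$nodes$name
  if (!is.null(config$composition)) {
    prob <- setNames(rep(0, length(types)), types)
    prob[names(config$composition)] <- config$composition
    sample(types, config$n_cells_total, replace = TRUE, prob = prob)
  } else {
    npt <- config$n_cells_per_type
    n <- if (length(npt) > 1) {
      v <- setNames(rep(0L, length(types)), types)
      v[names(npt)] <- as.integer(npt)
      v
    } else setNames(rep(as.integer(npt), length(types)), types)
    rep(types, times = n[types])
  }
}

# NB count draw for a block of cells with given per-cell expected totals and
# a shared relative-expression profile.
nb_block <- function(libsizes, prop, size_g, batch_rows = NULL) {
  n <- length(libsizes); G <- length(prop)
  mu <- outer(libsizes, prop)
  if (!is.null(batch_rows)) mu <- mu * batch_rows
  matrix(stats::rnbinom(n * G, size = rep(size_g, each = n), mu = mu), n, G)
}

simulate_cells <- function(config, model, cell_types, donors, id_prefix) {
  genes <- model$genes
  n <- length(cell_types)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  libsizes <- stats::rlnorm(n, config$libsize_meanlog, config$libsize_sdlog)
  batch <- matrix(stats::rlnorm(config$n_donors * length(genes),
                                0, config$batch_sigma),
                  config$n_donors, length(genes))
  blocks <- list()
  for (t in unique(cell_types)) {
    i <- which(cell_types == t)
    cnt <- nb_block(libsizes[i], model$type_props[t, ], model$size_g,
                    batch[donors[i], , drop = FALSE])
    rownames(cnt) <- ids[i]
    blocks[[t]] <- cnt
  }
  m <- do.call(rbind, blocks)[ids, , drop = FALSE]
  colnames(m) <- genes
  count_matrix(m, donor_labels = paste0("donor", donors))
}

#' Simulate a multi-donor reference cohort
#'
#' Draws cells of every tree cell type with negative-binomial counts around
#' type-specific mean profiles (marker boosts plus gradient blending along
#' solid edges), lognormal library sizes, and mild per-donor batch factors.
#' Fully reproducible from `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with `counts` (a [count_matrix()]) and `truth`
#'   (`SyntheticTruth`: per-cell types and donors, per-type mean profiles,
#'   marker lists, realized composition, the model and config).
#' @export
simulate_reference_cohort <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  model <- synthetic_model(config)
  local_seed(config$seed + 1L, {
    cell_types <- draw_cell_types(config)
    donors <- sample.int(config$n_donors, length(cell_types), replace = TRUE)
    counts <- simulate_cells(config, model, cell_types, donors, "cell_")
    comp <- table(cell_types) / length(cell_types)
    truth <- structure(list(
      cell_types = setNames(cell_types, cell_ids(counts)),
      donors = setNames(paste0("donor", donors), cell_ids(counts)),
      type_means = model$type_props,
      markers = model$markers,
      composition = setNames(as.vector(comp), names(comp)),
      model = model, config = config), class = "SyntheticTruth")
    list(counts = counts, truth = truth)
  })
}

#' Simulate a leukemic sample with one expanded blast population
#'
#' The composition is rebalanced so `blast_type` holds `blast_fraction` of
#' the cells (remaining types scaled down proportionally). The blast mean
#' profile is `(1 - shift) * type mean + shift * root mean`, with mild
#' lognormal perturbation, emulating blasts that resemble, but deviate
#' from, their normal counterpart.
#'
#' @param truth `SyntheticTruth` from [simulate_reference_cohort()].
#' @param blast_type Tree node the blasts expand from.
#' @param blast_fraction Fraction of cells that are blasts.
#' @param shift Blend toward the root profile in `[0, 1]` (default 0.3).
#' @param n_cells Number of cells (default: size of the reference cohort).
#' @param blast_noise_sigma Lognormal sigma of the blast perturbation
#'   (default 0.05).
#' @param seed RNG seed.
#' @return A list with `counts` and `truth` (composition records
#'   `blast_fraction` for `blast_type` exactly).
#' @export
simulate_leukemia_sample <- function(truth, blast_type, blast_fraction,
                                     shift = 0.3, n_cells = NULL,
                                     blast_noise_sigma = 0.05, seed = 1L) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  config <- truth$config
  types <- config$tree$nodes$name
  if (!blast_type %in% types)
    stopf("blast_type '%s' is not a tree node", blast_type)
  if (blast_fraction <= 0 || blast_fraction >= 1)
    stopf("blast_fraction must lie in (0, 1)")
  n_cells <- n_cells %||% length(truth$cell_types)
  base <- setNames(rep(0, length(types)), types)
  base[names(truth$composition)] <- truth$composition
  rest <- base[setdiff(types, blast_type)]
  rest <- if (sum(rest) > 0) rest / sum(rest) * (1 - blast_fraction)
          else rest
  comp <- setNames(rep(0, length(types)), types)
  comp[blast_type] <- blast_fraction
  comp[names(rest)] <- rest

  model <- truth$model
  local_seed(seed, {
    blast_mean <- (1 - shift) * model$type_props[blast_type, ] +
      shift * model$type_props[config$tree$root, ]
    blast_mean <- blast_mean *
      stats::rlnorm(length(blast_mean), 0, blast_noise_sigma)
    model$type_props[blast_type, ] <- blast_mean / sum(blast_mean)
    cell_types <- sample(types, n_cells, replace = TRUE, prob = comp)
    donors <- rep(1L, n_cells)               # one patient
    counts <- simulate_cells(config, model, cell_types, donors, "leuk_")
    out_truth <- structure(list(
      cell_types = setNames(cell_types, cell_ids(counts)),
      donors = setNames(rep("patient", n_cells), cell_ids(counts)),
      type_means = model$type_props,
      markers = model$markers,
      composition = comp,
      blast_type = blast_type, blast_fraction = blast_fraction,
      shift = shift, model = model, config = config),
      class = "SyntheticTruth")
    list(counts = counts, truth = out_truth)
  })
}

#' Simulate a pseudobulk cohort with known mixing proportions
#'
#' Each sample profile is the proportion-weighted mixture of the per-type
#' mean profiles, scaled to a TPM-like depth of 1e6, with per-gene lognormal
#' multiplicative noise. Proportions are Dirichlet-distributed.
#'
#' @param truth `SyntheticTruth` from [simulate_reference_cohort()].
#' @param n_samples Number of bulk samples (default 20).
#' @param dirichlet_alpha Dirichlet concentration (default 2).
#' @param noise_sigma Lognormal noise sigma (default 0.1).
#' @param seed RNG seed.
#' @param fractions Optional samples x types matrix of mixing proportions
#'   (rows summing to 1); overrides the Dirichlet draw.
#' @return A list with `bulk` (genes x samples matrix) and `fractions`
#'   (samples x types matrix of true proportions).
#' @export
simulate_bulk_cohort <- function(truth, n_samples = 20L, dirichlet_alpha = 2,
                                 noise_sigma = 0.1, seed = 1L,
                                 fractions = NULL) {
  stopifnot(inherits(truth, "SyntheticTruth"))
  props <- truth$type_means
  types <- rownames(props)
  if (!is.null(fractions)) {
    stopifnot(all(colnames(fractions) %in% types),
              all(abs(rowSums(fractions) - 1) < 1e-9))
    n_samples <- nrow(fractions)
  }
  local_seed(seed, {
    fr <- if (!is.null(fractions)) {
      full <- matrix(0, n_samples, length(types),
                     dimnames = list(rownames(fractions) %||%
                                       sprintf("sample_%02d", seq_len(n_samples)),
                                     types))
      full[, colnames(fractions)] <- fractions
      full
    } else {
      g <- matrix(stats::rgamma(n_samples * length(types),
                                shape = dirichlet_alpha),
                  n_samples, length(types),
                  dimnames = list(sprintf("sample_%02d", seq_len(n_samples)),
                                  types))
      g / rowSums(g)
    }
    prof <- t(props) %*% t(fr) * 1e6                  # genes x samples
    if (noise_sigma > 0)
      prof <- prof * matrix(stats::rlnorm(length(prof), 0, noise_sigma),
                            nrow(prof), ncol(prof))
    dimnames(prof) <- list(colnames(props), rownames(fr))
    list(bulk = prof, fractions = fr)
  })
}

#' Gaussian blob embedding
#'
#' Directly simulates an embedding of isotropic Gaussian blobs in `d`
#' dimensions (no counts involved); used to exercise the clustering and
#' subclustering steps in isolation.
#'
#' @param n_per_center Cells per blob (scalar or vector).
#' @param centers Matrix of blob centers (blobs x d), or a scalar number of
#'   blobs placed at separation `sep` along the axes.
#' @param d Dimensionality (default 30).
#' @param sd Isotropic standard deviation (default 1).
#' @param sep Separation between auto-placed centers (default 20).
#' @param seed RNG seed.
#' @return A list with `embedding` (usable wherever an `Embedding` is
#'   expected) and `labels` (true blob of each cell).
#' @export
simulate_blob_embedding <- function(n_per_center, centers = 1L, d = 30L,
                                    sd = 1, sep = 20, seed = 1L) {
  if (is.matrix(centers)) {
    ctr <- centers
  } else {
    ctr <- matrix(0, centers, d)
    if (centers > 1)
      for (b in 2:centers) ctr[b, ((b - 2) %% d) + 1] <- sep * (1 + (b - 2) %/% d)
  }
  nb <- nrow(ctr)
  n <- rep_len(n_per_center, nb)
  local_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(nb), function(b) {
      matrix(stats::rnorm(n[b] * ncol(ctr), 0, sd), n[b], ncol(ctr)) +
        matrix(ctr[b, ], n[b], ncol(ctr), byrow = TRUE)
    }))
    ids <- sprintf("cell_%05d", seq_len(nrow(coords)))
    rownames(coords) <- ids
    colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
    labels <- rep(paste0("blob", seq_len(nb)), times = n)
    list(embedding = structure(list(coords = coords, d = ncol(coords),
                                    explained_variance = NULL),
                               class = "Embedding"),
         labels = setNames(labels, ids))
  })
}
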
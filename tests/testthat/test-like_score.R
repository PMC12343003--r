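# Hand-built reference for exact LIKE checks: root, one myeloid type, one
# T/NK type, on nearly orthogonal profiles.
toy_atlas <- function() {
  genes <- paste0("g", 1:6)
  B <- rbind(`HSC/MPP|s1` = c(1, 1, 0, 0, 0, 0),
             `GMP|s1` = c(0, 1, 1, 0.2, 0, 0),
             `T/NK|s1` = c(0, 0, 0, 0, 1, 1),
             `T/NK|s2` = c(0, 0, 0, 0.3, 1, 0.5))
  colnames(B) <- genes
  tree <- hierarchy_tree(
    data.frame(name = c("HSC/MPP", "GMP", "T/NK"), population = "P",
               lineage_class = c("HSPC", "myeloid", "TNK")),
    data.frame(parent = c("HSC/MPP", "HSC/MPP"), child = c("GMP", "T/NK"),
               kind = c("solid", "dashed")))
  structure(list(B = B, C = B[1, , drop = FALSE],
                 subcluster_map = setNames(c("HSC/MPP", "GMP", "T/NK", "T/NK"),
                                           rownames(B)),
                 normal_composition = c(`HSC/MPP` = 0.25, GMP = 0.25,
                                        `T/NK` = 0.5),
                 hvg = genes, tree = tree,
                 subcluster_sizes = setNames(rep(10, 4), rownames(B)),
                 version = "hematree-atlas-1"),
            class = "ReferenceAtlas")
}

test_that("cosine similarity and distance match closed forms", {
  set.seed(31)
  for (rep in 1:5) {
    x <- runif(10)
    expect_equal(cosine_similarity(x, x), 1, tolerance = 1e-12)
    expect_equal(cosine_distance(x, x), 0, tolerance = 1e-12)
  }
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_similarity(c(1, 1, 0), c(1, 0, 0)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosine_distance(c(1, 1, 0), c(1, 0, 0)), 1 - 1 / sqrt(2),
               tolerance = 1e-12)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero profile")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("hsc_sin_theta obeys the Pythagorean relation in both modes", {
  C <- matrix(c(1, 0), 1, 2, dimnames = list("r", c("g1", "g2")))
  # query identical to the root mean
  th <- hsc_sin_theta(c(1, 0), C)
  expect_equal(th$cos_theta, 1, tolerance = 1e-12)
  expect_equal(th$sin_theta, 0, tolerance = 1e-12)
  # cos 0.8 -> sin 0.6
  th2 <- hsc_sin_theta(c(0.8, 0.6), C)
  expect_equal(th2$cos_theta, 0.8, tolerance = 1e-12)
  expect_equal(th2$sin_theta, 0.6, tolerance = 1e-12)
  # orthogonal query
  th3 <- hsc_sin_theta(c(0, 1), C)
  expect_equal(th3$sin_theta, 1, tolerance = 1e-12)
  # axis_offset: query on the root->b axis has angle 0
  th4 <- hsc_sin_theta(c(3, 2), C, mode = "axis_offset", b = c(2, 1))
  expect_equal(th4$sin_theta, 0, tolerance = 1e-6)
  expect_warning(th5 <- hsc_sin_theta(c(1, 0), C, mode = "axis_offset",
                                      b = c(0, 1)), "sin\\(theta\\)")
  expect_equal(th5$sin_theta, 0)
})

test_that("LIKE scores honor the T/NK bypass, ranges, and argmax invariance", {
  atlas <- toy_atlas()
  q <- query_profiles(rbind(qT = atlas$B["T/NK|s1", ],
                            qG = atlas$B["GMP|s1", ],
                            qH = atlas$B["HSC/MPP|s1", ]),
                      c(qT = 10, qG = 30, qH = 5))
  res <- like_score_matrix(q, atlas)

  # T/NK bypass exact: query equal to a TNK row scores like = sim = 1 there
  expect_equal(res$like["qT", "T/NK|s1"], 1, tolerance = 1e-12)
  expect_equal(res$table$assigned_type[res$table$subcluster == "qT"],
               "T/NK-like")
  # myeloid self-query: like = sim * sin(theta) at the matched row
  thG <- hsc_sin_theta(atlas$B["GMP|s1", ], atlas$C)
  expect_equal(res$like["qG", "GMP|s1"], thG$sin_theta, tolerance = 1e-12)
  expect_equal(res$table$assigned_type[res$table$subcluster == "qG"],
               "GMP-like")
  # root self-query assigns to the root type
  expect_equal(res$table$assigned_type[res$table$subcluster == "qH"],
               "HSC/MPP-like")
  # sin = sqrt(1 - cos^2) and best_score = max(like)
  expect_equal(res$table$sin_theta,
               sqrt(1 - res$table$cos_theta^2), tolerance = 1e-12)
  expect_equal(res$table$best_score, unname(apply(res$like, 1, max)),
               tolerance = 1e-12)

  # structural ranges and argmax invariance on random non-negative queries
  set.seed(32)
  for (rep in 1:20) {
    a <- runif(6)
    qq <- query_profiles(matrix(a, 1, 6, dimnames = list("q", atlas$hvg)), 1)
    r <- like_score_matrix(qq, atlas)
    expect_true(all(r$sim >= 0 & r$sim <= 1 + 1e-12))
    expect_true(all(r$like >= 0 & r$like <= 1 + 1e-12))
    non_tnk <- c("HSC/MPP|s1", "GMP|s1")
    expect_equal(names(which.max(r$like[1, non_tnk])),
                 names(which.max(r$sim[1, non_tnk])))
    # assignment equals the raw-similarity argmax
    expect_equal(r$table$best_subcluster,
                 colnames(r$sim)[which.max(r$sim[1, ])])
  }

  # gene-space contracts
  qq <- query_profiles(matrix(1, 1, 2, dimnames = list("q", c("g1", "g2"))), 1)
  expect_error(like_score_matrix(qq, atlas), "50%")
  qz <- query_profiles(matrix(1, 1, 6, dimnames = list("q", paste0("x", 1:6))), 1)
  expect_error(like_score_matrix(qz, atlas), "shared|50%")
  # declared T-lineage queries are refused
  qok <- query_profiles(atlas$B, rep(1, 4))
  expect_error(like_score_matrix(qok, atlas, declared_lineage = "T"),
               "extramedullary")
})

test_that("self-projection of a well-separated synthetic atlas is near-perfect", {
  atlas <- fx_atlas()$atlas
  q <- query_profiles(atlas$B, setNames(rep(10, nrow(atlas$B)),
                                        rownames(atlas$B)))
  res <- like_score_matrix(q, atlas)
  acc <- mean(res$table$ref_type ==
                unname(atlas$subcluster_map[res$table$subcluster]))
  expect_gte(acc, 0.95)
})

test_that("blast-shifted queries score lower than unshifted ones", {
  co <- fx_cohort()
  atlas <- fx_atlas()$atlas
  scores <- sapply(c(0, 0.5), function(sh) {
    lk <- simulate_leukemia_sample(co$truth, "GMP", 0.7, shift = sh,
                                   n_cells = 800, seed = 77)
    ann <- run_annotate(lk$counts, atlas, n_hvg = 600, verbose = FALSE)
    mean(ann$like$table$best_score)
  })
  expect_lt(scores[2], scores[1])
})

test_that("estimate_composition aggregates member counts by assigned type", {
  atlas <- toy_atlas()
  q <- query_profiles(rbind(q1 = atlas$B["GMP|s1", ],
                            q2 = atlas$B["T/NK|s1", ]),
                      c(q1 = 60, q2 = 40))
  res <- like_score_matrix(q, atlas)
  comp <- estimate_composition(res)
  expect_equal(comp$fractions[c("GMP", "T/NK")],
               c(GMP = 0.6, `T/NK` = 0.4))
  expect_equal(comp$total_cells, 100L)
  expect_equal(sum(comp$fractions), 1)

  # all subclusters assigned one type
  q1 <- query_profiles(rbind(a = atlas$B["GMP|s1", ],
                             b = atlas$B["GMP|s1", ] * 2), c(a = 5, b = 15))
  comp1 <- estimate_composition(like_score_matrix(q1, atlas))
  expect_equal(comp1$fractions, c(GMP = 1))
})
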
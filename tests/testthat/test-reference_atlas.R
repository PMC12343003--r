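test_that("hierarchy_tree validation rejects malformed trees", {
  nodes <- data.frame(name = c("R", "A", "B"),
                      population = "P", lineage_class = "HSPC")
  ok <- hierarchy_tree(nodes, data.frame(parent = c("R", "R"),
                                         child = c("A", "B"),
                                         kind = "solid"))
  expect_s3_class(ok, "HierarchyTree")
  expect_equal(ok$root, "R")

  # cycle (A -> B -> A) leaves nodes unreachable / multi-parented
  expect_error(hierarchy_tree(nodes,
                              data.frame(parent = c("A", "B"),
                                         child = c("B", "A"),
                                         kind = "solid")),
               "root|unreachable|multiple")
  # two roots
  expect_error(hierarchy_tree(nodes,
                              data.frame(parent = "R", child = "A",
                                         kind = "solid")),
               "exactly one root")
  # dashed edge into a non-recruited lineage
  nodes2 <- data.frame(name = c("R", "M"), population = "P",
                       lineage_class = c("HSPC", "myeloid"))
  expect_error(hierarchy_tree(nodes2,
                              data.frame(parent = "R", child = "M",
                                         kind = "dashed")),
               "dashed")
  # dashed into TNK is allowed
  nodes3 <- data.frame(name = c("R", "T/NK"), population = "P",
                       lineage_class = c("HSPC", "TNK"))
  expect_s3_class(hierarchy_tree(nodes3,
                                 data.frame(parent = "R", child = "T/NK",
                                            kind = "dashed")),
                  "HierarchyTree")
})

test_that("shipped trees are valid and round-trip through the config format", {
  mini <- miniature_tree()
  expect_equal(nrow(mini$nodes), 11L)
  expect_equal(mini$root, "HSC/MPP")
  full <- bmmc_tree()
  expect_equal(nrow(full$nodes), 38L)
  expect_equal(nrow(full$edges), 37L)
  expect_equal(full$root, "HSC/MPP")
  # dashed edges only into TNK / memory-B
  cls <- setNames(full$nodes$lineage_class, full$nodes$name)
  dashed <- full$edges$child[full$edges$kind == "dashed"]
  expect_true(all(cls[dashed] == "TNK" | grepl("Memory B", dashed)))

  tf <- tempfile(fileext = ".tsv")
  write_tree_config(full, tf)
  back <- read_tree_config(tf)
  expect_equal(back$nodes, full$nodes)
  expect_equal(back$edges, full$edges)
})

test_that("centroid_profiles equals a loop-based mean oracle", {
  set.seed(21)
  v <- matrix(runif(60), 10, 6,
              dimnames = list(sprintf("c%02d", 1:10), sprintf("g%02d", 1:6)))
  nm <- make_norm(v)
  labs <- cluster_labels(rownames(v),
                         c("s1", rep(c("s2", "s3"), c(4, 5))), 4L)
  cent <- centroid_profiles(nm, labs)
  expect_equal(rownames(cent), c("s1", "s2", "s3"))
  # single-cell subcluster equals the cell profile
  expect_equal(cent["s1", ], v[1, ], tolerance = 1e-12)
  # loop oracle
  for (s in c("s2", "s3")) {
    members <- labs$cell_ids[labs$labels == s]
    oracle <- colMeans(v[members, , drop = FALSE])
    expect_equal(cent[s, ], oracle, tolerance = 1e-12)
  }
  # two cells with values 0 and 2 -> centroid 1
  v2 <- matrix(c(0, 2), 2, 1, dimnames = list(c("a", "b"), "g"))
  c2 <- centroid_profiles(make_norm(v2),
                          cluster_labels(c("a", "b"), c("s", "s"), 4L))
  expect_equal(as.numeric(c2), 1)
})

test_that("build_reference assembles composition, C and errors correctly", {
  set.seed(22)
  tree <- hierarchy_tree(
    data.frame(name = c("HSC/MPP", "A", "B"), population = "P",
               lineage_class = "HSPC"),
    data.frame(parent = c("HSC/MPP", "HSC/MPP"), child = c("A", "B"),
               kind = "solid"))
  n <- c(`HSC/MPP` = 50, A = 30, B = 20)
  cells <- sprintf("c%03d", 1:100)
  v <- matrix(runif(100 * 12), 100, 12,
              dimnames = list(cells, sprintf("g%02d", 1:12)))
  nm <- make_norm(v)
  labs <- cluster_labels(cells, rep(c("root|s1", "A|s1", "B|s1"), n), 4L)
  ann <- data.frame(subcluster = c("root|s1", "A|s1", "B|s1"),
                    cell_type = c("HSC/MPP", "A", "B"))
  hvg <- sprintf("g%02d", 1:8)
  atlas <- build_reference(nm, labs, ann, tree, hvg)
  expect_equal(atlas$normal_composition[c("HSC/MPP", "A", "B")],
               c(`HSC/MPP` = 0.5, A = 0.3, B = 0.2), tolerance = 1e-12)
  expect_equal(colnames(atlas$B), hvg)
  expect_equal(rownames(atlas$C), "root|s1")

  # annotations naming unknown nodes are refused, listing offenders
  bad <- ann; bad$cell_type[2] <- "nonsense"
  expect_error(build_reference(nm, labs, bad, tree, hvg), "nonsense")
  # atlas without a root-type subcluster is refused
  no_root <- ann; no_root$cell_type[1] <- "A"
  expect_error(build_reference(nm, labs, no_root, tree, hvg), "root")

  # permutation invariance to input cell order
  perm <- sample(100)
  labs_p <- cluster_labels(cells[perm], labs$labels[perm], 4L)
  atlas_p <- build_reference(nm, labs_p, ann, tree, hvg)
  expect_equal(atlas_p$B, atlas$B, tolerance = 1e-12)
  expect_equal(atlas_p$normal_composition, atlas$normal_composition)
})

test_that("atlas subcluster count follows the choose_k rule on a synthetic cohort", {
  co <- fx_cohort()
  br <- fx_atlas()
  n_per_type <- table(co$truth$cell_types)
  expected <- sum(vapply(as.vector(n_per_type), choose_k, integer(1)))
  expect_equal(nrow(br$atlas$B), expected)
})

test_that("robustness_downsample is calibrated and deterministic", {
  br <- fx_atlas()
  tab <- robustness_downsample(br$atlas, br$norm, br$labels4,
                               fractions = c(0.1, 0.9, 1.0), n_rep = 2,
                               seed = 5)
  expect_equal(nrow(tab), 6L)
  # fraction 1.0 reproduces the centroids exactly
  expect_equal(tab$mean_r[tab$fraction == 1], c(1, 1), tolerance = 1e-12)
  # heavier downsampling degrades the correlation
  expect_lt(mean(tab$mean_r[tab$fraction == 0.1]),
            mean(tab$mean_r[tab$fraction == 0.9]))
  tab2 <- robustness_downsample(br$atlas, br$norm, br$labels4,
                                fractions = c(0.1, 0.9, 1.0), n_rep = 2,
                                seed = 5)
  expect_identical(tab, tab2)
  expect_error(robustness_downsample(br$atlas, br$norm, br$labels4,
                                     fractions = c(0, 0.5)), "\\(0, 1\\]")
})

test_that("atlas bundles round-trip through disk and reject tampering", {
  atlas <- fx_atlas()$atlas
  d <- tempfile()
  save_atlas(atlas, d)
  back <- load_atlas(d)
  expect_equal(back$subcluster_map, atlas$subcluster_map)
  expect_equal(back$normal_composition, atlas$normal_composition,
               tolerance = 1e-12)
  expect_equal(back$hvg, atlas$hvg)
  expect_equal(back$tree$nodes, atlas$tree$nodes)
  expect_equal(back$tree$edges, atlas$tree$edges)
  expect_equal(back$B, atlas$B, tolerance = 1e-12)
  expect_equal(back$C, atlas$C, tolerance = 1e-12)

  file.remove(file.path(d, "C.tsv"))
  expect_error(load_atlas(d), "missing HSC/MPP matrix")
  writeLines("other-version", file.path(d, "version.txt"))
  expect_error(load_atlas(d), "hematree-atlas-1")
})
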
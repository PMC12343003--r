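tree_preorder <- hematree:::tree_preorder

test_that("relative_ratio matches a per-type division oracle", {
  # identical profiles -> ratios 1 (epsilon-induced deviation < 1e-3)
  p <- c(A = 0.5, B = 0.3, C = 0.2)
  r <- relative_ratio(p, p)
  expect_true(all(abs(r$ratio - 1) < 1e-3))
  # q(GMP) = 0.4 vs p(GMP) = 0.1 -> ratio ~ 4
  q2 <- c(GMP = 0.4, Other = 0.6); p2 <- c(GMP = 0.1, Other = 0.9)
  expect_equal(unname(relative_ratio(q2, p2)$ratio["GMP"]), 4,
               tolerance = 5e-3)
  # hand-built 5-type toy vs long-division oracle; missing types count as 0
  set.seed(41)
  q5 <- c(a = 0.3, b = 0.25, c = 0.2, d = 0.25)
  p5 <- c(a = 0.1, b = 0.4, c = 0.2, e = 0.3)
  eps <- 1e-4
  r5 <- relative_ratio(q5, p5, epsilon = eps)
  for (t in union(names(q5), names(p5))) {
    qv <- if (t %in% names(q5)) q5[[t]] else 0
    pv <- if (t %in% names(p5)) p5[[t]] else 0
    expect_equal(unname(r5$ratio[t]), (qv + eps) / (pv + eps),
                 tolerance = 1e-12)
  }
  expect_equal(r5$epsilon, eps)
})

test_that("flag_aberrations thresholds and locates initiating sites on solid paths", {
  tree <- miniature_tree()
  base <- setNames(rep(1, nrow(tree$nodes)), tree$nodes$name)

  # ratio 1.3 at GMP only -> GMP flagged, sole initiating site
  r <- base; r["GMP"] <- 1.3
  ab <- flag_aberrations(structure(list(ratio = r, epsilon = 0),
                                   class = "AberrationProfile"), tree)
  expect_equal(unname(ab$flags["GMP"]), "proliferation")
  expect_equal(sum(ab$flags == "proliferation"), 1L)
  expect_equal(ab$initiating_sites, "GMP")
  # boundary: exactly 1.25 is not aberrant
  r2 <- base; r2["GMP"] <- 1.25
  ab2 <- flag_aberrations(structure(list(ratio = r2, epsilon = 0),
                                    class = "AberrationProfile"), tree)
  expect_equal(unname(ab2$flags["GMP"]), "normal")

  # all ratios 1 -> no flags
  ab3 <- flag_aberrations(structure(list(ratio = base, epsilon = 0),
                                    class = "AberrationProfile"), tree)
  expect_true(all(ab3$flags == "normal"))
  expect_length(ab3$initiating_sites, 0)

  # myeloid path {HSC/MPP: 2, CMP: 3, GMP: 5} -> root-proximal rule
  r4 <- base; r4[c("HSC/MPP", "CMP", "GMP")] <- c(2, 3, 5)
  ab4 <- flag_aberrations(structure(list(ratio = r4, epsilon = 0),
                                    class = "AberrationProfile"), tree)
  expect_equal(ab4$initiating_sites, "HSC/MPP")

  # suppression below 1/threshold
  r5 <- base; r5["Ery"] <- 0.5
  ab5 <- flag_aberrations(structure(list(ratio = r5, epsilon = 0),
                                    class = "AberrationProfile"), tree)
  expect_equal(unname(ab5$flags["Ery"]), "suppression")

  # dashed edges never propagate initiation: CLP and T/NK both flagged,
  # T/NK stays an initiating site because its incoming edge is dashed
  r6 <- base; r6[c("CLP", "T/NK")] <- 2
  ab6 <- flag_aberrations(structure(list(ratio = r6, epsilon = 0),
                                    class = "AberrationProfile"), tree)
  expect_setequal(ab6$initiating_sites, c("CLP", "T/NK"))

  # missing ratios default to 1.0 with a message
  expect_message(
    ab7 <- flag_aberrations(relative_ratio(c(GMP = 1), c(GMP = 1)), tree),
    "defaulted")
  expect_true(all(ab7$flags[setdiff(tree$nodes$name, "GMP")] == "normal"))
})

test_that("swapping query and normal maps proliferation to suppression exactly", {
  tree <- miniature_tree()
  set.seed(42)
  types <- tree$nodes$name
  q <- stats::runif(length(types), 0.02, 0.2); q <- setNames(q / sum(q), types)
  p <- stats::runif(length(types), 0.02, 0.2); p <- setNames(p / sum(p), types)
  fwd <- flag_aberrations(relative_ratio(q, p, epsilon = 0), tree)
  rev <- flag_aberrations(relative_ratio(p, q, epsilon = 0), tree)
  expect_equal(unname(fwd$ratio[types]), unname(1 / rev$ratio[types]),
               tolerance = 1e-12)
  map <- c(proliferation = "suppression", suppression = "proliferation",
           normal = "normal")
  expect_equal(unname(map[fwd$flags[types]]), unname(rev$flags[types]))
})

test_that("tree_layout is deterministic with clamped log-scaled radii", {
  tree <- miniature_tree()
  base <- setNames(rep(1, nrow(tree$nodes)), tree$nodes$name)
  ab <- structure(list(ratio = base, epsilon = 0), class = "AberrationProfile")
  lay <- tree_layout(ab, tree)
  # ratio 1 everywhere -> unit radii
  expect_true(all(lay$nodes$node_radius == 1))
  # root at the origin, children at depth-proportional radius
  expect_equal(lay$nodes$x[lay$nodes$node == "HSC/MPP"], 0)
  expect_true(all(is.finite(lay$nodes$x) & is.finite(lay$nodes$y)))

  # clamping at both ends
  r <- base; r["GMP"] <- 100; r["Ery"] <- 1e-4
  ab2 <- structure(list(ratio = r, epsilon = 0), class = "AberrationProfile")
  lay2 <- tree_layout(ab2, tree)
  expect_equal(lay2$nodes$node_radius[lay2$nodes$node == "GMP"], 4)
  expect_equal(lay2$nodes$node_radius[lay2$nodes$node == "Ery"], 0.25)

  # deterministic across reruns
  expect_identical(tree_layout(ab2, tree), lay2)

  # edge widths reflect the subtree composition
  comp <- setNames(rep(0, length(base)), names(base))
  comp["GMP"] <- 0.2; comp["CD14 Mono"] <- 0.3; comp["HSC/MPP"] <- 0.5
  lay3 <- tree_layout(ab, tree, composition = comp)
  ed <- lay3$edges
  expect_equal(ed$width[ed$child == "GMP"], 0.5)       # GMP + CD14 Mono
  expect_equal(ed$width[ed$child == "CD14 Mono"], 0.3)
  expect_equal(ed$width[ed$child == "Ery"], 0)
})

test_that("radar_table composes relative_ratio over tree-ordered rows", {
  tree <- miniature_tree()
  p <- setNames(rep(1 / 11, 11), tree$nodes$name)
  # identical profile -> all-1 column (up to epsilon)
  tab1 <- radar_table(list(self = p), p, tree = tree)
  expect_true(all(abs(tab1$self - 1) < 1e-3))
  expect_equal(tab1$cell_type, tree_preorder(tree))

  # two disease profiles -> two columns matching relative_ratio per cell
  q1 <- p; q1["GMP"] <- q1["GMP"] * 3; q1 <- q1 / sum(q1)
  q2 <- p; q2["pre-B"] <- q2["pre-B"] * 2; q2 <- q2 / sum(q2)
  tab2 <- radar_table(list(aml = q1, ball = q2), p, tree = tree)
  expect_equal(setdiff(names(tab2), "cell_type"), c("aml", "ball"))
  r1 <- relative_ratio(q1, p)$ratio
  expect_equal(tab2$aml, unname(r1[tab2$cell_type]), tolerance = 1e-12)
})
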
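# Small trainable centroid panel: 3 cell types x 10 subclusters each, one
# perfectly discriminating gene per type plus noise genes.
deconv_panel <- function(seed = 51) {
  set.seed(seed)
  types <- c("alpha", "beta", "gamma")
  n_sub <- 10; n_noise <- 40
  B <- matrix(rnorm(3 * n_sub * (3 + n_noise), sd = 0.3),
              3 * n_sub, 3 + n_noise)
  for (k in 1:3)
    B[((k - 1) * n_sub + 1):(k * n_sub), k] <- 1 + rnorm(n_sub, sd = 0.05)
  dimnames(B) <- list(sprintf("%s|s%02d", rep(types, each = n_sub),
                              rep(1:n_sub, 3)),
                      c(sprintf("disc_%s", types),
                        sprintf("noise%02d", 1:n_noise)))
  list(B = B, map = setNames(rep(types, each = n_sub), rownames(B)))
}

test_that("train_models finds discriminating genes and is deterministic", {
  pan <- deconv_panel()
  ms <- train_models(pan$B, pan$map, seed = 3)
  expect_setequal(names(ms$models), c("alpha", "beta", "gamma"))
  for (t in names(ms$models)) {
    cf <- ms$models[[t]]$coefficients
    expect_gt(length(cf), 0)
    expect_equal(names(which.max(abs(cf))), paste0("disc_", t))
    # lambda_opt minimizes the mean CV error on the grid
    cv <- ms$models[[t]]$cv_table
    expect_equal(ms$models[[t]]$lambda_opt, cv$lambda[which.min(cv$cvm)])
  }
  ms2 <- train_models(pan$B, pan$map, seed = 3)
  expect_equal(ms$models$alpha$lambda_opt, ms2$models$alpha$lambda_opt)
  expect_equal(ms$models$alpha$coefficients, ms2$models$alpha$coefficients)

  # a type with a single member subcluster is skipped with a warning
  map2 <- pan$map
  map2[1] <- "lonely"
  expect_warning(ms3 <- train_models(pan$B, map2, seed = 3), "lonely")
  expect_false("lonely" %in% names(ms3$models))
})

test_that("coefficient sparsity is monotone along the lambda grid", {
  pan <- deconv_panel()
  ms <- train_models(pan$B, pan$map, seed = 1)
  for (t in names(ms$models)) {
    nz <- as.integer(ms$models[[t]]$nzero)   # ordered by decreasing lambda
    # at the grid maximum the model is empty (intercept only)
    expect_equal(nz[1], 0L)
    # support grows as lambda decreases, up to small coordinate-descent
    # fluctuations in the active set
    expect_true(all(diff(nz) >= -3))
    expect_gt(cor(seq_along(nz), nz, method = "spearman"), 0.9)
  }
})

test_that("score_samples separates members on training data and uses frozen standardization", {
  pan <- deconv_panel()
  ms <- train_models(pan$B, pan$map, seed = 3)
  sc <- score_samples(t(pan$B), ms)
  for (t in colnames(sc$raw)) {
    members <- pan$map[rownames(sc$raw)] == t
    expect_gt(mean(sc$raw[members, t]), mean(sc$raw[!members, t]))
  }
  # a sample sitting at the training gene means scores exactly the intercept
  mean_sample <- matrix(ms$gene_mean, ncol = 1,
                        dimnames = list(ms$genes, "m"))
  sc0 <- score_samples(mean_sample, ms)
  for (t in colnames(sc0$raw))
    expect_equal(unname(sc0$raw["m", t]), ms$models[[t]]$intercept,
                 tolerance = 1e-12)
  # missing genes contribute zero, warned when over half are absent
  keep <- rownames(t(pan$B))[1:2]
  w <- capture_warnings(score_samples(t(pan$B)[keep, , drop = FALSE], ms))
  expect_true(any(grepl("model genes", w)))
  expect_error(score_samples(matrix(1, 2, 2,
                                    dimnames = list(c("x1", "x2"), NULL)),
                             ms), "no genes shared")
})

test_that("normalize_scores centers the normal panel and matches a subtract-mean oracle", {
  raw <- matrix(c(1, 2, 6, 0.5, 1.5, 9), 3, 2,
                dimnames = list(c("n1", "n2", "q"), c("tA", "tB")))
  sc <- structure(list(raw = raw), class = "ScoreTable")
  out <- normalize_scores(sc, c("n1", "n2"))
  expect_equal(colMeans(out$normalized[c("n1", "n2"), ]), c(tA = 0, tB = 0),
               tolerance = 1e-12)
  for (t in colnames(raw))
    expect_equal(out$normalized[, t], raw[, t] - mean(raw[c("n1", "n2"), t]),
                 tolerance = 1e-12)
  # z-score is the within-type standardization across all samples
  expect_equal(out$z_score[, "tA"],
               (raw[, "tA"] - mean(raw[, "tA"])) / sd(raw[, "tA"]),
               tolerance = 1e-12)
  expect_error(normalize_scores(sc, c("n1", "ghost")), "ghost")
  expect_error(normalize_scores(sc, "n1"), "at least 2")
})

test_that("call_aberrant applies the min-shifted fold-change rule at 1.25", {
  # normal panel raw {0, 2}: shifted normal = {1, 3}, mean 2;
  # query q maps to fold change (q + 1) / 2
  mk <- function(q) {
    raw <- matrix(c(0, 2, q), 3, 1,
                  dimnames = list(c("n1", "n2", "q"), "t"))
    call_aberrant(normalize_scores(structure(list(raw = raw),
                                             class = "ScoreTable"),
                                   c("n1", "n2")))
  }
  expect_equal(unname(mk(1.48)$calls["q", "t"]), "normal")        # fc 1.24
  expect_equal(unname(mk(1.52)$calls["q", "t"]), "aberrant_high") # fc 1.26
  expect_equal(unname(mk(0.55)$calls["q", "t"]), "aberrant_low")  # fc 0.775
  # query at the normal mean is called normal
  expect_equal(unname(mk(1)$calls["q", "t"]), "normal")
  # a tight normal panel is itself entirely normal
  raw_t <- matrix(c(1.9, 2.1, 2.0), 3, 1,
                  dimnames = list(c("n1", "n2", "q"), "t"))
  res_t <- call_aberrant(normalize_scores(structure(list(raw = raw_t),
                                                    class = "ScoreTable"),
                                          c("n1", "n2")))
  expect_true(all(res_t$calls[, "t"] == "normal"))
  # degenerate normal spread suppresses calls
  raw <- matrix(c(1, 1, 5), 3, 1,
                dimnames = list(c("n1", "n2", "q"), "t"))
  st <- normalize_scores(structure(list(raw = raw), class = "ScoreTable"),
                         c("n1", "n2"))
  expect_warning(deg <- call_aberrant(st), "degenerate")
  expect_true(all(is.na(deg$calls[, "t"])))
})

test_that("normalize_between maps query columns onto the pooled reference distribution", {
  set.seed(52)
  genes <- sprintf("g%03d", 1:150)
  ref <- matrix(rexp(300), 150, 2, dimnames = list(genes, c("r1", "r2")))
  target <- rowMeans(apply(ref, 2, sort))
  # query already equal to the reference distribution is unchanged
  q <- matrix(sample(target), 150, 1, dimnames = list(genes, "q"))
  out <- normalize_between(q, ref)
  expect_equal(out, q, tolerance = 1e-9)
  # hand-computed mapping: value of rank k becomes the k-th pooled quantile
  q2 <- matrix(rnorm(150), 150, 1, dimnames = list(genes, "q"))
  out2 <- normalize_between(q2, ref)
  expect_equal(as.numeric(out2), target[rank(q2[, 1])], tolerance = 1e-12)
  # permuting samples permutes the output identically
  q3 <- cbind(q2, q2[, 1, drop = FALSE] * 2)
  colnames(q3) <- c("a", "b")
  out3 <- normalize_between(q3, ref)
  out3r <- normalize_between(q3[, c("b", "a")], ref)
  expect_equal(out3r[, c("a", "b")], out3, tolerance = 1e-12)
  # too little overlap is refused
  expect_error(normalize_between(q2[1:50, , drop = FALSE], ref), "100")
})
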
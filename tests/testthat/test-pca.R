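test_that("run_pca matches closed forms and PCA identities", {
  # identical rows: all eigenvalues 0, scores at origin (unstandardized;
  # standardization is impossible for constant columns)
  m0 <- matrix(5, nrow = 3, ncol = 4)
  p0 <- run_pca(m0, standardize = FALSE)
  expect_equal(p0$eigenvalues, rep(0, 4))
  expect_equal(max(abs(p0$scores)), 0)
  expect_error(run_pca(m0, standardize = TRUE), "zero variance")

  # 2x2 worked example: rows (0,0),(2,2) -> covariance [[2,2],[2,2]],
  # eigenvalues (4, 0)
  p1 <- run_pca(rbind(c(0, 0), c(2, 2)), standardize = FALSE)
  expect_equal(p1$eigenvalues, c(4, 0))

  # reconstruction: scores %*% t(loadings) recovers the centered matrix
  set.seed(1)
  x <- matrix(rnorm(60), nrow = 6)
  p <- run_pca(x, standardize = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  expect_lt(max(abs(p$scores %*% t(p$loadings) - xc)), 1e-8)

  expect_error(run_pca(x[1, , drop = FALSE]), "at least 2")
})

test_that("eigen route agrees with the SVD route (prcomp)", {
  set.seed(2)
  for (i in 1:10) {
    n <- sample(5:20, 1); pcols <- sample(3:30, 1)
    x <- matrix(rnorm(n * pcols), n, pcols)
    for (std in c(FALSE, TRUE)) {
      p <- run_pca(x, standardize = std)
      pr <- prcomp(x, center = TRUE, scale. = std)
      k <- min(length(p$eigenvalues), length(pr$sdev))
      expect_equal(p$eigenvalues[1:k], pr$sdev[1:k]^2, tolerance = 1e-8)
      for (j in 1:min(3, k)) {   # scores agree up to the sign convention
        s <- sign(sum(p$scores[, j] * pr$x[, j]))
        expect_lt(max(abs(p$scores[, j] - s * pr$x[, j])), 1e-8)
      }
    }
  }
})

test_that("variable contributions are squared loadings in percent", {
  # eigenvector (1/sqrt2, 1/sqrt2) -> contributions (50, 50)
  x <- rbind(c(0, 0), c(2, 2), c(4, 4))
  p <- run_pca(x, standardize = FALSE)
  vc <- variable_contributions(p, 1)
  expect_equal(vc$percent, c(50, 50))
  # contributions sum to 100 per component, ties keep column order
  set.seed(3)
  y <- matrix(rnorm(50), 10, 5)
  py <- run_pca(y)
  expect_equal(unname(colSums(py$contributions)), rep(100, 5), tolerance = 1e-9)
  expect_equal(variable_contributions(py, 2)$percent,
               unname(sort(py$contributions[, 2], decreasing = TRUE)))
  expect_error(variable_contributions(py, 9), "out of range")
  # single retained variable -> contribution 100
  z <- cbind(c(1, 2, 3), c(5, 5, 5))
  pz <- run_pca(z, standardize = TRUE)
  expect_equal(variable_contributions(pz, 1)$percent, 100)
  expect_identical(pz$dropped, "V2")  # unnamed matrix: positional name
})

test_that("loadings are orthonormal with the sign convention", {
  set.seed(4)
  x <- matrix(rnorm(80), 8, 10)
  p <- run_pca(x)
  g <- t(p$loadings) %*% p$loadings
  expect_lt(max(abs(g - diag(ncol(g)))), 1e-9)
  for (k in seq_len(ncol(p$loadings)))
    expect_gt(p$loadings[which.max(abs(p$loadings[, k])), k], 0)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
})

test_that("group_dispersion measures mean pairwise distance in K dims", {
  set.seed(5)
  x <- matrix(rnorm(40), 8, 5)
  p <- run_pca(x)
  strat <- c("a", rep("b", 2), rep("c", 5))
  rep1 <- group_dispersion(p, strat, K = 2)
  tab <- rep1$table
  expect_equal(tab$dispersion[tab$strategy == "a"], 0)  # single tree
  d2 <- sqrt(sum((p$scores[2, 1:2] - p$scores[3, 1:2])^2))
  expect_equal(tab$dispersion[tab$strategy == "b"], d2) # two points: distance
  expect_error(group_dispersion(p, strat, K = 99), "exceeds")

  # permuting rows permutes scores but not eigenvalues or dispersions
  perm <- sample(8)
  p2 <- run_pca(x[perm, ])
  expect_equal(p2$eigenvalues, p$eigenvalues)
  rep2 <- group_dispersion(p2, strat[perm], K = 2)
  expect_equal(rep2$table$dispersion, rep1$table$dispersion, tolerance = 1e-8)

  # duplicating a strategy's points keeps its centroid, never raises dispersion
  p3 <- p
  p3$scores <- rbind(p$scores, p$scores[4:8, ])
  rep3 <- group_dispersion(p3, c(strat, rep("c", 5)), K = 2)
  expect_equal(rep3$centroids["c", ], rep1$centroids["c", ])
  expect_lte(rep3$table$dispersion[rep3$table$strategy == "c"],
             rep1$table$dispersion[rep1$table$strategy == "c"] + 1e-12)
})

test_that("total_tree_length sums branch lengths", {
  expect_equal(total_tree_length(parse_newick("((A:1,B:2):0.5,(C:1,D:1):0.5);")), 6)
  expect_equal(total_tree_length(parse_newick("((A:0,B:0):0,(C:0,D:0):0);")), 0)
  set.seed(6)
  tr <- parse_newick(rand_newick(12, lengths = TRUE))
  expect_equal(total_tree_length(tr), sum(tr$edge.length))
  expect_error(total_tree_length(parse_newick("((A,B),(C,D));")), "missing")
})

test_that("summarize_tree_stats uses linearly interpolated quartiles", {
  df <- data.frame(strategy = "s", len = c(1, 2, 3, 4))
  out <- summarize_tree_stats(df)
  expect_equal(out$q1, 1.75)
  expect_equal(out$q3, 3.25)
  df2 <- data.frame(strategy = rep(c("a", "b"), each = 3),
                    len = c(1, 2, 3, 4, 5, 6), ll = rnorm(6))
  out2 <- summarize_tree_stats(df2)
  expect_equal(nrow(out2), 4L)   # 2 strategies x 2 metrics
  expect_equal(out2$median[out2$strategy == "a" & out2$metric == "len"], 2)
  expect_equal(out2$mean[out2$strategy == "a" & out2$metric == "len"], 2)
})

test_that("strategy clouds separate along planted backbones", {
  # two backbone families one NNI apart; PC1-2 should separate them
  hits <- 0L
  for (s in 1:15) {
    sim <- generate_treeset(default_synth_cfg(
      seed = 1000 + s, n_trees = 6L, kappa = c(100, 100, 100),
      jitter = c(0.05, 0.05, 0.05), nni = c(0L, 1L, 1L)))
    m <- build_support_matrix(sim$treeset)
    p <- run_pca(m, standardize = TRUE)
    fam <- ifelse(sim$treeset$strategies == "manual", "base", "nni")
    if (mean_silhouette(p$scores[, 1:2], fam) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 13L)
})
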
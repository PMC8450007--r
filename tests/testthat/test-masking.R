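test_that("gap_block_mask applies the keep-threshold and block rules", {
  # column with exactly half gaps survives the 0.5 threshold (">=" boundary)
  mat <- matrix("A", 4, 3)
  mat[1:2, 2] <- "-"
  a <- msa_from_matrix(mat)
  expect_equal(gap_block_mask(a, 0.5, 1)$kept_columns, 1:3)

  # hand-enumerated 8-column example: step-1 keep pattern K,K,G,K,K,K,G,K
  # with min_block 3 leaves only the middle run (columns 4..6 here,
  # i.e. {3,4,5} 0-based)
  m8 <- matrix("A", 4, 8)
  m8[1:3, 3] <- "-"
  m8[1:3, 7] <- "-"
  a8 <- msa_from_matrix(m8)
  res <- gap_block_mask(a8, 0.5, 3)
  expect_equal(res$kept_columns, 4:6)
  expect_equal(res$alignment$length, 3L)

  # identity policy
  set.seed(8)
  fx <- generate_alignment_fixture(n_seq = 6, n_sites = 40, gap_prob = 0.3,
                                   seed = 8)
  expect_equal(gap_block_mask(fx$alignment, 0, 1)$kept_columns, 1:40)

  # all-gap columns removed at any positive threshold, warning when empty
  mall <- matrix("-", 3, 4)
  expect_warning(res0 <- gap_block_mask(msa_from_matrix(mall), 0.5, 1),
                 "every column")
  expect_length(res0$kept_columns, 0L)
})

test_that("gap_block_mask is idempotent", {
  set.seed(9)
  for (i in 1:20) {
    fx <- generate_alignment_fixture(n_seq = 8, n_sites = 60,
                                     gap_prob = runif(60, 0, 0.9),
                                     seed = 900 + i)
    r1 <- gap_block_mask(fx$alignment, 0.5, 3)
    if (!length(r1$kept_columns)) next
    r2 <- gap_block_mask(r1$alignment, 0.5, 3)
    expect_equal(r2$kept_columns, seq_along(r1$kept_columns))
  }
})

test_that("score_threshold_series removes columns below each cutoff", {
  mat <- matrix("A", 3, 6)
  a <- msa_from_matrix(mat)
  s <- site_scores(c(0.2, 0.8, 0.9, 0.5, 1.0, 0.7))
  # single threshold 0.7: kept {1,2,4,5} 0-based = columns 2,3,5,6
  out <- score_threshold_series(a, s, thresholds = 0.7)
  expect_equal(out[[1]]$kept_columns, c(2L, 3L, 5L, 6L))
  # threshold 0 is the identity for scores in [0,1]
  out0 <- score_threshold_series(a, s, thresholds = 1e-9)
  expect_equal(out0[[1]]$kept_columns, 1:6)
  # the seven-step confidence-score series is the accepted default policy
  fx <- generate_alignment_fixture(n_seq = 5, n_sites = 120, seed = 10)
  series <- score_threshold_series(fx$alignment, fx$scores)
  expect_length(series, 7L)
  expect_error(score_threshold_series(a, s, thresholds = c(0.9, 0.5)),
               "ascending")
  expect_error(score_threshold_series(a, site_scores(rep(1, 5))), "length")
})

test_that("rate_strip_series removes fastest categories stepwise", {
  counts <- c(10L, 8L, 6L, 4L)
  cats <- rep(1:4, times = counts)
  a <- msa_from_matrix(matrix("A", 2, sum(counts)))
  s <- site_scores(runif(sum(counts)), cats)
  series <- rate_strip_series(a, s)
  expect_length(series, 4L)
  expect_equal(vapply(series, function(x) length(x$kept_columns), integer(1)),
               c(28L, 24L, 18L, 10L))
  # C = 2: identity plus exactly one removal step
  s2 <- site_scores(runif(5), c(1L, 1L, 2L, 1L, 2L))
  a2 <- msa_from_matrix(matrix("A", 2, 5))
  series2 <- rate_strip_series(a2, s2)
  expect_length(series2, 2L)
  # all columns slowest with a declared C = 2: the removal step removes nothing
  s3 <- site_scores(runif(4), rep(1L, 4))
  a3 <- msa_from_matrix(matrix("A", 2, 4))
  series3 <- rate_strip_series(a3, s3, n_categories = 2)
  expect_equal(vapply(series3, function(x) length(x$kept_columns), integer(1)),
               c(4L, 4L))
  expect_error(rate_strip_series(a3, s3), "at least 2")  # C inferred as 1
  expect_error(rate_strip_series(a3, site_scores(runif(4))), "categories")
})

test_that("series are nested with non-increasing lengths; provenance maps kept columns", {
  set.seed(11)
  for (i in 1:25) {
    fx <- generate_alignment_fixture(n_seq = 6, n_sites = 80,
                                     gap_prob = runif(1, 0, .4),
                                     seed = 1100 + i)
    sc <- score_threshold_series(fx$alignment, fx$scores)
    lens <- vapply(sc, function(x) length(x$kept_columns), integer(1))
    expect_true(all(diff(lens) <= 0))
    for (k in seq_len(length(sc) - 1))
      expect_true(all(sc[[k + 1]]$kept_columns %in% sc[[k]]$kept_columns))
    rs <- rate_strip_series(fx$alignment, fx$scores)
    lens2 <- vapply(rs, function(x) length(x$kept_columns), integer(1))
    expect_true(all(diff(lens2) <= 0))
    expect_equal(lens2[1], 80L)   # step 0 is the identity
    for (k in seq_len(length(rs) - 1))
      expect_true(all(rs[[k + 1]]$kept_columns %in% rs[[k]]$kept_columns))
    # provenance bijection: masked column c holds original column kept[c]
    ma <- sc[[1]]
    orig <- splitscape:::msa_matrix(fx$alignment)
    expect_identical(splitscape:::msa_matrix(ma$alignment),
                     orig[, ma$kept_columns, drop = FALSE])
    # ids and row order preserved
    expect_identical(ma$alignment$ids, fx$alignment$ids)
  }
})
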
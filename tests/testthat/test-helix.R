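test_that("parse_dotbracket stack-matches pairs and classifies loops", {
  h <- parse_dotbracket("GGGAAACCC", "(((...)))")
  expect_equal(nrow(h$pairs), 3L)
  expect_identical(h$loops$type, "hairpin")
  expect_equal(h$loops$size5, 3L)

  # one 1-nt 3' bulge: pairs (1,13),(2,12),(3,10),(4,9) 1-based
  h2 <- parse_dotbracket(strrep("N", 13), "((((....)).))")
  expect_equal(unname(h2$pairs[, "p5"]), 1:4)
  expect_equal(unname(h2$pairs[, "p3"]), c(13L, 12L, 10L, 9L))
  expect_identical(sort(h2$loops$type), c("bulge3", "hairpin"))

  expect_error(parse_dotbracket("NNN", "(()"), "unbalanced")
  expect_error(parse_dotbracket("NNN", "())"), "unbalanced")
  expect_error(parse_dotbracket("NN", "..."), "equal length")
  expect_error(parse_dotbracket("NNN", "(x)"), "only")
})

test_that("loop sizes account for every position", {
  set.seed(12)
  gen_db <- function(len) {
    # random nested structure by recursive insertion
    s <- rep(".", len)
    place <- function(lo, hi, depth) {
      if (hi - lo < 4 || depth > 6 || runif(1) < .2) return()
      s[lo] <<- "("; s[hi] <<- ")"
      place(lo + 1 + rpois(1, .6), hi - 1 - rpois(1, .6), depth + 1)
    }
    place(1 + rpois(1, 1), len - rpois(1, 1), 0)
    paste0(s, collapse = "")
  }
  for (i in 1:40) {
    db <- gen_db(sample(10:40, 1))
    h <- parse_dotbracket(strrep("N", nchar(db)), db)
    npaired <- 2L * nrow(h$pairs)
    ndots <- sum(strsplit(db, "")[[1]] == ".")
    expect_equal(npaired + ndots, nchar(db))
  }
})

test_that("bulge_signature classifies helix-17-like states", {
  one <- bulge_signature(parse_dotbracket(strrep("N", 13), "((((....)).))"))
  expect_equal(one$n_bulge3_1nt, 1L)
  expect_identical(one$label, "typical")

  two <- bulge_signature(parse_dotbracket(strrep("N", 14), "((((....)).).)"))
  expect_equal(two$n_bulge3_1nt, 2L)
  expect_identical(two$label, "double-bulge")

  perfect <- bulge_signature(parse_dotbracket(strrep("N", 10), "(((....)))"))
  expect_equal(c(perfect$n_bulge5_1nt, perfect$n_bulge3_1nt,
                 perfect$n_other_loops), c(0L, 0L, 0L))
  expect_identical(perfect$label, "other")

  # 5' bulge and internal loops are "other"
  b5 <- bulge_signature(parse_dotbracket(strrep("N", 13), "((.((....))))"))
  expect_equal(b5$n_bulge5_1nt, 1L)
  expect_identical(b5$label, "other")

  # window restricts counting to one helix of a larger structure
  db <- paste0("((((....)).))", "...", "(((....)))")
  h <- parse_dotbracket(strrep("N", nchar(db)), db)
  expect_identical(bulge_signature(h, window = c(1, 13))$label, "typical")
})

test_that("fitch_transitions matches hand cases and the brute-force oracle", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_transitions(tr, c(A = 0, B = 0, C = 1, D = 1))$count, 1L)
  expect_equal(fitch_transitions(tr, c(A = 1, B = 1, C = 1, D = 1))$count, 0L)
  tr6 <- parse_newick("((A,(B,C)),(D,(E,F)));")
  st6 <- c(A = "0", B = "1", C = "0", D = "1", E = "1", F = "0")
  expect_equal(fitch_transitions(tr6, st6)$count, brute_fitch(tr6, st6))
  expect_error(fitch_transitions(tr, c(A = 0, B = 0, C = 1)), "missing tip")

  # multi-character opaque states (loop-pattern strings)
  stp <- c(A = "bulge-2bp-bulge", B = "bulge-2bp-bulge",
           C = "internal-2bp-bulge", D = "internal-2bp-bulge")
  expect_equal(fitch_transitions(tr, stp)$count, 1L)

  set.seed(13)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    tree <- parse_newick(rand_newick(n))
    states <- stats::setNames(as.character(sample(0:2, n, replace = TRUE)),
                              tree$tip.label)
    got <- fitch_transitions(tree, states)
    expect_equal(got$count, brute_fitch(tree, states))
    # the returned labeling realizes the count
    realized <- sum(got$states[tree$edge[, 1]] != got$states[tree$edge[, 2]])
    expect_equal(realized, got$count)
  }
})

test_that("fitch count is invariant under rerooting", {
  set.seed(14)
  for (i in 1:15) {
    n <- sample(5:8, 1)
    tree <- parse_newick(rand_newick(n))
    states <- stats::setNames(as.character(sample(0:1, n, replace = TRUE)),
                              tree$tip.label)
    base <- fitch_transitions(tree, states)$count
    phy <- as_phylo(tree)
    for (tip in sample(tree$tip.label, 2)) {
      # suppressWarnings: ape::root labels the new root "Root" (non-numeric)
      rerooted <- suppressWarnings(
        parse_newick(ape::write.tree(ape::root(phy, outgroup = tip,
                                               resolve.root = TRUE))))
      expect_equal(fitch_transitions(rerooted, states)$count, base)
    }
  }
})

test_that("read_structure_table produces annotations per record", {
  p <- write_lines_tmp(c("id\tsequence\tstructure",
                         paste("r1", strrep("N", 13), "((((....)).))", sep = "\t"),
                         paste("r2", strrep("N", 10), "(((....)))", sep = "\t")),
                       ".tsv")
  anns <- read_structure_table(p)
  expect_length(anns, 2L)
  expect_identical(bulge_signature(anns$r1)$label, "typical")
})
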
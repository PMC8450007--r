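# Independent oracles. Tree generation and split enumeration go through ape
# (rtree/write.tree/prop.part), a code path fully disjoint from the package's
# own parser and split extraction.

# Random rooted binary tree rendered as Newick by ape.
rand_newick <- function(n, lengths = FALSE) {
  ph <- ape::rtree(n, br = if (lengths) stats::runif else NULL)
  ape::write.tree(ph)
}

# Canonical split keys of an ape phylo, computed with ape::prop.part.
oracle_split_keys <- function(phy, taxa = sort(phy$tip.label)) {
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  n <- length(taxa)
  keys <- vapply(pp, function(clade) {
    mem <- sort(match(labs[clade], taxa))
    if (1L %in% mem) mem <- setdiff(seq_len(n), mem)
    if (length(mem) < 2L || length(mem) > n - 2L) return(NA_character_)
    paste(mem, collapse = ",")
  }, character(1))
  unique(keys[!is.na(keys)])
}

oracle_rf <- function(phy1, phy2) {
  taxa <- sort(phy1$tip.label)
  k1 <- oracle_split_keys(phy1, taxa)
  k2 <- oracle_split_keys(phy2, taxa)
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

# Exhaustive small-parsimony minimum over all internal-state assignments.
brute_fitch <- function(tree, tip_states) {
  n <- length(tree$tip.label)
  states <- sort(unique(unname(tip_states)))
  internal <- seq.int(n + 1L, n + tree$Nnode)
  combos <- expand.grid(rep(list(states), length(internal)),
                        stringsAsFactors = FALSE)
  S <- matrix("", nrow = nrow(combos), ncol = n + tree$Nnode)
  for (i in seq_len(n)) S[, i] <- tip_states[[tree$tip.label[i]]]
  for (j in seq_along(internal)) S[, internal[j]] <- combos[[j]]
  cost <- rep(0L, nrow(combos))
  for (e in seq_len(nrow(tree$edge)))
    cost <- cost + (S[, tree$edge[e, 1L]] != S[, tree$edge[e, 2L]])
  min(cost)
}

# Naive double-loop backbone reduction oracle (independent of reduce_matrix).
naive_reduce_kept <- function(vals, splits, taxa, assignment,
                              min_support, min_presence) {
  kept <- logical(ncol(vals))
  groups <- unique(unname(assignment))
  for (j in seq_len(ncol(vals))) {
    side1 <- taxa[splits[[j]]]
    side0 <- setdiff(taxa, side1)
    ok <- TRUE
    n_in <- 0L; n_out <- 0L
    for (g in groups) {
      gtaxa <- names(assignment)[assignment == g]
      if (all(gtaxa %in% side1)) n_in <- n_in + 1L
      else if (all(gtaxa %in% side0)) n_out <- n_out + 1L
      else { ok <- FALSE; break }
    }
    if (!ok || n_in == 0L || n_out == 0L) next
    cnt <- 0L
    for (i in seq_len(nrow(vals)))
      if (!is.na(vals[i, j]) && vals[i, j] >= min_support) cnt <- cnt + 1L
    kept[j] <- (cnt / nrow(vals)) >= min_presence
  }
  which(kept)
}

# Mean silhouette width of a labelling in a Euclidean point cloud.
mean_silhouette <- function(pts, labels) {
  d <- as.matrix(stats::dist(pts))
  sil <- vapply(seq_len(nrow(pts)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(pts)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}
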
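## Synthetic fixtures
## ------------------
## Strategy-labelled tree clouds around (possibly rearranged) backbone
## topologies with beta-distributed support noise, plus alignments with
## per-column gap probabilities, confidence scores and discretized-gamma
## style rate categories. Everything is reproducible from a single seed;
## per-stage seeds are derived deterministically so that, e.g., adding trees
## never perturbs the alignment fixture stream.

## Random binary tree by sequential random joins over given recursive nodes.
join_random_binary <- function(nodes, to_root = FALSE) {
  while (length(nodes) > if (to_root) 3L else 1L) {
    i <- sample.int(length(nodes), 2L)
    joined <- rnode(children = nodes[i])
    nodes <- c(nodes[-i], list(joined))
  }
  if (to_root) rnode(children = nodes) else nodes[[1L]]
}

#' Generate a random unrooted binary tree
#'
#' @param labels Leaf labels (>= 4).
#' @return A `support_tree` without supports or branch lengths.
#' @export
random_binary_tree <- function(labels) {
  if (length(labels) < 4L) ss_validation_error("need >= 4 leaves")
  tips <- lapply(labels, function(l) rnode(label = l))
  flatten_rnodes(join_random_binary(tips, to_root = TRUE))
}

## One NNI at the internal edge above node v: swap one child of v with one
## sibling of v. Choices are by smallest clade taxon index unless explicit.
st_nni <- function(tree, v, sibling_choice = 1L, child_choice = 1L) {
  n <- st_ntips(tree)
  root <- st_root(tree)
  if (v <= n || v == root) ss_validation_error("NNI requires an internal non-root node")
  parent <- st_parent(tree)
  p <- parent[v]
  children <- st_children(tree)
  taxa <- sort(tree$tip.label)
  idx <- match(tree$tip.label, taxa)
  clades <- st_clades(tree, children)
  minidx <- vapply(clades, function(cl) min(idx[cl]), numeric(1))
  sibs <- setdiff(children[[p]], v)
  sibs <- sibs[order(minidx[sibs])]
  kids <- children[[v]][order(minidx[children[[v]]])]
  s <- sibs[((sibling_choice - 1L) %% length(sibs)) + 1L]
  cc <- kids[((child_choice - 1L) %% length(kids)) + 1L]
  row_s <- which(tree$edge[, 1L] == p & tree$edge[, 2L] == s)
  row_c <- which(tree$edge[, 1L] == v & tree$edge[, 2L] == cc)
  tree$edge[row_s, ] <- c(p, cc)
  tree$edge[row_c, ] <- c(v, s)
  # supports no longer describe the new splits: invalidate
  tree$support[] <- NA_real_
  st_canonicalize(tree)
}

## Internal non-root nodes eligible for NNI, ordered by canonical split
## (size, then membership mask) for deterministic focal-edge selection.
st_internal_edge_nodes <- function(tree, taxa = sort(tree$tip.label)) {
  n <- st_ntips(tree)
  root <- st_root(tree)
  nodes <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  clades <- st_clades(tree)
  idx <- match(tree$tip.label, taxa)
  mem <- lapply(nodes, function(v) split_canonical(idx[clades[[v]]], length(taxa)))
  keep <- !vapply(mem, split_is_trivial, logical(1), n_taxa = length(taxa))
  nodes <- nodes[keep]; mem <- mem[keep]
  masks <- vapply(mem, split_mask, character(1), n_taxa = length(taxa))
  nodes[order(lengths(mem), masks)]
}

#' Simulate beta-noise supports on a tree's internal edges
#'
#' Each internal edge receives `round(100 * B)` with
#' `B ~ Beta(mu * kappa, (1 - mu) * kappa)` (mean mu, concentration kappa),
#' clipped to \[0, 100\]. `mu` may be a single mean or a per-edge vector
#' aligned with the tree's internal non-root nodes.
#'
#' @param tree A `support_tree`.
#' @param mu Mean support in \[0, 1\] (scalar or per-edge).
#' @param kappa Beta concentration (> 0); large kappa degenerates to
#'   `round(100 * mu)`.
#' @param seed Optional seed applied before drawing.
#' @return The tree with percent-scale supports filled in.
#' @export
simulate_supports <- function(tree, mu, kappa, seed = NULL) {
  stopifnot(inherits(tree, "support_tree"))
  if (kappa <= 0) ss_validation_error("kappa must be > 0")
  if (any(mu < 0 | mu > 1)) ss_validation_error("mu must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- st_ntips(tree)
  root <- st_root(tree)
  nodes <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  mu <- rep_len(mu, length(nodes))
  draws <- stats::rbeta(length(nodes), shape1 = mu * kappa,
                        shape2 = (1 - mu) * kappa)
  # rbeta returns NaN for degenerate shape parameters at mu = 0 or 1
  draws[is.nan(draws)] <- mu[is.nan(draws)]
  tree$support[nodes - n] <- pmin(100, pmax(0, round(100 * draws)))
  tree$scale <- "percent"
  tree
}

#' Configuration for a synthetic strategy-labelled tree set
#'
#' @param group_sizes Integer vector of taxa per group (>= 3 groups of >= 2
#'   taxa recommended); taxa are named `g<i>t<j>` and groups `G<i>`.
#' @param strategies Data frame with columns `label`, `n_trees`, `nni`
#'   (backbone variant: NNI moves applied to the focal backbone edge),
#'   `jitter` (per-edge probability of a random NNI per tree), `kappa`
#'   (support concentration), and optionally `mu_stable`, `mu_var`
#'   (mean support of within-group and backbone edges).
#' @param seed Mandatory integer seed.
#' @param mu_stable,mu_var Default edge-class support means (0.95 / 0.75).
#' @param brlen_mean Mean of the exponential branch-length distribution
#'   (default 0.1 substitutions/site).
#' @return A `synth_config` list.
#' @export
synth_config <- function(group_sizes, strategies, seed,
                         mu_stable = 0.95, mu_var = 0.75, brlen_mean = 0.1) {
  if (missing(seed) || is.null(seed)) ss_validation_error("seed is mandatory")
  if (sum(group_sizes) < 6L) ss_validation_error("need at least 6 taxa")
  strategies <- as.data.frame(strategies, stringsAsFactors = FALSE)
  need <- c("label", "n_trees", "nni", "jitter", "kappa")
  if (!all(need %in% names(strategies)))
    ss_validation_error(sprintf("strategies needs columns: %s",
                                paste(need, collapse = ", ")))
  if (is.null(strategies$mu_stable)) strategies$mu_stable <- mu_stable
  if (is.null(strategies$mu_var)) strategies$mu_var <- mu_var
  if (any(strategies$kappa <= 0)) ss_validation_error("kappa must be > 0")
  structure(list(group_sizes = as.integer(group_sizes),
                 strategies = strategies, seed = as.integer(seed),
                 brlen_mean = brlen_mean),
            class = "synth_config")
}

## Base topology: random binary subtree per group joined by a random binary
## backbone, so every group starts monophyletic.
synth_base_tree <- function(group_sizes) {
  gnodes <- lapply(seq_along(group_sizes), function(g) {
    tips <- lapply(seq_len(group_sizes[g]),
                   function(j) rnode(label = sprintf("g%dt%d", g, j)))
    join_random_binary(tips)
  })
  # suppress_root guards the 2-group case (root would have degree 2)
  flatten_rnodes(suppress_root(join_random_binary(gnodes, to_root = TRUE)))
}

synth_scheme <- function(group_sizes) {
  assignment <- unlist(lapply(seq_along(group_sizes), function(g)
    stats::setNames(rep(sprintf("G%d", g), group_sizes[g]),
                    sprintf("g%dt%d", g, seq_len(group_sizes[g])))))
  group_scheme(assignment)
}

## Deterministic focal edge: group-respecting internal edge with the lowest
## canonical split in (size, mask) order.
synth_focal_node <- function(tree, scheme, taxa) {
  nodes <- st_internal_edge_nodes(tree, taxa)
  clades <- st_clades(tree)
  idx <- match(tree$tip.label, taxa)
  for (v in nodes) {
    mem <- split_canonical(idx[clades[[v]]], length(taxa))
    r <- is_group_respecting(mem, scheme, taxa, unassigned = "error")
    if (r$respecting) return(v)
  }
  ss_data_error("no group-respecting internal edge available for the focal NNI")
}

## Per-edge support means: backbone (group-respecting) edges take mu_var,
## within-group edges mu_stable.
synth_edge_mu <- function(tree, scheme, taxa, mu_stable, mu_var) {
  n <- st_ntips(tree)
  root <- st_root(tree)
  nodes <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  clades <- st_clades(tree)
  idx <- match(tree$tip.label, taxa)
  vapply(nodes, function(v) {
    mem <- split_canonical(idx[clades[[v]]], length(taxa))
    if (split_is_trivial(mem, length(taxa))) return(mu_stable)
    r <- is_group_respecting(mem, scheme, taxa, unassigned = "error")
    if (r$respecting) mu_var else mu_stable
  }, numeric(1))
}

#' Generate a strategy-labelled synthetic tree set with known truth
#'
#' A base random binary tree with monophyletic groups is drawn once. Each
#' strategy's backbone applies its configured number of NNI moves to the
#' focal backbone edge (chosen deterministically as the lowest canonical
#' group-respecting split). Each tree of a strategy then receives
#' independent jitter NNIs (per internal edge with the configured
#' probability), exponential branch lengths, and beta-noise supports whose
#' means depend on the edge class (within-group vs backbone).
#'
#' @param cfg A `synth_config`.
#' @return List with `treeset` (a `tree_set`), `scheme` (the
#'   `group_scheme`), and `truth` (base/backbone Newick strings and the
#'   per-strategy generative parameters).
#' @export
generate_treeset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  scheme <- synth_scheme(cfg$group_sizes)
  set.seed(substream_seed(cfg$seed, "base_tree"))
  base <- synth_base_tree(cfg$group_sizes)
  taxa <- sort(base$tip.label)

  backbones <- list()
  trees <- list()
  strategies <- character(0)
  for (si in seq_len(nrow(cfg$strategies))) {
    st_row <- cfg$strategies[si, ]
    backbone <- base
    if (st_row$nni > 0) {
      for (k in seq_len(st_row$nni)) {
        v <- synth_focal_node(backbone, scheme, taxa)
        backbone <- st_nni(backbone, v, sibling_choice = 1L, child_choice = 1L)
      }
    }
    backbones[[st_row$label]] <- backbone
    set.seed(substream_seed(cfg$seed, paste0("strategy_", st_row$label)))
    for (t in seq_len(st_row$n_trees)) {
      tr <- backbone
      n_int <- length(st_internal_edge_nodes(tr, taxa))
      for (e in seq_len(n_int)) {
        if (stats::runif(1) < st_row$jitter) {
          cand <- st_internal_edge_nodes(tr, taxa)
          v <- cand[sample.int(length(cand), 1L)]
          tr <- st_nni(tr, v,
                       sibling_choice = sample.int(2L, 1L),
                       child_choice = sample.int(2L, 1L))
        }
      }
      tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / cfg$brlen_mean)
      mu <- synth_edge_mu(tr, scheme, taxa, st_row$mu_stable, st_row$mu_var)
      tr <- simulate_supports(tr, mu, st_row$kappa)
      id <- sprintf("%s_%03d", st_row$label, t)
      tr$meta <- list(strategy = st_row$label, source = "synthetic")
      trees[[id]] <- tr
      strategies[id] <- st_row$label
    }
  }
  truth <- list(base = write_newick(base, taxa),
                backbones = vapply(backbones, write_newick, character(1),
                                   taxa = taxa),
                strategies = cfg$strategies,
                seed = cfg$seed)
  list(treeset = tree_set(trees, strategies), scheme = scheme, truth = truth)
}

#' Generate a synthetic alignment with site scores and rate categories
#'
#' Residues are uniform over A/C/G/T with independent per-cell gaps at the
#' column's gap probability. Per-column confidence scores are drawn from
#' `score_dist` on \[0, 1\] (default Beta(4, 1), i.e. mostly-confident
#' columns). Rate categories emulate a discretized gamma with
#' `n_categories` equal-probability classes (category 1 = slowest): a gamma
#' rate (shape = rate = `gamma_shape`) is drawn per column and binned at the
#' gamma quantile boundaries.
#'
#' @param n_seq Number of sequences (>= 2).
#' @param n_sites Number of columns.
#' @param gap_prob Per-column gap probability (scalar or length `n_sites`).
#' @param score_dist Function of n returning n scores in \[0, 1\].
#' @param n_categories Number of rate categories (>= 2, default 8).
#' @param gamma_shape Gamma shape for the rate distribution (default 0.5).
#' @param seed Mandatory seed.
#' @return List with `alignment` (an `msa`) and `scores` (a `site_scores`
#'   with categories).
#' @export
generate_alignment_fixture <- function(n_seq = 10L, n_sites = 200L,
                                       gap_prob = 0.05,
                                       score_dist = function(n) stats::rbeta(n, 4, 1),
                                       n_categories = 8L, gamma_shape = 0.5,
                                       seed) {
  if (missing(seed) || is.null(seed)) ss_validation_error("seed is mandatory")
  if (n_seq < 2L) ss_validation_error("need at least 2 sequences")
  if (n_categories < 2L) ss_validation_error("need at least 2 rate categories")
  gap_prob <- rep_len(gap_prob, n_sites)
  set.seed(substream_seed(seed, "alignment"))
  mat <- matrix(sample(c("A", "C", "G", "T"), n_seq * n_sites, replace = TRUE),
                nrow = n_seq)
  gaps <- matrix(stats::runif(n_seq * n_sites), nrow = n_seq) <
    matrix(gap_prob, nrow = n_seq, ncol = n_sites, byrow = TRUE)
  mat[gaps] <- "-"
  a <- msa(sprintf("seq%03d", seq_len(n_seq)),
           apply(mat, 1L, paste0, collapse = ""))
  set.seed(substream_seed(seed, "scores"))
  values <- pmin(1, pmax(0, score_dist(n_sites)))
  set.seed(substream_seed(seed, "rates"))
  rates <- stats::rgamma(n_sites, shape = gamma_shape, rate = gamma_shape)
  breaks <- stats::qgamma(seq(0, 1, length.out = n_categories + 1L),
                          shape = gamma_shape, rate = gamma_shape)
  breaks[1] <- 0; breaks[length(breaks)] <- Inf
  categories <- as.integer(cut(rates, breaks = breaks, include.lowest = TRUE))
  list(alignment = a, scores = site_scores(values, categories))
}
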
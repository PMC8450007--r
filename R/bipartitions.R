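## Bipartitions (splits)
## ---------------------
## A bipartition is the pair of complementary leaf sets induced by removing
## an internal edge of an unrooted tree. Canonical orientation: the side NOT
## containing the first taxon of the (sorted) taxon universe. Splits are kept
## as sorted integer index vectors with a string key for set algebra.

split_canonical <- function(members, n_taxa) {
  members <- sort(unique(as.integer(members)))
  if (1L %in% members) members <- setdiff(seq_len(n_taxa), members)
  members
}

split_key <- function(members) paste(members, collapse = ",")

split_mask <- function(members, n_taxa) {
  m <- rep("0", n_taxa)
  m[members] <- "1"
  paste0(m, collapse = "")
}

split_is_trivial <- function(members, n_taxa) {
  length(members) < 2L || length(members) > n_taxa - 2L
}

#' Extract canonical bipartitions with their supports
#'
#' One entry per internal edge of the unrooted tree. Trivial splits (single
#' leaf or its complement) are excluded. Edges lacking a support value carry
#' `NA` as an absent-support marker.
#'
#' @param tree A `support_tree` over at least 4 taxa.
#' @param taxa Taxon universe (superset of the tree's leaves) fixing the
#'   canonical orientation and indices; defaults to the tree's sorted leaf
#'   labels.
#' @return A data frame with columns `key` (canonical index-set key),
#'   `size` (canonical side size) and `support`; the list of canonical
#'   member-index vectors is in `attr(, "members")` and `taxa` in
#'   `attr(, "taxa")`.
#' @export
extract_bipartitions <- function(tree, taxa = NULL) {
  stopifnot(inherits(tree, "support_tree"))
  if (is.null(taxa)) taxa <- sort(tree$tip.label)
  miss <- setdiff(tree$tip.label, taxa)
  if (length(miss))
    ss_data_error(sprintf("tree taxa not in taxon universe: %s",
                          paste(miss, collapse = ", ")))
  n <- length(taxa)
  ntip <- st_ntips(tree)
  if (ntip < 4L) ss_validation_error("bipartitions require a tree over >= 4 taxa")
  tipidx <- match(tree$tip.label, taxa)
  children <- st_children(tree)
  clades <- st_clades(tree, children)
  root <- st_root(tree)
  keys <- character(0); members <- list(); supports <- numeric(0)
  for (node in seq.int(ntip + 1L, ntip + tree$Nnode)) {
    if (node == root) next
    mem <- split_canonical(tipidx[clades[[node]]], n)
    if (split_is_trivial(mem, n)) next
    keys <- c(keys, split_key(mem))
    members[[length(members) + 1L]] <- mem
    supports <- c(supports, tree$support[node - ntip])
  }
  out <- data.frame(key = keys,
                    size = lengths(members),
                    support = supports,
                    stringsAsFactors = FALSE)
  attr(out, "members") <- members
  attr(out, "taxa") <- taxa
  out
}

#' Robinson-Foulds distance between two support trees
#'
#' Cardinality of the symmetric difference of the two canonical split sets.
#'
#' @param t1,t2 `support_tree` objects over identical leaf sets.
#' @return A non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  l1 <- sort(t1$tip.label); l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) ss_data_error("rf_distance requires identical leaf sets")
  k1 <- extract_bipartitions(t1, l1)$key
  k2 <- extract_bipartitions(t2, l2)$key
  length(setdiff(k1, k2)) + length(setdiff(k2, k1))
}

#' Assemble the trees x bipartitions support matrix
#'
#' Columns are the union of canonical splits over all trees, ordered by
#' split size then lexicographic membership mask (byte-stable). Entry (i, j)
#' is the support of split j in tree i, or `fill` when the split is absent
#' from that tree. A split present in a tree but lacking a support value is
#' recorded as `NA` (the absent-support sentinel, rejected by [run_pca()]).
#'
#' @param treeset A `tree_set`.
#' @param fill Value for splits absent from a tree (default 0, i.e.
#'   "absent" = "no support"); use `NA` for an explicit missing marker.
#' @return A `bipartition_matrix`: numeric matrix (rows = trees) with
#'   attributes `taxa`, `splits` (canonical member-index vectors per column),
#'   `strategies`, `scale` and `fill`. Column names encode each split as its
#'   canonical side's sorted taxon names joined by `|`.
#' @export
build_support_matrix <- function(treeset, fill = 0) {
  stopifnot(inherits(treeset, "tree_set"))
  if (length(treeset$trees) < 2L)
    ss_validation_error("support matrix requires at least 2 trees")
  taxa <- treeset$taxa
  bips <- lapply(treeset$trees, extract_bipartitions, taxa = taxa)
  all_members <- list(); seen <- character(0)
  for (b in bips) {
    mem <- attr(b, "members")
    new <- !(b$key %in% seen)
    all_members <- c(all_members, mem[new])
    seen <- c(seen, b$key[new])
  }
  if (!length(all_members)) ss_data_error("no non-trivial splits in tree set")
  sizes <- lengths(all_members)
  masks <- vapply(all_members, split_mask, character(1), n_taxa = length(taxa))
  ord <- order(sizes, masks)
  all_members <- all_members[ord]
  keys <- seen[ord]
  m <- matrix(fill, nrow = length(bips), ncol = length(keys),
              dimnames = list(names(treeset$trees),
                              vapply(all_members, function(mm)
                                paste(taxa[mm], collapse = "|"), character(1))))
  for (i in seq_along(bips)) {
    j <- match(bips[[i]]$key, keys)
    m[i, j] <- bips[[i]]$support
  }
  structure(m,
            taxa = taxa,
            splits = all_members,
            keys = keys,
            strategies = treeset$strategies,
            scale = treeset$trees[[1L]]$scale,
            fill = fill,
            class = c("bipartition_matrix", "matrix", "array"))
}

## Rebuild a bipartition_matrix around a column subset, keeping attributes.
bsm_subset_cols <- function(m, j) {
  structure(unclass(m)[, j, drop = FALSE],
            taxa = attr(m, "taxa"),
            splits = attr(m, "splits")[j],
            keys = attr(m, "keys")[j],
            strategies = attr(m, "strategies"),
            scale = attr(m, "scale"),
            fill = attr(m, "fill"),
            class = class(m))
}

#' @export
print.bipartition_matrix <- function(x, ...) {
  cat(sprintf("<bipartition_matrix> %d trees x %d splits (scale %s, fill %s)\n",
              nrow(x), ncol(x), attr(x, "scale"),
              fmt_num(attr(x, "fill"))))
  invisible(x)
}

#' Export a bipartition support matrix to CSV
#'
#' Writes rows = trees with `tree` and `strategy` columns; split columns are
#' headed by the canonical side's sorted taxon names joined by `|`. The first
#' line is a `#taxa=` comment carrying the full taxon universe, which the
#' split headers alone cannot recover.
#'
#' @param m A `bipartition_matrix`.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(m, path) {
  stopifnot(inherits(m, "bipartition_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#taxa=", paste(attr(m, "taxa"), collapse = "|"),
                    ";scale=", attr(m, "scale"),
                    ";fill=", fmt_num(attr(m, "fill"))), con)
  df <- data.frame(tree = rownames(m),
                   strategy = unname(attr(m, "strategies")[rownames(m)]),
                   unclass(m), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Import a bipartition support matrix written by [write_matrix_csv()]
#'
#' @param path CSV path.
#' @return A `bipartition_matrix`.
#' @export
read_matrix_csv <- function(path) {
  if (!file.exists(path)) ss_validation_error(sprintf("matrix file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#taxa="))
    ss_data_error("matrix CSV must start with a '#taxa=' header line")
  hdr <- strsplit(sub("^#", "", first), ";")[[1]]
  kv <- strsplit(hdr, "=")
  vals <- stats::setNames(vapply(kv, `[`, character(1), 2L),
                          vapply(kv, `[`, character(1), 1L))
  taxa <- strsplit(vals[["taxa"]], "|", fixed = TRUE)[[1]]
  df <- utils::read.csv(path, skip = 1L, check.names = FALSE,
                        stringsAsFactors = FALSE)
  splitnames <- setdiff(names(df), c("tree", "strategy"))
  members <- lapply(strsplit(splitnames, "|", fixed = TRUE), function(nms) {
    idx <- match(nms, taxa)
    if (anyNA(idx)) ss_data_error("split header names a taxon missing from #taxa=")
    sort(idx)
  })
  m <- as.matrix(df[, splitnames, drop = FALSE])
  rownames(m) <- df$tree
  structure(m,
            taxa = taxa,
            splits = members,
            keys = vapply(members, split_key, character(1)),
            strategies = stats::setNames(df$strategy, df$tree),
            scale = vals[["scale"]],
            fill = as.numeric(vals[["fill"]]),
            class = c("bipartition_matrix", "matrix", "array"))
}

#' Export a bipartition support matrix to JSON
#'
#' @param m A `bipartition_matrix`.
#' @param path Output JSON path.
#' @export
write_matrix_json <- function(m, path) {
  stopifnot(inherits(m, "bipartition_matrix"))
  obj <- list(taxa = attr(m, "taxa"),
              scale = attr(m, "scale"),
              fill = attr(m, "fill"),
              trees = rownames(m),
              strategies = unname(attr(m, "strategies")[rownames(m)]),
              splits = lapply(attr(m, "splits"), function(mm) attr(m, "taxa")[mm]),
              values = unclass(m))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
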
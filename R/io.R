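#' Read a collection of Newick tree files grouped by strategy
#'
#' The manifest associates each tree file with an alignment/masking strategy
#' label. Files may contain several `;`-terminated Newick statements. By
#' default all trees must share an identical leaf set; with
#' `prune_to_common = TRUE` every tree is pruned to the intersection of leaf
#' sets and the dropped taxa are recorded.
#'
#' @param manifest Either a data frame with columns `path` and `strategy`, or
#'   the path of a TSV file with those columns (paths resolved relative to
#'   the manifest's directory).
#' @param scale Declared support scale for the whole collection (`"percent"`
#'   or `"probability"`). Mixing scales across files is not supported;
#'   use `normalize = TRUE` to convert probability supports to percent.
#' @param prune_to_common Prune all trees to the common taxon set instead of
#'   erroring on leaf-set differences.
#' @param normalize Convert probability-scale supports to percent
#'   (multiplied by 100) after reading.
#' @param conflict Passed to [parse_newick()].
#' @return A `tree_set`: list with `taxa` (sorted taxon universe), `trees`
#'   (named list of `support_tree`), `strategies` (named character vector)
#'   and `dropped` (taxa removed in prune mode).
#' @export
read_tree_collection <- function(manifest, scale = c("percent", "probability"),
                                 prune_to_common = FALSE, normalize = FALSE,
                                 conflict = "error") {
  scale <- match.arg(scale)
  if (is.character(manifest) && length(manifest) == 1L) {
    dir <- dirname(manifest)
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
    if (!all(c("path", "strategy") %in% names(manifest)))
      ss_validation_error("manifest must have columns 'path' and 'strategy'")
    manifest$path <- ifelse(grepl("^/", manifest$path), manifest$path,
                            file.path(dir, manifest$path))
  }
  if (!is.data.frame(manifest) || !all(c("path", "strategy") %in% names(manifest)))
    ss_validation_error("manifest must be a data frame with columns 'path' and 'strategy'")
  if (nrow(manifest) == 0L) ss_validation_error("empty manifest")

  trees <- list()
  strategies <- character(0)
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[i]
    if (!file.exists(path)) ss_validation_error(sprintf("tree file not found: %s", path))
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    stmts <- regmatches(txt, gregexpr("[^;]+;", txt))[[1]]
    stmts <- stmts[grepl("[^[:space:]]", gsub(";", "", stmts))]
    if (!length(stmts)) ss_data_error(sprintf("no Newick tree in file: %s", path))
    base <- sub("\\.[^.]*$", "", basename(path))
    for (k in seq_along(stmts)) {
      id <- if (length(stmts) == 1L) base else sprintf("%s.%d", base, k)
      if (id %in% names(trees)) id <- sprintf("%s.%d", id, i)
      tr <- parse_newick(stmts[k], scale = scale, conflict = conflict,
                         meta = list(strategy = manifest$strategy[i],
                                     source = path))
      trees[[id]] <- tr
      strategies[id] <- manifest$strategy[i]
    }
  }

  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  dropped <- character(0)
  if (!prune_to_common) {
    ref <- leafsets[[1L]]
    for (id in names(leafsets)) {
      if (!identical(leafsets[[id]], ref))
        ss_data_error(sprintf(
          "leaf set of '%s' differs from '%s' (use prune_to_common = TRUE to prune)",
          id, names(leafsets)[1L]))
    }
    taxa <- ref
  } else {
    taxa <- Reduce(intersect, leafsets)
    if (length(taxa) < 4L)
      ss_data_error(sprintf("common taxon set has only %d taxa (< 4)", length(taxa)))
    taxa <- sort(taxa)
    dropped <- sort(setdiff(unique(unlist(leafsets)), taxa))
    trees <- lapply(trees, function(t) {
      if (length(t$tip.label) > length(taxa)) st_prune(t, taxa) else t
    })
  }

  if (normalize && scale == "probability") {
    trees <- lapply(trees, function(t) {
      t$support <- t$support * 100
      t$scale <- "percent"
      t
    })
  }
  structure(list(taxa = taxa, trees = trees, strategies = strategies,
                 dropped = dropped),
            class = "tree_set")
}

#' Build a tree set from in-memory trees
#'
#' @param trees Named list of `support_tree` objects with identical leaf sets.
#' @param strategies Character vector of strategy labels, one per tree.
#' @return A `tree_set`.
#' @export
tree_set <- function(trees, strategies) {
  if (!length(trees)) ss_validation_error("empty tree list")
  if (is.null(names(trees))) names(trees) <- sprintf("tree%03d", seq_along(trees))
  if (length(strategies) != length(trees))
    ss_validation_error("one strategy label per tree required")
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  for (i in seq_along(leafsets))
    if (!identical(leafsets[[i]], leafsets[[1L]]))
      ss_data_error(sprintf("leaf set of tree %d differs from tree 1", i))
  structure(list(taxa = leafsets[[1L]], trees = trees,
                 strategies = stats::setNames(as.character(strategies), names(trees)),
                 dropped = character(0)),
            class = "tree_set")
}

#' @export
print.tree_set <- function(x, ...) {
  cat(sprintf("<tree_set> %d trees over %d taxa; strategies: %s\n",
              length(x$trees), length(x$taxa),
              paste(sprintf("%s (%d)", names(table(x$strategies)),
                            as.integer(table(x$strategies))), collapse = ", ")))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Records must all have the same length; `.` gap characters are normalized
#' to `-`; case is preserved. Record ids are the first whitespace-delimited
#' token of each header.
#'
#' @param path FASTA file path.
#' @return An `msa`: list with `ids`, `seqs` (character vector) and `length`.
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) ss_validation_error(sprintf("FASTA not found: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) ss_data_error("empty FASTA file")
  if (length(set) < 2L) ss_data_error("an alignment needs at least 2 records")
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  msa(ids, seqs)
}

#' Construct an alignment object from sequences
#'
#' @param ids Unique record identifiers.
#' @param seqs Character vector of equal-length aligned sequences.
#' @return An `msa` object.
#' @export
msa <- function(ids, seqs) {
  if (anyDuplicated(ids))
    ss_data_error(sprintf("duplicate record ids: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  lens <- unname(nchar(seqs))
  if (length(unique(lens)) > 1L) {
    bad <- ids[lens != lens[1L]][1L]
    ss_data_error(sprintf("record '%s' has length %d, expected %d",
                          bad, lens[ids == bad][1L], lens[1L]))
  }
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  structure(list(ids = as.character(ids), seqs = unname(seqs),
                 length = lens[1L]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", length(x$ids), x$length))
  invisible(x)
}

#' Write an alignment to FASTA
#'
#' @param a An `msa`.
#' @param path Output file path.
#' @export
write_alignment <- function(a, path) {
  stopifnot(inherits(a, "msa"))
  set <- Biostrings::BStringSet(stats::setNames(a$seqs, a$ids))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

## Character matrix view of an alignment (rows = sequences).
msa_matrix <- function(a) {
  do.call(rbind, strsplit(a$seqs, "", fixed = TRUE))
}

## Column subset preserving ids and row order.
msa_select <- function(a, cols) {
  if (!length(cols)) return(msa(a$ids, rep("", length(a$ids))))
  m <- msa_matrix(a)[, cols, drop = FALSE]
  msa(a$ids, apply(m, 1L, paste0, collapse = ""))
}

#' Read a per-column site table (scores and optional rate categories)
#'
#' @param path TSV with columns `site`, `value` and optionally `category`.
#'   Sites must cover `1..n_sites` exactly (or `0..n_sites-1` with
#'   `one_based = FALSE`); categories, when present, must be integers forming
#'   a contiguous range starting at 1 (1 = slowest).
#' @param n_sites Expected number of alignment columns.
#' @param one_based Whether site indices in the file start at 1.
#' @return A `site_scores`: list with `values` and `categories` (or NULL).
#' @export
read_site_table <- function(path, n_sites, one_based = TRUE) {
  if (!file.exists(path)) ss_validation_error(sprintf("site table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("site", "value") %in% names(df)))
    ss_validation_error("site table must have columns 'site' and 'value'")
  site <- as.integer(df$site) + if (one_based) 0L else 1L
  if (anyDuplicated(site))
    ss_data_error(sprintf("duplicate site indices: %s",
                          paste(unique(site[duplicated(site)]), collapse = ", ")))
  if (!setequal(site, seq_len(n_sites))) {
    extra <- setdiff(site, seq_len(n_sites))
    missing <- setdiff(seq_len(n_sites), site)
    ss_data_error(sprintf(
      "site indices must cover 1..%d exactly (missing: %s; out of range: %s)",
      n_sites,
      if (length(missing)) paste(utils::head(missing, 5), collapse = ",") else "none",
      if (length(extra)) paste(utils::head(extra, 5), collapse = ",") else "none"))
  }
  ord <- order(site)
  values <- as.numeric(df$value)[ord]
  categories <- NULL
  if ("category" %in% names(df)) {
    categories <- as.integer(df$category)[ord]
    u <- sort(unique(categories))
    if (!identical(u, seq_len(max(u))))
      ss_data_error(sprintf(
        "categories must form a contiguous integer range starting at 1, got {%s}",
        paste(u, collapse = ",")))
  }
  site_scores(values, categories)
}

#' Construct per-column site scores
#'
#' @param values Numeric per-column vector.
#' @param categories Optional integer per-column rate categories (1 = slowest).
#' @return A `site_scores` object.
#' @export
site_scores <- function(values, categories = NULL) {
  if (!is.null(categories) && length(categories) != length(values))
    ss_validation_error("categories must match values in length")
  structure(list(values = as.numeric(values),
                 categories = if (is.null(categories)) NULL else as.integer(categories)),
            class = "site_scores")
}

#' Write a site table to TSV
#'
#' Inverse of [read_site_table()].
#'
#' @param s A `site_scores`.
#' @param path Output path.
#' @param one_based Write 1-based site indices (default).
#' @export
write_site_table <- function(s, path, one_based = TRUE) {
  stopifnot(inherits(s, "site_scores"))
  df <- data.frame(site = seq_along(s$values) - if (one_based) 0L else 1L,
                   value = s$values)
  if (!is.null(s$categories)) df$category <- s$categories
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-to-group scheme table
#'
#' @param path TSV with columns `taxon` and `group`.
#' @return A `group_scheme`.
#' @export
read_group_scheme <- function(path) {
  if (!file.exists(path)) ss_validation_error(sprintf("group scheme not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "group") %in% names(df)))
    ss_validation_error("group scheme must have columns 'taxon' and 'group'")
  group_scheme(stats::setNames(df$group, df$taxon))
}

#' Construct a taxon-to-group scheme
#'
#' @param assignment Named character vector: names are taxa, values group
#'   labels.
#' @return A `group_scheme`: list with `assignment` and sorted `groups`.
#' @export
group_scheme <- function(assignment) {
  if (is.null(names(assignment)) || anyDuplicated(names(assignment)))
    ss_validation_error("assignment must be a named vector with unique taxon names")
  groups <- sort(unique(unname(assignment)))
  if (length(groups) < 2L)
    ss_validation_error("a group scheme needs at least 2 groups")
  structure(list(assignment = stats::setNames(as.character(assignment),
                                              names(assignment)),
                 groups = groups),
            class = "group_scheme")
}
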
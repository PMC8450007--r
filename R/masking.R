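new_masked_alignment <- function(a, kept, policy) {
  structure(list(alignment = msa_select(a, kept),
                 kept_columns = as.integer(kept),
                 policy = policy),
            class = "masked_alignment")
}

#' @export
print.masked_alignment <- function(x, ...) {
  cat(sprintf("<masked_alignment> %d columns kept (%s)\n",
              length(x$kept_columns), x$policy))
  invisible(x)
}

#' Gap-threshold and minimum-block-size column masking
#'
#' Two-step rule in the style of alignment trimmers: (1) keep column c iff
#' its fraction of non-gap residues is at least `gap_threshold` ("at least"
#' at the boundary, so a column with exactly half gaps survives a 0.5
#' threshold); (2) among the kept columns, drop maximal runs of consecutive
#' kept columns shorter than `min_block`. Blocks are evaluated once, after
#' the gap step, not recursively.
#'
#' @param a An `msa`.
#' @param gap_threshold Minimum non-gap fraction to keep a column
#'   (default 0.5).
#' @param min_block Minimum run length of consecutive kept columns
#'   (default 3).
#' @return A `masked_alignment`: masked `alignment` plus `kept_columns`
#'   (ascending original 1-based indices) and a `policy` description.
#' @export
gap_block_mask <- function(a, gap_threshold = 0.5, min_block = 3L) {
  stopifnot(inherits(a, "msa"))
  if (gap_threshold < 0 || gap_threshold > 1)
    ss_validation_error("gap_threshold must be in [0, 1]")
  if (min_block < 1L) ss_validation_error("min_block must be >= 1")
  mat <- msa_matrix(a)
  nongap <- colMeans(mat != "-")
  keep1 <- nongap >= gap_threshold
  keep <- keep1
  r <- rle(keep1)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  short <- which(r$values & r$lengths < min_block)
  for (i in short) keep[starts[i]:ends[i]] <- FALSE
  kept <- which(keep)
  if (!length(kept))
    warning("gap/block masking removed every column", call. = FALSE)
  new_masked_alignment(a, kept,
                       sprintf("gap_block gt=%s block=%d", fmt_num(gap_threshold),
                               as.integer(min_block)))
}

#' Confidence-score threshold masking series
#'
#' For each threshold t (strictly ascending), removes the columns whose
#' per-column confidence score is below t. The resulting alignments are
#' nested: each kept column set contains the next.
#'
#' @param a An `msa`.
#' @param s A `site_scores` whose length matches the alignment.
#' @param thresholds Strictly ascending numeric cutoffs; the default is the
#'   seven-step series 0.715, 0.794, 0.900, 0.942, 0.970, 0.973, 0.990 used
#'   with GUIDANCE2-style column confidence scores.
#' @return List of `masked_alignment`, one per threshold, in order.
#' @export
score_threshold_series <- function(a, s,
                                   thresholds = c(0.715, 0.794, 0.900, 0.942,
                                                  0.970, 0.973, 0.990)) {
  stopifnot(inherits(a, "msa"), inherits(s, "site_scores"))
  if (length(s$values) != a$length)
    ss_validation_error("site scores length must equal alignment length")
  if (length(thresholds) < 1L || any(diff(thresholds) <= 0))
    ss_validation_error("thresholds must be strictly ascending")
  lapply(thresholds, function(t) {
    new_masked_alignment(a, which(s$values >= t),
                         sprintf("score_threshold t=%s", fmt_num(t)))
  })
}

#' Stepwise removal of fastest-rate site categories
#'
#' With per-column rate categories 1..C (1 = slowest), step k removes all
#' columns whose category is among the k fastest (largest indices). The
#' returned series starts with the identity (step 0) and ends with only the
#' slowest category retained (step C - 1); lengths are non-increasing and
#' the kept column sets nested.
#'
#' @param a An `msa`.
#' @param s A `site_scores` with `categories` present.
#' @param n_categories Declared number of categories C; defaults to the
#'   largest category observed (categories absent from the data simply
#'   produce steps that remove nothing).
#' @return List of `masked_alignment` of length C.
#' @export
rate_strip_series <- function(a, s, n_categories = max(s$categories)) {
  stopifnot(inherits(a, "msa"), inherits(s, "site_scores"))
  if (is.null(s$categories))
    ss_validation_error("rate_strip_series requires per-column rate categories")
  if (length(s$categories) != a$length)
    ss_validation_error("site categories length must equal alignment length")
  C <- as.integer(n_categories)
  if (C < 2L) ss_validation_error("rate stripping requires at least 2 categories")
  if (C < max(s$categories))
    ss_validation_error("n_categories is smaller than the largest observed category")
  lapply(0:(C - 1L), function(k) {
    new_masked_alignment(a, which(s$categories <= C - k),
                         sprintf("rate_strip step=%d keep_cat<=%d", k, C - k))
  })
}

#' Write a masking series to FASTA files plus a column map
#'
#' One FASTA per step (file names embed the policy) and a TSV mapping
#' (step, policy, new_column, original_column).
#'
#' @param series A `masked_alignment` or list of them.
#' @param outdir Output directory (created if absent).
#' @param prefix File-name prefix.
#' @return Invisibly, the vector of FASTA paths written.
#' @export
write_masking_series <- function(series, outdir, prefix = "masked") {
  if (inherits(series, "masked_alignment")) series <- list(series)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  maps <- list()
  for (i in seq_along(series)) {
    ma <- series[[i]]
    tag <- gsub("[^A-Za-z0-9._=-]+", "_", ma$policy)
    p <- file.path(outdir, sprintf("%s_step%02d_%s.fasta", prefix, i - 1L, tag))
    write_alignment(ma$alignment, p)
    paths <- c(paths, p)
    if (length(ma$kept_columns))
      maps[[i]] <- data.frame(step = i - 1L, policy = ma$policy,
                              new_column = seq_along(ma$kept_columns),
                              original_column = ma$kept_columns)
  }
  map <- do.call(rbind, maps)
  utils::write.table(map, file.path(outdir, paste0(prefix, "_columns.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
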
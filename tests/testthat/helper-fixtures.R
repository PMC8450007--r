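# Small in-code fixtures shared across test files.

# Alignment from a character matrix (rows = sequences).
msa_from_matrix <- function(mat, ids = sprintf("s%d", seq_len(nrow(mat)))) {
  msa(ids, apply(mat, 1L, paste0, collapse = ""))
}

# Construct a bipartition_matrix directly from values + canonical member
# index lists (bypasses tree machinery, for reduction/PCA tests).
make_bsm <- function(vals, splits, taxa,
                     strategies = rep("s", nrow(vals)), fill = 0) {
  rownames(vals) <- rownames(vals) %||% sprintf("t%d", seq_len(nrow(vals)))
  colnames(vals) <- vapply(splits, function(mm) paste(taxa[mm], collapse = "|"),
                           character(1))
  structure(vals,
            taxa = taxa,
            splits = splits,
            keys = vapply(splits, function(mm) paste(mm, collapse = ","),
                          character(1)),
            strategies = stats::setNames(strategies, rownames(vals)),
            scale = "percent", fill = fill,
            class = c("bipartition_matrix", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default three-strategy synthetic configuration used in several tests:
# 4 groups x 4 taxa; backbone variants 0/1/2 NNI; jitter and support noise
# increasing from "manual" to "guidance".
default_synth_cfg <- function(seed, n_trees = 12L,
                              kappa = c(200, 50, 10),
                              jitter = c(0, 0.1, 0.3),
                              nni = c(0L, 1L, 2L)) {
  synth_config(
    group_sizes = c(4, 4, 4, 4),
    strategies = data.frame(
      label = c("manual", "structural", "guidance"),
      n_trees = n_trees, nni = nni, jitter = jitter, kappa = kappa),
    seed = seed)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
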
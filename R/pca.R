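#' Principal component analysis of a bipartition support matrix
#'
#' Columns (splits) are mean-centered and, with `standardize = TRUE`
#' (default), scaled to unit variance; zero-variance columns are then
#' dropped and reported. The decomposition is the eigendecomposition of the
#' covariance matrix (denominator n - 1). Component signs are fixed by
#' making the largest-magnitude loading of each component positive, so
#' results are reproducible across platforms.
#'
#' @param m A `bipartition_matrix` (or plain numeric matrix) with at least
#'   2 rows and no missing entries.
#' @param standardize Scale columns to unit variance (default TRUE).
#' @return A `split_pca`: list with `eigenvalues` (descending, >= 0),
#'   `scores` (trees x components), `loadings` (variables x components,
#'   orthonormal), `contributions` (percent, columns sum to 100),
#'   `explained` (variance fractions), `dropped` (zero-variance columns
#'   removed), `center`, `scale_values`, `standardize` and `strategies`
#'   (carried over from the matrix when present).
#' @export
run_pca <- function(m, standardize = TRUE) {
  strategies <- attr(m, "strategies")
  x <- unclass(m)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (nrow(x) < 2L) ss_validation_error("PCA requires at least 2 trees (rows)")
  if (anyNA(x))
    ss_data_error("matrix contains missing support markers; impute or rebuild with a numeric fill")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  sds <- apply(x, 2L, stats::sd)
  dropped <- character(0)
  scale_values <- rep(1, ncol(x))
  if (standardize) {
    zero <- sds == 0
    cn <- colnames(x) %||% paste0("V", seq_len(ncol(x)))
    dropped <- cn[zero]
    if (all(zero)) ss_data_error("all columns have zero variance; nothing to standardize")
    xc <- xc[, !zero, drop = FALSE]
    scale_values <- sds[!zero]
    xc <- sweep(xc, 2L, scale_values, "/")
  }
  S <- stats::cov(xc)
  ee <- eigen(S, symmetric = TRUE)
  ev <- pmax(ee$values, 0)
  loadings <- ee$vectors
  # deterministic sign: largest |loading| per component made positive
  for (k in seq_len(ncol(loadings))) {
    j <- which.max(abs(loadings[, k]))
    if (loadings[j, k] < 0) loadings[, k] <- -loadings[, k]
  }
  scores <- xc %*% loadings
  comp <- paste0("PC", seq_len(ncol(loadings)))
  dimnames(loadings) <- list(colnames(xc), comp)
  dimnames(scores) <- list(rownames(x), comp)
  tot <- sum(ev)
  explained <- if (tot > 0) ev / tot else rep(NA_real_, length(ev))
  contributions <- 100 * loadings^2
  structure(list(eigenvalues = ev, scores = scores, loadings = loadings,
                 contributions = contributions, explained = explained,
                 dropped = dropped, center = center,
                 scale_values = scale_values, standardize = standardize,
                 strategies = strategies),
            class = "split_pca")
}

#' @export
print.split_pca <- function(x, ...) {
  k <- min(5L, length(x$eigenvalues))
  cat(sprintf("<split_pca> %d trees, %d variables\n",
              nrow(x$scores), nrow(x$loadings)))
  cat("  explained variance:",
      paste(sprintf("%s %.1f%%", paste0("PC", seq_len(k)),
                    100 * x$explained[seq_len(k)]), collapse = ", "), "\n")
  if (length(x$dropped))
    cat(sprintf("  dropped %d zero-variance columns\n", length(x$dropped)))
  invisible(x)
}

#' Per-variable contributions to a principal component
#'
#' The contribution of variable j to component k is `100 * loading_jk^2`;
#' with orthonormal loadings these sum to 100 over the retained variables.
#'
#' @param p A `split_pca`.
#' @param k Component index (1-based).
#' @return Data frame (`variable`, `percent`) sorted by decreasing
#'   contribution; ties keep the original column order.
#' @export
variable_contributions <- function(p, k = 1L) {
  stopifnot(inherits(p, "split_pca"))
  if (k < 1L || k > ncol(p$loadings))
    ss_validation_error(sprintf("component index %d out of range 1..%d",
                                k, ncol(p$loadings)))
  pc <- p$contributions[, k]
  ord <- order(-pc, seq_along(pc))
  data.frame(variable = rownames(p$loadings)[ord], percent = unname(pc[ord]),
             stringsAsFactors = FALSE)
}

#' Per-strategy dispersion (stability) in PCA score space
#'
#' The dispersion of a strategy is the mean pairwise Euclidean distance
#' among its trees' scores restricted to the first `K` components; a denser
#' cloud indicates a more stable strategy. Strategies are ranked ascending
#' (rank 1 = most stable). A single-tree strategy has dispersion 0.
#'
#' @param p A `split_pca`.
#' @param strategies Tree-to-strategy labels (named by tree id or in row
#'   order); defaults to labels carried over from the matrix.
#' @param K Subspace dimension (default 2: components 1-2).
#' @return A `stability_report`: list with `table` (strategy, n, dispersion,
#'   rank), `centroids` (strategy x component means) and `K`.
#' @export
group_dispersion <- function(p, strategies = NULL, K = 2L) {
  stopifnot(inherits(p, "split_pca"))
  strategies <- strategies %||% p$strategies
  if (is.null(strategies)) ss_validation_error("no strategy labels available")
  if (K < 1L || K > ncol(p$scores))
    ss_validation_error(sprintf("K = %d exceeds the %d available components",
                                K, ncol(p$scores)))
  if (!is.null(names(strategies)) && !is.null(rownames(p$scores)))
    strategies <- strategies[rownames(p$scores)]
  if (length(strategies) != nrow(p$scores) || anyNA(strategies))
    ss_validation_error("every tree needs a strategy label")
  pts <- p$scores[, seq_len(K), drop = FALSE]
  labs <- sort(unique(as.character(strategies)))
  disp <- vapply(labs, function(s) {
    sub <- pts[strategies == s, , drop = FALSE]
    if (nrow(sub) < 2L) 0 else mean(stats::dist(sub))
  }, numeric(1))
  centroids <- do.call(rbind, lapply(labs, function(s)
    colMeans(pts[strategies == s, , drop = FALSE])))
  rownames(centroids) <- labs
  tab <- data.frame(strategy = labs,
                    n = as.integer(table(factor(strategies, levels = labs))),
                    dispersion = unname(disp),
                    rank = rank(disp, ties.method = "min"),
                    stringsAsFactors = FALSE)
  structure(list(table = tab[order(tab$rank), , drop = FALSE],
                 centroids = centroids, K = K),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> K = %d (rank 1 = most stable)\n", x$K))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Total tree length
#'
#' Sum of all branch lengths of a tree.
#'
#' @param tree A `support_tree`.
#' @param strict Error when any branch length is missing (default); with
#'   `strict = FALSE` missing lengths are treated as 0.
#' @return A non-negative number.
#' @export
total_tree_length <- function(tree, strict = TRUE) {
  stopifnot(inherits(tree, "support_tree"))
  if (is.null(tree$edge.length) || (strict && anyNA(tree$edge.length)))
    if (strict) ss_data_error("tree has missing branch lengths")
  if (is.null(tree$edge.length)) return(0)
  sum(tree$edge.length, na.rm = TRUE)
}

#' Per-strategy summaries of tree statistics
#'
#' Summarizes numeric per-tree statistics (e.g. total tree length and
#' log-likelihood) by strategy: n, mean, min, quartiles (linear
#' interpolation, type 7) and max, as a tidy table.
#'
#' @param stats_df Data frame with a `strategy` column and one or more
#'   numeric statistic columns.
#' @return Tidy data frame: strategy, metric, n, mean, min, q1, median, q3,
#'   max.
#' @export
summarize_tree_stats <- function(stats_df) {
  if (!"strategy" %in% names(stats_df))
    ss_validation_error("stats_df needs a 'strategy' column")
  metrics <- names(stats_df)[vapply(stats_df, is.numeric, logical(1))]
  if (!length(metrics)) ss_validation_error("no numeric statistic columns")
  rows <- list()
  for (s in sort(unique(stats_df$strategy))) {
    sub <- stats_df[stats_df$strategy == s, , drop = FALSE]
    for (mcol in metrics) {
      v <- sub[[mcol]]
      q <- stats::quantile(v, c(.25, .5, .75), type = 7, names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        strategy = s, metric = mcol, n = length(v), mean = mean(v),
        min = min(v), q1 = q[1], median = q[2], q3 = q[3], max = max(v),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
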
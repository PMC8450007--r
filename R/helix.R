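#' Parse a dot-bracket RNA secondary structure
#'
#' Stack-matches `(`/`)` pairs (pseudoknot-free grammar) and classifies the
#' loops between consecutive nested pairs (i, j) > (i', j'): with
#' a = i' - i - 1 unpaired bases on the 5' side and b = j - j' - 1 on the
#' 3' side, a > 0, b = 0 is a 5' bulge; a = 0, b > 0 a 3' bulge; both > 0 an
#' internal loop. The innermost pair closing no other pair closes a hairpin
#' of size j - i - 1. Pairs enclosing two or more helices are labelled
#' `multi`.
#'
#' @param sequence Residue string.
#' @param structure Dot-bracket string of the same length over `(`, `)`, `.`.
#' @return A `helix_annotation`: list with `sequence`, `structure`, `pairs`
#'   (2-column matrix of 1-based positions, 5' strand first) and `loops`
#'   (data frame: type, size5, size3, outer5, outer3 = closing pair).
#' @export
parse_dotbracket <- function(sequence, structure) {
  if (nchar(sequence) != nchar(structure))
    ss_validation_error("sequence and structure must have equal length")
  sym <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(sym %in% c("(", ")", ".")))
    ss_data_error("structure may contain only '(', ')' and '.'")
  open <- integer(0)
  p5 <- integer(0); p3 <- integer(0)
  for (i in seq_along(sym)) {
    if (sym[i] == "(") {
      open <- c(open, i)
    } else if (sym[i] == ")") {
      if (!length(open)) ss_data_error("unbalanced brackets: unmatched ')'")
      p5 <- c(p5, open[length(open)])
      p3 <- c(p3, i)
      open <- open[-length(open)]
    }
  }
  if (length(open)) ss_data_error("unbalanced brackets: unmatched '('")
  pairs <- cbind(p5 = p5, p3 = p3)
  loops <- classify_loops(pairs)
  structure(list(sequence = sequence, structure = structure,
                 pairs = pairs[order(pairs[, 1L]), , drop = FALSE],
                 loops = loops),
            class = "helix_annotation")
}

## Loop features between each pair and the pairs directly nested in it.
classify_loops <- function(pairs) {
  empty <- data.frame(type = character(0), size5 = integer(0),
                      size3 = integer(0), outer5 = integer(0),
                      outer3 = integer(0), stringsAsFactors = FALSE)
  if (!nrow(pairs)) return(empty)
  ord <- order(pairs[, 1L])
  pairs <- pairs[ord, , drop = FALSE]
  np <- nrow(pairs)
  # direct parent of each pair: tightest enclosing pair
  parent <- rep(NA_integer_, np)
  for (k in seq_len(np)) {
    enclosing <- which(pairs[, 1L] < pairs[k, 1L] & pairs[, 2L] > pairs[k, 2L])
    if (length(enclosing))
      parent[k] <- enclosing[which.max(pairs[enclosing, 1L])]
  }
  rows <- list()
  for (k in seq_len(np)) {
    kids <- which(!is.na(parent) & parent == k)
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!length(kids)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = "hairpin", size5 = j - i - 1L, size3 = 0L,
        outer5 = i, outer3 = j, stringsAsFactors = FALSE)
    } else if (length(kids) == 1L) {
      a <- pairs[kids, 1L] - i - 1L
      b <- j - pairs[kids, 2L] - 1L
      if (a == 0L && b == 0L) next      # stacked pair, no loop
      type <- if (a > 0L && b == 0L) "bulge5"
              else if (a == 0L && b > 0L) "bulge3"
              else "internal"
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, size5 = a, size3 = b,
        outer5 = i, outer3 = j, stringsAsFactors = FALSE)
    } else {
      unpaired <- (j - i - 1L) -
        sum(pairs[kids, 2L] - pairs[kids, 1L] + 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        type = "multi", size5 = unpaired, size3 = 0L,
        outer5 = i, outer3 = j, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' @export
print.helix_annotation <- function(x, ...) {
  cat(sprintf("<helix_annotation> %d nt, %d pairs, %d loops\n",
              nchar(x$sequence), nrow(x$pairs), nrow(x$loops)))
  invisible(x)
}

#' Bulge signature of a helix
#'
#' Counts 1-nucleotide bulges by strand within the annotation (optionally
#' restricted to a position window) and classifies the helix: `"typical"`
#' for exactly one 1-nt bulge on the 3' strand and nothing else, the
#' eukaryote-typical state of SSU rRNA helix 17; `"double-bulge"` for two
#' such 3' bulges, the derived state produced by an additional nucleotide in
#' the 3' strand; anything else is `"other"`. Hairpin loops do not count.
#'
#' @param h A `helix_annotation`.
#' @param window Optional integer range of positions; only loops whose
#'   closing pair lies entirely inside the window are counted. Useful to
#'   restrict the signature to one helix of a larger structure.
#' @return A `bulge_signature`: list with `n_bulge5_1nt`, `n_bulge3_1nt`,
#'   `n_other_loops` and `label`.
#' @export
bulge_signature <- function(h, window = NULL) {
  stopifnot(inherits(h, "helix_annotation"))
  loops <- h$loops
  if (!is.null(window))
    loops <- loops[loops$outer5 >= min(window) & loops$outer3 <= max(window), ,
                   drop = FALSE]
  loops <- loops[loops$type != "hairpin", , drop = FALSE]
  b5 <- sum(loops$type == "bulge5" & loops$size5 == 1L)
  b3 <- sum(loops$type == "bulge3" & loops$size3 == 1L)
  other <- nrow(loops) - b5 - b3
  label <- if (b3 == 1L && b5 == 0L && other == 0L) "typical"
           else if (b3 == 2L && b5 == 0L && other == 0L) "double-bulge"
           else "other"
  structure(list(n_bulge5_1nt = b5, n_bulge3_1nt = b3,
                 n_other_loops = other, label = label),
            class = "bulge_signature")
}

#' @export
print.bulge_signature <- function(x, ...) {
  cat(sprintf("<bulge_signature> %s (5' 1-nt bulges: %d, 3' 1-nt bulges: %d, other loops: %d)\n",
              x$label, x$n_bulge5_1nt, x$n_bulge3_1nt, x$n_other_loops))
  invisible(x)
}

#' Minimal parsimony transition count of a discrete character on a tree
#'
#' Small-parsimony count of state changes for an arbitrary discrete
#' character (states are opaque symbols, e.g. whole loop-pattern strings
#' such as "bulge-2bp-bulge") on a tree. The bottom-up dynamic program uses
#' unit change costs and handles multifurcations exactly; the count is
#' invariant to rooting. A top-down pass returns one optimal internal-state
#' assignment (ties broken towards the parent state, then lexicographically).
#'
#' @param tree A `support_tree`; any supports are ignored.
#' @param tip_states Named character (or coercible) vector: one state per
#'   leaf label.
#' @return List with `count` (minimal number of transitions) and `states`
#'   (one optimal state per node: tips 1..n in `tip.label` order, then
#'   internal nodes).
#' @export
fitch_transitions <- function(tree, tip_states) {
  stopifnot(inherits(tree, "support_tree"))
  n <- st_ntips(tree)
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  miss <- setdiff(tree$tip.label, names(tip_states))
  if (length(miss))
    ss_data_error(sprintf("missing tip states: %s", paste(miss, collapse = ", ")))
  S <- sort(unique(unname(tip_states[tree$tip.label])))
  ns <- length(S)
  children <- st_children(tree)
  parent <- st_parent(tree)
  po <- st_postorder(tree, children)
  nn <- n + tree$Nnode
  cost <- matrix(Inf, nrow = nn, ncol = ns, dimnames = list(NULL, S))
  for (node in po) {
    if (node <= n) {
      cost[node, tip_states[[tree$tip.label[node]]]] <- 0
    } else {
      acc <- numeric(ns)
      for (kid in children[[node]]) {
        ck <- cost[kid, ]
        best <- min(ck)
        # staying in state s costs ck[s]; switching costs best + 1
        acc <- acc + pmin(ck, best + 1)
      }
      cost[node, ] <- acc
    }
  }
  root <- st_root(tree)
  count <- min(cost[root, ])
  states <- character(nn)
  pick <- function(v, prefer) {
    cand <- S[v <= min(v)]
    if (!is.null(prefer) && prefer %in% cand) prefer else cand[1L]
  }
  states[root] <- pick(cost[root, ], NULL)
  for (node in rev(po)) {
    if (node == root) next
    ps <- states[parent[node]]
    v <- cost[node, ] + (S != ps)
    states[node] <- pick(v, ps)
  }
  list(count = as.integer(count), states = states)
}

#' Read two-line (sequence, dot-bracket) structure records
#'
#' @param path TSV with columns `id`, `sequence`, `structure`.
#' @return Named list of `helix_annotation`.
#' @export
read_structure_table <- function(path) {
  if (!file.exists(path)) ss_validation_error(sprintf("structure table not found: %s", path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "sequence", "structure") %in% names(df)))
    ss_validation_error("structure table must have columns 'id', 'sequence', 'structure'")
  out <- lapply(seq_len(nrow(df)), function(i)
    parse_dotbracket(df$sequence[i], df$structure[i]))
  names(out) <- df$id
  out
}
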
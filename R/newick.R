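#' Parse a Newick string with branch-support labels
#'
#' Reads one Newick statement in the convention of modern ML/Bayesian tree
#' software: numeric labels attached to internal nodes are edge supports
#' (ultrafast-bootstrap percentages or posterior probabilities) for the edge
#' above that node. The tree is normalized to its unrooted form: internal
#' nodes of degree 2 are suppressed and a bifurcating root is collapsed, with
#' the two merged root edges required to agree on their support.
#'
#' @param text A single Newick statement ending in `;`.
#' @param scale Declared support scale, `"percent"` (values in \[0, 100\]) or
#'   `"probability"` (values in \[0, 1\]).
#' @param conflict What to do when the two edges merged at a suppressed
#'   degree-2 root carry unequal supports: `"error"` (default) or `"max"`.
#' @param meta Optional named list of metadata (e.g. `strategy`, `source`,
#'   `loglik`) attached to the tree.
#' @return A `support_tree`.
#' @examples
#' tr <- parse_newick("((A,B)95,(C,D));")
#' extract_bipartitions(tr)
#' @export
parse_newick <- function(text, scale = c("percent", "probability"),
                         conflict = c("error", "max"), meta = list()) {
  scale <- match.arg(scale)
  conflict <- match.arg(conflict)
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) ss_data_error("empty Newick string")
  if (!grepl(";\\s*$", text)) ss_data_error("Newick statement must end in ';'")

  toks <- regmatches(text, gregexpr("[(),;]|:[^(),:;[:space:]]+|[^(),:;[:space:]]+",
                                    text))[[1]]
  pending <- NULL          # last completed node awaiting label/length/comma
  stack <- list()          # open parenthesis frames (lists of children)
  done <- FALSE
  push_pending <- function() {
    if (is.null(pending)) ss_data_error("malformed Newick: empty node")
    if (!length(stack)) ss_data_error("malformed Newick: unbalanced parentheses")
    stack[[length(stack)]][[length(stack[[length(stack)]]) + 1L]] <<- pending
    pending <<- NULL
  }
  for (tok in toks) {
    if (done) ss_data_error("text after terminating ';'")
    if (tok == "(") {
      if (!is.null(pending)) ss_data_error("malformed Newick: '(' after a node")
      stack[[length(stack) + 1L]] <- list()
    } else if (tok == ",") {
      push_pending()
    } else if (tok == ")") {
      push_pending()
      kids <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pending <- rnode(children = kids)
    } else if (tok == ";") {
      done <- TRUE
    } else if (startsWith(tok, ":")) {
      len <- suppressWarnings(as.numeric(substring(tok, 2L)))
      if (is.null(pending) || is.na(len))
        ss_data_error(sprintf("malformed branch length '%s'", tok))
      pending$length <- len
    } else {
      if (is.null(pending)) {
        pending <- rnode(label = tok)
      } else if (!rnode_is_tip(pending) && is.na(pending$label)) {
        pending$label <- tok
      } else {
        ss_data_error(sprintf("unexpected label '%s'", tok))
      }
    }
  }
  if (!done) ss_data_error("Newick statement must end in ';'")
  if (length(stack)) ss_data_error("malformed Newick: unbalanced parentheses")
  if (is.null(pending)) ss_data_error("empty Newick statement")

  root <- label_to_support(pending)
  root <- suppress_root(collapse_singles(root, conflict), conflict)
  tree <- flatten_rnodes(root, scale = scale, meta = meta)
  tree
}

## Internal-node labels -> numeric supports; non-numeric labels are dropped
## with a warning (e.g. clade names some programs emit).
label_to_support <- function(nd) {
  if (rnode_is_tip(nd)) return(nd)
  nd$children <- lapply(nd$children, label_to_support)
  if (!is.na(nd$label)) {
    if (is_number_like(nd$label)) {
      nd$support <- as.numeric(nd$label)
    } else {
      warning(sprintf("ignoring non-numeric internal node label '%s'", nd$label),
              call. = FALSE)
    }
    nd$label <- NA_character_
  }
  nd
}

#' Write a support tree as a canonical Newick string
#'
#' Output is deterministic: at every node, children are ordered by the
#' smallest taxon index (position in the sorted taxon universe) contained in
#' their clade. Supports are written as internal node labels and branch
#' lengths with `:` when present.
#'
#' @param tree A `support_tree`.
#' @param taxa Taxon universe defining the index order; defaults to the
#'   tree's own sorted leaf labels.
#' @return A single Newick string ending in `;`.
#' @export
write_newick <- function(tree, taxa = sort(tree$tip.label)) {
  stopifnot(inherits(tree, "support_tree"))
  n <- st_ntips(tree)
  idx <- match(tree$tip.label, taxa)
  if (anyNA(idx)) ss_data_error("tree contains taxa absent from `taxa`")
  children <- st_children(tree)
  elen <- st_elen_by_child(tree)
  root <- st_root(tree)
  rec <- function(node) {
    if (node <= n) {
      str <- tree$tip.label[node]
      mn <- idx[node]
    } else {
      parts <- lapply(children[[node]], rec)
      ord <- order(vapply(parts, `[[`, numeric(1), "min"))
      str <- paste0("(", paste(vapply(parts[ord], `[[`, character(1), "str"),
                               collapse = ","), ")")
      if (node != root && !is.na(tree$support[node - n]))
        str <- paste0(str, fmt_num(tree$support[node - n]))
      mn <- min(vapply(parts, `[[`, numeric(1), "min"))
    }
    if (node != root && !is.na(elen[node]))
      str <- paste0(str, ":", fmt_num(elen[node]))
    list(str = str, min = mn)
  }
  paste0(rec(root)$str, ";")
}
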
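## Internal tree representation
## ----------------------------
## A `support_tree` stores an unrooted topology in the usual flat edge-matrix
## layout (tips 1..n, internal nodes n+1..n+Nnode, basal node = n+1 after
## canonical numbering). Edge supports live on the child node of each internal
## edge, matching the internal-node-label convention of ML/BI tree files.
## The basal node itself carries no support (entry NA).

new_support_tree <- function(edge, tip.label, Nnode, support,
                             edge.length = NULL, scale = "percent",
                             meta = list()) {
  obj <- structure(
    list(edge = edge, tip.label = tip.label, Nnode = Nnode,
         support = support, edge.length = edge.length,
         scale = scale, meta = meta),
    class = "support_tree")
  st_validate(obj)
  obj
}

st_validate <- function(tree) {
  n <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    ss_data_error(sprintf("duplicate leaf labels: %s",
                          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                                collapse = ", ")))
  if (length(tree$support) != tree$Nnode)
    ss_data_error("support vector length must equal the number of internal nodes")
  if (!is.null(tree$edge.length) && length(tree$edge.length) != nrow(tree$edge))
    ss_data_error("edge.length must have one entry per edge")
  check_support_scale(tree$support, tree$scale)
  invisible(tree)
}

check_support_scale <- function(support, scale) {
  s <- support[!is.na(support)]
  lim <- switch(scale, percent = 100, probability = 1,
                ss_validation_error(sprintf("unknown support scale '%s'", scale)))
  if (any(s < 0 | s > lim))
    ss_data_error(sprintf(
      "support value outside declared %s scale [0, %s]: %s",
      scale, lim, paste(fmt_num(s[s < 0 | s > lim]), collapse = ", ")))
  invisible(TRUE)
}

st_ntips <- function(tree) length(tree$tip.label)

st_root <- function(tree) st_ntips(tree) + 1L

st_children <- function(tree) {
  nn <- st_ntips(tree) + tree$Nnode
  ch <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

st_parent <- function(tree) {
  nn <- st_ntips(tree) + tree$Nnode
  par <- rep(NA_integer_, nn)
  par[tree$edge[, 2L]] <- tree$edge[, 1L]
  par
}

## Reverse preorder: every child precedes its parent. Works for any internal
## numbering (edges may have been rearranged by NNI surgery).
st_postorder <- function(tree, children = st_children(tree)) {
  root <- st_root(tree)
  nn <- st_ntips(tree) + tree$Nnode
  out <- integer(nn)
  k <- 0L
  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    out[k] <- node
    if (!is.null(children[[node]])) stack <- c(stack, children[[node]])
  }
  rev(out[seq_len(k)])
}

## Sorted tip ids of the clade below every node.
st_clades <- function(tree, children = st_children(tree)) {
  n <- st_ntips(tree)
  nn <- n + tree$Nnode
  clades <- vector("list", nn)
  for (node in st_postorder(tree, children)) {
    if (node <= n) {
      clades[[node]] <- node
    } else {
      clades[[node]] <- sort(unlist(clades[children[[node]]], use.names = FALSE))
    }
  }
  clades
}

## Edge length indexed by child node (NA when absent).
st_elen_by_child <- function(tree) {
  nn <- st_ntips(tree) + tree$Nnode
  len <- rep(NA_real_, nn)
  if (!is.null(tree$edge.length)) len[tree$edge[, 2L]] <- tree$edge.length
  len
}

## ---------------------------------------------------------------------------
## Recursive ("rnode") working form used by the parser, pruning and NNI code.
## rnode: list(children = list(), label, length, support)

rnode <- function(children = list(), label = NA_character_,
                  length = NA_real_, support = NA_real_) {
  list(children = children, label = label, length = length, support = support)
}

rnode_is_tip <- function(nd) length(nd$children) == 0L

resolve_support <- function(a, b, conflict = c("error", "max")) {
  conflict <- match.arg(conflict)
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  if (isTRUE(all.equal(a, b))) return(a)
  if (conflict == "max") return(max(a, b))
  ss_data_error(sprintf(
    "conflicting support values on edges merged at a suppressed degree-2 root: %s vs %s",
    fmt_num(a), fmt_num(b)))
}

sum_lengths <- function(a, b) {
  if (is.na(a) && is.na(b)) NA_real_ else sum(a, b, na.rm = TRUE)
}

## Remove internal nodes of out-degree 1 (their two incident edges describe
## the same split: supports must agree, lengths add).
collapse_singles <- function(nd, conflict = "error") {
  if (rnode_is_tip(nd)) return(nd)
  nd$children <- lapply(nd$children, function(ch) {
    while (!rnode_is_tip(ch) && length(ch$children) == 1L) {
      g <- ch$children[[1L]]
      g$length <- sum_lengths(ch$length, g$length)
      if (!rnode_is_tip(g)) g$support <- resolve_support(ch$support, g$support, conflict)
      ch <- g
    }
    collapse_singles(ch, conflict)
  })
  nd
}

## Suppress a degree-2 root: its two child edges are one edge of the unrooted
## tree. If both children are internal and carry unequal supports this is an
## error (or max under conflict = "max").
suppress_root <- function(root, conflict = "error") {
  while (length(root$children) == 1L) {
    only <- root$children[[1L]]
    if (rnode_is_tip(only)) break
    only$length <- NA_real_
    only$support <- NA_real_
    root <- only
  }
  if (length(root$children) != 2L) return(root)
  a <- root$children[[1L]]
  b <- root$children[[2L]]
  if (rnode_is_tip(a) && rnode_is_tip(b)) return(root)   # 2-taxon tree
  if (!rnode_is_tip(a)) { keep <- a; other <- b } else { keep <- b; other <- a }
  s <- if (rnode_is_tip(other)) NA_real_
       else resolve_support(keep$support, other$support, conflict)
  other$length <- sum_lengths(a$length, b$length)
  other$support <- if (rnode_is_tip(other)) NA_real_ else s
  rnode(children = c(keep$children, list(other)))
}

## Flatten the recursive form into the flat arrays, numbering nodes in
## preorder (tips in encounter order, basal node = n+1).
flatten_rnodes <- function(root, scale = "percent", meta = list()) {
  count_tips <- function(nd) {
    if (rnode_is_tip(nd)) 1L else sum(vapply(nd$children, count_tips, integer(1)))
  }
  n <- count_tips(root)
  if (n < 2L) ss_data_error("a tree needs at least 2 leaves")
  env <- new.env(parent = emptyenv())
  env$tip <- 0L; env$int <- n
  env$tiplab <- character(n)
  env$parents <- integer(0); env$childs <- integer(0)
  env$lens <- numeric(0); env$supp <- numeric(0)
  walk <- function(nd) {
    if (rnode_is_tip(nd)) {
      env$tip <- env$tip + 1L
      id <- env$tip
      env$tiplab[id] <- nd$label
    } else {
      env$int <- env$int + 1L
      id <- env$int
      env$supp[id - n] <- nd$support %||% NA_real_
      for (ch in nd$children) {
        cid <- walk(ch)
        env$parents <- c(env$parents, id)
        env$childs <- c(env$childs, cid)
        env$lens <- c(env$lens, ch$length %||% NA_real_)
      }
    }
    id
  }
  walk(root)
  Nnode <- env$int - n
  supp <- env$supp
  length(supp) <- Nnode
  supp[1L] <- NA_real_   # basal node carries no edge support
  edge <- cbind(env$parents, env$childs)
  lens <- env$lens
  # reorder edge rows into DFS preorder ("cladewise"), so the flat form is
  # also a structurally valid ape phylo layout
  rows_of <- vector("list", n + Nnode)
  for (r in seq_len(nrow(edge)))
    rows_of[[edge[r, 1L]]] <- c(rows_of[[edge[r, 1L]]], r)
  ord <- integer(nrow(edge))
  k <- 0L
  stack <- rev(rows_of[[n + 1L]])
  while (length(stack)) {
    r <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    k <- k + 1L
    ord[k] <- r
    kid <- edge[r, 2L]
    if (kid > n) stack <- c(stack, rev(rows_of[[kid]]))
  }
  edge <- edge[ord, , drop = FALSE]
  lens <- if (all(is.na(lens))) NULL else lens[ord]
  new_support_tree(edge = edge, tip.label = env$tiplab, Nnode = Nnode,
                   support = supp, edge.length = lens,
                   scale = scale, meta = meta)
}

## Flat -> recursive (children in edge-row order).
tree_to_rnodes <- function(tree) {
  n <- st_ntips(tree)
  children <- st_children(tree)
  elen <- st_elen_by_child(tree)
  build <- function(node) {
    if (node <= n)
      return(rnode(label = tree$tip.label[node], length = elen[node]))
    rnode(children = lapply(children[[node]], build),
          length = elen[node],
          support = if (node == st_root(tree)) NA_real_ else tree$support[node - n])
  }
  build(st_root(tree))
}

## Renumber nodes canonically (preorder) after structural surgery.
st_canonicalize <- function(tree) {
  flatten_rnodes(tree_to_rnodes(tree), scale = tree$scale, meta = tree$meta)
}

## Restrict a tree to a subset of its leaves, collapsing redundant nodes.
st_prune <- function(tree, keep) {
  keep <- as.character(keep)
  miss <- setdiff(keep, tree$tip.label)
  if (length(miss))
    ss_data_error(sprintf("taxa not in tree: %s", paste(miss, collapse = ", ")))
  filt <- function(nd) {
    if (rnode_is_tip(nd)) {
      if (nd$label %in% keep) return(nd)
      return(NULL)
    }
    kids <- Filter(Negate(is.null), lapply(nd$children, filt))
    if (!length(kids)) return(NULL)
    nd$children <- kids
    nd
  }
  root <- filt(tree_to_rnodes(tree))
  if (is.null(root)) ss_data_error("pruning removed every leaf")
  root <- suppress_root(collapse_singles(root, "max"), conflict = "max")
  flatten_rnodes(root, scale = tree$scale, meta = tree$meta)
}

#' Convert a support tree to an \pkg{ape} "phylo" object
#'
#' Convenience interoperability layer (plotting, cross-checks). Supports are
#' placed in `node.label`; the conversion requires \pkg{ape} only at call
#' time.
#'
#' @param tree A `support_tree`.
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "support_tree"))
  tree <- st_canonicalize(tree)
  n <- st_ntips(tree)
  phy <- list(edge = unname(tree$edge), Nnode = tree$Nnode,
              tip.label = tree$tip.label)
  if (!is.null(tree$edge.length)) phy$edge.length <- tree$edge.length
  phy$node.label <- ifelse(is.na(tree$support), "", fmt_num(tree$support))
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' @export
print.support_tree <- function(x, ...) {
  cat(sprintf("<support_tree> %d tips, %d internal nodes, scale = %s\n",
              st_ntips(x), x$Nnode, x$scale))
  if (!is.null(x$meta$strategy))
    cat(sprintf("  strategy: %s\n", x$meta$strategy))
  invisible(x)
}
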
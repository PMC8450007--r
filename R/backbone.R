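#' Does a bipartition respect a taxon grouping?
#'
#' A split is group-respecting when every group of the scheme lies entirely
#' on one side of it and the induced split of the group labels is itself
#' non-trivial (at least one group on each side). Such splits express only
#' the interrelationships of the groups (backbone splits).
#'
#' @param members Canonical member-index vector of the split (see
#'   [extract_bipartitions()]).
#' @param scheme A `group_scheme`.
#' @param taxa Taxon universe the indices refer to.
#' @param unassigned How to treat taxa without a group: `"error"` (default)
#'   or `"wildcard"` (they never violate a group and are excluded from the
#'   projection).
#' @return List with `respecting` (logical) and, when TRUE, `projection`
#'   (list with the group labels on the canonical side, `inside`, and the
#'   rest, `outside`).
#' @export
is_group_respecting <- function(members, scheme, taxa,
                                unassigned = c("error", "wildcard")) {
  unassigned <- match.arg(unassigned)
  stopifnot(inherits(scheme, "group_scheme"))
  grp <- scheme$assignment[taxa]
  if (anyNA(grp)) {
    if (unassigned == "error")
      ss_data_error(sprintf("taxa without group assignment: %s",
                            paste(taxa[is.na(grp)], collapse = ", ")))
  }
  inside <- seq_along(taxa) %in% members
  res <- tapply(inside[!is.na(grp)], grp[!is.na(grp)], function(v) {
    if (all(v)) 1L else if (!any(v)) 0L else -1L
  })
  if (any(res == -1L))
    return(list(respecting = FALSE, projection = NULL))
  gin <- names(res)[res == 1L]
  gout <- names(res)[res == 0L]
  if (!length(gin) || !length(gout))
    return(list(respecting = FALSE, projection = NULL))
  list(respecting = TRUE, projection = list(inside = gin, outside = gout))
}

#' Reduce a support matrix to well-supported backbone splits
#'
#' Keeps exactly the columns that (i) are group-respecting under the scheme
#' and (ii) carry support at least `min_support` in at least a `min_presence`
#' fraction of trees. The row set is unchanged. This operationalizes the
#' reduction of a full split set to the splits expressing only the
#' interrelationships of predefined, consistently recovered taxon groups.
#'
#' @param m A `bipartition_matrix`.
#' @param scheme A `group_scheme` over the matrix's taxa.
#' @param min_support Minimum support counting towards presence (default 50,
#'   percent scale).
#' @param min_presence Minimum fraction of trees meeting `min_support`
#'   (default 0.5).
#' @param unassigned Passed to [is_group_respecting()].
#' @return A `bipartition_matrix` with the kept columns; the per-column
#'   report (split, group_respecting, presence, kept, reason) is attached as
#'   `attr(, "report")`.
#' @export
reduce_matrix <- function(m, scheme, min_support = 50, min_presence = 0.5,
                          unassigned = "error") {
  stopifnot(inherits(m, "bipartition_matrix"))
  if (min_presence < 0 || min_presence > 1)
    ss_validation_error("min_presence must be in [0, 1]")
  if (length(scheme$groups) < 3L)
    warning("fewer than 3 groups: backbone reduction cannot express a non-trivial group topology",
            call. = FALSE)
  taxa <- attr(m, "taxa")
  splits <- attr(m, "splits")
  vals <- unclass(m)
  gr <- logical(ncol(m)); presence <- numeric(ncol(m)); proj <- character(ncol(m))
  for (j in seq_len(ncol(m))) {
    r <- is_group_respecting(splits[[j]], scheme, taxa, unassigned = unassigned)
    gr[j] <- r$respecting
    proj[j] <- if (r$respecting)
      paste0(paste(r$projection$inside, collapse = "|"), " vs ",
             paste(r$projection$outside, collapse = "|")) else ""
    # NA = absent-support sentinel: does not count towards presence
    presence[j] <- mean(!is.na(vals[, j]) & vals[, j] >= min_support)
  }
  kept <- gr & presence >= min_presence
  reason <- ifelse(kept, "kept",
                   ifelse(!gr, "not group-respecting",
                          sprintf("presence %.3f < %.3f", presence, min_presence)))
  report <- data.frame(split = colnames(m), group_respecting = gr,
                       projection = proj, presence = presence,
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  if (!any(kept))
    ss_data_error(sprintf(
      "reduction removed every column (%d not group-respecting, %d below presence threshold)",
      sum(!gr), sum(gr & presence < min_presence)))
  out <- bsm_subset_cols(m, which(kept))
  attr(out, "report") <- report
  out
}
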
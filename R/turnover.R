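# Gene copy-number turnover: per-branch gain/loss/stable classification per
# OG, either from a parsed external turnover report or from an internal
# Wagner (linear-cost Sankoff) parsimony reconstruction that substitutes
# for a birth-death likelihood model at desk scale.

#' Branch labels of a rooted tree (one per edge, named by the child node)
#'
#' Tips keep their tip labels; internal nodes use their node labels when
#' present, otherwise `N<node-number>`.
#'
#' @param tree `species_tree`.
#' @return character vector, one label per edge (edge order of the phylo).
#' @export
branch_labels <- function(tree) {
  phy <- tree$phylo
  child <- phy$edge[, 2]
  lab <- character(length(child))
  is_tip <- child <= ape::Ntip(phy)
  lab[is_tip] <- phy$tip.label[child[is_tip]]
  nl <- phy$node.label
  int_ids <- child[!is_tip] - ape::Ntip(phy)
  lab[!is_tip] <- if (!is.null(nl) && all(nzchar(nl[int_ids])))
    nl[int_ids] else paste0("N", child[!is_tip])
  lab
}

#' Ancestral copy-number reconstruction by linear-cost (Wagner) parsimony
#'
#' Sankoff dynamic program over integer states `0..max_count` with cost
#' `|i - j|` per branch. Species absent from the OG contribute leaf count 0
#' (loss is observable). Among minimal-cost assignments, each node takes the
#' smallest state attaining the minimum given its parent (root: smallest
#' state attaining the global minimum), which makes the reconstruction
#' deterministic.
#'
#' @param leaf_counts named integer vector over all tree tips.
#' @param tree `species_tree`.
#' @param max_count state-space cap; default max leaf count + 2 to allow
#'   ancestral overshoot.
#' @return list with `states` (integer per node, ape node numbering),
#'   `cost` (minimal total cost).
#' @export
reconstruct_counts_parsimony <- function(leaf_counts, tree,
                                         max_count = max(leaf_counts) + 2L) {
  phy <- tree$phylo
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  if (!all(phy$tip.label %in% names(leaf_counts)))
    stop("leaf_counts must cover all tips", call. = FALSE)
  counts <- as.integer(leaf_counts[phy$tip.label])
  if (any(counts < 0)) stop("negative leaf counts", call. = FALSE)
  if (max_count < max(counts)) stop("max_count below max leaf count", call. = FALSE)
  states <- 0:max_count
  k <- length(states)
  step_cost <- abs(outer(states, states, "-"))  # k x k: |parent - child|
  total <- ntip + nnode
  dp <- matrix(Inf, nrow = total, ncol = k)
  for (i in seq_len(ntip)) dp[i, ] <- ifelse(states == counts[i], 0, Inf)
  # post-order over edges (ape reorder "postorder" visits children first)
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    if (all(!is.finite(dp[parent, ]))) dp[parent, ] <- 0
    # min over child state j of dp[child, j] + |i - j| for each parent state i
    contrib <- apply(step_cost + rep(dp[child, ], each = k), 1, min)
    dp[parent, ] <- dp[parent, ] + contrib
  }
  root <- ntip + 1L
  if (all(!is.finite(dp[root, ]))) dp[root, ] <- 0  # degenerate single-tip
  cost <- min(dp[root, ])
  assigned <- integer(total)
  assigned[root] <- states[which(dp[root, ] == cost)[1]]
  # pre-order assignment: smallest child state minimizing dp + step cost
  pre <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    parent <- pre[e, 1]; child <- pre[e, 2]
    v <- dp[child, ] + abs(states - assigned[parent])
    assigned[child] <- states[which(v == min(v))[1]]
  }
  list(states = assigned, cost = cost)
}

#' Per-branch gain/loss/stable events for every OG
#'
#' Runs the parsimony reconstruction per OG and labels every edge of the
#' rooted tree by the sign of (child state - parent state).
#'
#' @param orthology `orthology_table`.
#' @param tree `species_tree`; its tips must cover the orthology species.
#' @param max_count optional state cap passed through per OG.
#' @return `branch_events` data.frame: `og_id`, `branch`, `delta`, `label`.
#' @export
branch_events <- function(orthology, tree, max_count = NULL) {
  phy <- tree$phylo
  if (!all(orthology$species %in% phy$tip.label))
    stop("orthology species missing from tree", call. = FALSE)
  labels <- branch_labels(tree)
  full <- stats::setNames(integer(length(phy$tip.label)), phy$tip.label)
  res <- lapply(orthology$og_ids, function(og) {
    cnt <- full
    cnt[orthology$species] <- orthology$counts[og, ]
    mc <- if (is.null(max_count)) max(cnt) + 2L else max_count
    rec <- reconstruct_counts_parsimony(cnt, tree, max_count = mc)
    delta <- rec$states[phy$edge[, 2]] - rec$states[phy$edge[, 1]]
    data.frame(og_id = og, branch = labels, delta = delta,
               label = ifelse(delta > 0, "gain",
                              ifelse(delta < 0, "loss", "stable")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("branch_events", "data.frame")
  out
}

#' Turnover proportions (EXP, CON, STA) per OG
#'
#' EXP = gain branches / branches, CON = loss branches / branches,
#' STA = stable branches / branches, over all edges of the rooted tree
#' (the three always sum to exactly 1). With `internal_only = TRUE` only
#' edges whose child is an internal node are counted.
#'
#' @param events `branch_events` (from [branch_events()] or
#'   [parse_cafe_report()]).
#' @param tree `species_tree`; required for `internal_only`.
#' @param internal_only restrict to internal edges.
#' @return data.frame `og_id`, `EXP`, `CON`, `STA`.
#' @export
turnover_proportions <- function(events, tree = NULL, internal_only = FALSE) {
  if (internal_only) {
    if (is.null(tree)) stop("tree required for internal_only", call. = FALSE)
    labs <- branch_labels(tree)
    internal <- labs[tree$phylo$edge[, 2] > ape::Ntip(tree$phylo)]
    events <- events[events$branch %in% internal, , drop = FALSE]
  }
  agg <- function(lbl) tapply(events$label == lbl, events$og_id, mean)
  e <- agg("gain"); c_ <- agg("loss"); s <- agg("stable")
  out <- data.frame(og_id = names(e), EXP = as.numeric(e),
                    CON = as.numeric(c_), STA = as.numeric(s),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
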
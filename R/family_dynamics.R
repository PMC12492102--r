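#' Ancestral gene-family sizes by integer-count parsimony
#'
#' Sankoff dynamic programming over integer states `0..max(count)` with
#' linear cost `|i - j|` per branch (optionally asymmetric gain/loss unit
#' costs). The linear cost lets each message be computed in a two-pass
#' distance transform, so the program is linear in the number of states.
#' Ties are broken deterministically: the root takes the smallest state
#' attaining the minimum, every other node the admissible state closest to
#' its parent's assigned state (smaller state on an exact distance tie).
#'
#' @param tree A `time_tree`.
#' @param counts Integer matrix, OG x species; column names must be exactly
#'   the tree's leaves.
#' @param gain_cost,loss_cost Unit cost of a gain (child > parent step) and
#'   a loss. Equal by default.
#' @return List: `states` (matrix OG x nodes, reconstructed count per tree
#'   node; leaf columns equal the input), `cost` (minimal total parsimony
#'   cost per OG), `node_branch_id` (branch id per non-root node column).
#' @export
reconstruct_counts <- function(tree, counts, gain_cost = 1, loss_cost = 1) {
  counts <- as.matrix(counts)
  leaves <- tree_leaves(tree)
  missing_sp <- setdiff(leaves, colnames(counts))
  extra_sp <- setdiff(colnames(counts), leaves)
  if (length(missing_sp) > 0L || length(extra_sp) > 0L) {
    stop("species/leaf mismatch; missing from counts: {",
         paste(missing_sp, collapse = ", "), "}; not in tree: {",
         paste(extra_sp, collapse = ", "), "}", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[, leaves, drop = FALSE]
  phy <- tree$phy
  ntip <- length(leaves)
  nnode <- ntip + phy$Nnode
  depth <- node_depths(phy)
  post <- order(depth[phy$edge[, 2L]], decreasing = TRUE) # children first
  pre <- rev(post)
  children <- split(phy$edge[, 2L], factor(phy$edge[, 1L], levels = seq_len(nnode)))
  parent <- integer(nnode)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]

  n_og <- nrow(counts)
  og_ids <- rownames(counts) %||% sprintf("OG%06d", seq_len(n_og))
  states <- matrix(0L, nrow = n_og, ncol = nnode,
                   dimnames = list(og_ids, NULL))
  total_cost <- numeric(n_og)

  for (f in seq_len(n_og)) {
    smax <- max(counts[f, ])
    S <- smax + 1L # states 0..smax
    cost <- matrix(Inf, nrow = S, ncol = nnode)
    for (tip in seq_len(ntip)) cost[counts[f, tip] + 1L, tip] <- 0
    # Upward pass: node cost = sum over children of min_i(child_cost_i + d(i, j)).
    for (k in post) {
      chd <- phy$edge[k, 2L]; par <- phy$edge[k, 1L]
      if (all(!is.finite(cost[, par]))) cost[, par] <- 0
      cost[, par] <- cost[, par] + linear_cost_message(cost[, chd],
                                                      gain_cost, loss_cost)
    }
    # Root cost column may still be Inf-initialised when the root has no
    # tips among its direct children processed above; handle the 1-tip tree.
    root_cost <- cost[, tree$root]
    if (all(!is.finite(root_cost))) root_cost <- rep(0, S)
    total_cost[f] <- min(root_cost)
    states[f, tree$root] <- which(root_cost == min(root_cost))[1L] - 1L
    # Downward pass in preorder.
    for (k in pre) {
      par <- phy$edge[k, 1L]; chd <- phy$edge[k, 2L]
      sp <- states[f, par]
      cand_cost <- cost[, chd] + step_cost(seq_len(S) - 1L, sp,
                                           gain_cost, loss_cost)
      best <- which(cand_cost == min(cand_cost)) - 1L
      best <- best[order(abs(best - sp), best)]
      states[f, chd] <- best[1L]
    }
  }
  list(states = states, cost = total_cost,
       node_branch_id = tree$branch_id)
}

# d(parent_state = from, child_state = to): gains cost gain_cost per copy.
step_cost <- function(to, from, gain_cost, loss_cost) {
  ifelse(to >= from, (to - from) * gain_cost, (from - to) * loss_cost)
}

# min-plus message for linear cost: m(j) = min_i c(i) + d(i -> j), where a
# step up (j > i, i.e. a gain on the branch) costs gain_cost per copy.
# Two cumulative passes give O(S).
linear_cost_message <- function(c_child, gain_cost, loss_cost) {
  S <- length(c_child)
  if (S == 1L) return(c_child)
  # Message indexed by parent state i; child state j costs d(i -> j), where
  # j > i is a gain. Seen from the parent side: moving the parent state down
  # by one (i - 1 -> same j) adds gain_cost; moving it up adds loss_cost.
  up <- numeric(S)   # best over j >= i: c(j) + (j - i) * gain_cost
  dn <- numeric(S)   # best over j <= i: c(j) + (i - j) * loss_cost
  up[S] <- c_child[S]
  for (i in (S - 1L):1L) up[i] <- min(c_child[i], up[i + 1L] + gain_cost)
  dn[1L] <- c_child[1L]
  for (i in 2:S) dn[i] <- min(c_child[i], dn[i - 1L] + loss_cost)
  pmin(up, dn)
}

#' Per-branch gene-family count changes
#'
#' Converts a reconstruction into the per-(OG, branch) signed count change
#' `delta = count(child) - count(parent)`. Positive deltas are gains,
#' negative deltas losses.
#'
#' @param tree A `time_tree`.
#' @param recon Output of [reconstruct_counts()].
#' @return data.frame `og_id`, `branch_id`, `delta`.
#' @export
compute_events <- function(tree, recon) {
  phy <- tree$phy
  ids <- branch_ids(tree)
  child <- phy$edge[, 2L]
  par <- phy$edge[, 1L]
  n_og <- nrow(recon$states)
  og_ids <- rownames(recon$states)
  delta <- recon$states[, child, drop = FALSE] -
    recon$states[, par, drop = FALSE]
  data.frame(
    og_id = rep(og_ids, times = length(ids)),
    branch_id = rep(ids, each = n_og),
    delta = as.integer(delta),
    stringsAsFactors = FALSE
  )
}

#' Gene gain-and-loss rate per million years
#'
#' The clade-level (or global) turnover rate: the sum of absolute
#' per-branch count changes over all selected OGs and branches, divided by
#' the summed branch time of the selected branches. Zero-length branches
#' are excluded from both numerator and denominator (a per-My rate is
#' undefined on them); the alternative `denominator = "root_age"` divides
#' by the age of the root instead of the branch-length sum.
#'
#' @param events Event table (`og_id`, `branch_id`, `delta`).
#' @param tree A `time_tree`.
#' @param branches Branch identifiers defining the scope (default: all).
#' @param ogs OG identifiers to include (default: all).
#' @param denominator `"branch_sum"` (default) or `"root_age"`.
#' @return Rate in events per My.
#' @export
gain_loss_rate <- function(events, tree, branches = NULL, ogs = NULL,
                           denominator = c("branch_sum", "root_age")) {
  denominator <- match.arg(denominator)
  len <- branch_lengths(tree)
  if (is.null(branches)) branches <- names(len)
  unknown <- setdiff(branches, names(len))
  if (length(unknown) > 0L) {
    stop("unknown branch id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  usable <- branches[len[branches] > 0]
  dropped <- setdiff(branches, usable)
  if (length(dropped) > 0L) {
    log_skip("excluding ", length(dropped), " zero-length branch(es) from rate")
  }
  if (length(usable) == 0L) stop("no usable branches in scope", call. = FALSE)
  ev <- events[events$branch_id %in% usable, , drop = FALSE]
  if (!is.null(ogs)) ev <- ev[ev$og_id %in% ogs, , drop = FALSE]
  denom <- switch(denominator,
    branch_sum = sum(len[usable]),
    root_age = max(ape::node.depth.edgelength(tree$phy))
  )
  if (denom <= 0) stop("scope has zero total time", call. = FALSE)
  sum(abs(ev$delta)) / denom
}

#' Flag rapid evolutionary events against a Poisson background
#'
#' A per-family background event rate is estimated as the total absolute
#' count change across all OGs and branches divided by (number of families
#' x total tree length). Each (OG, branch) change of magnitude `d >= 1` is
#' then scored against `Poisson(lambda = rate x branch length)`:
#' `p = P(X >= d)`. Changes with `p < alpha` are flagged rapid — the same
#' role as the per-family significance call of likelihood-based gain/loss
#' tools, with a transparent closed-form null.
#'
#' @param events Event table (`og_id`, `branch_id`, `delta`).
#' @param tree A `time_tree`.
#' @param alpha Significance threshold (default 0.05).
#' @param n_families Number of families behind `events` (default: number of
#'   distinct `og_id`).
#' @return `events` with columns `p_event` and `rapid` appended.
#' @export
flag_rapid_events <- function(events, tree, alpha = 0.05,
                              n_families = length(unique(events$og_id))) {
  len <- branch_lengths(tree)
  total_len <- sum(len[len > 0])
  total_events <- sum(abs(events$delta))
  events$p_event <- 1
  if (total_events == 0) {
    events$rapid <- FALSE
    return(events)
  }
  rate_per_family <- total_events / (n_families * total_len)
  lambda <- rate_per_family * len[events$branch_id]
  d <- abs(events$delta)
  nz <- d >= 1L
  events$p_event[nz] <- stats::ppois(d[nz] - 1L, lambda[nz], lower.tail = FALSE)
  events$rapid <- events$p_event < alpha
  events
}
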
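# Independent oracles used across test files. These deliberately take
# different computational routes from the package implementation.

# Mann-Whitney permutation oracle via pair counting (not rank sums):
# U = #{(i, j): a_i > b_j} + 0.5 * #{ties}, enumerated over all labelings.
mw_oracle <- function(a, b, alternative) {
  pool <- c(a, b)
  na <- length(a); n <- length(pool)
  u_pairs <- function(x, y) {
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_pairs(a, b)
  labelings <- utils::combn(n, na)
  u_all <- apply(labelings, 2L, function(ix) {
    u_pairs(pool[ix], pool[-ix])
  })
  mu <- na * (n - na) / 2
  eps <- 1e-9
  switch(alternative,
    greater   = mean(u_all >= u_obs - eps),
    less      = mean(u_all <= u_obs + eps),
    two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
  )
}

# Exhaustive parsimony oracle: minimum of sum(|child - parent|) over every
# assignment of states 0..smax to the internal nodes.
sankoff_oracle <- function(phy, tip_counts) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  smax <- max(tip_counts)
  grids <- rep(list(0:smax), nnode)
  combos <- as.matrix(expand.grid(grids))
  state_of <- function(assign_row, node) {
    if (node <= ntip) tip_counts[node] else assign_row[node - ntip]
  }
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    cost <- 0
    for (k in seq_len(nrow(phy$edge))) {
      cost <- cost + abs(state_of(combos[r, ], phy$edge[k, 2L]) -
                           state_of(combos[r, ], phy$edge[k, 1L]))
    }
    if (cost < best) best <- cost
  }
  unname(best)
}

# Small fixture: the demo tree and its three clades, rescaled to 500 My.
demo_fixture <- function(seed = 1L) {
  tree <- sim_time_tree(seed = seed, total_length = 500)
  specs <- list(
    PAR = clade_spec("PAR", grep("^PAR", tree_leaves(tree), value = TRUE), "leaf_list"),
    ACU = clade_spec("ACU", grep("^ACU", tree_leaves(tree), value = TRUE), "leaf_list"),
    OUT = clade_spec("OUT", grep("^OUT", tree_leaves(tree), value = TRUE), "leaf_list")
  )
  clades <- lapply(specs, resolve_clade, tree = tree)
  list(tree = tree, specs = specs, clades = clades)
}

# Fabricated resolved clade over abstract branch ids (for contrast tests
# that do not need a real tree).
fake_clade <- function(name, branches, species = character(0)) {
  structure(list(name = name, leaves = species, species = species,
                 branches = branches, total_time_my = length(branches)),
            class = "resolved_clade")
}
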
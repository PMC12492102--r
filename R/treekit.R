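#' Parse a time-calibrated Newick tree
#'
#' Reads a rooted Newick tree whose branch lengths are divergence times in
#' million years (My) and indexes it for clade-level analyses. Every non-root
#' branch receives a deterministic identifier derived from the sorted set of
#' leaf names below it, so identifiers are invariant to the leaf order of the
#' input string and stable across serialisations. These identifiers are the
#' join keys for all per-branch tables (events, rates).
#'
#' @param text Newick string (exactly one tree). Mutually exclusive with
#'   `file`.
#' @param file Path to a Newick file.
#' @return An object of class `time_tree`: a list with elements `phy` (the
#'   underlying [ape::read.tree()] phylo object), `branch_id` (character,
#'   indexed by child-node number, `NA` for the root), `leaf_sets` (list of
#'   sorted descendant leaf names per node), and `root` (root node number).
#' @details Polytomies are accepted as-is. Zero-length branches are allowed
#'   but are excluded from any per-My rate denominator downstream. Duplicate
#'   leaf names or missing branch lengths are validation errors.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' total_tree_length(tr)
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of 'text' or 'file'", call. = FALSE)
  }
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  check_newick_syntax(text)
  phy <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(phy)) stop("Newick parse error: no tree found in input", call. = FALSE)
  as_time_tree(phy)
}

# Cheap structural pre-check so malformed input errors name a position.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop(sprintf("malformed Newick: unbalanced ')' at position %d", i),
             call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth),
         call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop(sprintf("malformed Newick: missing ';' terminator at position %d",
                 nchar(text)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Wrap an ape phylo object as a time_tree
#'
#' @param phy A rooted `phylo` object with branch lengths in My.
#' @return A `time_tree` (see [parse_newick()]).
#' @export
as_time_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("'phy' must be a phylo object", call. = FALSE)
  if (anyDuplicated(phy$tip.label)) {
    dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf names: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (is.null(phy$edge.length)) {
    stop("tree has no branch lengths; time-calibrated branch lengths in My are required",
         call. = FALSE)
  }
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    stop("all branch lengths must be finite and >= 0", call. = FALSE)
  }
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  # Descendant leaf-name set per node, built in post-order.
  leaf_sets <- vector("list", nnode)
  for (tip in seq_len(ntip)) leaf_sets[[tip]] <- phy$tip.label[tip]
  # Process edges children-first (deeper child nodes before shallower ones).
  depth <- node_depths(phy)
  ord <- order(depth[phy$edge[, 2L]], decreasing = TRUE)
  for (k in ord) {
    par <- phy$edge[k, 1L]; chd <- phy$edge[k, 2L]
    leaf_sets[[par]] <- c(leaf_sets[[par]], leaf_sets[[chd]])
  }
  leaf_sets <- lapply(leaf_sets, sort)
  branch_id <- rep(NA_character_, nnode)
  for (k in seq_len(nrow(phy$edge))) {
    chd <- phy$edge[k, 2L]
    branch_id[chd] <- make_branch_id(leaf_sets[[chd]])
  }
  # Singleton (unary) internal nodes share their only child's leaf set;
  # disambiguate deterministically by depth (deepest node keeps the plain
  # id, ancestors get #2, #3, ... walking rootward).
  dup_ids <- unique(branch_id[!is.na(branch_id)][duplicated(branch_id[!is.na(branch_id)])])
  for (id in dup_ids) {
    nodes <- which(!is.na(branch_id) & branch_id == id)
    nodes <- nodes[order(depth[nodes], decreasing = TRUE)]
    for (j in seq_along(nodes)[-1]) {
      branch_id[nodes[j]] <- sprintf("%s#%d", id, j)
    }
  }
  structure(
    list(phy = phy, branch_id = branch_id, leaf_sets = leaf_sets, root = root),
    class = "time_tree"
  )
}

# Number of edges between each node and the root.
node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  depth <- rep(NA_real_, nnode)
  depth[ntip + 1L] <- 0
  # Edges in a phylo object are not guaranteed parent-first; iterate until
  # all depths are assigned.
  repeat {
    known <- !is.na(depth[phy$edge[, 1L]]) & is.na(depth[phy$edge[, 2L]])
    if (!any(known)) break
    depth[phy$edge[known, 2L]] <- depth[phy$edge[known, 1L]] + 1
  }
  depth
}

make_branch_id <- function(leaves) {
  if (length(leaves) == 1L) return(leaves)
  sprintf("clade%02d_%s", length(leaves) %% 100L,
          poly_hash(paste(leaves, collapse = "|")))
}

#' @export
print.time_tree <- function(x, ...) {
  cat(sprintf("time_tree: %d leaves, %d branches, total length %.4g My\n",
              length(x$phy$tip.label), nrow(x$phy$edge), total_tree_length(x)))
  invisible(x)
}

#' Leaf names of a time tree
#' @param tree A `time_tree`.
#' @return Character vector of leaf names.
#' @export
tree_leaves <- function(tree) tree$phy$tip.label

#' Branch identifiers and lengths
#'
#' @param tree A `time_tree`.
#' @return `branch_ids`: character vector of all non-root branch identifiers.
#'   `branch_lengths`: numeric vector of branch lengths in My, named by
#'   branch identifier.
#' @export
branch_ids <- function(tree) {
  tree$branch_id[tree$phy$edge[, 2L]]
}

#' @rdname branch_ids
#' @export
branch_lengths <- function(tree) {
  len <- tree$phy$edge.length
  names(len) <- branch_ids(tree)
  len
}

#' Total branch length of the tree in My
#' @param tree A `time_tree`.
#' @return Sum of all branch lengths.
#' @export
total_tree_length <- function(tree) sum(tree$phy$edge.length)

#' Rescale a tree to a target total branch length
#'
#' Multiplies every branch length by a common factor so that the sum of
#' branch lengths equals `total_length`. Topology and branch identifiers are
#' unchanged.
#'
#' @param tree A `time_tree`.
#' @param total_length Target sum of branch lengths (My).
#' @return A rescaled `time_tree`.
#' @export
scale_tree <- function(tree, total_length) {
  stop_if_not_scalar_number(total_length, "total_length")
  cur <- total_tree_length(tree)
  if (cur <= 0) stop("cannot rescale a tree with zero total length", call. = FALSE)
  phy <- tree$phy
  phy$edge.length <- phy$edge.length * (total_length / cur)
  as_time_tree(phy)
}

#' Serialize a time tree to Newick
#' @param tree A `time_tree`.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @return Newick string (invisibly when writing to file).
#' @export
write_newick <- function(tree, file = NULL) {
  txt <- ape::write.tree(tree$phy)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Define a named clade
#'
#' A clade is declared either as the most recent common ancestor (MRCA) of
#' two or more named leaves, or as an explicit leaf list (the MRCA of that
#' list). `include_stem` controls whether the branch subtending the MRCA is
#' part of the clade's branch set; clade-level statistics in this package
#' default to crown clades (stem excluded).
#'
#' @param name Clade label used in reports and configuration maps.
#' @param leaves Character vector of leaf names.
#' @param type `"mrca"` (default) or `"leaf_list"`.
#' @param include_stem Logical; include the stem branch of the MRCA.
#' @return An object of class `clade_spec`.
#' @export
clade_spec <- function(name, leaves, type = c("mrca", "leaf_list"),
                       include_stem = FALSE) {
  type <- match.arg(type)
  if (!is.character(leaves) || length(leaves) < 1L) {
    stop("'leaves' must be a non-empty character vector", call. = FALSE)
  }
  if (type == "mrca" && length(leaves) < 2L) {
    stop("an MRCA clade needs at least two named leaves", call. = FALSE)
  }
  structure(list(name = name, leaves = unique(leaves), type = type,
                 include_stem = isTRUE(include_stem)),
            class = "clade_spec")
}

#' Resolve a clade specification on a tree
#'
#' Maps a [clade_spec()] to the concrete leaf set, branch set and summed
#' branch time of the clade on a given tree. The branch set contains every
#' branch in the subtree below the MRCA of the named leaves, plus the stem
#' branch when `include_stem = TRUE` (never for the root, which has no stem).
#'
#' @param tree A `time_tree`.
#' @param spec A `clade_spec`.
#' @return A list of class `resolved_clade`: `name`, `leaves` (all leaf names
#'   in the clade), `branches` (branch identifiers), `species` (alias for
#'   `leaves`), and `total_time_my` (sum of branch lengths in the branch set).
#' @export
resolve_clade <- function(tree, spec) {
  if (!inherits(spec, "clade_spec")) stop("'spec' must be a clade_spec", call. = FALSE)
  missing_leaves <- setdiff(spec$leaves, tree_leaves(tree))
  if (length(missing_leaves) > 0L) {
    stop("clade '", spec$name, "' references leaves absent from the tree: ",
         paste(missing_leaves, collapse = ", "), call. = FALSE)
  }
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  if (length(spec$leaves) == 1L) {
    mrca <- match(spec$leaves, phy$tip.label)
  } else {
    mrca <- ape::getMRCA(phy, spec$leaves)
  }
  # All nodes at or below the MRCA.
  below <- mrca
  repeat {
    kids <- phy$edge[phy$edge[, 1L] %in% below, 2L]
    new <- setdiff(kids, below)
    if (length(new) == 0L) break
    below <- c(below, new)
  }
  in_set <- phy$edge[, 2L] %in% setdiff(below, mrca)
  if (spec$include_stem && mrca != tree$root) {
    in_set <- in_set | phy$edge[, 2L] == mrca
  }
  br <- tree$branch_id[phy$edge[in_set, 2L]]
  leaves <- tree$leaf_sets[[mrca]]
  structure(
    list(name = spec$name, leaves = leaves, species = leaves,
         branches = br,
         total_time_my = sum(phy$edge.length[in_set])),
    class = "resolved_clade"
  )
}

#' @export
print.resolved_clade <- function(x, ...) {
  cat(sprintf("clade '%s': %d leaves, %d branches, %.4g My total time\n",
              x$name, length(x$leaves), length(x$branches), x$total_time_my))
  invisible(x)
}

# Internal: check that two resolved clades share no branch.
check_disjoint_clades <- function(a, b) {
  shared <- intersect(a$branches, b$branches)
  if (length(shared) > 0L) {
    stop(sprintf("clades '%s' and '%s' overlap on %d branch(es)",
                 a$name, b$name, length(shared)), call. = FALSE)
  }
  invisible(TRUE)
}

# Internal: per-branch clade membership lookup (first match wins; overlap is
# an error). Returns a named character vector branch_id -> clade name, with
# NA for branches in no clade.
branch_clade_map <- function(tree, clades) {
  ids <- branch_ids(tree)
  map <- rep(NA_character_, length(ids))
  names(map) <- ids
  for (cl in clades) {
    hit <- map[cl$branches]
    bad <- !is.na(hit)
    if (any(bad)) {
      stop("clades overlap on branches: ",
           paste(cl$branches[bad], collapse = ", "), call. = FALSE)
    }
    map[cl$branches] <- cl$name
  }
  map
}
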
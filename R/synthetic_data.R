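#' Configuration for the synthetic-data generator
#'
#' Bundles the parameters of the three simulators: gene-family counts
#' evolving by a per-copy linear birth-death (gain/loss) process along the
#' tree, per-branch dN/dS values with clade-specific location and dispersion
#' shifts, and species enzyme (EC) profiles derived from ancestral pathways
#' with clade-specific enzyme-loss probabilities.
#'
#' The defaults describe the study conditions used throughout the package's
#' tests: 2,000 families, a shifted-geometric root copy number
#' (`1 + Geom(0.5)`, mean 2), symmetric per-copy gain and loss rates of
#' 0.1 events per copy per My on a tree rescaled to 500 My of total branch
#' length, lognormal dN/dS noise around a purifying baseline of 0.2, and a
#' 30% enzyme-loss probability in the focal clade versus 0 in its sister.
#'
#' @param seed Integer master seed; every per-family, per-OG and per-species
#'   stream is derived from it by a counter, so results do not depend on
#'   iteration order.
#' @param n_families Number of gene families (OGs) to simulate.
#' @param root_count_law Either `list("geometric", p)` (root count
#'   `1 + Geom(p)`, support >= 1) or `list("fixed", k)`.
#' @param gain_rate,loss_rate Per-copy gain/loss rates (events per copy per
#'   My); family size 0 is absorbing (a gain needs a template copy).
#' @param clade_multipliers Named numeric vector: clade name -> multiplier
#'   applied to both rates on that clade's branches.
#' @param omega_base Baseline dN/dS.
#' @param omega_clade_shift Named numeric: clade -> multiplicative shift of
#'   the dN/dS location.
#' @param omega_noise_cv Coefficient of variation of the lognormal dN/dS
#'   noise (mean 1).
#' @param omega_cv_clade Named numeric: clade -> noise CV overriding
#'   `omega_noise_cv` on that clade's branches (dispersion shifts).
#' @param ec_loss_prob Named numeric in `[0, 1]`: clade -> probability that
#'   a non-outgroup species loses each ancestral enzyme independently.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_families = 2000L,
                       root_count_law = list("geometric", 0.5),
                       gain_rate = 0.1,
                       loss_rate = 0.1,
                       clade_multipliers = numeric(0),
                       omega_base = 0.2,
                       omega_clade_shift = numeric(0),
                       omega_noise_cv = 0.5,
                       omega_cv_clade = numeric(0),
                       ec_loss_prob = c(PAR = 0.3, ACU = 0)) {
  cfg <- list(seed = as.integer(seed), n_families = as.integer(n_families),
              root_count_law = root_count_law,
              gain_rate = gain_rate, loss_rate = loss_rate,
              clade_multipliers = clade_multipliers,
              omega_base = omega_base, omega_clade_shift = omega_clade_shift,
              omega_noise_cv = omega_noise_cv,
              omega_cv_clade = omega_cv_clade,
              ec_loss_prob = ec_loss_prob)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_if_not_scalar_number(cfg$gain_rate, "gain_rate")
  stop_if_not_scalar_number(cfg$loss_rate, "loss_rate")
  if (cfg$gain_rate < 0 || cfg$loss_rate < 0) {
    stop("gain/loss rates must be >= 0", call. = FALSE)
  }
  if (cfg$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  law <- cfg$root_count_law
  if (!is.list(law) || length(law) != 2L ||
      !law[[1]] %in% c("geometric", "fixed")) {
    stop("root_count_law must be list(\"geometric\"|\"fixed\", parameter)",
         call. = FALSE)
  }
  if (any(cfg$clade_multipliers <= 0)) {
    stop("clade multipliers must be > 0", call. = FALSE)
  }
  if (cfg$omega_base <= 0) stop("omega_base must be > 0", call. = FALSE)
  if (cfg$omega_noise_cv < 0 || any(cfg$omega_cv_clade < 0)) {
    stop("omega noise CV must be >= 0", call. = FALSE)
  }
  if (any(cfg$ec_loss_prob < 0 | cfg$ec_loss_prob > 1)) {
    stop("ec_loss_prob values must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

draw_root_count <- function(law) {
  if (law[[1]] == "fixed") return(as.integer(law[[2]]))
  1L + stats::rgeom(1L, prob = law[[2]])
}

# Linear birth-death on copy number along one branch (Gillespie stepping).
# Per-copy rates; 0 is absorbing because a gain needs a template copy.
sim_branch_bd <- function(n0, gain, loss, t) {
  n <- n0
  if (gain + loss == 0 || t == 0) return(n)
  elapsed <- 0
  repeat {
    if (n == 0L) return(0L)
    total <- n * (gain + loss)
    elapsed <- elapsed + stats::rexp(1L, rate = total)
    if (elapsed > t) return(n)
    if (stats::runif(1L) < gain / (gain + loss)) n <- n + 1L else n <- n - 1L
  }
}

# Per-branch rate multipliers from clade membership.
clade_multiplier_vec <- function(tree, clades, multipliers) {
  ids <- branch_ids(tree)
  mult <- rep(1, length(ids))
  names(mult) <- ids
  if (length(multipliers) == 0L) return(mult)
  unknown <- setdiff(names(multipliers), vapply(clades, `[[`, "", "name"))
  if (length(unknown) > 0L) {
    stop("clade_multipliers references unknown clade(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  map <- branch_clade_map(tree, clades)
  for (nm in names(multipliers)) {
    mult[!is.na(map) & map == nm] <- multipliers[[nm]]
  }
  mult
}

#' Simulate gene-family counts on a tree
#'
#' Evolves each family's copy number from a root draw down every branch by a
#' linear birth-death process with per-copy gain and loss rates (optionally
#' scaled per clade), stepping event by event. Returns both the leaf count
#' matrix and the true per-branch net changes (child minus parent), which
#' downstream reconstruction can be benchmarked against.
#'
#' @param tree A `time_tree`.
#' @param cfg A [sim_config()].
#' @param clades List of `resolved_clade` objects referenced by
#'   `cfg$clade_multipliers` (may be empty).
#' @return List with `counts` (integer matrix, OG x species) and `events`
#'   (data.frame `og_id`, `branch_id`, `delta` of true net changes).
#' @export
simulate_counts <- function(tree, cfg, clades = list()) {
  validate_sim_config(cfg)
  phy <- tree$phy
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  mult <- clade_multiplier_vec(tree, clades, cfg$clade_multipliers)
  # Edges ordered parents-first so each child's parent count exists.
  depth <- node_depths(phy)
  edge_ord <- order(depth[phy$edge[, 2L]])
  ids <- branch_ids(tree)
  og_ids <- sprintf("OG%06d", seq_len(cfg$n_families))
  counts <- matrix(0L, nrow = cfg$n_families, ncol = ntip,
                   dimnames = list(og_ids, phy$tip.label))
  nb <- nrow(phy$edge)
  delta <- matrix(0L, nrow = cfg$n_families, ncol = nb,
                  dimnames = list(og_ids, ids))
  for (f in seq_len(cfg$n_families)) {
    set.seed(derive_seed(cfg$seed, f))
    state <- integer(nnode)
    state[tree$root] <- draw_root_count(cfg$root_count_law)
    for (k in edge_ord) {
      par <- phy$edge[k, 1L]; chd <- phy$edge[k, 2L]
      m <- mult[[ids[k]]]
      state[chd] <- sim_branch_bd(state[par], cfg$gain_rate * m,
                                  cfg$loss_rate * m, phy$edge.length[k])
      delta[f, k] <- state[chd] - state[par]
    }
    counts[f, ] <- state[seq_len(ntip)]
  }
  events <- data.frame(
    og_id = rep(og_ids, each = nb),
    branch_id = rep(ids, times = cfg$n_families),
    delta = as.integer(t(delta)),
    stringsAsFactors = FALSE
  )
  list(counts = counts, events = events)
}

#' Simulate per-branch dN/dS values
#'
#' Draws `omega(og, branch) = omega_base * clade_shift * noise`, where the
#' noise is lognormal with mean 1 and coefficient of variation given by the
#' branch's clade (`omega_cv_clade`) or the global `omega_noise_cv`. Values
#' are strictly positive; output emulates a per-branch free-ratio table.
#'
#' @param tree A `time_tree`.
#' @param n_ogs Number of OGs.
#' @param cfg A [sim_config()].
#' @param clades List of `resolved_clade` objects referenced by the omega
#'   maps.
#' @return data.frame `og_id`, `branch_id`, `omega`.
#' @export
simulate_branch_rates <- function(tree, n_ogs, cfg, clades = list()) {
  validate_sim_config(cfg)
  if (n_ogs < 1L) stop("n_ogs must be >= 1", call. = FALSE)
  ids <- branch_ids(tree)
  shift <- rep(1, length(ids)); names(shift) <- ids
  cvs <- rep(cfg$omega_noise_cv, length(ids)); names(cvs) <- ids
  if (length(cfg$omega_clade_shift) > 0L || length(cfg$omega_cv_clade) > 0L) {
    map <- branch_clade_map(tree, clades)
    for (nm in names(cfg$omega_clade_shift)) {
      shift[!is.na(map) & map == nm] <- cfg$omega_clade_shift[[nm]]
    }
    for (nm in names(cfg$omega_cv_clade)) {
      cvs[!is.na(map) & map == nm] <- cfg$omega_cv_clade[[nm]]
    }
  }
  # Lognormal with mean 1 and CV c: sdlog^2 = log(1 + c^2).
  sdlog <- sqrt(log(1 + cvs^2))
  meanlog <- -sdlog^2 / 2
  og_ids <- sprintf("OG%06d", seq_len(n_ogs))
  nb <- length(ids)
  omega <- matrix(0, nrow = n_ogs, ncol = nb)
  for (f in seq_len(n_ogs)) {
    set.seed(derive_seed(cfg$seed, 500000L + f))
    noise <- ifelse(sdlog > 0,
                    stats::rlnorm(nb, meanlog = meanlog, sdlog = sdlog), 1)
    omega[f, ] <- cfg$omega_base * shift * noise
  }
  data.frame(
    og_id = rep(og_ids, each = nb),
    branch_id = rep(ids, times = n_ogs),
    omega = as.numeric(t(omega)),
    stringsAsFactors = FALSE
  )
}

#' Simulate species EC (enzyme) profiles
#'
#' Outgroup species carry the complete EC complement of the pathway table;
#' every other species independently drops each EC with its clade's
#' `ec_loss_prob` (species outside any configured clade keep everything).
#' This emulates genome-wide enzyme annotations downstream of ancestral
#' pathway loss.
#'
#' @param pathways Pathway table as returned by [sim_pathway_db()] or
#'   [read_pathway_db()].
#' @param tree A `time_tree`.
#' @param cfg A [sim_config()]; `cfg$ec_loss_prob` names must match clades.
#' @param clades List of `resolved_clade` objects.
#' @param outgroup_species Character vector of outgroup leaf names.
#' @return Named list: species -> character vector of retained ECs.
#' @export
simulate_ec_profiles <- function(pathways, tree, cfg, clades,
                                 outgroup_species) {
  validate_sim_config(cfg)
  if (nrow(pathways) == 0L) stop("pathway table is empty", call. = FALSE)
  clade_names <- vapply(clades, `[[`, "", "name")
  unknown <- setdiff(names(cfg$ec_loss_prob), clade_names)
  if (length(unknown) > 0L) {
    stop("ec_loss_prob references unknown clade(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  all_ecs <- sort(unique(unlist(strsplit(pathways$ecs, ";", fixed = TRUE))))
  species <- tree_leaves(tree)
  species_clade <- rep(NA_character_, length(species))
  names(species_clade) <- species
  for (cl in clades) species_clade[cl$species] <- cl$name
  profiles <- vector("list", length(species))
  names(profiles) <- species
  for (i in seq_along(species)) {
    sp <- species[i]
    set.seed(derive_seed(cfg$seed, 900000L + i))
    if (sp %in% outgroup_species) {
      profiles[[sp]] <- all_ecs
      next
    }
    cl <- species_clade[[sp]]
    p_loss <- if (!is.na(cl) && cl %in% names(cfg$ec_loss_prob)) {
      cfg$ec_loss_prob[[cl]]
    } else 0
    keep <- stats::runif(length(all_ecs)) >= p_loss
    profiles[[sp]] <- all_ecs[keep]
  }
  profiles
}

#' Build a synthetic ultrametric demonstration tree
#'
#' Assembles a time-calibrated tree with three named groups: an early
#' phytophagous outgroup (`OUT*`) and two sister clades (`PAR*`, `ACU*`)
#' mirroring the parasitoid/stinging split of wasp-waisted Hymenoptera.
#' Crown topologies within groups are random coalescent trees scaled to
#' fixed crown ages (root 281 My, sister split 243 My), so the tree is
#' ultrametric with My branch lengths. Optionally rescaled to a target total
#' branch length.
#'
#' @param n_out,n_par,n_acu Leaves per group.
#' @param seed Integer seed for the random crown topologies.
#' @param total_length If non-`NULL`, rescale so branch lengths sum to this.
#' @return A `time_tree`.
#' @export
sim_time_tree <- function(n_out = 8L, n_par = 12L, n_acu = 12L, seed = 1L,
                          total_length = NULL) {
  set.seed(derive_seed(seed, 42L))
  crown_newick <- function(n, prefix, crown_age) {
    stopifnot(n >= 2L)
    phy <- ape::rcoal(n)
    phy$tip.label <- sprintf("%s%02d", prefix, seq_len(n))
    node_h <- max(ape::node.depth.edgelength(phy))
    phy$edge.length <- phy$edge.length * (crown_age / node_h)
    sub(";$", "", ape::write.tree(phy))
  }
  out_txt <- crown_newick(n_out, "OUT", 150)
  par_txt <- crown_newick(n_par, "PAR", 180)
  acu_txt <- crown_newick(n_acu, "ACU", 170)
  newick <- sprintf("(%s:%g,(%s:%g,%s:%g):%g);",
                    out_txt, 281 - 150,
                    par_txt, 243 - 180, acu_txt, 243 - 170, 281 - 243)
  tr <- parse_newick(text = newick)
  if (!is.null(total_length)) tr <- scale_tree(tr, total_length)
  tr
}

#' Build a synthetic pathway definition table
#'
#' Generates a reference pathway table with synthetic EC numbers grouped
#' into superpathways, in the same dialect [read_pathway_db()] consumes.
#'
#' @param n_pathways Number of pathways.
#' @param n_super Number of superpathways (pathways assigned round-robin).
#' @param ecs_per_pathway Mean number of ECs per pathway (varies 6..14).
#' @param seed Integer seed.
#' @return data.frame `pathway_id`, `superpathway_id`, `name`,
#'   `has_reference`, `ecs` (semicolon-joined EC numbers).
#' @export
sim_pathway_db <- function(n_pathways = 20L, n_super = 5L,
                           ecs_per_pathway = 10L, seed = 1L) {
  set.seed(derive_seed(seed, 777L))
  sizes <- pmax(6L, pmin(14L, stats::rpois(n_pathways, ecs_per_pathway)))
  ec_pool <- sprintf("%d.%d.%d.%d",
                     sample(1:6, 400, replace = TRUE),
                     sample(1:20, 400, replace = TRUE),
                     sample(1:30, 400, replace = TRUE),
                     sample(1:99, 400, replace = TRUE))
  ec_pool <- unique(ec_pool)
  ecs <- character(n_pathways)
  offset <- 0L
  for (i in seq_len(n_pathways)) {
    take <- ec_pool[(offset + 1L):(offset + sizes[i])]
    offset <- offset + sizes[i]
    ecs[i] <- paste(take, collapse = ";")
  }
  data.frame(
    pathway_id = sprintf("pw%05d", seq_len(n_pathways)),
    superpathway_id = sprintf("sp%02d", ((seq_len(n_pathways) - 1L) %% n_super) + 1L),
    name = sprintf("synthetic pathway %d", seq_len(n_pathways)),
    has_reference = TRUE,
    ecs = ecs,
    stringsAsFactors = FALSE
  )
}
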
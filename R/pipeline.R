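# Configuration-driven end-to-end runner: simulate an input bundle, or run
# every analysis stage over a bundle on disk, writing deterministic TSV
# reports with provenance headers.

#' Pipeline run configuration
#'
#' Collects the input file paths, clade names, thresholds and seed of one
#' pipeline run. All input files live in `input_dir` under fixed names
#' (written by [simulate_dataset()], or supplied by the user in the same
#' dialects): `tree.nwk`, `gene_counts.tsv`, `branch_rates.tsv`,
#' `genome_rates.tsv`, `ec_profiles.tsv`, `pathways.tsv`, `clades.yaml`.
#'
#' @param input_dir Directory of the input bundle.
#' @param output_dir Directory for report TSVs (created if needed).
#' @param seed Integer seed for the simulation stages.
#' @param clade_a,clade_b Names of the two contrasted clades (must exist in
#'   `clades.yaml`; default the parasitoid-like `"PAR"` vs the
#'   aculeate-like `"ACU"` demo clades).
#' @param outgroup Name of the outgroup clade used for ancestral pathways
#'   and presence classes.
#' @param alpha Per-event significance threshold for rapid flags.
#' @param alpha_fdr FDR threshold for all scans.
#' @param presence_frac Presence threshold of [presence_classes()].
#' @param frac_a,frac_other Loss thresholds of [differential_loss()].
#' @param min_ecs Minimum retained ECs of [build_ancestral()].
#' @param top_frac,bottom_frac Decile fractions of [cov_contrast()].
#' @param sim A [sim_config()] used by [simulate_dataset()].
#' @param n_rate_ogs Number of OGs in the simulated dN/dS table.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(input_dir, output_dir,
                       seed = 1L,
                       clade_a = "PAR", clade_b = "ACU", outgroup = "OUT",
                       alpha = 0.05, alpha_fdr = 0.05,
                       presence_frac = 0.70,
                       frac_a = 0.20, frac_other = 0.02,
                       min_ecs = 5L,
                       top_frac = 0.10, bottom_frac = 0.10,
                       sim = sim_config(seed = seed),
                       n_rate_ogs = 500L) {
  cfg <- list(input_dir = input_dir, output_dir = output_dir,
              seed = as.integer(seed),
              clade_a = clade_a, clade_b = clade_b, outgroup = outgroup,
              alpha = alpha, alpha_fdr = alpha_fdr,
              presence_frac = presence_frac,
              frac_a = frac_a, frac_other = frac_other,
              min_ecs = as.integer(min_ecs),
              top_frac = top_frac, bottom_frac = bottom_frac,
              sim = sim, n_rate_ogs = as.integer(n_rate_ogs))
  for (nm in c("alpha", "alpha_fdr", "presence_frac", "frac_a", "frac_other",
               "top_frac", "bottom_frac")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v > 1) {
      stop(sprintf("threshold '%s' must lie in (0, 1]", nm), call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

input_paths <- function(config) {
  files <- c(tree = "tree.nwk", counts = "gene_counts.tsv",
             rates = "branch_rates.tsv", genome_rates = "genome_rates.tsv",
             ec = "ec_profiles.tsv", pathways = "pathways.tsv",
             clades = "clades.yaml")
  stats::setNames(file.path(config$input_dir, files), names(files))
}

config_provenance <- function(config) {
  # Hash the scientific configuration only; directory locations must not
  # affect the provenance of otherwise identical runs.
  sci <- config[setdiff(names(config), c("input_dir", "output_dir"))]
  hash <- poly_hash(paste(deparse(sci), collapse = ""))
  sprintf("cladevol %s; seed=%d; config_hash=%s",
          as.character(utils::packageVersion("cladevol")),
          config$seed, hash)
}

#' Simulate a complete input bundle on disk
#'
#' Builds the demonstration tree ([sim_time_tree()], rescaled to 500 My of
#' total branch length), simulates gene-family counts, per-branch dN/dS
#' values with substitution rates, species EC profiles and a pathway table,
#' and writes everything into `config$input_dir` in the exact dialects
#' [run_pipeline()] reads.
#'
#' @param config A [run_config()].
#' @return Invisibly, the named vector of written file paths.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "run_config")) stop("need a run_config", call. = FALSE)
  dir.create(config$input_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- input_paths(config)
  prov <- config_provenance(config)

  tree <- sim_time_tree(seed = config$seed, total_length = 500)
  write_newick(tree, paths["tree"])

  specs <- list(
    clade_spec("PAR", grep("^PAR", tree_leaves(tree), value = TRUE), "leaf_list"),
    clade_spec("ACU", grep("^ACU", tree_leaves(tree), value = TRUE), "leaf_list"),
    clade_spec("OUT", grep("^OUT", tree_leaves(tree), value = TRUE), "leaf_list")
  )
  write_clade_config(specs, paths["clades"])
  clades <- lapply(specs, resolve_clade, tree = tree)
  names(clades) <- vapply(clades, `[[`, "", "name")

  simc <- config$sim
  sim <- simulate_counts(tree, simc,
                         clades = clades[names(simc$clade_multipliers)])
  write_gene_counts(sim$counts, paths["counts"], prov)

  rate_clades <- clades[unique(c(names(simc$omega_clade_shift),
                                 names(simc$omega_cv_clade)))]
  rates <- simulate_branch_rates(tree, config$n_rate_ogs, simc,
                                 clades = rate_clades)
  # Substitution-rate layer: genome-wide background of 0.0025 aa
  # substitutions/site/My with lognormal branch effects; per-OG rates are
  # lognormal perturbations of the background on each branch.
  set.seed(derive_seed(simc$seed, 314159L))
  ids <- branch_ids(tree)
  genome_rates <- 0.0025 * stats::rlnorm(length(ids), -0.125, 0.5)
  names(genome_rates) <- ids
  rates$subst_rate <- genome_rates[rates$branch_id] *
    stats::rlnorm(nrow(rates), -0.02, 0.2)
  write_branch_rates(rates, paths["rates"], prov)
  write_genome_rates(genome_rates, paths["genome_rates"], prov)

  pathways <- sim_pathway_db(n_pathways = 20L, seed = simc$seed)
  write_pathway_db(pathways, paths["pathways"], prov)
  profiles <- simulate_ec_profiles(pathways, tree, simc, clades,
                                   outgroup_species = clades[[config$outgroup]]$species)
  write_ec_profiles(profiles, paths["ec"], prov)
  invisible(paths)
}

#' Run every analysis stage over an input bundle
#'
#' Executes, in dependency order: tree and clade resolution; parsimony
#' reconstruction, event derivation, rapid-event flagging and gain/loss
#' rates; the clade contrasts (rapid-event enrichment, rate, size,
#' presence/loss classes); the dN/dS contrasts (per-OG location, CoV with
#' decile intersection, normalized substitution rates); and the pathway
#' stage (ancestral reconstruction, coverage, PC and PC-CoV contrasts).
#' Every output table is written to `config$output_dir` with a provenance
#' comment line; reruns with an identical configuration and inputs are
#' byte-identical.
#'
#' @param config A [run_config()]; all input files must exist.
#' @return Invisibly, a run report: `manifest` (named vector of output
#'   files) and `summary` (named numeric key statistics).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("need a run_config", call. = FALSE)
  paths <- input_paths(config)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0L) {
    stop("missing input file(s): ", paste(missing_files, collapse = ", "),
         call. = FALSE)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  prov <- config_provenance(config)
  out <- function(name) file.path(config$output_dir, name)
  manifest <- character(0)
  emit <- function(df, name) {
    write_tsv_file(df, out(name), prov)
    manifest[[name]] <<- out(name)
    manifest
  }

  stage <- "tree"
  report <- tryCatch({
    tree <- parse_newick(file = paths["tree"])
    specs <- read_clade_config(paths["clades"])
    clades <- lapply(specs, resolve_clade, tree = tree)
    names(clades) <- vapply(clades, `[[`, "", "name")
    for (nm in c(config$clade_a, config$clade_b, config$outgroup)) {
      if (!nm %in% names(clades)) {
        stop("clade '", nm, "' not defined in clade config", call. = FALSE)
      }
    }
    ca <- clades[[config$clade_a]]; cb <- clades[[config$clade_b]]
    check_disjoint_clades(ca, cb)

    stage <- "family_dynamics"
    counts <- read_gene_counts(paths["counts"])
    recon <- reconstruct_counts(tree, counts)
    events <- compute_events(tree, recon)
    events <- flag_rapid_events(events, tree, alpha = config$alpha)
    emit(events, "events.tsv")
    summary <- c(
      global_gain_loss_rate = gain_loss_rate(events, tree),
      rate_clade_a = gain_loss_rate(events, tree, branches = ca$branches),
      rate_clade_b = gain_loss_rate(events, tree, branches = cb$branches)
    )

    stage <- "clade_contrast"
    enr <- rapid_enrichment(events, ca, cb, alpha_fdr = config$alpha_fdr)
    emit(enr, "rapid_enrichment.tsv")
    rc <- rate_contrast(events, tree, ca, cb, alpha_fdr = config$alpha_fdr)
    emit(rc, "rate_contrast.tsv")
    others <- setdiff(colnames(counts), ca$species)
    sc <- suppressWarnings(
      size_contrast(counts, ca$species, others, name_a = ca$name,
                    name_b = "other", alpha_fdr = config$alpha_fdr))
    emit(sc, "size_contrast.tsv")
    pcls <- presence_classes(counts,
                             test_species = c(ca$species, cb$species),
                             outgroup_species = clades[[config$outgroup]]$species,
                             presence_frac = config$presence_frac)
    emit(data.frame(og_id = c(pcls$missing, pcls$novel_core),
                    class = rep(c("missing", "novel_core"),
                                c(length(pcls$missing), length(pcls$novel_core))),
                    stringsAsFactors = FALSE),
         "presence_classes.tsv")
    dl <- differential_loss(counts, ca$species, others,
                            frac_a = config$frac_a,
                            frac_other = config$frac_other)
    emit(data.frame(og_id = dl, stringsAsFactors = FALSE),
         "differential_loss.tsv")
    summary <- c(summary,
                 n_rapid_enriched_a = sum(enr$decision & enr$direction == ca$name),
                 n_rate_higher_a = sum(rc$decision & rc$direction == ca$name),
                 n_size_larger_a = sum(sc$decision & sc$direction == ca$name),
                 n_missing = length(pcls$missing),
                 n_novel_core = length(pcls$novel_core),
                 n_differential_loss = length(dl))

    stage <- "rate_evolution"
    rates <- read_branch_rates(paths["rates"])
    dn <- og_dnds_contrast(rates, ca, cb, alpha_fdr = config$alpha_fdr)
    emit(dn, "dnds_contrast.tsv")
    cc <- cov_contrast(rates, ca, cb, top_frac = config$top_frac,
                       bottom_frac = config$bottom_frac)
    emit(cc$cov_table, "dnds_cov.tsv")
    emit(data.frame(og_id = cc$intersection, stringsAsFactors = FALSE),
         "dnds_cov_intersection.tsv")
    summary <- c(summary,
                 n_dnds_significant = sum(dn$decision),
                 cov_global_p = cc$global$p_value,
                 cov_fraction_a_greater = cc$fraction_a_greater,
                 n_cov_intersection = length(cc$intersection))
    if (!is.null(rates$subst_rate)) {
      genome_rates <- read_genome_rates(paths["genome_rates"])
      nr <- vapply(split(rates, rates$og_id), function(d) {
        normalized_rate(stats::setNames(d$subst_rate, d$branch_id),
                        genome_rates)
      }, 0)
      emit(data.frame(og_id = names(nr), normalized_rate = unname(nr),
                      stringsAsFactors = FALSE),
           "normalized_rates.tsv")
    }

    stage <- "pathway_coverage"
    db <- read_pathway_db(paths["pathways"])
    profiles <- read_ec_profiles(paths["ec"])
    og_sp <- clades[[config$outgroup]]$species
    anc <- build_ancestral(db, profiles[intersect(names(profiles), og_sp)],
                           min_ecs = config$min_ecs)
    pc <- coverage(profiles, anc)
    pcc <- pc_contrast(pc, ca$species, cb$species,
                       name_a = ca$name, name_b = cb$name,
                       alpha_fdr = config$alpha_fdr)
    emit(pcc$per_pathway, "pc_contrast.tsv")
    pcv <- pc_cov_contrast(pc, anc, ca$species, cb$species,
                           alpha_fdr = config$alpha_fdr)
    emit(pcv, "pc_cov_contrast.tsv")
    summary <- c(summary,
                 n_pathways_kept = length(anc$retained),
                 pc_global_p = pcc$global$p_value,
                 n_pc_lower_a = sum(pcc$per_pathway[[paste0("lower_in_", ca$name)]]),
                 n_pc_cov_higher_a = sum(pcv$decision))

    emit(data.frame(statistic = names(summary), value = unname(summary),
                    stringsAsFactors = FALSE),
         "run_summary.tsv")
    list(manifest = manifest, summary = summary)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(report)
}
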
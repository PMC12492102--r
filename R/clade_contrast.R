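# Family-level contrasts between two named clades (e.g. parasitoid wasps
# versus stinging aculeates): rapid-event enrichment, gain/loss-rate and
# family-size shifts, and presence/absence classification rules.

contrast_report <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("contrast_report", "data.frame")
  df
}

#' Rapid-event enrichment between two clades
#'
#' For every OG with at least one rapid event in either clade, builds the
#' 2x2 table of (rapid, non-rapid) branch counts per clade, applies the
#' Pearson chi-square test, and adjusts p-values across the tested OGs with
#' Benjamini-Hochberg. An OG is called enriched in clade A when the adjusted
#' p is below `alpha_fdr` and the odds ratio (A in the first row) exceeds 1;
#' the symmetric call is made for clade B with the reciprocal criterion.
#'
#' @param events Flagged event table from [flag_rapid_events()] (needs a
#'   `rapid` column).
#' @param clade_a,clade_b Disjoint `resolved_clade` objects.
#' @param alpha_fdr FDR threshold (default 0.05).
#' @param correct Yates continuity correction for the chi-square test.
#' @return A `contrast_report` data.frame with one row per tested OG:
#'   `og_id`, `rapid_a`, `n_a`, `rapid_b`, `n_b`, `statistic`, `odds_ratio`,
#'   `p`, `p_adj`, `direction` (clade name with the higher rapid fraction),
#'   `decision`.
#' @export
rapid_enrichment <- function(events, clade_a, clade_b, alpha_fdr = 0.05,
                             correct = FALSE) {
  check_disjoint_clades(clade_a, clade_b)
  if (length(clade_a$branches) < 1L || length(clade_b$branches) < 1L) {
    stop("both clades need at least one branch", call. = FALSE)
  }
  if (is.null(events$rapid)) {
    stop("'events' has no 'rapid' column; run flag_rapid_events() first",
         call. = FALSE)
  }
  ev_a <- events[events$branch_id %in% clade_a$branches, ]
  ev_b <- events[events$branch_id %in% clade_b$branches, ]
  n_a <- length(clade_a$branches)
  n_b <- length(clade_b$branches)
  rapid_a <- tapply(ev_a$rapid, ev_a$og_id, sum)
  rapid_b <- tapply(ev_b$rapid, ev_b$og_id, sum)
  ogs <- sort(union(names(rapid_a), names(rapid_b)))
  ra <- ifelse(is.na(rapid_a[ogs]), 0L, rapid_a[ogs])
  rb <- ifelse(is.na(rapid_b[ogs]), 0L, rapid_b[ogs])
  testable <- (ra + rb) > 0
  skipped <- sum(!testable)
  if (skipped > 0L) {
    log_skip(skipped, " OG(s) with no rapid events excluded from enrichment scan")
  }
  ogs <- ogs[testable]; ra <- ra[testable]; rb <- rb[testable]
  res <- lapply(seq_along(ogs), function(i) {
    tab <- matrix(c(ra[i], rb[i], n_a - ra[i], n_b - rb[i]), nrow = 2L)
    chi2_2x2(tab, correct = correct)
  })
  p <- vapply(res, `[[`, 0, "p_value")
  or <- vapply(res, `[[`, 0, "odds_ratio")
  stat <- vapply(res, `[[`, 0, "chi2")
  p_adj <- bh_fdr(p)
  direction <- ifelse(or > 1, clade_a$name, ifelse(or < 1, clade_b$name, "none"))
  contrast_report(data.frame(
    og_id = ogs, rapid_a = as.integer(ra), n_a = n_a,
    rapid_b = as.integer(rb), n_b = n_b,
    statistic = stat, odds_ratio = or, p = p, p_adj = p_adj,
    direction = direction,
    decision = p_adj < alpha_fdr & or != 1,
    stringsAsFactors = FALSE
  ))
}

# Per-OG per-branch turnover rates |delta| / t for one clade, as a named
# list og_id -> numeric vector (zero-length branches skipped).
per_branch_rates <- function(events, tree, clade) {
  len <- branch_lengths(tree)
  usable <- clade$branches[len[clade$branches] > 0]
  if (length(usable) < length(clade$branches)) {
    log_skip("clade '", clade$name, "': skipping ",
             length(clade$branches) - length(usable), " zero-length branch(es)")
  }
  ev <- events[events$branch_id %in% usable, ]
  rate <- abs(ev$delta) / len[ev$branch_id]
  split(rate, ev$og_id)
}

#' Per-family gain/loss-rate contrast between two clades
#'
#' For each OG, compares the per-branch turnover rates (`|delta| / branch
#' length`) across the branches of clade A against those of clade B with a
#' one-tailed Mann-Whitney U test (alternative: A greater by default),
#' followed by Benjamini-Hochberg adjustment over the tested OGs.
#'
#' @param events Event table (`og_id`, `branch_id`, `delta`).
#' @param tree A `time_tree`.
#' @param clade_a,clade_b Disjoint `resolved_clade` objects.
#' @param alternative Test direction for clade A (default `"greater"`).
#' @param alpha_fdr FDR threshold.
#' @param min_branches Minimum usable branches per clade for an OG to be
#'   tested (default 2).
#' @return A `contrast_report` with `og_id`, `n_a`, `n_b`, `statistic`
#'   (U for clade A), `p`, `p_adj`, `direction`, `decision`.
#' @export
rate_contrast <- function(events, tree, clade_a, clade_b,
                          alternative = "greater", alpha_fdr = 0.05,
                          min_branches = 2L) {
  check_disjoint_clades(clade_a, clade_b)
  rates_a <- per_branch_rates(events, tree, clade_a)
  rates_b <- per_branch_rates(events, tree, clade_b)
  ogs <- sort(intersect(names(rates_a), names(rates_b)))
  two_sample_scan(ogs, rates_a, rates_b, clade_a$name, clade_b$name,
                  alternative, alpha_fdr, min_n = min_branches)
}

#' Family-size contrast between two species groups
#'
#' For each OG, compares per-species gene counts between the species of one
#' group and those of another with a one-tailed Mann-Whitney U test
#' (default: first group larger), adjusted with Benjamini-Hochberg.
#'
#' @param counts Integer matrix, OG x species.
#' @param group_a,group_b Character vectors of species names (disjoint,
#'   each of size >= 2).
#' @param name_a,name_b Labels for the report's `direction` column.
#' @param alternative Test direction for group A (default `"greater"`).
#' @param alpha_fdr FDR threshold.
#' @return A `contrast_report` as in [rate_contrast()].
#' @export
size_contrast <- function(counts, group_a, group_b,
                          name_a = "A", name_b = "B",
                          alternative = "greater", alpha_fdr = 0.05) {
  check_species_groups(counts, group_a, group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("both species groups need >= 2 species", call. = FALSE)
  }
  ogs <- rownames(counts)
  vals_a <- lapply(ogs, function(og) counts[og, group_a])
  vals_b <- lapply(ogs, function(og) counts[og, group_b])
  names(vals_a) <- names(vals_b) <- ogs
  two_sample_scan(ogs, vals_a, vals_b, name_a, name_b, alternative,
                  alpha_fdr, min_n = 2L)
}

# Shared Mann-Whitney + BH scan over OGs.
two_sample_scan <- function(ogs, vals_a, vals_b, name_a, name_b,
                            alternative, alpha_fdr, min_n) {
  keep <- vapply(ogs, function(og) {
    length(vals_a[[og]]) >= min_n && length(vals_b[[og]]) >= min_n
  }, TRUE)
  if (any(!keep)) {
    log_skip(sum(!keep), " OG(s) below the per-group support floor skipped")
  }
  ogs <- ogs[keep]
  if (length(ogs) == 0L) stop("no testable OGs in scan", call. = FALSE)
  stat <- p <- numeric(length(ogs))
  n_a <- n_b <- integer(length(ogs))
  for (i in seq_along(ogs)) {
    a <- vals_a[[ogs[i]]]; b <- vals_b[[ogs[i]]]
    r <- mann_whitney(a, b, alternative = alternative)
    stat[i] <- r$statistic; p[i] <- r$p_value
    n_a[i] <- length(a); n_b[i] <- length(b)
  }
  p_adj <- bh_fdr(p)
  mu <- n_a * n_b / 2
  direction <- ifelse(stat > mu, name_a, ifelse(stat < mu, name_b, "none"))
  contrast_report(data.frame(
    og_id = ogs, n_a = n_a, n_b = n_b, statistic = stat,
    p = p, p_adj = p_adj, direction = direction,
    decision = p_adj < alpha_fdr,
    stringsAsFactors = FALSE
  ))
}

check_species_groups <- function(counts, group_a, group_b,
                                 warn_unused = TRUE) {
  both <- intersect(group_a, group_b)
  if (length(both) > 0L) {
    stop("species in both groups: ", paste(both, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(c(group_a, group_b), colnames(counts))
  if (length(unknown) > 0L) {
    stop("species absent from the count matrix: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  neither <- setdiff(colnames(counts), c(group_a, group_b))
  if (warn_unused && length(neither) > 0L) {
    warning(length(neither), " species in neither group are ignored",
            call. = FALSE)
  }
  invisible(TRUE)
}

#' Missing and novel-core family classification
#'
#' Presence of a family in a species means count >= 1. A family is
#' *missing* in the test group when it is present in strictly more than
#' `presence_frac` of outgroup species and absent from every test-group
#' species (the absence side is configurable via `test_absence_frac`:
#' a family qualifies when its test-group presence fraction is at most
#' that value). A *novel core* family is the mirror image: present in
#' strictly more than `presence_frac` of test-group species and absent from
#' all outgroup species.
#'
#' @param counts Integer matrix, OG x species.
#' @param test_species,outgroup_species Disjoint non-empty species sets.
#' @param presence_frac Retention threshold (strict `>`; default 0.70).
#' @param test_absence_frac Maximum presence fraction tolerated on the
#'   "absent" side (default 0: complete absence).
#' @return List with character vectors `missing` and `novel_core`.
#' @export
presence_classes <- function(counts, test_species, outgroup_species,
                             presence_frac = 0.70, test_absence_frac = 0) {
  if (length(test_species) == 0L || length(outgroup_species) == 0L) {
    stop("both species groups must be non-empty", call. = FALSE)
  }
  check_species_groups(counts, test_species, outgroup_species, warn_unused = FALSE)
  pres <- counts >= 1
  frac_test <- rowMeans(pres[, test_species, drop = FALSE])
  frac_out <- rowMeans(pres[, outgroup_species, drop = FALSE])
  missing <- rownames(counts)[frac_out > presence_frac &
                                frac_test <= test_absence_frac]
  novel <- rownames(counts)[frac_test > presence_frac &
                              frac_out <= test_absence_frac]
  list(missing = missing, novel_core = novel)
}

#' Differentially lost families between a clade and the remaining taxa
#'
#' A family is reported when it is lost (count 0) in strictly more than
#' `frac_a` of the clade's species while being lost in at most `frac_other`
#' of the other species — the asymmetric-loss screen used to find families
#' repeatedly dropped within one clade.
#'
#' @param counts Integer matrix, OG x species.
#' @param clade_species,other_species Disjoint non-empty species sets.
#' @param frac_a Loss-fraction threshold in the clade (strict `>`,
#'   default 0.20).
#' @param frac_other Maximum loss fraction tolerated elsewhere (inclusive
#'   `<=`, default 0.02).
#' @return Character vector of family identifiers.
#' @export
differential_loss <- function(counts, clade_species, other_species,
                              frac_a = 0.20, frac_other = 0.02) {
  if (length(clade_species) == 0L || length(other_species) == 0L) {
    stop("both species groups must be non-empty", call. = FALSE)
  }
  check_species_groups(counts, clade_species, other_species, warn_unused = FALSE)
  lost <- counts == 0
  frac_clade <- rowMeans(lost[, clade_species, drop = FALSE])
  frac_rest <- rowMeans(lost[, other_species, drop = FALSE])
  rownames(counts)[frac_clade > frac_a & frac_rest <= frac_other]
}
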
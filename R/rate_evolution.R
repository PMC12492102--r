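# dN/dS-based clade contrasts: per-OG location tests, coefficient-of-
# variation contrast with decile-intersection screening, and normalized
# evolutionary rates of OGs.

# Split a rates table (og_id, branch_id, omega) into og -> values for the
# branches of one clade.
clade_omega <- function(rates, clade) {
  sel <- rates[rates$branch_id %in% clade$branches, ]
  split(sel$omega, sel$og_id)
}

#' Per-OG dN/dS location contrast between two clades
#'
#' Two-tailed Mann-Whitney U test per OG on the per-branch dN/dS values of
#' the two clades, Benjamini-Hochberg adjusted across tested OGs. OGs with
#' fewer than `min_branches` values in either clade are skipped.
#'
#' @param rates data.frame `og_id`, `branch_id`, `omega` (omega > 0).
#' @param clade_a,clade_b Disjoint `resolved_clade` objects.
#' @param alpha_fdr FDR threshold.
#' @param min_branches Per-clade support floor (default 2).
#' @return A `contrast_report` (see [rate_contrast()]).
#' @export
og_dnds_contrast <- function(rates, clade_a, clade_b, alpha_fdr = 0.05,
                             min_branches = 2L) {
  check_disjoint_clades(clade_a, clade_b)
  check_omega(rates)
  va <- clade_omega(rates, clade_a)
  vb <- clade_omega(rates, clade_b)
  ogs <- sort(intersect(names(va), names(vb)))
  two_sample_scan(ogs, va, vb, clade_a$name, clade_b$name,
                  alternative = "two_sided", alpha_fdr = alpha_fdr,
                  min_n = min_branches)
}

check_omega <- function(rates) {
  if (!all(c("og_id", "branch_id", "omega") %in% names(rates))) {
    stop("rates table needs columns og_id, branch_id, omega", call. = FALSE)
  }
  if (any(!is.finite(rates$omega)) || any(rates$omega <= 0)) {
    stop("omega values must be finite and > 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' dN/dS dispersion (CoV) contrast between two clades
#'
#' Computes, per OG, the coefficient of variation of the per-branch dN/dS
#' values within each clade, then (i) a global one-tailed Mann-Whitney U
#' test across OGs (clade A's CoV distribution greater), (ii) the fraction
#' of OGs whose CoV is larger in clade A, and (iii) the OGs ranked in the
#' top `top_frac` by clade-A CoV *and* the bottom `bottom_frac` by clade-B
#' CoV — the candidates under conspicuously more variable selection in A.
#' Rank ties are resolved by OG identifier.
#'
#' @param rates data.frame `og_id`, `branch_id`, `omega`.
#' @param clade_a,clade_b Disjoint `resolved_clade` objects.
#' @param top_frac,bottom_frac Decile fractions (defaults 0.10).
#' @param min_branches Per-clade support floor for a CoV (default 2).
#' @return List: `global` (a `test_result`), `fraction_a_greater`,
#'   `intersection` (character vector of OG ids), `cov_table`
#'   (data.frame `og_id`, `cov_a`, `cov_b`).
#' @export
cov_contrast <- function(rates, clade_a, clade_b,
                         top_frac = 0.10, bottom_frac = 0.10,
                         min_branches = 2L) {
  check_disjoint_clades(clade_a, clade_b)
  check_omega(rates)
  va <- clade_omega(rates, clade_a)
  vb <- clade_omega(rates, clade_b)
  ogs <- sort(intersect(names(va), names(vb)))
  cov_a <- vapply(ogs, function(og) cov_value(va[[og]]), 0)
  cov_b <- vapply(ogs, function(og) cov_value(vb[[og]]), 0)
  ok <- !is.na(cov_a) & !is.na(cov_b) &
    vapply(ogs, function(og) length(va[[og]]) >= min_branches &&
             length(vb[[og]]) >= min_branches, TRUE)
  if (!any(ok)) stop("no OG passes the CoV support filter", call. = FALSE)
  if (any(!ok)) log_skip(sum(!ok), " OG(s) without a defined CoV skipped")
  ogs <- ogs[ok]; cov_a <- cov_a[ok]; cov_b <- cov_b[ok]
  global <- mann_whitney(cov_a, cov_b, alternative = "greater")
  n <- length(ogs)
  k_top <- ceiling(top_frac * n)
  k_bot <- ceiling(bottom_frac * n)
  top_a <- ogs[order(-cov_a, ogs)][seq_len(k_top)]
  bot_b <- ogs[order(cov_b, ogs)][seq_len(k_bot)]
  list(
    global = global,
    fraction_a_greater = mean(cov_a > cov_b),
    intersection = sort(intersect(top_a, bot_b)),
    cov_table = data.frame(og_id = ogs, cov_a = unname(cov_a),
                           cov_b = unname(cov_b), stringsAsFactors = FALSE)
  )
}

#' Normalized evolutionary rate of an OG
#'
#' The mean, over branches, of the OG's amino-acid substitution rate
#' divided by the genome-wide substitution rate on the same branch. A value
#' above 1 marks an OG evolving faster than the genomic background.
#' Branches with zero genome-wide rate are excluded (and logged).
#'
#' @param og_rates Numeric vector of per-branch OG substitution rates.
#' @param genome_rates Numeric vector of genome-wide rates on the same
#'   branches (aligned by position or by shared names).
#' @return The normalized rate (scalar).
#' @export
normalized_rate <- function(og_rates, genome_rates) {
  if (!is.null(names(og_rates)) && !is.null(names(genome_rates))) {
    shared <- intersect(names(og_rates), names(genome_rates))
    og_rates <- og_rates[shared]
    genome_rates <- genome_rates[shared]
  }
  if (length(og_rates) != length(genome_rates)) {
    stop("rate vectors must be aligned on the same branch set", call. = FALSE)
  }
  usable <- is.finite(genome_rates) & genome_rates > 0 & is.finite(og_rates)
  if (sum(usable) == 0L) stop("no usable branches (genome rate > 0)", call. = FALSE)
  if (any(!usable)) {
    log_skip(sum(!usable), " branch(es) with zero genome-wide rate excluded")
  }
  mean(og_rates[usable] / genome_rates[usable])
}
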
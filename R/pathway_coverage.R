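# Ancestral metabolic-pathway reconstruction from outgroup enzyme (EC)
# annotations, per-species pathway coverage, and clade contrasts of
# coverage and its variability.

ec_pattern <- "^[0-9]+\\.([0-9]+|-)\\.([0-9]+|-)\\.([0-9]+|-)$"

validate_ecs <- function(ecs, context) {
  bad <- ecs[!grepl(ec_pattern, ecs)]
  if (length(bad) > 0L) {
    stop(context, ": invalid EC number(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

validate_pathway_db <- function(db) {
  need <- c("pathway_id", "superpathway_id", "name", "has_reference", "ecs")
  miss <- setdiff(need, names(db))
  if (length(miss) > 0L) {
    stop("pathway table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(db$ecs))) stop("pathway with empty EC set", call. = FALSE)
  for (i in seq_len(nrow(db))) {
    validate_ecs(strsplit(db$ecs[i], ";", fixed = TRUE)[[1]],
                 paste0("pathway ", db$pathway_id[i]))
  }
  invisible(db)
}

#' Reconstruct ancestral pathways from outgroup EC annotations
#'
#' The ancestral complement of each reference pathway is the combination of
#' the outgroup species' EC sets (union by default, intersection or
#' majority-rule optional) intersected with the pathway's EC set. A pathway
#' is kept only when the retained set has at least `min_ecs` enzymes and,
#' by default, when the reference database flags a reference species for it.
#'
#' @param db Pathway table (`pathway_id`, `superpathway_id`, `name`,
#'   `has_reference`, `ecs` semicolon-joined).
#' @param outgroup_ecs Named list: outgroup species -> character vector of
#'   annotated ECs.
#' @param mode `"union"` (default), `"intersection"`, or `"majority"`
#'   (present in > 50% of outgroup species).
#' @param min_ecs Minimum retained ECs for a pathway to be kept (default 5).
#' @param require_reference Drop pathways without a reference species.
#' @return A list of class `ancestral_pathways`: `retained` (named list
#'   pathway_id -> EC vector), `db` (kept rows of `db`), `mode`,
#'   `outgroup_species`.
#' @export
build_ancestral <- function(db, outgroup_ecs,
                            mode = c("union", "intersection", "majority"),
                            min_ecs = 5L, require_reference = TRUE) {
  mode <- match.arg(mode)
  validate_pathway_db(db)
  if (length(outgroup_ecs) == 0L) stop("outgroup is empty", call. = FALSE)
  for (sp in names(outgroup_ecs)) {
    validate_ecs(outgroup_ecs[[sp]], paste0("species ", sp))
  }
  combined <- switch(mode,
    union = sort(unique(unlist(outgroup_ecs))),
    intersection = sort(Reduce(intersect, outgroup_ecs)),
    majority = {
      tab <- table(unlist(lapply(outgroup_ecs, unique)))
      sort(names(tab)[tab > length(outgroup_ecs) / 2])
    }
  )
  retained <- list()
  keep_row <- logical(nrow(db))
  for (i in seq_len(nrow(db))) {
    if (require_reference && !isTRUE(as.logical(db$has_reference[i]))) {
      log_skip("pathway ", db$pathway_id[i], " dropped: no reference species")
      next
    }
    ecs <- strsplit(db$ecs[i], ";", fixed = TRUE)[[1]]
    ret <- intersect(ecs, combined)
    if (length(ret) < min_ecs) {
      log_skip("pathway ", db$pathway_id[i], " dropped: only ",
               length(ret), " retained EC(s)")
      next
    }
    retained[[db$pathway_id[i]]] <- sort(ret)
    keep_row[i] <- TRUE
  }
  structure(
    list(retained = retained, db = db[keep_row, , drop = FALSE],
         mode = mode, outgroup_species = names(outgroup_ecs)),
    class = "ancestral_pathways"
  )
}

#' @export
print.ancestral_pathways <- function(x, ...) {
  cat(sprintf("ancestral pathways: %d kept (mode=%s, %d outgroup species)\n",
              length(x$retained), x$mode, length(x$outgroup_species)))
  invisible(x)
}

#' Pathway coverage of species
#'
#' Pathway coverage (PC) of a species for a pathway is the fraction of the
#' ancestral pathway's retained ECs annotated in that species.
#'
#' @param species_ecs Named list: species -> character vector of ECs.
#' @param ancestral An `ancestral_pathways` object.
#' @return Numeric matrix, pathway x species, values in `[0, 1]`.
#' @export
coverage <- function(species_ecs, ancestral) {
  if (length(ancestral$retained) == 0L) {
    stop("ancestral pathway set is empty", call. = FALSE)
  }
  pw <- names(ancestral$retained)
  species <- names(species_ecs)
  pc <- matrix(0, nrow = length(pw), ncol = length(species),
               dimnames = list(pw, species))
  for (s in species) {
    ecs <- species_ecs[[s]]
    for (p in pw) {
      ret <- ancestral$retained[[p]]
      pc[p, s] <- length(intersect(ecs, ret)) / length(ret)
    }
  }
  pc
}

#' Pathway-coverage contrast between two clades
#'
#' The global test pools every (pathway, species) PC value per clade and
#' applies a one-tailed Mann-Whitney U test (default alternative: clade A
#' lower). Each pathway is additionally tested on its per-species PC
#' vectors in both directions, with Benjamini-Hochberg adjustment per
#' direction across the tested pathways.
#'
#' @param pc Coverage matrix from [coverage()].
#' @param species_a,species_b Disjoint species sets (>= 2 each with
#'   coverage values).
#' @param name_a,name_b Clade labels for the report.
#' @param alternative Global/per-pathway direction for clade A
#'   (default `"less"`).
#' @param alpha_fdr FDR threshold.
#' @return List: `global` (`test_result`), `per_pathway` (a
#'   `contrast_report` with one row per tested pathway and direction calls
#'   `lower_in_a` / `lower_in_b`).
#' @export
pc_contrast <- function(pc, species_a, species_b,
                        name_a = "A", name_b = "B",
                        alternative = "less", alpha_fdr = 0.05) {
  species_a <- intersect(species_a, colnames(pc))
  species_b <- intersect(species_b, colnames(pc))
  if (length(intersect(species_a, species_b)) > 0L) {
    stop("species groups overlap", call. = FALSE)
  }
  if (length(species_a) < 2L || length(species_b) < 2L) {
    stop("both clades need >= 2 species with coverage values", call. = FALSE)
  }
  va <- as.numeric(pc[, species_a])
  vb <- as.numeric(pc[, species_b])
  global <- mann_whitney(va, vb, alternative = alternative)
  pw <- rownames(pc)
  p_less <- p_greater <- stat <- numeric(length(pw))
  for (i in seq_along(pw)) {
    a <- pc[pw[i], species_a]; b <- pc[pw[i], species_b]
    r_less <- mann_whitney(a, b, alternative = "less")
    r_greater <- mann_whitney(a, b, alternative = "greater")
    stat[i] <- r_less$statistic
    p_less[i] <- r_less$p_value
    p_greater[i] <- r_greater$p_value
  }
  adj_less <- bh_fdr(p_less)
  adj_greater <- bh_fdr(p_greater)
  per_pathway <- contrast_report(data.frame(
    pathway_id = pw, n_a = length(species_a), n_b = length(species_b),
    statistic = stat,
    p_lower_a = p_less, p_adj_lower_a = adj_less,
    p_lower_b = p_greater, p_adj_lower_b = adj_greater,
    lower_in_a = adj_less < alpha_fdr,
    lower_in_b = adj_greater < alpha_fdr,
    stringsAsFactors = FALSE
  ))
  names(per_pathway) <- sub("_a$", paste0("_", name_a), names(per_pathway))
  names(per_pathway) <- sub("_b$", paste0("_", name_b), names(per_pathway))
  list(global = global, per_pathway = per_pathway)
}

#' Superpathway-level contrast of coverage variability
#'
#' For every kept pathway and each clade, computes the coefficient of
#' variation of PC across the clade's species; then, per superpathway with
#' at least `min_pathways` pathways, applies a one-tailed Mann-Whitney U
#' test across its pathways' CoV values (clade A more variable), adjusted
#' with Benjamini-Hochberg across superpathways.
#'
#' @param pc Coverage matrix from [coverage()].
#' @param ancestral An `ancestral_pathways` object (provides superpathway
#'   membership of the kept pathways).
#' @param species_a,species_b Disjoint species sets.
#' @param alpha_fdr FDR threshold.
#' @param min_pathways Minimum pathways per superpathway (default 2).
#' @return A `contrast_report`: `superpathway_id`, `n_pathways`,
#'   `statistic`, `p`, `p_adj`, `decision` plus a `cov_table` attribute
#'   (pathway-level CoV values per clade).
#' @export
pc_cov_contrast <- function(pc, ancestral, species_a, species_b,
                            alpha_fdr = 0.05, min_pathways = 2L) {
  db <- ancestral$db
  pw <- intersect(rownames(pc), db$pathway_id)
  cov_a <- vapply(pw, function(p) cov_value(pc[p, species_a]), 0)
  cov_b <- vapply(pw, function(p) cov_value(pc[p, species_b]), 0)
  super <- db$superpathway_id[match(pw, db$pathway_id)]
  ok <- !is.na(cov_a) & !is.na(cov_b)
  if (any(!ok)) log_skip(sum(!ok), " pathway(s) without defined CoV skipped")
  pw <- pw[ok]; cov_a <- cov_a[ok]; cov_b <- cov_b[ok]; super <- super[ok]
  sp_ids <- sort(unique(super))
  rows <- list()
  for (sp in sp_ids) {
    idx <- super == sp
    if (sum(idx) < min_pathways) {
      log_skip("superpathway ", sp, " skipped: fewer than ", min_pathways,
               " pathways")
      next
    }
    r <- mann_whitney(cov_a[idx], cov_b[idx], alternative = "greater")
    rows[[sp]] <- data.frame(superpathway_id = sp, n_pathways = sum(idx),
                             statistic = r$statistic, p = r$p_value,
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    stop("no superpathway passes the pathway-count floor", call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_fdr(out$p)
  out$decision <- out$p_adj < alpha_fdr
  out <- contrast_report(out)
  attr(out, "cov_table") <- data.frame(
    pathway_id = pw, superpathway_id = super,
    cov_a = unname(cov_a), cov_b = unname(cov_b), stringsAsFactors = FALSE)
  out
}
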
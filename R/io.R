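# Readers and writers for the pipeline's plain-text dialects. All tables
# are tab-separated with a header; writers may prepend '#'-prefixed
# provenance comment lines, which every reader skips.

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

write_tsv_file <- function(df, path, provenance = NULL) {
  con <- file(path, open = "wb") # binary mode: stable line endings
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n")
  invisible(path)
}

#' Read and write gene-family count matrices
#'
#' The count dialect is the orthology-inference `GeneCount` TSV: a first
#' column `Orthogroup`, one integer column per species, and an optional
#' trailing `Total` column, which is ignored on read and re-derived on
#' write.
#'
#' @param path File path.
#' @return `read_gene_counts`: integer matrix OG x species.
#' @export
read_gene_counts <- function(path) {
  df <- read_tsv_file(path)
  if (names(df)[1] != "Orthogroup") {
    stop("count table must have 'Orthogroup' as its first column", call. = FALSE)
  }
  df <- df[, names(df) != "Total", drop = FALSE]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$Orthogroup
  m
}

#' @rdname read_gene_counts
#' @param counts Integer matrix OG x species.
#' @param provenance Optional provenance comment string.
#' @export
write_gene_counts <- function(counts, path, provenance = NULL) {
  df <- data.frame(Orthogroup = rownames(counts), counts,
                   Total = rowSums(counts), check.names = FALSE)
  write_tsv_file(df, path, provenance)
}

#' Read and write per-branch dN/dS tables
#'
#' Columns: `og_id`, `branch_id`, `omega`, optional `subst_rate`.
#' @param path File path.
#' @return data.frame.
#' @export
read_branch_rates <- function(path) {
  df <- read_tsv_file(path)
  check_omega(df)
  df
}

#' @rdname read_branch_rates
#' @param rates data.frame to write.
#' @param provenance Optional provenance comment string.
#' @export
write_branch_rates <- function(rates, path, provenance = NULL) {
  write_tsv_file(rates, path, provenance)
}

#' Read and write genome-wide branch rates
#'
#' Columns: `branch_id`, `rate` (e.g. amino-acid substitutions per site per
#' My averaged over the genome).
#' @param path File path.
#' @return Named numeric vector (names = branch ids).
#' @export
read_genome_rates <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("branch_id", "rate") %in% names(df))) {
    stop("genome rate table needs columns branch_id, rate", call. = FALSE)
  }
  stats::setNames(df$rate, df$branch_id)
}

#' @rdname read_genome_rates
#' @param rates Named numeric vector.
#' @param provenance Optional provenance comment string.
#' @export
write_genome_rates <- function(rates, path, provenance = NULL) {
  write_tsv_file(data.frame(branch_id = names(rates), rate = unname(rates)),
                 path, provenance)
}

#' Read and write species EC annotation tables
#'
#' One `(species, ec)` pair per line.
#' @param path File path.
#' @return Named list: species -> character vector of ECs.
#' @export
read_ec_profiles <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("species", "ec") %in% names(df))) {
    stop("EC table needs columns species, ec", call. = FALSE)
  }
  validate_ecs(df$ec, "EC table")
  split(df$ec, df$species)
}

#' @rdname read_ec_profiles
#' @param profiles Named list species -> EC vector.
#' @param provenance Optional provenance comment string.
#' @export
write_ec_profiles <- function(profiles, path, provenance = NULL) {
  df <- data.frame(
    species = rep(names(profiles), lengths(profiles)),
    ec = unlist(profiles, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv_file(df, path, provenance)
}

#' Read and write pathway definition tables
#'
#' Columns: `pathway_id`, `superpathway_id`, `name`, `has_reference`
#' (logical), `ecs` (semicolon-joined EC numbers).
#' @param path File path.
#' @return data.frame.
#' @export
read_pathway_db <- function(path) {
  df <- read_tsv_file(path)
  df$has_reference <- as.logical(df$has_reference)
  validate_pathway_db(df)
  df
}

#' @rdname read_pathway_db
#' @param db Pathway data.frame.
#' @param provenance Optional provenance comment string.
#' @export
write_pathway_db <- function(db, path, provenance = NULL) {
  write_tsv_file(db, path, provenance)
}

#' Read and write branch event tables
#'
#' Columns: `og_id`, `branch_id`, `delta`, optional `p_event`, `rapid`.
#' An externally produced event/flag table in this dialect can stand in for
#' the built-in parsimony reconstruction.
#' @param path File path.
#' @return data.frame.
#' @export
read_events <- function(path) {
  df <- read_tsv_file(path)
  if (!all(c("og_id", "branch_id", "delta") %in% names(df))) {
    stop("event table needs columns og_id, branch_id, delta", call. = FALSE)
  }
  if (!is.null(df$rapid)) df$rapid <- as.logical(df$rapid)
  df
}

#' @rdname read_events
#' @param events data.frame to write.
#' @param provenance Optional provenance comment string.
#' @export
write_events <- function(events, path, provenance = NULL) {
  write_tsv_file(events, path, provenance)
}

#' Read and write clade configuration files
#'
#' YAML with a top-level `clades` list; each entry has `name`,
#' `type` (`mrca` or `leaf_list`), `leaves`, and optional `include_stem`.
#' @param path File path.
#' @return List of [clade_spec()] objects.
#' @export
read_clade_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$clades)) stop("clade config needs a 'clades' list", call. = FALSE)
  lapply(cfg$clades, function(x) {
    clade_spec(name = x$name, leaves = unlist(x$leaves),
               type = x$type %||% "mrca",
               include_stem = isTRUE(x$include_stem))
  })
}

#' @rdname read_clade_config
#' @param specs List of `clade_spec` objects.
#' @export
write_clade_config <- function(specs, path) {
  yaml::write_yaml(list(clades = lapply(specs, function(s) {
    list(name = s$name, type = s$type, leaves = as.list(s$leaves),
         include_stem = s$include_stem)
  })), path)
  invisible(path)
}
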
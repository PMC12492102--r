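# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Deterministic 31-polynomial string hash, reported as 8 hex digits.
# Used only to build compact stable identifiers; not cryptographic.
poly_hash <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Derive a per-unit seed below 2^31 from a base seed and a unit counter, so
# per-family / per-species draws are reproducible independent of iteration
# order.
derive_seed <- function(seed, i) {
  ((seed %% 2147483647) * 48271 + i) %% 2147483647
}

# Skip/exclusion logging, silenced unless options(cladevol.verbose = TRUE).
log_skip <- function(...) {
  if (isTRUE(getOption("cladevol.verbose", FALSE))) {
    message("[cladevol] ", ...)
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
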
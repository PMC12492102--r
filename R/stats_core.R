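#' Mann-Whitney U test with exact enumeration for small samples
#'
#' Computes the Mann-Whitney U statistic for sample `a` (with midranks for
#' ties) and its p-value. When the combined sample size is at most
#' `exact_cutoff` the p-value is exact: every one of the
#' `choose(n_a + n_b, n_a)` group labelings of the pooled values is
#' enumerated and the permutation tail probability is reported (ties are
#' handled exactly by this route). Larger samples use the normal
#' approximation with tie correction and a 0.5 continuity correction, the
#' standard choice for the branch- and species-level contrasts in this
#' package.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two_sided"`, `"greater"` (a tends larger) or
#'   `"less"`.
#' @param exact_cutoff Maximum `length(a) + length(b)` for exact enumeration.
#' @return A list of class `test_result`: `statistic` (U for sample `a`),
#'   `p_value`, `alternative`, `method` (`"exact"` or `"normal_approx"`).
#' @examples
#' mann_whitney(c(5, 6, 7), c(1, 2, 3), alternative = "greater")$p_value # 0.05
#' @export
mann_whitney <- function(a, b,
                         alternative = c("two_sided", "greater", "less"),
                         exact_cutoff = 12L) {
  alternative <- match.arg(alternative)
  if (length(a) < 1L || length(b) < 1L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  if (anyNA(a) || anyNA(b)) stop("samples must not contain NA", call. = FALSE)
  na <- length(a); nb <- length(b); n <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2

  if (n <= exact_cutoff) {
    combos <- utils::combn(n, na)
    u_all <- apply(combos, 2L, function(idx) {
      sum(r[idx]) - na * (na + 1) / 2
    })
    eps <- 1e-9
    p <- switch(alternative,
      greater   = mean(u_all >= u_obs - eps),
      less      = mean(u_all <= u_obs + eps),
      two_sided = mean(abs(u_all - mu) >= abs(u_obs - mu) - eps)
    )
    method <- "exact"
  } else {
    tie_tab <- table(pooled)
    tie_term <- sum(tie_tab^3 - tie_tab)
    sigma2 <- na * nb / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) {
      # Every pooled value identical: no evidence either way.
      p <- 1
    } else {
      sigma <- sqrt(sigma2)
      p <- switch(alternative,
        greater   = stats::pnorm((u_obs - mu - 0.5) / sigma, lower.tail = FALSE),
        less      = stats::pnorm((u_obs - mu + 0.5) / sigma),
        two_sided = min(1, 2 * stats::pnorm((abs(u_obs - mu) - 0.5) / sigma,
                                            lower.tail = FALSE))
      )
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u_obs, p_value = min(1, max(0, p)),
                 alternative = alternative, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, p = %.4g (%s)\n",
              x$method, x$statistic, x$p_value, x$alternative))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table with odds ratio
#'
#' Pearson chi-square with one degree of freedom and no Yates continuity
#' correction by default (the usual choice for enrichment scans; a flag
#' enables it). The odds ratio is `ad/bc`; when any cell is zero the
#' Haldane-Anscombe correction adds 0.5 to every cell before forming the
#' ratio. Tables with a zero row or column total carry no information and
#' return `chi2 = 0`, `p = 1` with `degenerate = TRUE`.
#'
#' @param tab 2x2 matrix of non-negative counts; rows are groups, columns
#'   are outcome states. The odds ratio is oriented so that values above 1
#'   mean the first row is enriched for the first column.
#' @param correct Apply the Yates continuity correction.
#' @return List: `chi2`, `p_value`, `odds_ratio`, `expected_lt5` (any
#'   expected count below 5), `degenerate`.
#' @examples
#' chi2_2x2(matrix(c(10, 2, 90, 98), nrow = 2)) # chi2 = 5.6738, OR = 5.4444
#' @export
chi2_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("'tab' must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("'tab' must contain non-negative integer counts", call. = FALSE)
  }
  total <- sum(tab)
  if (total < 1) stop("table total must be >= 1", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p_value = 1, odds_ratio = odds_ratio_2x2(tab),
                expected_lt5 = TRUE, degenerate = TRUE))
  }
  expected <- outer(rowSums(tab), colSums(tab)) / total
  res <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(res$statistic), p_value = unname(res$p.value),
       odds_ratio = odds_ratio_2x2(tab),
       expected_lt5 = any(expected < 5), degenerate = FALSE)
}

odds_ratio_2x2 <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a vector of p-values, preserving input order.
#' Thin validated wrapper around [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("'p' must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Coefficient of variation
#'
#' Sample standard deviation (denominator `n - 1`) divided by the mean.
#' Undefined for fewer than two values or a zero mean; those cases return
#' `NA` and log the reason (see `options(cladevol.verbose = TRUE)`).
#'
#' @param values Numeric vector.
#' @return The coefficient of variation, or `NA_real_` when undefined.
#' @examples
#' cov_value(c(1, 2, 3)) # 0.5
#' @export
cov_value <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) {
    log_skip("CoV undefined: fewer than 2 values")
    return(NA_real_)
  }
  m <- mean(values)
  if (m == 0) {
    log_skip("CoV undefined: mean is zero")
    return(NA_real_)
  }
  stats::sd(values) / m
}
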
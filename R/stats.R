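# 2x2 stratum comparisons: exact two-sided hypergeometric test and
# Pearson chi-square.

#' Construct a 2x2 contingency table
#'
#' Rows are the two strata, columns flagged / not flagged.
#'
#' @param a,b Flagged and not-flagged counts in stratum 1.
#' @param c,d Flagged and not-flagged counts in stratum 2.
#' @param labels Character vector of the two stratum names.
#' @return An integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d, labels = c("stratum1", "stratum2")) {
  counts <- c(a, b, c, d)
  if (!all(vapply(counts, is_count, logical(1)))) {
    af_stop("contingency table counts must be non-negative integers",
            "af_validation_error")
  }
  m <- matrix(as.integer(counts), nrow = 2, byrow = TRUE,
              dimnames = list(labels, c("flagged", "not_flagged")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

check_margins <- function(t) {
  if (any(rowSums(t) == 0L) || any(colSums(t) == 0L)) {
    af_stop("degenerate 2x2 table: a row or column margin is zero",
            "af_degenerate_table")
  }
  invisible(TRUE)
}

#' Build a 2x2 table from classified variants and a stratifying predicate
#'
#' @param classified Output of [flag_variants()].
#' @param stratifier Either a logical vector over the rows of `classified`
#'   or a function of the classified `data.frame` returning one; it must
#'   be total (no `NA`). `TRUE` selects stratum 1.
#' @param labels Stratum names for the table rows.
#' @return A `contingency_2x2`; its four cells sum to `nrow(classified)`.
#' @export
build_table <- function(classified, stratifier, labels = c("stratum1", "stratum2")) {
  s <- if (is.function(stratifier)) stratifier(classified) else stratifier
  if (!is.logical(s) || length(s) != nrow(classified) || anyNA(s)) {
    af_stop("stratifier must yield one non-NA logical per variant",
            "af_precondition_error")
  }
  f <- classified$flagged
  contingency_2x2(sum(s & f), sum(s & !f), sum(!s & f), sum(!s & !f),
                  labels = labels)
}

#' Exact two-sided test for a 2x2 table
#'
#' Conditional on fixed margins, the first cell follows a hypergeometric
#' distribution. The two-sided p-value is the sum of the point
#' probabilities of all tables no more probable than the observed one
#' (the point-probability / minimum-likelihood convention of mainstream
#' statistical software), with ties included up to a relative tolerance.
#' Accumulation is done in log space.
#'
#' @param t A `contingency_2x2` (or plain 2x2 matrix of counts).
#' @param rel_tol Relative tolerance for counting a point probability as
#'   tied with the observed one.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_two_sided(contingency_2x2(12, 43, 6, 379))
#' @export
fisher_exact_two_sided <- function(t, rel_tol = 1e-12) {
  stopifnot(is.matrix(t), all(dim(t) == c(2L, 2L)))
  check_margins(t)
  r1 <- sum(t[1, ]); r2 <- sum(t[2, ]); k <- sum(t[, 1])
  support <- max(0L, k - r2):min(k, r1)
  logp <- stats::dhyper(support, r1, r2, k, log = TRUE)
  logp0 <- stats::dhyper(t[1, 1], r1, r2, k, log = TRUE)
  keep <- logp <= logp0 + log1p(rel_tol)
  min(1, exp(logsumexp(logp[keep])))
}

#' Pearson chi-square test for a 2x2 table
#'
#' @param t A `contingency_2x2` (or plain 2x2 matrix of counts).
#' @param yates Apply the Yates continuity correction.
#' @return List with `statistic` and `p_value` (chi-square reference
#'   distribution, 1 degree of freedom).
#' @examples
#' chi_square(contingency_2x2(1, 112, 17, 287))
#' @export
chi_square <- function(t, yates = FALSE) {
  stopifnot(is.matrix(t), all(dim(t) == c(2L, 2L)))
  check_margins(t)
  expected <- outer(rowSums(t), colSums(t)) / sum(t)
  dev <- abs(t - expected)
  if (yates) dev <- pmax(0, dev - 0.5)
  statistic <- sum(dev^2 / expected)
  list(statistic = statistic,
       p_value = stats::pchisq(statistic, df = 1L, lower.tail = FALSE))
}

#' Compare the flagging proportion between two strata
#'
#' Counts flagged variants per stratum, forms the 2x2 table, and reports
#' the stratum proportions with both the exact and the chi-square
#' p-value. When only the flagged variants are at hand (as for a
#' published flagged-variant table whose full registry is not packaged),
#' the stratum denominators can be supplied via `totals_override`.
#'
#' @param classified Output of [flag_variants()].
#' @param stratifier Logical vector or predicate function; `TRUE` selects
#'   stratum 1 (see [build_table()]).
#' @param totals_override Optional numeric pair: total sizes of stratum 1
#'   and stratum 2, replacing the observed sizes.
#' @param labels Stratum names.
#' @param yates Use the Yates correction in the chi-square test.
#' @return A `stratum_comparison`: list with the table, stratum labels,
#'   `proportion1`, `proportion2`, `p_chi2` and `p_fisher`.
#' @export
compare_strata <- function(classified, stratifier, totals_override = NULL,
                           labels = c("stratum1", "stratum2"), yates = FALSE) {
  t <- build_table(classified, stratifier, labels = labels)
  if (!is.null(totals_override)) {
    stopifnot(is.numeric(totals_override), length(totals_override) == 2L)
    flagged <- t[, "flagged"]
    if (any(totals_override < flagged)) {
      af_stop("totals_override smaller than the observed flagged counts",
              "af_validation_error")
    }
    t <- contingency_2x2(flagged[1], totals_override[1] - flagged[1],
                         flagged[2], totals_override[2] - flagged[2],
                         labels = labels)
  }
  n1 <- sum(t[1, ]); n2 <- sum(t[2, ])
  structure(list(
    table = t,
    label1 = labels[1], label2 = labels[2],
    proportion1 = t[1, 1] / n1,
    proportion2 = t[2, 1] / n2,
    p_chi2 = chi_square(t, yates = yates)$p_value,
    p_fisher = fisher_exact_two_sided(t)
  ), class = "stratum_comparison")
}

format_pct <- function(p) sprintf("%.1f%%", 100 * p)

#' @export
print.stratum_comparison <- function(x, ...) {
  cat(sprintf("%s: %d/%d (%s) vs %s: %d/%d (%s)\n",
              x$label1, x$table[1, 1], sum(x$table[1, ]), format_pct(x$proportion1),
              x$label2, x$table[2, 1], sum(x$table[2, ]), format_pct(x$proportion2)))
  cat(sprintf("  exact two-sided p = %.4g, chi-square p = %.4g\n",
              x$p_fisher, x$p_chi2))
  invisible(x)
}
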
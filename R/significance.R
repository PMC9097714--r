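#' Relative risk with a Katz log-normal confidence interval
#'
#' `RR = (kExp/nExp) / (kBg/nBg)`, the probability of the outcome event in
#' the exposed group divided by its probability in the matched background
#' group. The 95% interval uses the log-RR normal approximation
#' `exp(log RR +/- z * sqrt(1/kExp - 1/nExp + 1/kBg - 1/nBg))`. When any of
#' the four cells (`kExp`, `nExp - kExp`, `kBg`, `nBg - kBg`) is zero, the
#' Haldane-Anscombe correction adds 0.5 to all four cells for the interval
#' (and for the point estimate when `kBg = 0`); with
#' `continuity = FALSE` and `kBg = 0` the point estimate is `Inf`.
#'
#' @param kExp,nExp outcome count and size of the exposed group.
#' @param kBg,nBg outcome count and size of the background group.
#' @param conf confidence level.
#' @param continuity apply the 0.5 zero-cell correction.
#' @return list with `rr`, `ci_low`, `ci_high`.
#' @examples relativeRisk(30, 100, 10, 100)
#' @export
relativeRisk <- function(kExp, nExp, kBg, nBg, conf = 0.95,
                         continuity = TRUE) {
  if (nExp <= 0 || nBg <= 0) stop("empty group", call. = FALSE)
  if (kExp < 0 || kBg < 0 || kExp > nExp || kBg > nBg) {
    stop("invalid counts", call. = FALSE)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  anyZero <- kExp == 0 || kBg == 0 || kExp == nExp || kBg == nBg
  rr <- if (kBg == 0) {
    if (continuity) {
      ((kExp + 0.5) / (nExp + 1)) / ((kBg + 0.5) / (nBg + 1))
    } else {
      Inf
    }
  } else {
    (kExp / nExp) / (kBg / nBg)
  }
  if (anyZero && continuity) {
    k1 <- kExp + 0.5; n1 <- nExp + 1
    k2 <- kBg + 0.5; n2 <- nBg + 1
  } else {
    k1 <- kExp; n1 <- nExp
    k2 <- kBg; n2 <- nBg
  }
  if (k1 == 0 || k2 == 0) {
    return(list(rr = rr, ci_low = NaN, ci_high = NaN))
  }
  se <- sqrt(1 / k1 - 1 / n1 + 1 / k2 - 1 / n2)
  center <- log((k1 / n1) / (k2 / n2))
  list(rr = rr, ci_low = exp(center - z * se), ci_high = exp(center + z * se))
}

#' Fisher's exact association test for a matched pair
#'
#' Two-sided Fisher's exact test on the 2x2 table of outcome presence in
#' the exposed and background groups, using the probability-mass rule (the
#' p-value sums the probabilities of all tables with the observed margins
#' whose probability does not exceed the observed table's).
#'
#' @param kExp,nExp outcome count and size of the exposed group.
#' @param kBg,nBg outcome count and size of the background group.
#' @return Two-sided p-value.
#' @examples fisherAssociation(30, 100, 10, 100)
#' @export
fisherAssociation <- function(kExp, nExp, kBg, nBg) {
  cells <- c(kExp, nExp - kExp, kBg, nBg - kBg)
  if (any(cells < 0)) stop("negative cell in 2x2 table", call. = FALSE)
  tab <- matrix(cells, nrow = 2, byrow = TRUE)
  min(1, stats::fisher.test(tab)$p.value)
}

#' Exact binomial test of temporal direction
#'
#' Among all cohort units having both events of a pair (same-day
#' co-occurrences excluded by the minimum-gap parameter upstream), tests
#' whether the order E1-before-E2 dominates: an exact two-sided binomial
#' test of `nE1First` successes out of `nE1First + nE2First` trials at
#' success probability 0.5.
#'
#' @param nE1First units where E1's first occurrence precedes E2's.
#' @param nE2First units with the opposite order.
#' @return Two-sided p-value.
#' @examples binomialDirection(10, 0)
#' @export
binomialDirection <- function(nE1First, nE2First) {
  if (nE1First < 0 || nE2First < 0) stop("negative count", call. = FALSE)
  n <- nE1First + nE2First
  if (n == 0) stop("no ordered co-occurrences", call. = FALSE)
  min(1, stats::binom.test(nE1First, n, p = 0.5)$p.value)
}

#' Multiple-testing correction
#'
#' Bonferroni (`min(1, m * p)`) or Benjamini-Hochberg step-up false
#' discovery rate adjustment, order-preserving with the input.
#'
#' @param pvals vector of raw p-values in `[0, 1]`.
#' @param method `"fdr"` or `"bonferroni"`.
#' @return Adjusted p-values in the input order.
#' @examples adjustPvalues(c(0.01, 0.02, 0.03, 0.04), "fdr")
#' @export
adjustPvalues <- function(pvals, method = c("fdr", "bonferroni")) {
  method <- match.arg(method)
  stopifnot(all(is.na(pvals) | (pvals >= 0 & pvals <= 1)))
  out <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  out[ok] <- stats::p.adjust(pvals[ok],
                             method = if (method == "fdr") "BH"
                                      else "bonferroni")
  out
}

#' Classify tested pairs into significance categories
#'
#' A pair is a significant association when its adjusted Fisher p-value is
#' below `alpha` and its relative risk reaches `rrMin`; it is a significant
#' directional pair when it is additionally direction-significant (adjusted
#' binomial p below `alpha`) with E1-before-E2 the dominant order.
#'
#' @param table per-pair results data.frame carrying `fisher_p_adj`, `rr`,
#'   `binom_p_adj`, `n_e1_first`, `n_e2_first`.
#' @param params a [StudyParams-class].
#' @return The table with logical columns `significant_assoc` and
#'   `significant_direction`.
#' @export
classifyPairs <- function(table, params) {
  assoc <- !is.na(table$fisher_p_adj) & table$fisher_p_adj < params@alpha &
    !is.na(table$rr) & table$rr >= params@rrMin
  direct <- assoc & !is.na(table$binom_p_adj) &
    table$binom_p_adj < params@alpha &
    table$n_e1_first > table$n_e2_first
  table$significant_assoc <- assoc
  table$significant_direction <- direct
  table
}
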
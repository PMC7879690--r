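.check_counts <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x != floor(x)))
    stop(name, " must contain non-negative integers")
}

.check_totals <- function(n, name) {
  if (any(!is.finite(n)) || any(n < 1))
    stop(name, " must be >= 1")
}

#' Audic-Claverie conditional probability mass
#'
#' Probability of observing `y` reads for a transcript in a library of total
#' `n2`, conditional on `x` reads in a library of total `n1`, under the null
#' of equal underlying proportion:
#' \deqn{p(y \mid x) = \left(\frac{N_2}{N_1}\right)^y
#'   \frac{(x+y)!}{x!\,y!\,(1+N_2/N_1)^{x+y+1}}.}
#' The mass is evaluated in log space (log binomial coefficient plus log
#' probabilities) and exponentiated once, so it is stable for large counts. Algebraically it equals the negative
#' binomial mass with size `x + 1` and success probability `n1/(n1+n2)`,
#' which the test suite uses as an independent cross-check.
#'
#' @param y count in the comparison library (vectorized).
#' @param x count in the reference library.
#' @param n1,n2 total mapped reads of the reference and comparison library.
#' @return probabilities, same length as the recycled arguments.
#' @examples
#' acPmf(0, 0, 1e5, 1e5)  # 0.5: p(y|0) = 2^-(y+1) at equal totals
#' @seealso [acPvalue()]
#' @export
acPmf <- function(y, x, n1, n2) {
  .check_counts(x, "x"); .check_counts(y, "y")
  .check_totals(n1, "n1"); .check_totals(n2, "n2")
  # log-binomial via lchoose avoids the cancellation of three large lgammas
  p <- n1 / (n1 + n2)
  lp <- lchoose(x + y, y) + (x + 1) * log(p) + y * log1p(-p)
  exp(lp)
}

#' Audic-Claverie two-sided p-value
#'
#' Exact two-library comparison of one transcript's read counts. The lower
#' and upper tails of the conditional law (see [acPmf()]) are computed in
#' closed form through the regularized incomplete beta function (the
#' negative-binomial CDF identity), and the two-sided p-value is
#' `min(1, 2 * min(P(Y <= y), P(Y >= y)))`. The tie case `x = 0, y = 0`
#' returns 1 (no evidence by construction).
#'
#' @inheritParams acPmf
#' @param x count in the reference library (vectorized).
#' @return two-sided p-values in `[0, 1]`.
#' @examples
#' acPvalue(0, 2, 1e4, 1e4)  # 0.5: upper tail sum 2^-(k+1), k >= 2, doubled
#' @export
acPvalue <- function(x, y, n1, n2) {
  .check_counts(x, "x"); .check_counts(y, "y")
  .check_totals(n1, "n1"); .check_totals(n2, "n2")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  p <- n1 / (n1 + n2)
  p_le <- stats::pbeta(p, x + 1, y + 1)
  p_ge <- ifelse(y == 0, 1, stats::pbeta(1 - p, pmax(y, 1), x + 1))
  out <- pmin(1, 2 * pmin(p_le, p_ge))
  # a gene absent from both libraries carries no evidence, whatever the totals
  out[x == 0 & y == 0] <- 1
  out
}

#' Direction of a two-library comparison
#'
#' `"up"` when the comparison library's proportion `y/n2` exceeds the
#' reference `x/n1`, `"down"` when it is lower, `"none"` on exact equality.
#'
#' @inheritParams acPvalue
#' @return character vector in `{"up", "down", "none"}`.
#' @export
acDirection <- function(x, y, n1, n2) {
  .check_counts(x, "x"); .check_counts(y, "y")
  .check_totals(n1, "n1"); .check_totals(n2, "n2")
  d <- sign(y / n2 - x / n1)
  c("down", "none", "up")[d + 2]
}

#' Bonferroni adjustment
#'
#' Family-wise adjustment `min(1, p * m)`. The family size defaults to the
#' number of p-values but may be set larger, e.g. the number of contigs
#' tested within one pairwise library comparison when only a subset is
#' passed in.
#'
#' @param p raw p-values in `[0, 1]`.
#' @param m family size, `>= length(p)`.
#' @return adjusted p-values.
#' @examples
#' bonferroni(1e-5, m = 1957)  # 0.01957
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}

#' Run Audic-Claverie tests over a set of contigs
#'
#' Vectorized convenience wrapper producing one audit row per contig:
#' counts, totals, raw and Bonferroni-adjusted two-sided p-value, and
#' direction of change.
#'
#' @inheritParams acPvalue
#' @param contigIds optional contig identifiers.
#' @param m Bonferroni family size (default: number of contigs tested).
#' @return data.frame with columns `contig_id`, `x`, `y`, `N1`, `N2`,
#'   `p_raw`, `p_adj`, `direction`.
#' @export
acTest <- function(x, y, n1, n2, contigIds = NULL, m = NULL) {
  n <- max(length(x), length(y))
  if (is.null(contigIds)) contigIds <- as.character(seq_len(n))
  if (is.null(m)) m <- n
  p_raw <- acPvalue(x, y, n1, n2)
  data.frame(contig_id = contigIds,
             x = rep_len(x, n), y = rep_len(y, n),
             N1 = rep_len(n1, n), N2 = rep_len(n2, n),
             p_raw = p_raw, p_adj = bonferroni(p_raw, m),
             direction = acDirection(x, y, n1, n2),
             stringsAsFactors = FALSE)
}
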
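# Exact and closed-form statistical primitives: Fisher's exact test for 2x2
# tables (authored here, log-space, minimum-likelihood two-sided rule) and
# the one-tailed significance of a Pearson correlation coefficient.

#' Fisher's exact test for a 2x2 contingency table
#'
#' Conditional on both margins, the count `a` follows a hypergeometric
#' distribution.  The two-sided p-value sums the probabilities of all tables
#' with the observed margins whose probability does not exceed that of the
#' observed table (minimum-likelihood rule, with a relative tolerance of
#' 1e-7 for ties, matching the convention of the classical online 2x2
#' calculators).  Probabilities are computed in log space (`lchoose`), so
#' grand totals up to 1e6 are handled without overflow.
#'
#' @param a,b,c,d Cell counts: rows are feature present/absent, columns are
#'   in-category/not-in-category, so `a` = present & in-category.
#' @param alternative `"two.sided"` (default), `"greater"` (enrichment,
#'   larger `a`) or `"less"`.
#' @return List with `p` and `odds_ratio` (the sample odds ratio `ad/bc`;
#'   `Inf` when `bc = 0` and `ad > 0`, `NaN` for a degenerate table).
#' @examples
#' fisherExact2x2(2, 0, 0, 2)$p   # 1/3
#' @export
fisherExact2x2 <- function(a, b, c, d, alternative = "two.sided") {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop("cell counts must be non-negative integers")
  alternative <- match.arg(alternative, c("two.sided", "greater", "less"))
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- a + b + c + d
  if (N < 1) stop("grand total must be at least 1")
  oddsRatio <- (a * d) / (b * c)

  # support of the hypergeometric count in cell a
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  x <- lo:hi
  logp <- lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(N, c1)
  logObs <- logp[x == a]
  p <- switch(alternative,
    two.sided = sum(exp(logp[logp <= logObs + log(1 + 1e-7)])),
    greater   = sum(exp(logp[x >= a])),
    less      = sum(exp(logp[x <= a])))
  list(p = min(p, 1), odds_ratio = oddsRatio)
}

#' Pearson product-moment correlation coefficient
#'
#' @param x,y Numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return r in [-1, 1].
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired points")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sqrt(sum(dx^2)); sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0)
    stop("undefined correlation: zero variance")
  r <- sum(dx * dy) / (sx * sy)
  max(-1, min(1, r))
}

#' One-tailed p-value of a correlation coefficient
#'
#' `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t-distribution with
#' `n - 2` degrees of freedom; returns `P(T >= t)`, the upper-tail
#' probability for a positive hypothesized direction.  For the observed
#' direction pass `|r|`; `oneTailedP(-r, n) = 1 - oneTailedP(r, n)`.
#' At `|r| = 1` the limiting value (0 for `r = 1`, 1 for `r = -1`) is
#' returned.
#'
#' @param r Correlation coefficient in [-1, 1].
#' @param n Sample size (>= 3).
#' @return Upper-tail probability.
#' @examples
#' oneTailedP(0, 10)  # 0.5
#' @export
oneTailedP <- function(r, n) {
  if (n < 3) stop("need n >= 3")
  if (abs(r) > 1) stop("|r| must not exceed 1")
  if (abs(r) == 1) return(if (r > 0) 0 else 1)
  t <- r * sqrt((n - 2) / (1 - r^2))
  pt(t, df = n - 2, lower.tail = FALSE)
}
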
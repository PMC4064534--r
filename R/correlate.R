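# Per-category association of features with the A/C/N expression outcome,
# for the three variable types: yes/no (Fisher's exact test on 2x2 tables),
# and discrete/continuous (binned category-percentage profiles correlated
# with the feature value).

CATEGORY_LEVELS <- c("A", "C", "N")

#' Association of a yes/no feature with each category
#'
#' For each category k, the 2x2 table counts feature-present/absent against
#' in-category/not-in-category and is tested with [fisherExact2x2()]
#' (two-sided).  The direction of enrichment is the sign of
#' `odds ratio - 1`.  A feature with only one observed value yields ND for
#' all categories, with a warning.
#'
#' @param categories Factor of A/C/N categories (or an
#'   [ExpressionDataset-class]).
#' @param feature Logical (or 0/1) vector, one value per record; `NA`
#'   records are excluded.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per category: counts `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `direction` (+1/-1/0), `significant`, `sign`
#'   (`"+"`, `"-"` or `"ND"`).
#' @export
binaryAssociation <- function(categories, feature, alpha = 0.05) {
  if (is(categories, "ExpressionDataset")) categories <- categories(categories)
  feature <- as.logical(feature)
  keep <- !is.na(feature) & !is.na(categories)
  categories <- categories[keep]; feature <- feature[keep]
  res <- data.frame(category = CATEGORY_LEVELS,
                    a = NA_integer_, b = NA_integer_,
                    c = NA_integer_, d = NA_integer_,
                    odds_ratio = NA_real_, p = NA_real_,
                    direction = 0, significant = FALSE, sign = "ND",
                    stringsAsFactors = FALSE)
  if (length(unique(feature)) < 2L) {
    warning("feature is constant; association not determined (ND)")
    return(res)
  }
  for (i in seq_along(CATEGORY_LEVELS)) {
    k <- CATEGORY_LEVELS[i]
    inK <- categories == k
    a <- sum(feature & inK);  b <- sum(feature & !inK)
    cc <- sum(!feature & inK); d <- sum(!feature & !inK)
    f <- fisherExact2x2(a, b, cc, d)
    dir <- sign(f$odds_ratio - 1)
    if (is.nan(dir)) dir <- 0
    sig <- is.finite(f$p) && f$p < alpha && dir != 0
    res[i, c("a", "b", "c", "d")] <- c(a, b, cc, d)
    res$odds_ratio[i] <- f$odds_ratio
    res$p[i] <- f$p
    res$direction[i] <- dir
    res$significant[i] <- sig
    res$sign[i] <- if (sig) (if (dir > 0) "+" else "-") else "ND"
  }
  res
}

#' Bin a feature and profile the A/C/N percentages
#'
#' Discrete features get one bin per observed value, with adjacent sparse
#' values merged left-to-right until every bin holds at least `minBin`
#' records (a trailing sparse bin is merged into its predecessor).
#' Continuous features are cut at quantile breaks (`nBins` target bins; tied
#' quantiles collapse so ties stay in one bin).  For every bin the
#' percentage of A, C and N records and the record count are reported; the
#' bin representative `x` is the (count-weighted) value for discrete
#' features and the within-bin mean for continuous ones.
#'
#' @param categories Factor of A/C/N categories (or an
#'   [ExpressionDataset-class]).
#' @param feature Numeric vector, one value per record; `NA` excluded.
#' @param kind `"discrete"` or `"continuous"`.
#' @param nBins Target number of quantile bins for continuous features
#'   (default 10).
#' @param minBin Minimum records per bin (default 20).
#' @return Object of class `CategoryProfile`: list with `bins` (data.frame
#'   `x`, `count`, `pct_A`, `pct_C`, `pct_N`), `kind` and `usable` (FALSE
#'   when fewer than 3 bins resulted, mapping to ND downstream).
#' @export
profileFeature <- function(categories, feature, kind = c("continuous", "discrete"),
                           nBins = 10L, minBin = 20L) {
  if (is(categories, "ExpressionDataset")) categories <- categories(categories)
  kind <- match.arg(kind)
  keep <- !is.na(feature) & !is.na(categories)
  categories <- categories[keep]; feature <- feature[keep]
  if (length(feature) < minBin)
    stop(sprintf("need at least minBin = %d records", minBin))

  if (kind == "discrete") {
    vals <- sort(unique(feature))
    counts <- vapply(vals, function(v) sum(feature == v), numeric(1))
    # greedy left-to-right merge of sparse adjacent values
    grp <- integer(length(vals)); g <- 1L; acc <- 0
    for (i in seq_along(vals)) {
      grp[i] <- g
      acc <- acc + counts[i]
      if (acc >= minBin) { g <- g + 1L; acc <- 0 }
    }
    if (acc > 0 && acc < minBin && g > 1L)       # trailing sparse bin
      grp[grp == g] <- g - 1L
    binOf <- grp[match(feature, vals)]
  } else {
    probs <- seq(0, 1, length.out = nBins + 1L)
    breaks <- unique(quantile(feature, probs, names = FALSE, type = 7))
    if (length(breaks) < 2L) breaks <- c(breaks, breaks + 1)  # constant feature
    binOf <- as.integer(cut(feature, breaks, include.lowest = TRUE))
  }

  binIds <- sort(unique(binOf))
  bins <- do.call(rbind, lapply(binIds, function(bid) {
    inBin <- binOf == bid
    n <- sum(inBin)
    pct <- 100 * vapply(CATEGORY_LEVELS,
                        function(k) sum(categories[inBin] == k), numeric(1)) / n
    data.frame(x = mean(feature[inBin]), count = n,
               pct_A = pct[["A"]], pct_C = pct[["C"]], pct_N = pct[["N"]])
  }))
  structure(list(bins = bins, kind = kind,
                 usable = nrow(bins) >= 3L, n_records = length(feature)),
            class = "CategoryProfile")
}

#' @export
print.CategoryProfile <- function(x, ...) {
  cat(sprintf("CategoryProfile (%s, %d bins over %d records%s)\n",
              x$kind, nrow(x$bins), x$n_records,
              if (x$usable) "" else ", NOT usable for correlation"))
  print(x$bins, row.names = FALSE)
  invisible(x)
}

#' Smooth a category profile
#'
#' Centered moving average of each category's percentage curve over
#' `window` bins, shrinking the window at the edges; counts and bin
#' representatives are untouched.  Smoothing is a presentation aid;
#' correlation uses the unsmoothed profile unless explicitly requested.
#'
#' @param profile A `CategoryProfile` from [profileFeature()].
#' @param window Odd window width in bins (default 3); 1 is the identity.
#' @return A smoothed `CategoryProfile`.
#' @export
smoothProfile <- function(profile, window = 3L) {
  if (window %% 2L == 0L || window < 1L) stop("window must be odd and >= 1")
  half <- (window - 1L) %/% 2L
  nb <- nrow(profile$bins)
  for (col in c("pct_A", "pct_C", "pct_N")) {
    v <- profile$bins[[col]]
    profile$bins[[col]] <- vapply(seq_len(nb), function(i)
      mean(v[max(1L, i - half):min(nb, i + half)]), numeric(1))
  }
  profile
}

#' Correlate a category profile with the feature value
#'
#' For each category, pairs the per-bin percentage with the bin
#' representative value and computes Pearson's r with its one-tailed p for
#' the observed direction (`n` = number of bins).  Profiles with fewer than
#' 3 bins, or a category with zero percentage variance, yield ND.
#'
#' @param profile A `CategoryProfile`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per category: `r`, `n`, `p_one_tailed`,
#'   `significant`, `sign`.
#' @export
correlateProfile <- function(profile, alpha = 0.05) {
  res <- data.frame(category = CATEGORY_LEVELS, r = NA_real_,
                    n = nrow(profile$bins), p_one_tailed = NA_real_,
                    significant = FALSE, sign = "ND",
                    stringsAsFactors = FALSE)
  if (!isTRUE(profile$usable)) return(res)
  x <- profile$bins$x
  for (i in seq_along(CATEGORY_LEVELS)) {
    y <- profile$bins[[paste0("pct_", CATEGORY_LEVELS[i])]]
    r <- tryCatch(pearsonR(x, y), error = function(e) NA_real_)
    if (is.na(r)) next
    p <- oneTailedP(abs(r), length(x))
    sig <- p < alpha
    res$r[i] <- r
    res$p_one_tailed[i] <- p
    res$significant[i] <- sig
    res$sign[i] <- if (sig) (if (r > 0) "+" else "-") else "ND"
  }
  res
}

# split a profile into lower/upper halves of bins (sharing the middle bin
# when the count is odd); each half must keep >= 3 bins to be testable
.halfProfiles <- function(profile) {
  nb <- nrow(profile$bins)
  k <- ceiling(nb / 2)
  lower <- profile; lower$bins <- profile$bins[seq_len(k), , drop = FALSE]
  upper <- profile; upper$bins <- profile$bins[(nb + 1L - k):nb, , drop = FALSE]
  lower$usable <- k >= 3L; upper$usable <- k >= 3L
  list(lower = lower, upper = upper)
}

#' Qualitative sign call for a profiled feature
#'
#' Per category: `+` for a significant positive correlation, `-` for a
#' significant negative one; `±` when the full-range correlation is not
#' significant but the lower-half and upper-half bins are individually
#' significant with opposite signs (a non-monotone, e.g. U- or V-shaped,
#' association); `ND` otherwise.
#'
#' @param profile A `CategoryProfile`.
#' @param alpha Significance level (default 0.05).
#' @return data.frame with one row per category: `sign`, `r`, `n`,
#'   `p_one_tailed`.
#' @export
signCall <- function(profile, alpha = 0.05) {
  full <- correlateProfile(profile, alpha)
  halves <- .halfProfiles(profile)
  lowr <- correlateProfile(halves$lower, alpha)
  upr <- correlateProfile(halves$upper, alpha)
  full$sign <- vapply(seq_len(nrow(full)), function(i) {
    if (full$significant[i]) return(full$sign[i])
    if (lowr$significant[i] && upr$significant[i] &&
        !is.na(lowr$r[i]) && !is.na(upr$r[i]) &&
        sign(lowr$r[i]) != sign(upr$r[i])) return("±")
    "ND"
  }, character(1))
  full
}
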
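# Per-category association: contingency tables, profiles, smoothing,
# correlation and sign calls.

mkProfile <- function(x, pctA, pctC = NULL, counts = NULL) {
  nb <- length(x)
  if (is.null(pctC)) pctC <- (100 - pctA) / 2
  pctN <- 100 - pctA - pctC
  structure(list(bins = data.frame(x = x,
                                   count = counts %||% rep(50, nb),
                                   pct_A = pctA, pct_C = pctC, pct_N = pctN),
                 kind = "continuous", usable = nb >= 3, n_records = 50 * nb),
            class = "CategoryProfile")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("binary association builds per-category tables with full totals", {
  set.seed(41)
  n <- 300
  cats <- factor(sample(c("A", "C", "N"), n, replace = TRUE,
                        prob = c(0.3, 0.3, 0.4)), levels = c("A", "C", "N"))
  feat <- runif(n) < 0.4
  ba <- binaryAssociation(cats, feat)
  expect_equal(ba$category, c("A", "C", "N"))
  # each table partitions the whole dataset
  expect_equal(ba$a + ba$b + ba$c + ba$d, rep(n, 3))
  expect_equal(ba$a + ba$c, as.vector(table(cats)))
  expect_true(all(ba$p > 0 & ba$p <= 1))
})

test_that("a feature identical to the A indicator is maximally extreme", {
  set.seed(42)
  cats <- factor(sample(c("A", "C", "N"), 120, replace = TRUE),
                 levels = c("A", "C", "N"))
  feat <- cats == "A"
  ba <- binaryAssociation(cats, feat)
  rowA <- ba[ba$category == "A", ]
  expect_equal(rowA$b, 0)
  expect_equal(rowA$c, 0)
  expect_equal(rowA$sign, "+")
  # enumeration oracle: no value of cell a with these margins has smaller p
  nA <- sum(cats == "A"); n <- length(cats)
  allP <- vapply(0:nA, function(a)
    fisherOracle(a, nA - a, nA - a, n - 2 * nA + a), numeric(1))
  expect_equal(rowA$p, min(allP), tolerance = 1e-12)
})

test_that("constant features yield ND with a warning", {
  cats <- factor(rep(c("A", "C", "N"), 10), levels = c("A", "C", "N"))
  expect_warning(ba <- binaryAssociation(cats, rep(TRUE, 30)), "constant")
  expect_equal(ba$sign, rep("ND", 3))
  expect_false(any(ba$significant))
})

test_that("binary association under a planted null rejects at about alpha", {
  set.seed(43)
  hits <- matrix(FALSE, 120, 3)
  for (i in 1:120) {
    cats <- factor(sample(c("A", "C", "N"), 400, replace = TRUE,
                          prob = c(0.26, 0.34, 0.40)), levels = c("A", "C", "N"))
    feat <- runif(400) < 0.3
    hits[i, ] <- binaryAssociation(cats, feat)$p < 0.05
  }
  # loose 3-sigma sanity bound per category (tight envelope in acceptance)
  expect_true(all(colMeans(hits) < 0.05 + 3 * sqrt(0.05 * 0.95 / 120)))
})

test_that("profiles partition percentages and respect the merge rule", {
  set.seed(44)
  cats <- factor(sample(c("A", "C", "N"), 105, replace = TRUE),
                 levels = c("A", "C", "N"))
  feat <- c(rep(0, 50), rep(1, 50), rep(2, 5))
  prof <- profileFeature(cats, feat, kind = "discrete", minBin = 20)
  expect_equal(nrow(prof$bins), 2)            # {0}, {1,2}
  expect_equal(prof$bins$count, c(50, 55))
  expect_equal(prof$bins$x[1], 0)
  expect_equal(prof$bins$x[2], mean(c(rep(1, 50), rep(2, 5))))
  expect_equal(prof$bins$pct_A + prof$bins$pct_C + prof$bins$pct_N,
               rep(100, 2), tolerance = 1e-9)

  cont <- profileFeature(cats, rnorm(105), kind = "continuous", nBins = 5)
  expect_equal(sum(cont$bins$count), 105)
  expect_equal(cont$bins$pct_A + cont$bins$pct_C + cont$bins$pct_N,
               rep(100, nrow(cont$bins)), tolerance = 1e-9)
  expect_true(all(diff(cont$bins$x) > 0))

  const <- profileFeature(cats, rep(3.3, 105), kind = "continuous")
  expect_equal(nrow(const$bins), 1)
  expect_false(const$usable)
})

test_that("smoothing is a shrinking-window moving average", {
  prof <- mkProfile(1:3, pctA = c(0, 100, 0))
  sm <- smoothProfile(prof, window = 3)
  expect_equal(sm$bins$pct_A, c(50, 100 / 3, 50))
  expect_equal(sm$bins$count, prof$bins$count)   # counts untouched
  # window 1 is the identity; constant curves are fixed points
  expect_equal(smoothProfile(prof, 1), prof)
  flat <- mkProfile(1:5, pctA = rep(40, 5))
  expect_equal(smoothProfile(flat, 3)$bins$pct_A, rep(40, 5))
  expect_error(smoothProfile(prof, 2), "odd")
})

test_that("profile correlation recovers exact linear structure", {
  prof <- mkProfile(1:6, pctA = c(10, 20, 30, 40, 50, 60))
  res <- correlateProfile(prof)
  expect_equal(res$r[res$category == "A"], 1.0)
  expect_equal(res$sign[res$category == "A"], "+")
  expect_equal(res$n, rep(6, 3))
  # mirror-image A and C with N constant: r_A = -r_C
  prof2 <- structure(list(bins = data.frame(
    x = 1:5, count = rep(50, 5),
    pct_A = c(10, 20, 35, 40, 55), pct_C = 60 - c(10, 20, 35, 40, 55),
    pct_N = rep(40, 5)), kind = "continuous", usable = TRUE,
    n_records = 250), class = "CategoryProfile")
  res2 <- correlateProfile(prof2)
  expect_equal(res2$r[res2$category == "A"], -res2$r[res2$category == "C"],
               tolerance = 1e-12)
  # constant category percentage -> undefined correlation -> ND
  expect_equal(res2$sign[res2$category == "N"], "ND")
  # r = 0 gives the one-tailed null p of 0.5
  profFlat <- mkProfile(1:4, pctA = c(30, 40, 30, 40))
  rf <- correlateProfile(mkProfile(c(1, 2, 3, 4), pctA = c(30, 40, 40, 30)))
  expect_equal(rf$p_one_tailed[rf$category == "A"], 0.5, tolerance = 1e-9)
})

test_that("correlation is invariant under affine feature rescaling", {
  prof <- mkProfile(1:8, pctA = c(12, 18, 22, 31, 35, 41, 44, 52))
  scaled <- prof; scaled$bins$x <- 3.2 * prof$bins$x - 7
  flipped <- prof; flipped$bins$x <- -prof$bins$x
  r0 <- correlateProfile(prof)$r
  expect_equal(correlateProfile(scaled)$r, r0, tolerance = 1e-12)
  expect_equal(correlateProfile(flipped)$r, -r0, tolerance = 1e-12)
})

test_that("sign calls distinguish +, -, non-monotone and ND", {
  up <- signCall(mkProfile(1:10, pctA = seq(5, 75, length.out = 10)))
  expect_equal(up$sign[up$category == "A"], "+")
  down <- signCall(mkProfile(1:10, pctA = seq(75, 5, length.out = 10)))
  expect_equal(down$sign[down$category == "A"], "-")
  # V-shaped profile: halves significant with opposite signs
  v <- signCall(mkProfile(1:10, pctA = c(60, 48, 35, 22, 10, 10, 22, 35, 48, 60)))
  expect_equal(v$sign[v$category == "A"], "±")
  # weak noise: nothing fires
  nd <- signCall(mkProfile(1:10, pctA = c(30, 32, 29, 31, 30, 31, 29, 32, 30, 31)))
  expect_equal(nd$sign[nd$category == "A"], "ND")
  # unusable profile (< 3 bins) is ND everywhere
  tiny <- mkProfile(1:2, pctA = c(10, 90))
  expect_equal(signCall(tiny)$sign, rep("ND", 3))
})
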
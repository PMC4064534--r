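# Categorical assessment, sequence validation, dataset I/O.

test_that("sequence validation canonicalizes and rejects non-standard symbols", {
  expect_identical(validateSequence("p1", "acdk"), "ACDK")
  expect_identical(validateSequence("p3", "MKKLLPT"), "MKKLLPT")
  expect_identical(validateSequence("p4", " MK KL\n"), "MKKL")
  expect_error(validateSequence("p2", "AC*K"), "position 3")
  expect_error(validateSequence("p5", "ACBK"), "position 3")
  expect_error(validateSequence("px", "ACXK"), "position 3")
  expect_error(validateSequence("pu", "ACKU"), "position 4")
  expect_error(validateSequence("pe", "   "), "empty")
})

test_that("A/C/N assignment follows the yield threshold and truncation rules", {
  expect_equal(as.character(assignCategory(TRUE, 0.5, TRUE)), "A")
  expect_equal(as.character(assignCategory(TRUE, 0.0, TRUE)), "C")
  expect_equal(as.character(assignCategory(TRUE, 0.5, FALSE)), "N")  # truncated
  expect_equal(as.character(assignCategory(FALSE, 0.0, TRUE)), "N")
  # boundary: yield exactly at the threshold is C ("more than" rule)
  expect_equal(as.character(assignCategory(TRUE, 0.1, TRUE)), "C")
  expect_equal(as.character(assignCategory(TRUE, 0.1 + 1e-9, TRUE)), "A")
  expect_error(assignCategory(TRUE, -0.1, TRUE), "non-negative")
  expect_error(assignCategory(FALSE, 0.5, TRUE), "non-expressed")
})

test_that("categorization is an exhaustive partition over outcome space", {
  yields <- c(0, 0.05, 0.1 - 1e-9, 0.1, 0.1 + 1e-9, 0.5, 10)
  for (expressed in c(TRUE, FALSE))
    for (full in c(TRUE, FALSE))
      for (y in yields) {
        if (!expressed && y >= 0.1) next  # invalid combination, rejected
        cat <- assignCategory(expressed, y, full)
        expect_length(cat, 1)
        expect_false(is.na(cat))
        expect_true(as.character(cat) %in% c("A", "C", "N"))
      }
})

test_that("raising the yield threshold never moves a record from C to A", {
  yields <- runif(50, 0, 1)
  lo <- assignCategory(rep(TRUE, 50), yields, rep(TRUE, 50),
                       categorizationConfig(0.1))
  hi <- assignCategory(rep(TRUE, 50), yields, rep(TRUE, 50),
                       categorizationConfig(0.4))
  expect_false(any(lo == "C" & hi == "A"))
  expect_true(all(hi[lo == "C"] == "C"))
})

test_that("dataset round-trips through FASTA + outcome TSV", {
  set.seed(7)
  seqs <- setNames(vapply(1:5, function(i) randomSequence(60), character(1)),
                   paste0("q", 1:5))
  out <- data.frame(expressed = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                    soluble_yield = c(0.5, 0.02, 0.1, 0.0, 2.5),
                    full_length = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  ds <- ExpressionDataset(seqs, outcome = out)
  expect_equal(as.character(categories(ds)), c("A", "C", "C", "N", "N"))

  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeExpressionDataset(ds, fa, tsv)
  ds2 <- readExpressionDataset(fa, tsv)
  expect_identical(names(ds2), names(ds))
  expect_identical(as.character(sequenceSet(ds2)), as.character(sequenceSet(ds)))
  expect_identical(categories(ds2), categories(ds))
  expect_equal(outcomes(ds2)$soluble_yield, outcomes(ds)$soluble_yield)
})

test_that("reader joins by id and reports orphans, duplicates, bad rows", {
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">a", "MKLV", ">b", "MKAA"), fa)

  writeLines(c("id\texpressed\tsoluble_yield\tfull_length",
               "a\tTRUE\t0.5\tTRUE"), tsv)
  expect_error(readExpressionDataset(fa, tsv), "FASTA-only: \\[b\\]")

  writeLines(c("id\texpressed\tsoluble_yield\tfull_length",
               "a\tTRUE\t0.5\tTRUE", "b\tTRUE\t0.2\tTRUE",
               "c\tTRUE\t0.2\tTRUE"), tsv)
  expect_error(readExpressionDataset(fa, tsv), "table-only: \\[c\\]")

  writeLines(c("id\texpressed\tsoluble_yield\tfull_length",
               "a\tTRUE\tlots\tTRUE", "b\tTRUE\t0.2\tTRUE"), tsv)
  expect_error(readExpressionDataset(fa, tsv), "line 2")

  writeLines(c(">a", "MKLV", ">a", "MKAA"), fa)
  writeLines(c("id\tcategory", "a\tA"), tsv)
  expect_error(readExpressionDataset(fa, tsv), "duplicate")
})

test_that("pre-assigned category column is taken verbatim, no yields needed", {
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  writeLines(c(">a", "MKLV", ">b", "MKAA", ">c", "MWWC"), fa)
  writeLines(c("id\tcategory", "a\tC", "b\tA", "c\tN"), tsv)
  ds <- readExpressionDataset(fa, tsv)
  expect_equal(as.character(categories(ds)), c("C", "A", "N"))
  expect_equal(nrow(outcomes(ds)), 0L)
  expect_equal(length(ds), 3L)

  writeLines(c("id\tcategory", "a\tC", "b\tQ", "c\tN"), tsv)
  expect_error(readExpressionDataset(fa, tsv), "line 3")
})

test_that("dataset validity enforces unique ids and consistent categories", {
  expect_error(ExpressionDataset(c(a = "MKLV", a = "MKAA"),
                                 category = c("A", "C")),
               "duplicate")
  ds <- ExpressionDataset(c(a = "MKLV", b = "MKAA"), category = c("A", "C"))
  expect_error({ ds@category <- factor(c("C", "A"), levels = c("A", "C", "N"))
                 ds@outcome <- S4Vectors::DataFrame(
                   expressed = c(TRUE, TRUE), soluble_yield = c(0.5, 0.01),
                   full_length = c(TRUE, TRUE))
                 validObject(ds) },
               "disagree")
  # subsetting keeps alignment
  sub <- smallDataset(20)[c("rec003", "rec007")]
  expect_equal(names(sub), c("rec003", "rec007"))
  expect_equal(length(sub), 2L)
})

test_that("dataset summary export writes id, length, category", {
  ds <- smallDataset(10)
  p <- tempfile(fileext = ".tsv")
  tab <- exportDatasetSummary(ds, p)
  back <- read.delim(p, stringsAsFactors = FALSE)
  expect_equal(back$id, names(ds))
  expect_equal(back$length, unname(Biostrings::width(sequenceSet(ds))))
  expect_equal(back$category, as.character(categories(ds)))
  pj <- tempfile(fileext = ".json")
  exportDatasetSummary(ds, pj, format = "json")
  expect_equal(jsonlite::read_json(pj, simplifyVector = TRUE)$id, names(ds))
})
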
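# Structural features: PEST regions, coiled coils, baseline TM / disorder,
# external-feature adapter.

test_that("PEST regions need length, composition and charged flanks", {
  # no D/E/P/S/T at all
  expect_equal(nrow(findPest(strrep("AVLIG", 10))), 0)
  # every position is a flank
  expect_equal(nrow(findPest(strrep("K", 16))), 0)
  # shorter than 12 between flanks
  expect_equal(nrow(findPest(paste0("K", "EPSTEEPSTE", "R"))), 0)

  core <- "EPSTEEPSTEEP"
  reg <- findPest(paste0("K", core, "R"))
  expect_equal(nrow(reg), 1)
  expect_equal(reg$start, 2L)
  expect_equal(reg$end, 13L)
  # hand evaluation of the score formula on the fixed stretch:
  # all 12 residues are D/E/P/S/T -> mole% = 100
  # mean KD = (5*(-3.5) + 3*(-1.6) + 2*(-0.8) + 2*(-0.7)) / 12
  kd_mean <- (5 * -3.5 + 3 * -1.6 + 2 * -0.8 + 2 * -0.7) / 12
  expect_equal(reg$score, 0.55 * 100 - 0.5 * (kd_mean + 4.5) * 10,
               tolerance = 1e-9)
})

test_that("PEST flank handling: K-wrapped valid core gives exactly the core", {
  core <- "EPSTEEPSTEEPQQ"
  bare <- findPest(core)        # bounded by sequence ends
  wrapped <- findPest(paste0("K", core, "K"))
  expect_equal(nrow(bare), 1)
  expect_equal(nrow(wrapped), 1)
  expect_equal(bare$score, wrapped$score)
  expect_equal(wrapped$start, 2L)
  expect_equal(wrapped$end, nchar(core) + 1L)
})

test_that("coiled-coil homopolymer score equals the geometric-mean identity", {
  prop <- coiledCoilPropensities()
  for (res in c("L", "E", "G")) {
    cc <- coiledCoil(strrep(res, 35))
    expect_equal(cc$score, rep(exp(mean(log(prop[res, ]))), 35),
                 tolerance = 1e-12)
  }
})

test_that("coiled-coil equals the all-windows-all-registers oracle", {
  set.seed(21)
  for (rep in 1:6) {
    s <- randomSequence(sample(28:60, 1))
    expect_equal(coiledCoil(s)$score, coiledCoilOracle(s), tolerance = 1e-10)
  }
  # designed heptad repeat scores far above background
  heptad <- strrep("LEALEKE", 5)
  expect_gt(max(coiledCoil(heptad)$score), 1.5)
})

test_that("coiled-coil degenerate and threshold behaviour", {
  short <- coiledCoil(strrep("L", 20))
  expect_equal(short$score, rep(0, 20))
  expect_equal(nrow(short$segments), 0)
  # raising the threshold never lengthens any segment
  s <- paste0(strrep("A", 10), strrep("LEALEKE", 6), strrep("A", 10))
  lo <- coiledCoil(s, threshold = 1.2)
  hi <- coiledCoil(s, threshold = 1.5)
  expect_lte(sum(hi$segments$end - hi$segments$start + 1),
             sum(lo$segments$end - lo$segments$start + 1))
  expect_true(all(lo$score > 0))
  expect_equal(length(lo$score), nchar(s))
})

test_that("baseline TM segments are merged hydropathic windows", {
  seg <- tmSegments(strrep("L", 25))
  expect_equal(seg, data.frame(start = 1L, end = 25L))
  expect_equal(nrow(tmSegments(strrep("D", 60))), 0)
  # two hydrophobic stretches separated by a long polar linker
  s <- paste0(strrep("L", 22), strrep("D", 30), strrep("I", 22))
  expect_equal(nrow(tmSegments(s)), 2)
  # lowering the cutoff never loses covered residues
  cover <- function(seg) sum(seg$end - seg$start + 1)
  expect_gte(cover(tmSegments(s, cutoff = 1.0)), cover(tmSegments(s)))
})

test_that("baseline disorder fraction tracks the propensity scale", {
  expect_equal(disorderProfile(strrep("E", 40))$fraction, 1.0)
  expect_equal(disorderProfile(strrep("W", 40))$fraction, 0.0)
  set.seed(22)
  for (rep in 1:5) {
    d <- disorderProfile(randomSequence(80))
    expect_true(d$fraction >= 0 && d$fraction <= 1)
    expect_length(d$profile, 80)
  }
  expect_error(disorderProfile("MKLV", window = 4), "odd")
})

test_that("the structural feature table is complete and labelled baseline", {
  ds <- smallDataset(12)
  st <- structuralFeatures(ds)
  expect_equal(rownames(st), names(ds))
  expect_true(all(c("baseline_tm_count", "baseline_disorder_fraction")
                  %in% colnames(st)))
  expect_true(all(st$cc_fraction >= 0 & st$cc_fraction <= 1))
  expect_true(all(st$n_pest >= 0))
})

test_that("external feature adapter joins by id and validates kinds", {
  ds <- ExpressionDataset(c(a = "MKLV", b = "MKAA", c = "MWWC"),
                          category = c("A", "C", "N"))
  p <- tempfile(fileext = ".tsv")
  writeLines(c("id\tfeature\tkind\tvalue",
               "a\tacc\tcontinuous\t0.31", "b\tacc\tcontinuous\t0.52",
               "c\tacc\tcontinuous\t0.11",
               "a\tsignal\tbinary\t1", "b\tsignal\tbinary\t0"), p)
  expect_message(ext <- loadExternalFeatures(p, ds), "1 record")
  expect_equal(ext$values$acc, c(0.31, 0.52, 0.11))
  expect_equal(ext$values$signal, c(1, 0, NA))
  expect_equal(unname(ext$kind), c("continuous", "binary"))

  writeLines(c("id\tfeature\tkind\tvalue", "a\tsignal\tbinary\t0.5"), p)
  expect_error(loadExternalFeatures(p, ds), "outside \\{0,1\\}")
  writeLines(c("id\tfeature\tkind\tvalue", "a\tsignal\tternary\t1"), p)
  expect_error(loadExternalFeatures(p, ds), "unknown feature kind")
  writeLines(c("id\tfeature\tkind\tvalue", "a\tacc\tcontinuous\thigh"), p)
  expect_error(loadExternalFeatures(p, ds), "non-numeric")
  writeLines(c("id\tfeature\tkind\tvalue", "z\tacc\tcontinuous\t0.5"), p)
  expect_error(loadExternalFeatures(p, ds), "not in dataset")
})
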
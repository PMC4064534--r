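# Seeded generator of synthetic expression datasets with planted
# feature-category effects: the benchmarking testbed with known ground
# truth.  Categories are drawn from a multinomial logit whose baseline
# log-odds reproduce the configured A/C/N base rates and whose per-category
# shifts are beta * z(feature), with the feature z-standardized over the
# batch; this yields smooth monotone percentage curves, the structure the
# profile analysis assumes.

# background residue weights, roughly vertebrate average composition
.defaultComposition <- function() {
  c(A = 7.4, C = 2.5, D = 5.3, E = 6.2, F = 4.0, G = 7.4, H = 2.9,
    I = 3.8, K = 7.2, L = 7.6, M = 1.8, N = 4.4, P = 5.0, Q = 3.7,
    R = 4.2, S = 8.1, T = 6.2, V = 6.8, W = 1.3, Y = 3.3)
}

#' Synthetic dataset configuration
#'
#' @param n Number of records.
#' @param lengthRange Integer min/max sequence length (min >= 30).
#' @param composition Named residue sampling weights (20 residues);
#'   defaults to an average vertebrate composition.
#' @param baseRates Target marginal probabilities of categories A, C, N;
#'   must be positive and sum to 1.  Default `c(A = 0.257, C = 0.343,
#'   N = 0.400)`, putting the soluble rate at the benchmark 25.7%.
#' @param effects List of planted effects, each
#'   `list(feature = <name>, category = <"A"|"C"|"N">, beta = <numeric>)`.
#'   `feature` is a computable feature: one of `"gravy"`, `"length"`,
#'   `"pI"`, `"net_charge"`, or `"motif:<pattern>"` for presence of a
#'   catalogue pattern.  `beta` is the log-odds shift of the target
#'   category per standard unit of the feature.
#' @param motifPlants List of `list(pattern = <name>, fraction = <0..1>)`:
#'   a matching site for the named catalogue pattern is inserted at a
#'   uniform position into that fraction of sequences.
#' @param truncatedFraction Fraction of N-category records back-filled as
#'   truncated (expressed below expected size) rather than non-expressed.
#' @param seed RNG seed.
#' @return List of class `SynthConfig`.
#' @export
synthConfig <- function(n = 3000L, lengthRange = c(50L, 300L),
                        composition = .defaultComposition(),
                        baseRates = c(A = 0.257, C = 0.343, N = 0.400),
                        effects = list(), motifPlants = list(),
                        truncatedFraction = 0.3, seed = 1L) {
  stopifnot(n >= 1, length(lengthRange) == 2L, lengthRange[1] >= 30L,
            lengthRange[1] <= lengthRange[2],
            all(aminoAcidAlphabet() %in% names(composition)),
            all(composition >= 0), sum(composition) > 0,
            identical(sort(names(baseRates)), c("A", "C", "N")),
            all(baseRates > 0), abs(sum(baseRates) - 1) < 1e-9,
            truncatedFraction >= 0, truncatedFraction <= 1)
  for (e in effects)
    stopifnot(is.list(e), all(c("feature", "category", "beta") %in% names(e)),
              e$category %in% c("A", "C", "N"))
  for (p in motifPlants)
    stopifnot(is.list(p), all(c("pattern", "fraction") %in% names(p)),
              p$fraction >= 0, p$fraction <= 1)
  structure(list(n = as.integer(n), lengthRange = as.integer(lengthRange),
                 composition = composition[aminoAcidAlphabet()],
                 baseRates = baseRates[c("A", "C", "N")],
                 effects = effects, motifPlants = motifPlants,
                 truncatedFraction = truncatedFraction,
                 seed = as.integer(seed)),
            class = "SynthConfig")
}

# draw one match for a pattern from its first fixed-width expansion
.sampleMotifInstance <- function(pattern) {
  alt <- pattern@alternatives[[1]]
  if (alt$width == 0L) return("")
  alphabet <- aminoAcidAlphabet()
  paste(vapply(seq_len(alt$width), function(o) {
    allowed <- alphabet[alt$member[, o]]
    allowed[sample.int(length(allowed), 1L)]
  }, character(1)), collapse = "")
}

#' Sample one synthetic sequence
#'
#' Length uniform over the configured range; residues i.i.d. from the
#' composition weights; for each configured motif plant, with the given
#' probability a sampled instance of the pattern overwrites a uniformly
#' placed window (C-terminal placement for end-anchored patterns).
#'
#' @param cfg A [synthConfig()].  Uses the current RNG stream.
#' @param catalogue Catalogue resolving planted pattern names.
#' @return The sequence string.
#' @export
sampleSyntheticSequence <- function(cfg, catalogue = readMotifCatalogue()) {
  L <- sample(cfg$lengthRange[1]:cfg$lengthRange[2], 1L)
  res <- sample(aminoAcidAlphabet(), L, replace = TRUE,
                prob = cfg$composition / sum(cfg$composition))
  for (plant in cfg$motifPlants) {
    if (runif(1) >= plant$fraction) next
    pat <- catalogue@patterns[[plant$pattern]]
    if (is.null(pat)) stop(sprintf("unknown pattern '%s'", plant$pattern))
    inst <- strsplit(.sampleMotifInstance(pat), "")[[1]]
    w <- length(inst)
    if (w == 0L || w > L) next
    pos <- if (pat@anchoredEnd) L - w + 1L
           else if (pat@anchoredStart) 1L
           else sample.int(L - w + 1L, 1L)
    res[pos:(pos + w - 1L)] <- inst
  }
  paste(res, collapse = "")
}

# compute the feature values referenced by planted effects
.effectFeature <- function(name, seqs, catalogue) {
  if (startsWith(name, "motif:")) {
    pat <- catalogue@patterns[[sub("^motif:", "", name)]]
    if (is.null(pat)) stop(sprintf("unknown effect feature '%s'", name))
    return(vapply(seqs, function(s) as.numeric(nrow(scanProsite(s, pat)) > 0),
                  numeric(1)))
  }
  switch(name,
         gravy = vapply(seqs, gravy, numeric(1)),
         length = nchar(seqs),
         pI = vapply(seqs, isoelectricPoint, numeric(1)),
         net_charge = vapply(seqs, netCharge, numeric(1)),
         stop(sprintf("unknown effect feature '%s'", name)))
}

#' Generate a synthetic expression dataset
#'
#' Samples sequences, draws each record's category from the multinomial
#' logit with planted effects, back-fills a consistent experimental outcome
#' (A: soluble yield above the threshold; C: at or below it; N: not
#' expressed, or truncated for a configurable fraction), and returns the
#' dataset together with the ground-truth effect ledger.  Bit-for-bit
#' reproducible from the configuration (which includes the seed).
#'
#' @param cfg A [synthConfig()].
#' @param catalogue Catalogue resolving pattern names (default bundled).
#' @param config Categorization config used for back-filled outcomes.
#' @return List of class `SynthDataset`: `dataset`
#'   ([ExpressionDataset-class]), `truth` (data.frame `feature`,
#'   `category`, `beta`, `expected_sign`), `features` (data.frame of the
#'   effect features used), and `config`.
#' @export
generateSyntheticDataset <- function(cfg, catalogue = readMotifCatalogue(),
                                     config = categorizationConfig()) {
  stopifnot(inherits(cfg, "SynthConfig"))
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n), function(i)
    sampleSyntheticSequence(cfg, catalogue), character(1))
  names(seqs) <- sprintf("syn%05d", seq_len(cfg$n))

  # per-category linear predictor: baseline log base-rate + planted shifts
  eta <- matrix(log(cfg$baseRates), nrow = cfg$n, ncol = 3L, byrow = TRUE,
                dimnames = list(NULL, c("A", "C", "N")))
  effFeats <- list()
  for (e in cfg$effects) {
    v <- effFeats[[e$feature]]
    if (is.null(v)) {
      v <- .effectFeature(e$feature, seqs, catalogue)
      effFeats[[e$feature]] <- v
    }
    z <- if (sd(v) > 0) (v - mean(v)) / sd(v) else rep(0, cfg$n)
    eta[, e$category] <- eta[, e$category] + e$beta * z
  }
  prob <- exp(eta - apply(eta, 1L, max))
  prob <- prob / rowSums(prob)
  u <- runif(cfg$n)
  cum <- t(apply(prob, 1L, cumsum))
  category <- c("A", "C", "N")[1L + (u > cum[, 1]) + (u > cum[, 2])]

  # back-fill outcomes consistent with the categorical assessment
  thr <- config$yieldThreshold
  expressed <- category != "N"
  fullLength <- rep(TRUE, cfg$n)
  yield <- numeric(cfg$n)
  isA <- category == "A"; isC <- category == "C"; isN <- category == "N"
  yield[isA] <- thr + rexp(sum(isA), rate = 1 / (5 * thr))
  yield[isC] <- runif(sum(isC), 0, thr)
  truncated <- isN & runif(cfg$n) < cfg$truncatedFraction
  expressed[truncated] <- TRUE
  fullLength[truncated] <- FALSE
  yield[truncated] <- runif(sum(truncated), 0, 10 * thr)
  yield[isN & !truncated] <- runif(sum(isN & !truncated), 0, thr / 2)

  dataset <- ExpressionDataset(
    seqs,
    outcome = data.frame(expressed = expressed, soluble_yield = yield,
                         full_length = fullLength),
    config = config)

  truth <- if (length(cfg$effects)) {
    data.frame(feature = vapply(cfg$effects, `[[`, character(1), "feature"),
               category = vapply(cfg$effects, `[[`, character(1), "category"),
               beta = vapply(cfg$effects, function(e) as.numeric(e$beta),
                             numeric(1)))
  } else {
    data.frame(feature = character(0), category = character(0),
               beta = numeric(0))
  }
  truth$expected_sign <- ifelse(truth$beta > 0, "+",
                                ifelse(truth$beta < 0, "-", "ND"))

  structure(list(dataset = dataset, truth = truth,
                 features = as.data.frame(effFeats, optional = TRUE),
                 config = cfg),
            class = "SynthDataset")
}
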
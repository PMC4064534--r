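# Sequence-computable structural features: PEST regions, coiled coils,
# baseline transmembrane and disorder profiles, plus the adapter contract
# for externally computed feature tables.
#
# The transmembrane and disorder features are transparent hydropathy /
# composition-propensity baselines.  They are labelled with a `baseline_`
# prefix in every output so they are never mistaken for the output of
# trained predictors.

#' Find PEST regions
#'
#' A PEST region is a stretch of >= 12 residues free of the positively
#' charged flanking residues K, R, H (bounded by such residues or by the
#' sequence ends) that contains at least one P, at least one of D/E and at
#' least one of S/T.  The score is
#' `0.55 * mole%(D,E,P,S,T) - 0.5 * rescaled mean hydropathy`, where the
#' mean Kyte-Doolittle hydropathy of the stretch is rescaled from
#' [-4.5, 4.5] to a 0-90 scale.  Scores above ~+5 are conventionally
#' considered interesting.
#'
#' @param residues A validated sequence string.
#' @param minLength Minimum stretch length (default 12).
#' @return data.frame with columns `start`, `end` (1-based inclusive) and
#'   `score`, sorted by `start`.
#' @export
findPest <- function(residues, minLength = 12L) {
  seqChars <- strsplit(residues, "")[[1]]
  isFlank <- seqChars %in% c("K", "R", "H")
  L <- length(seqChars)
  # maximal flank-free runs
  runs <- rle(!isFlank)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= minLength
  out <- lapply(which(keep), function(k) {
    s <- starts[k]; e <- ends[k]
    core <- seqChars[s:e]
    if (!any(core == "P") || !any(core %in% c("D", "E")) ||
        !any(core %in% c("S", "T")))
      return(NULL)
    molePct <- 100 * mean(core %in% c("D", "E", "P", "S", "T"))
    kd <- kdHydropathy()
    hydro <- (mean(kd[core]) + 4.5) * 10  # 0-90 scale
    data.frame(start = s, end = e, score = 0.55 * molePct - 0.5 * hydro)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  out
}

#' Coiled-coil profile
#'
#' Sliding-window heptad score: for every window of `window` residues and
#' every one of the 7 heptad registers, the geometric mean of the bundled
#' position-specific propensities is computed; each residue's score is the
#' maximum over all windows covering it and all registers.  Segments are
#' maximal runs of residues with score >= `threshold`.  Sequences shorter
#' than the window get an all-zero profile.
#'
#' @param residues A validated sequence string.
#' @param window Window width in residues (default 28, i.e. four heptads).
#' @param threshold Segment-calling score threshold (default 1.3).
#' @param propensities 20 x 7 propensity matrix; default the bundled table.
#' @return List with `score` (per-residue numeric vector), `segments`
#'   (data.frame `start`, `end`) and `fraction` (fraction of residues in
#'   segments).
#' @export
coiledCoil <- function(residues, window = 28L, threshold = 1.3,
                       propensities = coiledCoilPropensities()) {
  seqChars <- strsplit(residues, "")[[1]]
  L <- length(seqChars)
  score <- numeric(L)
  if (L >= window) {
    # log-propensities per residue per heptad position
    logP <- log(propensities[seqChars, , drop = FALSE])  # L x 7
    nWin <- L - window + 1L
    winBest <- rep(-Inf, nWin)
    for (reg in 0:6) {
      # heptad position of residue i in register reg
      hp <- ((seq_len(L) - 1L + reg) %% 7L) + 1L
      v <- logP[cbind(seq_len(L), hp)]
      cs <- c(0, cumsum(v))
      winScore <- (cs[(window + 1L):(L + 1L)] - cs[seq_len(nWin)]) / window
      winBest <- pmax(winBest, winScore)
    }
    winBest <- exp(winBest)  # geometric mean
    # residue score = max over windows covering it
    for (i in seq_len(L)) {
      wlo <- max(1L, i - window + 1L)
      whi <- min(nWin, i)
      score[i] <- max(winBest[wlo:whi])
    }
  }
  above <- score >= threshold & L >= window
  segs <- if (any(above)) {
    r <- rle(above)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    data.frame(start = s[r$values], end = e[r$values])
  } else data.frame(start = integer(0), end = integer(0))
  list(score = score, segments = segs, fraction = mean(above))
}

#' Baseline transmembrane segments from hydropathy
#'
#' Maximal windows of `window` residues whose mean Kyte-Doolittle hydropathy
#' is at least `cutoff`, merged when overlapping.  A transparent hydropathy
#' baseline, reported as `baseline_tm_count`.
#'
#' @param residues A validated sequence string.
#' @param window Window width (default 19).
#' @param cutoff Mean-hydropathy cutoff (default 1.6).
#' @return data.frame with columns `start`, `end` of merged segments.
#' @export
tmSegments <- function(residues, window = 19L, cutoff = 1.6) {
  seqChars <- strsplit(residues, "")[[1]]
  L <- length(seqChars)
  if (L < window)
    return(data.frame(start = integer(0), end = integer(0)))
  kd <- kdHydropathy()[seqChars]
  cs <- c(0, cumsum(kd))
  nWin <- L - window + 1L
  winMean <- (cs[(window + 1L):(L + 1L)] - cs[seq_len(nWin)]) / window
  hit <- which(winMean >= cutoff)
  if (!length(hit)) return(data.frame(start = integer(0), end = integer(0)))
  # merge overlapping qualifying windows (next start <= current end)
  s <- hit; e <- hit + window - 1L
  grp <- cumsum(c(1L, diff(s) >= window))
  data.frame(start = as.integer(tapply(s, grp, min)),
             end = as.integer(tapply(e, grp, max)))
}

#' Baseline disorder fraction from residue propensities
#'
#' Running mean (window `window`, shrinking at the sequence ends) of the
#' bundled per-residue disorder-propensity scale; the feature is the fraction
#' of positions whose smoothed propensity exceeds `threshold`.  A transparent
#' composition baseline, reported as `baseline_disorder_fraction`.
#'
#' @param residues A validated sequence string.
#' @param window Running-mean window, odd (default 21).
#' @param threshold Propensity threshold (default 0.05).
#' @return List with `profile` (per-residue smoothed propensity) and
#'   `fraction` (in [0, 1]).
#' @export
disorderProfile <- function(residues, window = 21L, threshold = 0.05) {
  if (window %% 2L == 0L) stop("window must be odd")
  seqChars <- strsplit(residues, "")[[1]]
  v <- disorderPropensity()[seqChars]
  L <- length(v)
  half <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(L) - half, 1L)
  hi <- pmin(seq_len(L) + half, L)
  prof <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  list(profile = unname(prof), fraction = mean(prof > threshold))
}

#' All structural features for a dataset
#'
#' Per record: `n_pest` (count of PEST regions), `max_pest_score` (0 when no
#' region), `cc_fraction` (fraction of residues in coiled-coil segments),
#' `baseline_tm_count` and `baseline_disorder_fraction`.
#'
#' @param dataset An [ExpressionDataset-class].
#' @param ccPropensities Coiled-coil propensity matrix.
#' @return data.frame, one row per record, ids as row names.
#' @export
structuralFeatures <- function(dataset,
                               ccPropensities = coiledCoilPropensities()) {
  seqs <- as.character(sequenceSet(dataset))
  pest <- lapply(seqs, findPest)
  cc <- lapply(seqs, coiledCoil, propensities = ccPropensities)
  data.frame(
    n_pest = vapply(pest, nrow, integer(1)),
    max_pest_score = vapply(pest, function(p)
      if (nrow(p)) max(p$score) else 0, numeric(1)),
    cc_fraction = vapply(cc, `[[`, numeric(1), "fraction"),
    baseline_tm_count = vapply(seqs, function(s) nrow(tmSegments(s)),
                               integer(1)),
    baseline_disorder_fraction = vapply(seqs, function(s)
      disorderProfile(s)$fraction, numeric(1)),
    row.names = names(dataset))
}

#' Load an external feature table (adapter contract)
#'
#' Adapter for predictors the package does not re-implement (solvent
#' accessibility, secondary-structure content, signal peptides, disulfide
#' bonds, site-specific ubiquitination/SUMOylation/palmitoylation
#' predictions).  Format: TSV with header and columns
#' `id<TAB>feature<TAB>kind<TAB>value`, kind one of `binary`, `discrete`,
#' `continuous`.  Records of the dataset absent from the table get `NA`
#' (excluded from correlation downstream); their count is reported with a
#' message.
#'
#' @param path Adapter TSV path.
#' @param dataset An [ExpressionDataset-class].
#' @return List with `values` (data.frame records x features, NA for
#'   missing) and `kind` (named character vector per feature).
#' @export
loadExternalFeatures <- function(path, dataset) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "feature", "kind", "value")
  if (!all(need %in% names(tab)))
    stop("adapter table needs columns id, feature, kind, value")
  if (!all(tab$kind %in% c("binary", "discrete", "continuous"))) {
    bad <- which(!tab$kind %in% c("binary", "discrete", "continuous"))[1]
    stop(sprintf("unknown feature kind '%s' at line %d", tab$kind[bad],
                 bad + 1L))
  }
  extra <- setdiff(tab$id, names(dataset))
  if (length(extra))
    stop(sprintf("adapter ids not in dataset: %s",
                 paste(extra, collapse = ", ")))
  feats <- unique(tab$feature)
  kind <- vapply(feats, function(f) unique(tab$kind[tab$feature == f])[1],
                 character(1))
  vals <- data.frame(row.names = names(dataset))
  for (f in feats) {
    sub <- tab[tab$feature == f, ]
    v <- suppressWarnings(as.numeric(sub$value))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric value '%s' for feature '%s' (line %d)",
                   sub$value[bad], f, which(tab$feature == f)[bad] + 1L))
    }
    if (kind[[f]] == "binary" && !all(v %in% c(0, 1)))
      stop(sprintf("binary feature '%s' has a value outside {0,1}", f))
    col <- rep(NA_real_, length(names(dataset)))
    col[match(sub$id, names(dataset))] <- v
    nMiss <- sum(is.na(col))
    if (nMiss)
      message(sprintf("feature '%s': %d record(s) without a value, excluded",
                      f, nMiss))
    vals[[f]] <- col
  }
  list(values = vals, kind = kind)
}
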
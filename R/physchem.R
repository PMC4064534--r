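# ProtParam-class physicochemical features computed from sequence alone:
# composition, molecular weight, charge, pI, GRAVY.

#' Physicochemical configuration
#'
#' @param pka Named pKa vector covering `Nterm`, `Cterm` and the ionizable
#'   side chains C, D, E, H, K, R, Y; default [embossPka()].
#' @param masses Average residue masses (Da); default [residueMasses()].
#' @param hydropathy Per-residue hydropathy scale; default [kdHydropathy()].
#' @param chargePH pH at which the net-charge feature is reported (default 7).
#' @return List of class `PhyschemConfig`.
#' @export
physchemConfig <- function(pka = embossPka(), masses = residueMasses(),
                           hydropathy = kdHydropathy(), chargePH = 7.0) {
  stopifnot(all(aminoAcidAlphabet() %in% names(masses)),
            all(aminoAcidAlphabet() %in% names(hydropathy)),
            all(c("Nterm", "Cterm") %in% names(pka)),
            all(pka > 0 & pka < 14),
            chargePH > 0, chargePH < 14)
  structure(list(pka = pka, masses = masses, hydropathy = hydropathy,
                 chargePH = chargePH), class = "PhyschemConfig")
}

#' Amino-acid composition
#'
#' @param residues A validated sequence string.
#' @return Named numeric vector of 20 fractions summing to 1.
#' @examples
#' aminoAcidComposition("ACAC")  # A = C = 0.5
#' @export
aminoAcidComposition <- function(residues) {
  idx <- encodeResidues(residues)
  counts <- tabulate(idx, nbins = 20L)
  setNames(counts / length(idx), aminoAcidAlphabet())
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @param residues A validated sequence string.
#' @param config A [physchemConfig()].
#' @return Molecular weight in Da.
#' @examples
#' molecularWeight("G")  # free glycine, 75.07 Da
#' @export
molecularWeight <- function(residues, config = physchemConfig()) {
  m <- config$masses[aminoAcidAlphabet()]
  sum(m[encodeResidues(residues)]) + WATER_MASS
}

#' Net charge at a given pH
#'
#' Henderson-Hasselbalch titration over the ionizable groups: the N-terminus
#' and H, K, R contribute \eqn{+1/(1+10^{pH-pKa})} each; the C-terminus and
#' C, D, E, Y contribute \eqn{-1/(1+10^{pKa-pH})} each.
#'
#' @param residues A validated sequence string.
#' @param pH pH in (0, 14).
#' @param config A [physchemConfig()].
#' @return Net charge in elementary charges.
#' @export
netCharge <- function(residues, pH = 7.0, config = physchemConfig()) {
  counts <- aminoAcidComposition(residues) * nchar(residues)  # residue counts
  .chargeAt(counts, pH, config$pka)
}

# titration charge from residue counts; pH may be a vector
.chargeAt <- function(counts, pH, pka) {
  if (!is.numeric(pH) || any(pH <= 0 | pH >= 14))
    stop("pH must lie strictly inside (0, 14)")
  basic <- c(Nterm = 1, H = unname(counts["H"]), K = unname(counts["K"]),
             R = unname(counts["R"]))
  acidic <- c(Cterm = 1, C = unname(counts["C"]), D = unname(counts["D"]),
              E = unname(counts["E"]), Y = unname(counts["Y"]))
  vapply(pH, function(p) {
    pos <- sum(basic / (1 + 10^(p - pka[names(basic)])))
    neg <- sum(acidic / (1 + 10^(pka[names(acidic)] - p)))
    pos - neg
  }, numeric(1))
}

#' Isoelectric point
#'
#' pH at which the net charge crosses zero, found by bisection on (0, 14).
#' The titration charge is strictly decreasing in pH, so the root is unique.
#'
#' @param residues A validated sequence string.
#' @param config A [physchemConfig()].
#' @param tol Convergence tolerance on |charge| (default 1e-4).
#' @param maxIter Iteration cap for the bisection (default 200).
#' @return pI in pH units.
#' @examples
#' isoelectricPoint("GG")  # only termini ionizable: (8.6 + 3.6) / 2 = 6.1
#' @export
isoelectricPoint <- function(residues, config = physchemConfig(),
                             tol = 1e-4, maxIter = 200L) {
  counts <- aminoAcidComposition(residues) * nchar(residues)
  lo <- 1e-9; hi <- 14 - 1e-9
  for (i in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    q <- .chargeAt(counts, mid, config$pka)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection failed to converge")  # unreachable for monotone charge
}

#' GRAVY: grand average of hydropathy
#'
#' Arithmetic mean of the hydropathy scale over all residues (Kyte-Doolittle
#' by default).
#'
#' @param residues A validated sequence string.
#' @param config A [physchemConfig()].
#' @return Dimensionless mean hydropathy in [-4.5, 4.5] for the default scale.
#' @examples
#' gravy("AAAA")  # 1.8
#' gravy("AR")    # (1.8 - 4.5) / 2 = -1.35
#' @export
gravy <- function(residues, config = physchemConfig()) {
  h <- config$hydropathy[aminoAcidAlphabet()]
  mean(h[encodeResidues(residues)])
}

#' All physicochemical features for a dataset
#'
#' Computes, per record: `length`, `molecular_weight`, `net_charge` (at the
#' configured pH), `pI`, `gravy`, charged-residue counts `n_positive` (K+R)
#' and `n_negative` (D+E), and the corresponding per-length densities
#' `positive_density`, `negative_density`.  Densities rather than raw counts
#' are intended for correlation analysis so that length does not confound.
#'
#' @param dataset An [ExpressionDataset-class].
#' @param config A [physchemConfig()].
#' @return data.frame, one row per record, ids as row names.
#' @export
physchemFeatures <- function(dataset, config = physchemConfig()) {
  seqs <- as.character(sequenceSet(dataset))
  len <- nchar(seqs)
  comp <- t(vapply(seqs, aminoAcidComposition, numeric(20)))
  nPos <- round((comp[, "K"] + comp[, "R"]) * len)
  nNeg <- round((comp[, "D"] + comp[, "E"]) * len)
  data.frame(
    length = len,
    molecular_weight = vapply(seqs, molecularWeight, numeric(1), config = config),
    net_charge = vapply(seqs, netCharge, numeric(1), pH = config$chargePH,
                        config = config),
    pI = vapply(seqs, isoelectricPoint, numeric(1), config = config),
    gravy = vapply(seqs, gravy, numeric(1), config = config),
    n_positive = as.integer(nPos),
    n_negative = as.integer(nNeg),
    positive_density = nPos / len,
    negative_density = nNeg / len,
    row.names = names(dataset))
}
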
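# Residue-level lookup tables: alphabet, hydropathy, masses, pKa sets,
# disorder propensities.  All tables cover exactly the 20 standard residues.

#' The 20 standard amino-acid one-letter codes
#'
#' @return Character vector of the 20 canonical residue letters, sorted.
#' @export
aminoAcidAlphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy values; the mean over a sequence is its GRAVY
#' (grand average of hydropathy).  Range -4.5 (R) to +4.5 (I).
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
kdHydropathy <- function() {
  c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
    Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
    L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
    S = -0.8, T = -0.7, V =  4.2, W = -0.9, Y = -1.3)
}

#' Average residue masses
#'
#' Average (not monoisotopic) masses of amino-acid residues in Da, i.e. the
#' free amino acid minus one water.  Summing residue masses and adding one
#' water (18.0153 Da) gives the average molecular weight of the peptide,
#' following the ProtParam convention.
#'
#' @return Named numeric vector of residue masses in Da.
#' @export
residueMasses <- function() {
  c(A =  71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G =  57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P =  97.1167,
    S =  87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V =  99.1326)
}

# mass of one water molecule, Da
WATER_MASS <- 18.0153

#' EMBOSS pKa set for protein titration
#'
#' Default pKa values of the ionizable groups used by the charge and pI
#' calculations: the termini plus C, D, E, H, K, R, Y side chains.  These are
#' the EMBOSS values; an alternative set (e.g. Bjellqvist) can be supplied
#' through [physchemConfig()].
#'
#' @return Named numeric vector; names `Nterm`, `Cterm` and the residue codes.
#' @export
embossPka <- function() {
  c(Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
}

#' Per-residue disorder propensity scale
#'
#' TOP-IDP-style scale in which positive values mark disorder-promoting
#' residues (P, E, K, S ...) and negative values order-promoting ones
#' (W, F, I, Y ...).  Used by the baseline disorder profile.
#'
#' @return Named numeric vector over the 20 standard residues.
#' @export
disorderPropensity <- function() {
  c(A =  0.060, R =  0.180, N =  0.007, D =  0.192, C =  0.020,
    Q =  0.318, E =  0.736, G =  0.166, H =  0.303, I = -0.486,
    L = -0.326, K =  0.586, M = -0.397, F = -0.697, P =  0.987,
    S =  0.341, T =  0.059, V = -0.121, W = -0.884, Y = -0.510)
}

#' Heptad-position coiled-coil propensities
#'
#' Reads the bundled editable table of per-residue propensities at the seven
#' heptad positions a-g used by the sliding-window coiled-coil score.  Values
#' above 1 mark enrichment at that position in coiled-coil segments
#' (hydrophobics at a/d, charged residues at e/g).
#'
#' @param path Path to a propensity table; defaults to the bundled file.
#' @return Numeric matrix, 20 rows (residues) x 7 columns (`a` .. `g`).
#' @export
coiledCoilPropensities <- function(path = system.file("extdata",
                                                      "coiled_coil_propensities.tsv",
                                                      package = "soluprof")) {
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(identical(sort(tab$residue), aminoAcidAlphabet()))
  m <- as.matrix(tab[, c("a", "b", "c", "d", "e", "f", "g")])
  rownames(m) <- tab$residue
  if (any(m <= 0)) stop("coiled-coil propensities must be strictly positive")
  m
}

# integer-encode a residue string over the alphabet; NA for foreign symbols
encodeResidues <- function(residues) {
  match(strsplit(residues, "")[[1]], aminoAcidAlphabet())
}
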
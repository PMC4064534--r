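# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written with different numerics / machinery than
# the implementation paths they check.

randomSequence <- function(len, weights = NULL) {
  ab <- aminoAcidAlphabet()
  paste(sample(ab, len, replace = TRUE, prob = weights), collapse = "")
}

smallDataset <- function(n = 60, seed = 42, lengths = 40:80) {
  set.seed(seed)
  seqs <- setNames(vapply(seq_len(n), function(i)
    randomSequence(sample(lengths, 1)), character(1)),
    sprintf("rec%03d", seq_len(n)))
  ExpressionDataset(seqs,
                    category = sample(c("A", "C", "N"), n, replace = TRUE))
}

# --- Fisher oracle: direct hypergeometric enumeration via choose() ---------
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; N <- r1 + r2
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  xs <- lo:hi
  probs <- vapply(xs, function(x) choose(r1, x) * choose(r2, c1 - x),
                  numeric(1)) / choose(N, c1)
  pobs <- probs[xs == a]
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# --- pI oracle: 0.001-pH grid scan of the titration charge -----------------
piGridOracle <- function(residues) {
  ph <- seq(0.001, 13.999, by = 0.001)
  q <- netCharge(residues, ph)
  ph[which.min(abs(q))]
}

# --- PROSITE oracle: regex translation, overlapping matches via lookahead --
# Variable repeats become lazy quantifiers, so the per-start match is the
# lazy-shortest one, the same convention the scanner documents.
prositeToRegex <- function(raw) {
  txt <- trimws(sub("\\.$", "", raw))
  anchS <- startsWith(txt, "<"); if (anchS) txt <- substring(txt, 2)
  anchE <- endsWith(txt, ">");   if (anchE) txt <- substr(txt, 1, nchar(txt) - 1)
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  parts <- vapply(toks, function(tok) {
    m <- regmatches(tok, regexec(
      "^([A-Z]|x|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    body <- m[2]
    core <- if (body == "x") "."
            else if (startsWith(body, "{"))
              paste0("[^", substr(body, 2, nchar(body) - 1), "]")
            else body
    rep <- if (is.na(m[4]) || m[4] == "") ""
           else if (is.na(m[6]) || m[6] == "") sprintf("{%s}", m[4])
           else sprintf("{%s,%s}?", m[4], m[6])
    paste0(core, rep)
  }, character(1))
  rx <- paste0("(?=(", paste0(parts, collapse = ""),
               if (anchE) "$" else "", "))")
  if (anchS) paste0("^", rx) else rx
}

oracleScan <- function(residues, raw) {
  m <- gregexpr(prositeToRegex(raw), residues, perl = TRUE)[[1]]
  if (m[1] == -1)
    return(data.frame(start = integer(0), end = integer(0)))
  cs <- attr(m, "capture.start")[, 1]
  cl <- attr(m, "capture.length")[, 1]
  data.frame(start = as.integer(cs), end = as.integer(cs + cl - 1L))
}

# --- coiled-coil oracle: explicit loop over all windows and registers ------
coiledCoilOracle <- function(residues, window = 28L,
                             prop = coiledCoilPropensities()) {
  chars <- strsplit(residues, "")[[1]]
  L <- length(chars)
  score <- numeric(L)
  if (L < window) return(score)
  for (w0 in seq_len(L - window + 1L)) {
    best <- 0
    for (reg in 0:6) {
      g <- 1
      for (k in 0:(window - 1L)) {
        hp <- ((w0 + k - 1L + reg) %% 7L) + 1L
        g <- g * prop[chars[w0 + k], hp]
      }
      best <- max(best, g^(1 / window))
    }
    idx <- w0:(w0 + window - 1L)
    score[idx] <- pmax(score[idx], best)
  }
  score
}
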
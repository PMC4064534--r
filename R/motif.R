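# PROSITE-syntax pattern engine and the bundled PTM/motif catalogue.
#
# Grammar supported (classical PROSITE pattern syntax):
#   elements separated by '-'; each element is a literal residue, the
#   wildcard 'x', a residue set '[ST]', or a complement set '{P}', optionally
#   followed by a repeat '(n)' or '(n,m)'.  A leading '<' anchors the match
#   to the N-terminus, a trailing '>' to the C-terminus; a trailing '.' is
#   tolerated and stripped.
#
# Matching semantics: every start position is examined independently
# (overlapping matches are reported); at a given start, variable repeats are
# resolved lazily -- earlier elements take their minimal repeat count first --
# and the first (shortest-by-that-order) match is reported.  Coordinates are
# 1-based inclusive.

# maximum number of fixed-width expansions of a variable-repeat pattern
.MAX_ALTERNATIVES <- 4096L

#' Parse a PROSITE-syntax pattern
#'
#' @param raw Pattern text, e.g. `"N-{P}-[ST]-{P}"`.
#' @param name Optional pattern name.
#' @return A [MotifPattern-class] with parsed elements and compiled
#'   fixed-width expansions.
#' @examples
#' parseProsite("N-{P}-[ST]-{P}", "ASN_GLYCOSYLATION")
#' @export
parseProsite <- function(raw, name = raw) {
  if (!is.character(raw) || length(raw) != 1L || !nzchar(trimws(raw)))
    stop("pattern text must be a non-empty string")
  txt <- trimws(raw)
  txt <- sub("\\.$", "", txt)
  anchoredStart <- startsWith(txt, "<")
  if (anchoredStart) txt <- substring(txt, 2L)
  anchoredEnd <- endsWith(txt, ">")
  if (anchoredEnd) txt <- substring(txt, 1L, nchar(txt) - 1L)
  if (!nzchar(txt)) stop(sprintf("pattern '%s': no elements", raw))

  tokens <- strsplit(txt, "-", fixed = TRUE)[[1]]
  alphabet <- aminoAcidAlphabet()
  elements <- lapply(seq_along(tokens), function(i) {
    tok <- tokens[[i]]
    m <- regmatches(tok, regexec(
      "^([A-Z]|x|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    if (!length(m))
      stop(sprintf("pattern '%s': malformed element '%s' at token %d",
                   raw, tok, i))
    body <- m[2]
    if (body == "x") {
      residues <- alphabet
    } else if (startsWith(body, "[")) {
      residues <- strsplit(substr(body, 2L, nchar(body) - 1L), "")[[1]]
    } else if (startsWith(body, "{")) {
      excl <- strsplit(substr(body, 2L, nchar(body) - 1L), "")[[1]]
      if (!all(excl %in% alphabet))
        stop(sprintf("pattern '%s': non-standard residue in '%s' at token %d",
                     raw, tok, i))
      residues <- setdiff(alphabet, excl)
    } else {
      residues <- body
    }
    if (!all(residues %in% alphabet))
      stop(sprintf("pattern '%s': non-standard residue in '%s' at token %d",
                   raw, tok, i))
    if (!length(residues))
      stop(sprintf("pattern '%s': empty residue set at token %d", raw, i))
    lo <- if (is.na(m[4]) || m[4] == "") 1L else as.integer(m[4])
    hi <- if (is.na(m[6]) || m[6] == "") lo else as.integer(m[6])
    if (hi < lo)
      stop(sprintf("pattern '%s': repeat max < min at token %d", raw, i))
    list(residues = residues, min = lo, max = hi)
  })

  new("MotifPattern", name = name, raw = raw, elements = elements,
      anchoredStart = anchoredStart, anchoredEnd = anchoredEnd,
      alternatives = .compileAlternatives(elements))
}

# Expand variable repeats into an ordered list of fixed-width alternatives.
# Each alternative is a 20 x width logical membership matrix (residue allowed
# at offset).  Order is lazy: the repeat count of the EARLIEST variable
# element varies slowest and starts at its minimum, matching the backtracking
# order of a lazy regular-expression engine.
.compileAlternatives <- function(elements) {
  spans <- lapply(elements, function(e) seq(e$min, e$max))
  nAlt <- prod(vapply(spans, length, numeric(1)))
  if (nAlt > .MAX_ALTERNATIVES)
    stop(sprintf("pattern expands to %d alternatives (limit %d)",
                 nAlt, .MAX_ALTERNATIVES))
  # expand.grid varies the first factor fastest; feed reversed spans so the
  # first ELEMENT varies slowest, then restore column order
  grid <- do.call(expand.grid, rev(spans))
  grid <- grid[, rev(seq_along(spans)), drop = FALSE]
  alphabet <- aminoAcidAlphabet()
  memberOf <- lapply(elements, function(e) alphabet %in% e$residues)
  lapply(seq_len(nrow(grid)), function(r) {
    counts <- as.integer(grid[r, ])
    cols <- rep(seq_along(elements), counts)
    width <- length(cols)
    mat <- matrix(FALSE, nrow = 20L, ncol = max(width, 1L))
    for (j in seq_along(cols)) mat[, j] <- memberOf[[cols[j]]]
    list(width = width, member = mat)
  })
}

#' Scan a sequence with a PROSITE pattern
#'
#' Reports one match per matching start position (overlaps allowed); at a
#' start with several viable widths the lazy-shortest match is reported.
#'
#' @param residues A validated sequence string.
#' @param pattern A [MotifPattern-class] or PROSITE-syntax text.
#' @return data.frame with columns `pattern`, `start`, `end` (1-based,
#'   inclusive), sorted by `start`.
#' @examples
#' scanProsite("NGSA", "N-{P}-[ST]-{P}")   # one match, 1..4
#' @export
scanProsite <- function(residues, pattern) {
  if (is.character(pattern)) pattern <- parseProsite(pattern)
  stopifnot(is(pattern, "MotifPattern"))
  seqInt <- encodeResidues(residues)
  L <- length(seqInt)
  starts <- if (pattern@anchoredStart) 1L else seq_len(L)
  matchedEnd <- rep(NA_integer_, length(starts))
  for (alt in pattern@alternatives) {
    w <- alt$width
    if (w == 0L) next
    open <- which(is.na(matchedEnd) & starts + w - 1L <= L)
    if (pattern@anchoredEnd)
      open <- open[starts[open] + w - 1L == L]
    if (!length(open)) next
    ok <- rep(TRUE, length(open))
    for (off in seq_len(w)) {
      ok[ok] <- alt$member[cbind(seqInt[starts[open[ok]] + off - 1L], off)]
      if (!any(ok)) break
    }
    matchedEnd[open[ok]] <- starts[open[ok]] + w - 1L
  }
  hit <- which(!is.na(matchedEnd))
  data.frame(pattern = rep(pattern@name, length(hit)),
             start = starts[hit], end = matchedEnd[hit],
             stringsAsFactors = FALSE)
}

#' Read a motif catalogue file
#'
#' One pattern per non-comment line: `name<TAB>pattern<TAB>kind` with kind
#' `"count"` (discrete site count) or `"binary"` (presence only).  The
#' bundled catalogue carries the classical consensus patterns for the PTM
#' classes analyzed by the pipeline (N-glycosylation, phosphorylation by
#' PKA/PKC/CK2 and tyrosine kinases, myristoylation, amidation, Asx
#' hydroxylation, tyrosine sulfation, CAAX prenylation, glycosaminoglycan
#' attachment).
#'
#' @param path Catalogue path; defaults to the bundled file.
#' @return A [MotifCatalogue-class].
#' @export
readMotifCatalogue <- function(path = system.file("extdata",
                                                  "motif_catalogue.tsv",
                                                  package = "soluprof")) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 3L)
  if (length(bad))
    stop(sprintf("catalogue line %d: expected name<TAB>pattern<TAB>kind", bad[1]))
  nms <- vapply(parts, `[[`, character(1), 1L)
  if (anyDuplicated(nms))
    stop("duplicate pattern names in catalogue")
  pats <- lapply(parts, function(p) parseProsite(p[[2]], name = p[[1]]))
  kind <- vapply(parts, `[[`, character(1), 3L)
  if (!all(kind %in% c("count", "binary")))
    stop("catalogue kind must be 'count' or 'binary'")
  new("MotifCatalogue", patterns = setNames(pats, nms),
      kind = setNames(kind, nms))
}

#' Count motif sites across a dataset
#'
#' Scans every record with every catalogue pattern and returns, per pattern,
#' the per-record site count and presence flag.
#'
#' @param dataset An [ExpressionDataset-class].
#' @param catalogue A [MotifCatalogue-class].
#' @return List with `counts` (integer matrix, records x patterns),
#'   `presence` (logical matrix) and `matches` (data.frame `id`, `pattern`,
#'   `start`, `end` of every site).
#' @export
countMotifSites <- function(dataset, catalogue) {
  if (!length(catalogue@patterns)) stop("catalogue is empty")
  seqs <- as.character(sequenceSet(dataset))
  ids <- names(dataset)
  perPattern <- lapply(catalogue@patterns, function(pat) {
    hits <- lapply(seqs, scanProsite, pattern = pat)
    nHit <- vapply(hits, nrow, integer(1))
    list(counts = nHit,
         matches = if (any(nHit > 0)) {
           cbind(id = rep(ids, nHit), do.call(rbind, hits))
         } else NULL)
  })
  counts <- vapply(perPattern, `[[`, integer(length(seqs)), "counts")
  if (is.null(dim(counts)))
    counts <- matrix(counts, nrow = length(seqs),
                     dimnames = list(NULL, names(catalogue@patterns)))
  rownames(counts) <- ids
  matches <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(perPattern, `[[`, "matches")))
  if (is.null(matches))
    matches <- data.frame(id = character(0), pattern = character(0),
                          start = integer(0), end = integer(0))
  rownames(matches) <- NULL
  list(counts = counts, presence = counts > 0L, matches = matches)
}
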
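# S4 classes for the central containers.

#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom S4Vectors DataFrame
NULL

#' ExpressionDataset: sequences with cell-free expression outcomes
#'
#' The central container: an [Biostrings::AAStringSet] of protein sequences
#' (unique ids as names, 20-letter standard alphabet only), an optional
#' per-record outcome table (`expressed`, `soluble_yield` in mg per ml of
#' extract, `full_length`), and the A/C/N expression category of every
#' record.  When outcomes are present the stored category always equals the
#' category implied by [assignCategory()] at the dataset's yield threshold.
#'
#' @slot sequences An `AAStringSet`; names are the record ids.
#' @slot outcome A `DataFrame` with columns `expressed`, `soluble_yield`,
#'   `full_length` (zero rows when categories were supplied directly).
#' @slot category Factor with levels `A`, `C`, `N`, one value per record.
#' @slot yieldThreshold Soluble-yield threshold (mg/ml) separating A from C.
#'
#' @seealso [ExpressionDataset()] for construction,
#'   [readExpressionDataset()] for file input.
#' @export
setClass("ExpressionDataset",
         slots = c(sequences = "AAStringSet",
                   outcome = "DataFrame",
                   category = "factor",
                   yieldThreshold = "numeric"))

setValidity("ExpressionDataset", function(object) {
  msgs <- character(0)
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n < 1L) msgs <- c(msgs, "dataset must contain at least one record")
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msgs <- c(msgs, "every sequence must have a non-empty id")
  if (anyDuplicated(ids))
    msgs <- c(msgs, sprintf("duplicate ids: %s",
                            paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  bad <- grepl(sprintf("[^%s]", paste(aminoAcidAlphabet(), collapse = "")),
               as.character(object@sequences))
  if (any(bad))
    msgs <- c(msgs, sprintf("non-standard residues in: %s",
                            paste(ids[bad], collapse = ", ")))
  if (length(object@category) != n ||
      !identical(levels(object@category), c("A", "C", "N")))
    msgs <- c(msgs, "category must be a factor with levels A, C, N, one per record")
  if (anyNA(object@category))
    msgs <- c(msgs, "category may not contain NA")
  if (length(object@yieldThreshold) != 1L || !is.finite(object@yieldThreshold) ||
      object@yieldThreshold <= 0)
    msgs <- c(msgs, "yieldThreshold must be a single positive number")
  if (nrow(object@outcome) > 0L) {
    if (nrow(object@outcome) != n)
      msgs <- c(msgs, "outcome table must have one row per record")
    else {
      implied <- assignCategory(object@outcome$expressed,
                                object@outcome$soluble_yield,
                                object@outcome$full_length,
                                categorizationConfig(object@yieldThreshold))
      if (!identical(as.character(implied), as.character(object@category)))
        msgs <- c(msgs, "stored categories disagree with outcomes at the yield threshold")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' MotifPattern: a parsed PROSITE-syntax pattern
#'
#' @slot name Pattern name.
#' @slot raw The PROSITE-syntax source text.
#' @slot elements List of parsed elements; each element is a list with
#'   `residues` (allowed residue letters), `min`, `max` repeat counts.
#' @slot anchoredStart,anchoredEnd Logical anchor flags (`<` / `>`).
#' @slot alternatives Compiled fixed-width expansions used by the scanner,
#'   ordered so that earlier elements take their minimal repeat count first.
#' @seealso [parseProsite()], [scanProsite()]
#' @export
setClass("MotifPattern",
         slots = c(name = "character", raw = "character",
                   elements = "list",
                   anchoredStart = "logical", anchoredEnd = "logical",
                   alternatives = "list"))

#' MotifCatalogue: a named set of motif patterns
#'
#' @slot patterns Named list of [MotifPattern-class] objects.
#' @slot kind Character vector, per pattern, `"count"` or `"binary"`.
#' @seealso [readMotifCatalogue()]
#' @export
setClass("MotifCatalogue",
         slots = c(patterns = "list", kind = "character"))

setValidity("MotifCatalogue", function(object) {
  msgs <- character(0)
  nm <- names(object@patterns)
  if (is.null(nm) || anyDuplicated(nm))
    msgs <- c(msgs, "patterns must be uniquely named")
  if (!all(vapply(object@patterns, is, logical(1), "MotifPattern")))
    msgs <- c(msgs, "all entries must be MotifPattern objects")
  if (length(object@kind) != length(object@patterns) ||
      !all(object@kind %in% c("count", "binary")))
    msgs <- c(msgs, "kind must be 'count' or 'binary', one per pattern")
  if (length(msgs)) msgs else TRUE
})
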
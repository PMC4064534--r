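# Categorical assessment of cell-free expression outcomes and dataset I/O.
#
# Every record is scored into exactly one of three mutually exclusive
# categories: A (soluble product above the yield threshold), C (expressed
# full-length but insoluble or below threshold in the soluble fraction),
# N (non-expressed, or expressed at lower than the expected molecular size).

#' Categorization configuration
#'
#' @param yieldThreshold Soluble yield (mg per ml of cell-free extract) above
#'   which an expressed, full-length product is scored A.  Default 0.1 mg/ml.
#'   A yield exactly equal to the threshold is scored C ("more than" rule).
#' @return A list of class `CategorizationConfig`.
#' @export
categorizationConfig <- function(yieldThreshold = 0.1) {
  if (!is.numeric(yieldThreshold) || length(yieldThreshold) != 1L ||
      !is.finite(yieldThreshold) || yieldThreshold <= 0)
    stop("yieldThreshold must be a single strictly positive number")
  structure(list(yieldThreshold = yieldThreshold),
            class = "CategorizationConfig")
}

#' Validate and canonicalize an amino-acid sequence
#'
#' Strips whitespace, upper-cases, and rejects any symbol outside the 20
#' standard one-letter codes (ambiguity codes B/Z/X/U, stops `*` and gaps
#' are rejected, naming the first offending position).
#'
#' @param id Record identifier (used in error messages).
#' @param raw Raw sequence text.
#' @return The canonical uppercase sequence string.
#' @examples
#' validateSequence("p1", "acdk")   # "ACDK"
#' @export
validateSequence <- function(id, raw) {
  s <- toupper(gsub("[[:space:]]", "", raw))
  if (!nzchar(s))
    stop(sprintf("sequence '%s': empty after whitespace stripping", id))
  bad <- regexpr(sprintf("[^%s]", paste(aminoAcidAlphabet(), collapse = "")), s)
  if (bad > 0L)
    stop(sprintf("sequence '%s': non-standard symbol '%s' at position %d",
                 id, substr(s, bad, bad), bad))
  s
}

#' Assign A/C/N expression categories
#'
#' Vectorized categorical scoring of expression outcomes:
#' A if expressed, full length and soluble yield strictly above the
#' threshold; C if expressed and full length but at or below it; N if not
#' expressed or truncated (lower than expected molecular size).
#'
#' @param expressed Logical: was any product detected.
#' @param solubleYield Soluble yield, mg per ml of extract, finite and >= 0.
#' @param fullLength Logical: product at the expected molecular size.
#' @param config A [categorizationConfig()].
#' @return Factor with levels `A`, `C`, `N`.
#' @examples
#' assignCategory(TRUE, 0.5, TRUE)    # A
#' assignCategory(TRUE, 0.0, TRUE)    # C
#' assignCategory(TRUE, 0.5, FALSE)   # N (truncated)
#' @export
assignCategory <- function(expressed, solubleYield, fullLength,
                           config = categorizationConfig()) {
  n <- length(expressed)
  stopifnot(length(solubleYield) == n, length(fullLength) == n)
  if (anyNA(expressed) || anyNA(solubleYield) || anyNA(fullLength))
    stop("outcome fields may not contain NA")
  if (any(!is.finite(solubleYield)) || any(solubleYield < 0))
    stop("soluble_yield must be finite and non-negative")
  if (any(!expressed & solubleYield >= config$yieldThreshold))
    stop("a non-expressed record cannot have soluble_yield at or above the threshold")
  cat <- ifelse(!expressed | !fullLength, "N",
                ifelse(solubleYield > config$yieldThreshold, "A", "C"))
  factor(cat, levels = c("A", "C", "N"))
}

#' Construct an ExpressionDataset
#'
#' @param sequences Named character vector or `AAStringSet` of sequences
#'   (ids as names); validated with [validateSequence()].
#' @param outcome Optional data.frame with columns `expressed`,
#'   `soluble_yield`, `full_length` (one row per sequence, same order);
#'   categories are derived from it.
#' @param category Optional pre-assigned categories (`"A"/"C"/"N"`), used
#'   when no outcome table is available.
#' @param config A [categorizationConfig()].
#' @return An [ExpressionDataset-class].
#' @export
ExpressionDataset <- function(sequences, outcome = NULL, category = NULL,
                              config = categorizationConfig()) {
  if (is(sequences, "AAStringSet")) sequences <- as.character(sequences)
  ids <- names(sequences)
  if (is.null(ids)) stop("sequences must be named by record id")
  seqs <- vapply(seq_along(sequences),
                 function(i) validateSequence(ids[[i]], sequences[[i]]),
                 character(1))
  aas <- AAStringSet(setNames(seqs, ids))
  if (!is.null(outcome)) {
    outcome <- DataFrame(expressed = as.logical(outcome$expressed),
                         soluble_yield = as.numeric(outcome$soluble_yield),
                         full_length = as.logical(outcome$full_length))
    category <- assignCategory(outcome$expressed, outcome$soluble_yield,
                               outcome$full_length, config)
  } else {
    if (is.null(category)) stop("supply either an outcome table or categories")
    if (!all(as.character(category) %in% c("A", "C", "N")))
      stop("categories must be A, C or N")
    category <- factor(as.character(category), levels = c("A", "C", "N"))
    outcome <- DataFrame(expressed = logical(0), soluble_yield = numeric(0),
                         full_length = logical(0))
  }
  new("ExpressionDataset", sequences = aas, outcome = outcome,
      category = category, yieldThreshold = config$yieldThreshold)
}

#' Read an expression dataset from FASTA + outcome TSV
#'
#' The outcome table is tab-separated with a header and either the columns
#' `id, expressed, soluble_yield, full_length` (categories derived by
#' [assignCategory()]) or `id, category` (categories taken verbatim).
#' Record order follows the FASTA file; every FASTA id must have exactly one
#' outcome row and vice versa.
#'
#' @param fastaPath Path to a protein FASTA file.
#' @param outcomesPath Path to the outcome TSV.
#' @param config A [categorizationConfig()].
#' @param dropInvalid If `TRUE`, records whose sequence fails validation are
#'   skipped with a warning instead of aborting the read.
#' @return An [ExpressionDataset-class].
#' @export
readExpressionDataset <- function(fastaPath, outcomesPath,
                                  config = categorizationConfig(),
                                  dropInvalid = FALSE) {
  aas <- readAAStringSet(fastaPath)
  names(aas) <- sub("\\s.*$", "", names(aas))
  ids <- names(aas)
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  tab <- read.delim(outcomesPath, stringsAsFactors = FALSE)
  if (!"id" %in% names(tab)) stop("outcome table must have an 'id' column")
  if (anyDuplicated(tab$id))
    stop(sprintf("duplicate outcome ids: %s",
                 paste(unique(tab$id[duplicated(tab$id)]), collapse = ", ")))
  orphanFasta <- setdiff(ids, tab$id)
  orphanTab <- setdiff(tab$id, ids)
  if (length(orphanFasta) || length(orphanTab))
    stop(sprintf("id mismatch between FASTA and outcomes; FASTA-only: [%s]; table-only: [%s]",
                 paste(orphanFasta, collapse = ", "),
                 paste(orphanTab, collapse = ", ")))
  tab <- tab[match(ids, tab$id), , drop = FALSE]

  seqs <- as.character(aas)
  if (dropInvalid) {
    ok <- vapply(seq_along(seqs), function(i) {
      tryCatch({ validateSequence(ids[[i]], seqs[[i]]); TRUE },
               error = function(e) { warning(conditionMessage(e),
                                             call. = FALSE); FALSE })
    }, logical(1))
    seqs <- seqs[ok]; ids <- ids[ok]; tab <- tab[ok, , drop = FALSE]
    if (!length(seqs)) stop("no valid records left after --drop-invalid")
  }

  hasOutcome <- all(c("expressed", "soluble_yield", "full_length") %in% names(tab))
  if (hasOutcome) {
    for (col in c("expressed", "full_length")) {
      v <- tab[[col]]
      if (is.character(v)) v <- toupper(v) %in% c("TRUE", "T", "1", "YES")
      tab[[col]] <- as.logical(v)
      if (anyNA(tab[[col]]))
        stop(sprintf("malformed '%s' value at line %d of %s", col,
                     which(is.na(tab[[col]]))[1] + 1L, outcomesPath))
    }
    tab$soluble_yield <- suppressWarnings(as.numeric(tab$soluble_yield))
    if (anyNA(tab$soluble_yield))
      stop(sprintf("malformed soluble_yield at line %d of %s",
                   which(is.na(tab$soluble_yield))[1] + 1L, outcomesPath))
    ExpressionDataset(setNames(seqs, ids), outcome = tab, config = config)
  } else if ("category" %in% names(tab)) {
    bad <- which(!tab$category %in% c("A", "C", "N"))
    if (length(bad))
      stop(sprintf("malformed category '%s' at line %d of %s",
                   tab$category[bad[1]], bad[1] + 1L, outcomesPath))
    ExpressionDataset(setNames(seqs, ids), category = tab$category,
                      config = config)
  } else {
    stop("outcome table needs columns id, expressed, soluble_yield, full_length or id, category")
  }
}

#' Write an expression dataset to FASTA + outcome TSV
#'
#' Inverse of [readExpressionDataset()]: sequences go to FASTA, outcomes (or
#' bare categories when no outcomes are stored) to a TSV.
#'
#' @param x An [ExpressionDataset-class].
#' @param fastaPath,outcomesPath Output paths.
#' @return Invisibly, `x`.
#' @export
writeExpressionDataset <- function(x, fastaPath, outcomesPath) {
  writeXStringSet(sequenceSet(x), fastaPath)
  if (nrow(outcomes(x))) {
    tab <- data.frame(id = names(x),
                      expressed = outcomes(x)$expressed,
                      soluble_yield = outcomes(x)$soluble_yield,
                      full_length = outcomes(x)$full_length)
  } else {
    tab <- data.frame(id = names(x), category = as.character(categories(x)))
  }
  write.table(tab, outcomesPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Export a dataset summary table
#'
#' One row per record with `id`, `length` and `category`, as TSV or JSON.
#'
#' @param x An [ExpressionDataset-class].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return Invisibly, the exported data.frame.
#' @export
exportDatasetSummary <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  tab <- data.frame(id = names(x),
                    length = width(sequenceSet(x)),
                    category = as.character(categories(x)))
  if (format == "tsv")
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  else
    jsonlite::write_json(tab, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(tab)
}
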
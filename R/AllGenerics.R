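# Generics and accessors for the S4 containers.

#' @describeIn ExpressionDataset-class Number of records.
#' @param x,object An `ExpressionDataset`.
#' @export
setMethod("length", "ExpressionDataset", function(x) length(x@sequences))

#' @describeIn ExpressionDataset-class Record ids.
#' @export
setMethod("names", "ExpressionDataset", function(x) names(x@sequences))

#' Extract the sequences of a dataset
#'
#' @param x An [ExpressionDataset-class].
#' @return The `AAStringSet` of sequences.
#' @export
setGeneric("sequenceSet", function(x) standardGeneric("sequenceSet"))

#' @rdname sequenceSet
#' @export
setMethod("sequenceSet", "ExpressionDataset", function(x) x@sequences)

#' Extract the A/C/N categories of a dataset
#'
#' @param x An [ExpressionDataset-class].
#' @return Factor with levels `A`, `C`, `N`, named by record id.
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname categories
#' @export
setMethod("categories", "ExpressionDataset",
          function(x) setNames(x@category, names(x@sequences)))

#' Extract the outcome table of a dataset
#'
#' @param x An [ExpressionDataset-class].
#' @return `DataFrame` with columns `expressed`, `soluble_yield`,
#'   `full_length`; zero rows when categories were supplied directly.
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' @rdname outcomes
#' @export
setMethod("outcomes", "ExpressionDataset", function(x) x@outcome)

#' Yield threshold of a dataset
#'
#' @param x An [ExpressionDataset-class].
#' @return The soluble-yield threshold (mg/ml) separating category A from C.
#' @export
setGeneric("yieldThreshold", function(x) standardGeneric("yieldThreshold"))

#' @rdname yieldThreshold
#' @export
setMethod("yieldThreshold", "ExpressionDataset", function(x) x@yieldThreshold)

#' @describeIn ExpressionDataset-class Subset records by index, id or logical.
#' @param i Index vector.
#' @param j,drop,... Ignored; present for generic compatibility.
#' @export
setMethod("[", "ExpressionDataset", function(x, i, j, ..., drop = TRUE) {
  new("ExpressionDataset",
      sequences = x@sequences[i],
      outcome = if (nrow(x@outcome)) x@outcome[i, , drop = FALSE] else x@outcome,
      category = x@category[if (is.character(i)) match(i, names(x@sequences)) else i],
      yieldThreshold = x@yieldThreshold)
})

setMethod("show", "ExpressionDataset", function(object) {
  tab <- table(object@category)
  cat(sprintf("ExpressionDataset with %d records (threshold %.3g mg/ml)\n",
              length(object@sequences), object@yieldThreshold))
  cat(sprintf("  A (soluble): %d  C (insoluble): %d  N (non-expressed): %d\n",
              tab[["A"]], tab[["C"]], tab[["N"]]))
  cat(sprintf("  lengths: %d-%d residues; outcomes: %s\n",
              min(width(object@sequences)), max(width(object@sequences)),
              if (nrow(object@outcome)) "present" else "absent"))
})

setMethod("show", "MotifPattern", function(object) {
  cat(sprintf("MotifPattern '%s': %s  (%d elements%s%s)\n",
              object@name, object@raw, length(object@elements),
              if (object@anchoredStart) ", start-anchored" else "",
              if (object@anchoredEnd) ", end-anchored" else ""))
})

setMethod("show", "MotifCatalogue", function(object) {
  cat(sprintf("MotifCatalogue with %d patterns\n", length(object@patterns)))
  for (nm in names(object@patterns))
    cat(sprintf("  %-20s %-30s %s\n", nm, object@patterns[[nm]]@raw,
                object@kind[[nm]]))
})
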
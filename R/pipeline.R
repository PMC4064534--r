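# Orchestration: categorize -> featurize -> correlate -> test, ending in a
# sign-summary matrix (features x {Soluble, Insoluble, Undetectable}).

#' Compute the full feature matrix for a dataset
#'
#' Combines physicochemical features, structural features, motif-site
#' counts/presence flags and any external adapter tables into one table,
#' with a declared kind (binary / discrete / continuous) per feature.
#' Charged-residue features enter as per-length densities (continuous);
#' every motif pattern contributes `has_<pattern>` (binary presence) and
#' count-kind patterns additionally `n_<pattern>` (discrete site count).
#'
#' @param dataset An [ExpressionDataset-class].
#' @param catalogue A [MotifCatalogue-class] (default: bundled), or `NULL`
#'   to skip motif features.
#' @param physchem,struct Logical switches for the built-in feature blocks.
#' @param externalTables Character vector of adapter TSV paths (see
#'   [loadExternalFeatures()]).
#' @param physchemCfg A [physchemConfig()].
#' @return List with `values` (data.frame, records x features) and `kind`
#'   (named character vector: `"binary"`, `"discrete"` or `"continuous"`).
#' @export
computeFeatures <- function(dataset, catalogue = readMotifCatalogue(),
                            physchem = TRUE, struct = TRUE,
                            externalTables = character(0),
                            physchemCfg = physchemConfig()) {
  values <- data.frame(row.names = names(dataset))
  kind <- character(0)
  if (physchem) {
    pc <- physchemFeatures(dataset, physchemCfg)
    pc$n_positive <- NULL; pc$n_negative <- NULL  # densities go forward
    values <- cbind(values, pc)
    kind <- c(kind, setNames(rep("continuous", ncol(pc)), colnames(pc)))
    kind[["length"]] <- "discrete"
  }
  if (struct) {
    st <- structuralFeatures(dataset)
    values <- cbind(values, st)
    kind <- c(kind,
              n_pest = "discrete", max_pest_score = "continuous",
              cc_fraction = "continuous", baseline_tm_count = "discrete",
              baseline_disorder_fraction = "continuous")
  }
  if (!is.null(catalogue) && length(catalogue@patterns)) {
    ms <- countMotifSites(dataset, catalogue)
    for (nm in names(catalogue@patterns)) {
      # presence is always analyzed (yes/no test); count-kind patterns
      # additionally contribute the discrete site count
      values[[paste0("has_", nm)]] <- as.numeric(ms$presence[, nm])
      kind[[paste0("has_", nm)]] <- "binary"
      if (catalogue@kind[[nm]] == "count") {
        values[[paste0("n_", nm)]] <- ms$counts[, nm]
        kind[[paste0("n_", nm)]] <- "discrete"
      }
    }
  }
  for (path in externalTables) {
    ext <- loadExternalFeatures(path, dataset)
    for (f in names(ext$values)) {
      values[[f]] <- ext$values[[f]]
      kind[[f]] <- unname(ext$kind[[f]])
    }
  }
  if (!ncol(values)) stop("no features selected")
  list(values = values, kind = kind)
}

#' Analyze every feature against the A/C/N categories
#'
#' Binary features are tested with [binaryAssociation()]; discrete and
#' continuous features are profiled with [profileFeature()] (optionally
#' smoothed before correlation) and sign-called with [signCall()].
#'
#' @param dataset An [ExpressionDataset-class].
#' @param features Output of [computeFeatures()].
#' @param alpha Significance level (default 0.05).
#' @param nBins,minBin Binning parameters for [profileFeature()].
#' @param smoothWindow Odd moving-average window; 1 (default) correlates
#'   the unsmoothed profile.
#' @param bh Also report Benjamini-Hochberg adjusted p-values across all
#'   feature x category tests (default `TRUE`; the per-test `significant`
#'   flag still uses the raw p at `alpha`).
#' @return List with `results` (one row per feature x category: `feature`,
#'   `kind`, `category`, `n`, `statistic` (r or odds ratio), `p`,
#'   `p_bh`, `sign`) and `profiles` (named list of `CategoryProfile`s).
#' @export
analyzeFeatures <- function(dataset, features, alpha = 0.05,
                            nBins = 10L, minBin = 20L, smoothWindow = 1L,
                            bh = TRUE) {
  cats <- categories(dataset)
  rows <- list(); profiles <- list()
  for (f in colnames(features$values)) {
    v <- features$values[[f]]
    k <- features$kind[[f]]
    if (k == "binary") {
      ba <- suppressWarnings(binaryAssociation(cats, v, alpha))
      rows[[f]] <- data.frame(feature = f, kind = k, category = ba$category,
                              n = ba$a + ba$b + ba$c + ba$d,
                              statistic = ba$odds_ratio, p = ba$p,
                              sign = ba$sign, stringsAsFactors = FALSE)
    } else {
      prof <- profileFeature(cats, v, kind = k, nBins = nBins, minBin = minBin)
      if (smoothWindow > 1L) prof <- smoothProfile(prof, smoothWindow)
      profiles[[f]] <- prof
      sc <- signCall(prof, alpha)
      rows[[f]] <- data.frame(feature = f, kind = k, category = sc$category,
                              n = sc$n, statistic = sc$r,
                              p = sc$p_one_tailed, sign = sc$sign,
                              stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results$p_bh <- if (bh) stats::p.adjust(results$p, method = "BH") else NA_real_
  list(results = results, profiles = profiles)
}

#' Sign-summary matrix
#'
#' One row per feature, one column per expression category, using the
#' Soluble / Insoluble / Undetectable column semantics for A / C / N.
#'
#' @param results The `results` data.frame from [analyzeFeatures()].
#' @return data.frame with columns `feature`, `Soluble`, `Insoluble`,
#'   `Undetectable`.
#' @export
summarizeSigns <- function(results) {
  if (!nrow(results)) stop("no analyzed features")
  feats <- unique(results$feature)
  colFor <- c(A = "Soluble", C = "Insoluble", N = "Undetectable")
  out <- data.frame(feature = feats,
                    Soluble = NA_character_, Insoluble = NA_character_,
                    Undetectable = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    sub <- results[results$feature == feats[i], ]
    for (j in seq_len(nrow(sub)))
      out[i, colFor[[sub$category[j]]]] <- sub$sign[j]
  }
  out
}

#' Run the full analysis pipeline
#'
#' Categorize (read or accept a dataset) -> featurize -> profile/correlate
#' -> test -> summarize, writing the per-feature results TSV, per-feature
#' profile TSVs, the sign-summary matrix and a run log to `outDir`.
#' Outputs are deterministic given the same inputs and parameters.
#'
#' @param dataset An [ExpressionDataset-class], or `NULL` to read from
#'   `fastaPath` + `outcomesPath`.
#' @param fastaPath,outcomesPath Input files when `dataset` is `NULL`.
#' @param outDir Output directory, created if needed; `NULL` writes nothing.
#' @param catalogue Motif catalogue (`NULL` disables motif features).
#' @param physchem,struct,externalTables,alpha,nBins,minBin,smoothWindow,bh
#'   Passed through to [computeFeatures()] / [analyzeFeatures()].
#' @param categorizationCfg A [categorizationConfig()].
#' @return Invisibly, a list with `dataset`, `features`, `results`,
#'   `profiles`, `signs`.
#' @export
runPipeline <- function(dataset = NULL, fastaPath = NULL, outcomesPath = NULL,
                        outDir = NULL, catalogue = readMotifCatalogue(),
                        physchem = TRUE, struct = TRUE,
                        externalTables = character(0), alpha = 0.05,
                        nBins = 10L, minBin = 20L, smoothWindow = 1L,
                        bh = TRUE,
                        categorizationCfg = categorizationConfig()) {
  if (is.null(dataset)) {
    if (is.null(fastaPath) || is.null(outcomesPath))
      stop("stage categorize: supply a dataset or fastaPath + outcomesPath")
    dataset <- tryCatch(
      readExpressionDataset(fastaPath, outcomesPath, categorizationCfg),
      error = function(e) stop("stage categorize: ", conditionMessage(e)))
  }
  features <- tryCatch(
    computeFeatures(dataset, catalogue = catalogue, physchem = physchem,
                    struct = struct, externalTables = externalTables),
    error = function(e) stop("stage featurize: ", conditionMessage(e)))
  ana <- tryCatch(
    analyzeFeatures(dataset, features, alpha = alpha, nBins = nBins,
                    minBin = minBin, smoothWindow = smoothWindow, bh = bh),
    error = function(e) stop("stage correlate: ", conditionMessage(e)))
  signs <- summarizeSigns(ana$results)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    numFmt <- function(d) {
      for (col in names(d)) if (is.numeric(d[[col]]))
        d[[col]] <- formatC(d[[col]], digits = 10, format = "g")
      d
    }
    write.table(numFmt(ana$results), file.path(outDir, "results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(signs, file.path(outDir, "sign_summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    profDir <- file.path(outDir, "profiles")
    dir.create(profDir, showWarnings = FALSE)
    for (f in names(ana$profiles))
      write.table(numFmt(ana$profiles[[f]]$bins),
                  file.path(profDir, paste0(f, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    catSum <- if (!is.null(catalogue))
      paste(vapply(catalogue@patterns, function(p) p@raw, character(1)),
            collapse = "|") else ""
    log <- c(sprintf("soluprof %s",
                     as.character(utils::packageVersion("soluprof"))),
             sprintf("records: %d", length(dataset)),
             sprintf("alpha: %g  nBins: %d  minBin: %d  smoothWindow: %d",
                     alpha, nBins, minBin, smoothWindow),
             sprintf("yieldThreshold: %g", yieldThreshold(dataset)),
             sprintf("catalogue checksum: %08x",
                     sum(utf8ToInt(catSum) * seq_along(utf8ToInt(catSum))) %%
                       0xFFFFFFFF))
    writeLines(log, file.path(outDir, "run_log.txt"))
  }
  invisible(list(dataset = dataset, features = features,
                 results = ana$results, profiles = ana$profiles,
                 signs = signs))
}
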
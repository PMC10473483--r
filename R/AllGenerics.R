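#' Accessors for qrotate objects
#'
#' Small accessor generics so user code never reaches into slots:
#' `qValues()` returns the raw ranking matrix of a [QSortMatrix-class],
#' `gridOf()` its grid, `participants()` and `statements()` its labels;
#' `factorLoadings()` returns the loading matrix of an extraction or rotation
#' result, `communalities()` and `eigenvalues()` the corresponding spectra,
#' `zScores()` and `factorArrays()` the two faces of a [FactorScores-class],
#' `flaggedSorts()` / `loadedSorts()` the per-factor id lists of a
#' [FlagResult-class], and `distinguishing()` the per-factor statement sets.
#'
#' @param x an object of the documented class.
#' @return the slot content described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))
#' @rdname accessors
#' @export
setGeneric("statements", function(x) standardGeneric("statements"))
#' @rdname accessors
#' @export
setGeneric("factorLoadings", function(x) standardGeneric("factorLoadings"))
#' @rdname accessors
#' @export
setGeneric("communalities", function(x) standardGeneric("communalities"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("zScores", function(x) standardGeneric("zScores"))
#' @rdname accessors
#' @export
setGeneric("factorArrays", function(x) standardGeneric("factorArrays"))
#' @rdname accessors
#' @export
setGeneric("flaggedSorts", function(x) standardGeneric("flaggedSorts"))
#' @rdname accessors
#' @export
setGeneric("loadedSorts", function(x) standardGeneric("loadedSorts"))
#' @rdname accessors
#' @export
setGeneric("distinguishing", function(x) standardGeneric("distinguishing"))

#' @rdname accessors
setMethod("qValues", "QSortMatrix", function(x) {
  m <- x@values
  dimnames(m) <- list(x@statementIds, x@participantIds)
  m
})
#' @rdname accessors
setMethod("gridOf", "QSortMatrix", function(x) x@grid)
#' @rdname accessors
setMethod("gridOf", "FactorScores", function(x) x@grid)
#' @rdname accessors
setMethod("participants", "QSortMatrix", function(x) x@participantIds)
#' @rdname accessors
setMethod("statements", "QSortMatrix", function(x) x@statementIds)
#' @rdname accessors
setMethod("factorLoadings", "ExtractionResult", function(x) x@loadings)
#' @rdname accessors
setMethod("factorLoadings", "RotationResult", function(x) x@rotated)
#' @rdname accessors
setMethod("communalities", "ExtractionResult", function(x) x@communalities)
#' @rdname accessors
setMethod("communalities", "RotationResult",
          function(x) rowSums(x@rotated^2))
#' @rdname accessors
setMethod("eigenvalues", "ExtractionResult", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("zScores", "FactorScores", function(x) x@z)
#' @rdname accessors
setMethod("factorArrays", "FactorScores", function(x) x@arrays)
#' @rdname accessors
setMethod("flaggedSorts", "FlagResult", function(x) x@flagged)
#' @rdname accessors
setMethod("loadedSorts", "FlagResult", function(x) x@loaded)
#' @rdname accessors
setMethod("distinguishing", "DistinguishingSet", function(x) x@statements)

setMethod("show", "GridSpec", function(object) {
  cat("GridSpec:", length(object@columnValues), "columns,",
      sum(object@columnCapacities), "statements\n")
  cat("  values:    ", paste(sprintf("%+d", object@columnValues),
                             collapse = " "), "\n")
  cat("  capacities:", paste(sprintf("%2d", object@columnCapacities),
                             collapse = " "), "\n")
})

setMethod("show", "QSortMatrix", function(object) {
  cat(sprintf("QSortMatrix: %d statements x %d Q-sorts (%s distribution)\n",
              nrow(object@values), ncol(object@values),
              if (object@forced) "forced" else "free"))
  show(object@grid)
})

setMethod("show", "ExtractionResult", function(object) {
  cat(sprintf("ExtractionResult (%s): %d Q-sorts, %d factors\n",
              toupper(object@method), nrow(object@loadings),
              ncol(object@loadings)))
  cat("  eigenvalues:", paste(round(object@eigenvalues, 3), collapse = ", "),
      "\n")
  cat(sprintf("  explained variance: %.1f%%\n",
              100 * sum(object@eigenvalues) / nrow(object@loadings)))
})

setMethod("show", "RotationResult", function(object) {
  lab <- if (object@gamma == 0) "Quartimax"
         else if (object@gamma == 1) "Varimax"
         else sprintf("orthomax(gamma=%.3g)", object@gamma)
  cat(sprintf("RotationResult: %s, %d sweeps, criterion %.6g%s\n",
              lab, object@sweeps, object@criterion,
              if (object@converged) "" else " (max sweeps reached)"))
})

setMethod("show", "FlagResult", function(object) {
  cat(sprintf("FlagResult (threshold %.4f)\n", object@threshold))
  for (j in seq_along(object@loaded)) {
    cat(sprintf("  factor %d: %d loaded, %d flagged\n", j,
                length(object@loaded[[j]]), length(object@flagged[[j]])))
  }
  cat(sprintf("  confounded: %d, null: %d\n",
              length(object@confounded), length(object@null)))
})

setMethod("show", "FactorScores", function(object) {
  cat(sprintf("FactorScores: %d statements x %d factors\n",
              nrow(object@z), ncol(object@z)))
})

setMethod("show", "DistinguishingSet", function(object) {
  cat(sprintf("DistinguishingSet (effect size %.2f)\n", object@effectSize))
  for (j in seq_along(object@statements)) {
    s <- object@statements[[j]]
    cat(sprintf("  factor %d: %d statement(s)%s\n", j, length(s),
                if (length(s)) paste0(" [", paste(s, collapse = ", "), "]")
                else ""))
  }
})

setMethod("show", "SyntheticDataset", function(object) {
  cat(sprintf("SyntheticDataset: %d prototypes, group sizes %s\n",
              ncol(object@prototypes),
              paste(tabulate(object@trueLabels), collapse = "/")))
  show(object@qsorts)
})

setMethod("show", "ComparisonReport", function(object) {
  cat(sprintf("ComparisonReport: k = %d, threshold = %.4f, effect size = %.2f\n\n",
              object@k, object@threshold, object@effectSize))
  print(object@summary, row.names = FALSE)
})
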
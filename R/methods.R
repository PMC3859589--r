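# Accessor, show and coercion methods for the S4 containers.

#' @rdname accessors
#' @param object a metasucc S4 object.
#' @export
setMethod("counts", "AbundanceMatrix", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("sampleUnits", "AbundanceMatrix",
          function(object) rownames(object@counts))

#' @rdname accessors
#' @export
setMethod("speciesNames", "AbundanceMatrix",
          function(object) colnames(object@counts))

#' @rdname accessors
#' @export
setMethod("stratum", "AbundanceMatrix", function(object) object@stratum)

#' @rdname accessors
#' @export
setMethod("sampledArea", "AbundanceMatrix",
          function(object) object@sampledAreaM2)

#' @rdname accessors
#' @export
setMethod("unitData", "AbundanceMatrix", function(object) object@unitData)

#' @rdname accessors
#' @export
setMethod("membership", "ClassScheme", function(object) object@membership)

#' @rdname accessors
#' @export
setMethod("classSizes", "ClassScheme", function(object) {
  table(factor(object@membership, levels = object@labels))
})

#' @rdname accessors
#' @export
setMethod("ordScores", "OrdinationResult", function(object) object@scores)

#' @rdname accessors
#' @export
setMethod("pValue", "PermutationTestResult", function(object) object@pValue)

#' @export
#' @describeIn accessors dissimilarities as a base matrix.
setMethod("as.matrix", "DissimilarityMatrix", function(x, ...) x@values)

#' Convert a DissimilarityMatrix to a stats dist object
#' @param dm a [DissimilarityMatrix-class].
#' @return a \code{stats::dist}.
#' @export
asDist <- function(dm) {
  stopifnot(is(dm, "DissimilarityMatrix"))
  stats::as.dist(dm@values)
}

setMethod("show", "AbundanceMatrix", function(object) {
  cat(sprintf(
    "AbundanceMatrix: %d %s(s) x %d species (%s stratum%s)\n",
    nrow(object@counts), object@unitLevel, ncol(object@counts),
    paste(object@stratum, collapse = "+"),
    if (is.na(object@minDiameterCm)) ""
    else sprintf(", DBH >= %g cm", object@minDiameterCm)))
  cat(sprintf("  total stems: %d\n", as.integer(sum(object@counts))))
})

setMethod("show", "ClassScheme", function(object) {
  cat(sprintf("ClassScheme (%s): %d classes over %d sites\n",
              object@kind, length(object@labels), length(object@membership)))
  print(classSizes(object))
})

setMethod("show", "DissimilarityMatrix", function(object) {
  cat(sprintf("DissimilarityMatrix (%s): %d units\n",
              object@indexName, nrow(object@values)))
})

setMethod("show", "PermutationTestResult", function(object) {
  cat(sprintf("%s = %.4f, p = %.4g (%d permutations)\n",
              object@statName, object@statistic, object@pValue,
              object@permutations))
  if (length(object@details))
    cat("  ", paste(names(object@details),
                    vapply(object@details, function(d)
                      paste(signif(unlist(d), 4), collapse = ","), ""),
                    sep = "=", collapse = "; "), "\n")
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf(
    "NMDS (%s): %d units, k = %d, stress = %.4f, %sconverged\n",
    object@indexName, nrow(object@scores), object@k, object@stress,
    if (object@converged) "" else "NOT "))
})

setMethod("show", "SuccessionFit", function(object) {
  if (object@family == "ns") {
    cat("SuccessionFit: no significant model (ns)\n")
  } else {
    form <- switch(object@family,
      linear      = "y = a + b*x",
      power       = "y = a*x^b",
      exponential = "y = a*exp(b*x)")
    cat(sprintf("SuccessionFit [%s, %s]: a = %.4g, b = %.4g, R2 = %.3f, p = %.3g, n = %d\n",
                object@family, form, object@a, object@b, object@r2,
                object@pValue, object@n))
  }
})

setMethod("show", "ResampledGamma", function(object) {
  cat(sprintf(
    "Resampled gamma diversity (q = %g): mean %.2f [%.2f, %.2f] (%d x %d sites)\n",
    object@q, object@mean, object@ciLow, object@ciHigh,
    object@iterations, object@subsampleSize))
})
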
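#' @import methods
NULL

#' Sampling-unit by species abundance matrix
#'
#' Container for the stem counts of one stratum (or a pooled set of strata),
#' tallied per sampling unit (site or plot). Rows are units, columns species;
#' entries are numbers of individuals passing the stratum and minimum-diameter
#' filter. Carries the sampled area per unit so that densities remain
#' recoverable across strata censused on different areas.
#'
#' @slot counts integer-valued matrix, units x species, with dimnames.
#' @slot stratum character, the strata pooled into the matrix (subset of
#'   \code{"seedling"}, \code{"sapling"}, \code{"tree"}, \code{"liana"}).
#' @slot unitLevel \code{"site"} or \code{"plot"}.
#' @slot minDiameterCm minimum diameter applied when tallying (\code{NA} for
#'   seedlings, which carry no diameter).
#' @slot sampledAreaM2 named numeric, sampled area per unit in square metres.
#' @slot unitData data.frame of per-unit metadata (row names are unit ids);
#'   for plot-level matrices carries the parent \code{site_id}.
#'
#' @seealso [buildAbundanceMatrix()]
#' @export
setClass("AbundanceMatrix",
  slots = c(
    counts        = "matrix",
    stratum       = "character",
    unitLevel     = "character",
    minDiameterCm = "numeric",
    sampledAreaM2 = "numeric",
    unitData      = "data.frame"
  )
)

setValidity("AbundanceMatrix", function(object) {
  msg <- character()
  x <- object@counts
  if (is.null(rownames(x)) || (ncol(x) > 0 && is.null(colnames(x))))
    msg <- c(msg, "counts must have unit and species dimnames")
  if (length(x) && (any(x < 0) || any(x != round(x))))
    msg <- c(msg, "counts must be non-negative integers")
  if (ncol(x) > 0 && nrow(x) > 0 && any(colSums(x) == 0))
    msg <- c(msg, "all-zero species columns are not allowed")
  if (!object@unitLevel %in% c("site", "plot"))
    msg <- c(msg, "unitLevel must be 'site' or 'plot'")
  if (length(object@sampledAreaM2) &&
      !identical(names(object@sampledAreaM2), rownames(x)))
    msg <- c(msg, "sampledAreaM2 names must match unit order")
  if (nrow(object@unitData) && !identical(rownames(object@unitData), rownames(x)))
    msg <- c(msg, "unitData row names must match unit order")
  if (length(msg)) msg else TRUE
})

#' Site classification scheme (stand-basal-area or age classes)
#'
#' A partition of the sites of a chronosequence into ordered classes along a
#' successional axis. Stand-basal-area (SBA) classes use half-open intervals
#' (lower bound included, upper excluded); age classes use the field's
#' conventional integer labels with both ends included (e.g. "2-7 y" holds
#' ages 2, 3, ..., 7).
#'
#' @slot kind \code{"sba"} or \code{"age"}.
#' @slot boundaries ordered numeric interval edges.
#' @slot labels class labels, one fewer than \code{boundaries}.
#' @slot membership named character, site id to class label.
#'
#' @seealso [assignClasses()]
#' @export
setClass("ClassScheme",
  slots = c(
    kind       = "character",
    boundaries = "numeric",
    labels     = "character",
    membership = "character"
  )
)

setValidity("ClassScheme", function(object) {
  msg <- character()
  if (!object@kind %in% c("sba", "age"))
    msg <- c(msg, "kind must be 'sba' or 'age'")
  if (is.unsorted(object@boundaries, strictly = TRUE))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (length(object@labels) != length(object@boundaries) - 1L)
    msg <- c(msg, "need one label per interval")
  if (is.null(names(object@membership)) || anyNA(object@membership))
    msg <- c(msg, "membership must be a complete named site -> label map")
  if (length(object@membership) && !all(object@membership %in% object@labels))
    msg <- c(msg, "membership labels outside the scheme")
  if (length(msg)) msg else TRUE
})

#' Pairwise dissimilarity matrix among sampling units
#'
#' Square symmetric matrix of pairwise dissimilarities with a zero diagonal,
#' tagged with the index that produced it.
#'
#' @slot values symmetric numeric matrix with unit dimnames.
#' @slot indexName e.g. \code{"ruzicka"}, \code{"jaccard"}, \code{"chao"},
#'   \code{"morisita"}, \code{"euclidean"}.
#'
#' @seealso [dissimilarityMatrix()]
#' @export
setClass("DissimilarityMatrix",
  slots = c(values = "matrix", indexName = "character")
)

setValidity("DissimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v))) msg <- c(msg, "units must be named")
  if (nrow(v) > 0) {
    if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
    if (any(v < -1e-12)) msg <- c(msg, "dissimilarities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Result of a permutation test
#'
#' Holds the observed statistic, the number of permutations, and the one-sided
#' upper p-value computed with the +1 convention
#' \eqn{p = (1 + \#\{stat_{perm} \ge stat_{obs}\}) / (1 + n_{perm})},
#' so that \eqn{p \ge 1/(1+n_{perm})} always.
#'
#' @slot statName name of the statistic (e.g. "Mantel r", "pseudo-F").
#' @slot statistic observed value.
#' @slot permutations number of permutations used (for exhaustive tests,
#'   the number of non-identity relabelings).
#' @slot pValue the permutation p-value.
#' @slot seed RNG seed used (\code{NA} for exhaustive enumeration).
#' @slot details list of test-specific extras (R2, df, sums of squares, ...).
#' @export
setClass("PermutationTestResult",
  slots = c(
    statName     = "character",
    statistic    = "numeric",
    permutations = "integer",
    pValue       = "numeric",
    seed         = "numeric",
    details      = "list"
  )
)

setValidity("PermutationTestResult", function(object) {
  p <- object@pValue
  if (length(p) == 1 && (p <= 0 || p > 1)) "pValue must lie in (0, 1]" else TRUE
})

#' Non-metric multidimensional scaling result
#'
#' Best-of-several-starts NMDS configuration, PCA-rotated and centred so that
#' axis 1 carries the maximal variance.
#'
#' @slot scores unit x dimension coordinate matrix.
#' @slot stress Kruskal stress-1 of the best solution.
#' @slot k number of dimensions.
#' @slot nStarts number of random starts tried (a metric start is always added).
#' @slot converged TRUE when two independent starts agreed to within the
#'   Procrustes tolerance.
#' @slot procrustesRMSE Procrustes RMSE between the two best distinct solutions.
#' @slot seed RNG seed.
#' @slot indexName dissimilarity index of the input matrix.
#' @export
setClass("OrdinationResult",
  slots = c(
    scores         = "matrix",
    stress         = "numeric",
    k              = "integer",
    nStarts        = "integer",
    converged      = "logical",
    procrustesRMSE = "numeric",
    seed           = "numeric",
    indexName      = "character"
  )
)

#' Succession regression fit
#'
#' A two-parameter regression of a community metric on a successional
#' predictor: linear \eqn{y = a + b x}, power \eqn{y = a x^b}, or exponential
#' \eqn{y = a e^{b x}}. The coefficient of determination is always computed on
#' the response scale so fits are comparable across families. The family
#' \code{"ns"} marks the case where no candidate reached significance during
#' model selection.
#'
#' @slot family "linear", "power", "exponential" or "ns".
#' @slot a,b fitted parameters.
#' @slot r2 coefficient of determination on the response scale.
#' @slot pValue F-test p-value against the intercept-only model.
#' @slot n observations used.
#' @slot nDropped observations excluded (non-positive values under the
#'   power/exponential families).
#' @export
setClass("SuccessionFit",
  slots = c(
    family   = "character",
    a        = "numeric",
    b        = "numeric",
    r2       = "numeric",
    pValue   = "numeric",
    n        = "integer",
    nDropped = "integer"
  )
)

#' Resampled metacommunity (gamma) diversity
#'
#' Distribution of the Hill number of pooled random site subsets, with the
#' 0.025/0.975 empirical quantiles as confidence limits.
#'
#' @slot q Hill order.
#' @slot subsampleSize sites pooled per draw.
#' @slot iterations number of draws.
#' @slot mean mean of the resampling distribution.
#' @slot ciLow,ciHigh 0.025 and 0.975 empirical quantiles.
#' @slot values the full resampling distribution.
#' @export
setClass("ResampledGamma",
  slots = c(
    q            = "numeric",
    subsampleSize = "integer",
    iterations   = "integer",
    mean         = "numeric",
    ciLow        = "numeric",
    ciHigh       = "numeric",
    values       = "numeric"
  )
)

setValidity("ResampledGamma", function(object) {
  if (length(object@mean) == 1 &&
      (object@ciLow > object@mean + 1e-9 || object@ciHigh < object@mean - 1e-9))
    "confidence limits must bracket the mean" else TRUE
})
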
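# Non-metric multidimensional scaling with multiple starts, PCA rotation,
# and the frequent-species sensitivity analysis.

asDistInput <- function(d) {
  m <- if (is(d, "DissimilarityMatrix")) d@values else as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-10)
    stop("input must be a square symmetric dissimilarity matrix")
  if (any(m < -1e-12)) stop("negative dissimilarities")
  m
}

#' Non-metric multidimensional scaling
#'
#' Minimizes Kruskal stress-1 (monotone regression of configuration
#' distances on the input dissimilarities, primary treatment of ties; the
#' isotonic-regression engine is \code{vegan::monoMDS}) from several
#' starting configurations and keeps the best. A metric (principal
#' coordinates) start is always included alongside \code{nStarts} random
#' ones, so perfectly embeddable inputs are recovered exactly. The best
#' configuration is centred and PCA-rotated so axis 1 carries maximal
#' variance; when site ages are supplied the sign of axis 1 is chosen so
#' that its correlation with age is non-negative, for cross-run
#' comparability. Convergence is declared when the two best distinct
#' solutions agree to a Procrustes RMSE below \code{convTol}.
#'
#' @param d a [DissimilarityMatrix-class], \code{dist}, or square matrix.
#' @param k number of dimensions.
#' @param nStarts random starts.
#' @param maxit iteration cap per start.
#' @param seed RNG seed; fixes the solution bit-for-bit.
#' @param extraStarts optional list of configuration matrices used as
#'   additional starts (columns padded/truncated to k).
#' @param ageCovariate optional named numeric (site ages) for the axis-1
#'   sign convention.
#' @param convTol Procrustes RMSE below which two starts count as the same
#'   solution.
#' @return an [OrdinationResult-class].
#' @export
runNMDS <- function(d, k = 2, nStarts = 20, maxit = 500, seed = 1L,
                    extraStarts = NULL, ageCovariate = NULL,
                    convTol = 1e-4) {
  m <- asDistInput(d)
  stopifnot(k >= 1, nStarts >= 1)
  n <- nrow(m)
  dd <- stats::as.dist(m)
  set.seed(seed)
  pad <- function(cfg) {
    cfg <- as.matrix(cfg)
    if (ncol(cfg) >= k) return(cfg[, seq_len(k), drop = FALSE])
    cbind(cfg, matrix(stats::rnorm(n * (k - ncol(cfg)), sd = 1e-4),
                      n, k - ncol(cfg)))
  }
  metric <- suppressWarnings(stats::cmdscale(dd, k = min(k, n - 1)))
  starts <- c(list(pad(metric)),
              lapply(seq_len(nStarts), function(i)
                matrix(stats::rnorm(n * k), n, k)),
              lapply(extraStarts %||% list(), pad))
  fits <- lapply(starts, function(s0)
    vegan::monoMDS(dd, y = s0, k = k, model = "global", maxit = maxit,
                   smin = 1e-6, sfgrmin = 1e-8))
  stresses <- vapply(fits, function(f) f$stress, numeric(1))
  ord <- order(stresses)
  best <- fits[[ord[1]]]
  # convergence diagnostic: Procrustes agreement of the two best solutions
  prmse <- NA_real_
  converged <- length(fits) < 2
  if (length(fits) >= 2) {
    pr <- vegan::procrustes(best$points, fits[[ord[2]]]$points,
                            symmetric = TRUE)
    prmse <- sqrt(mean(stats::residuals(pr)^2))
    converged <- prmse < convTol
  }
  sc <- best$points
  sc <- scale(sc, center = TRUE, scale = FALSE)
  pc <- stats::prcomp(sc, center = FALSE)
  sc <- pc$x[, seq_len(k), drop = FALSE]
  colnames(sc) <- paste0("axis", seq_len(k))
  rownames(sc) <- rownames(m)
  if (!is.null(ageCovariate)) {
    a <- ageCovariate[rownames(sc)]
    if (!anyNA(a) && stats::sd(a) > 0 && stats::sd(sc[, 1]) > 0 &&
        stats::cor(sc[, 1], a) < 0)
      sc[, 1] <- -sc[, 1]
  }
  new("OrdinationResult", scores = sc, stress = best$stress,
      k = as.integer(k), nStarts = as.integer(nStarts),
      converged = converged, procrustesRMSE = prmse,
      seed = as.numeric(seed),
      indexName = if (is(d, "DissimilarityMatrix")) d@indexName
                  else "unknown")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Regress ordination axis-1 scores on a successional predictor
#'
#' Delegates to the succession regression machinery: the axis-1 site scores
#' are related to age, stand basal area, or understory light with the
#' linear/power/exponential families.
#'
#' @param ord an [OrdinationResult-class].
#' @param predictor named numeric vector (values per unit).
#' @param family one family to fit, or \code{NULL} to run model selection.
#' @param axis which axis to regress (default 1).
#' @return a [SuccessionFit-class] (or the selection list when
#'   \code{family = NULL}).
#' @export
axisRegression <- function(ord, predictor, family = NULL, axis = 1) {
  sc <- ordScores(ord)
  x <- predictor[rownames(sc)]
  if (anyNA(x))
    stop("predictor missing for unit(s): ",
         paste(rownames(sc)[is.na(x)], collapse = ", "))
  y <- sc[, axis]
  if (is.null(family)) selectSuccessionModel(x, y)
  else fitSuccessionModel(x, y, family)
}

#' Sensitivity of the ordination to the most frequent species
#'
#' Refits the NMDS keeping only species occurring in more than a given
#' fraction of the units, and correlates the resulting axis-1 scores with
#' the full-data axis-1 scores (Pearson, sign-aligned: the absolute value
#' is reported since an NMDS axis is defined up to reflection).
#'
#' @param mat an [AbundanceMatrix-class].
#' @param index dissimilarity index for [dissimilarityMatrix()].
#' @param thresholds occurrence-frequency thresholds in (0, 1).
#' @param k,nStarts,seed passed to [runNMDS()].
#' @return data.frame: \code{threshold}, \code{nSpecies}, \code{r} (absolute
#'   Pearson correlation of axis-1 scores with the full fit), \code{r2}.
#' @export
frequencyThresholdSensitivity <- function(mat, index = "ruzicka",
                                          thresholds = c(0.10, 0.25, 0.50),
                                          k = 2, nStarts = 20, seed = 1L) {
  stopifnot(all(thresholds > 0 & thresholds < 1))
  cnt <- if (is(mat, "AbundanceMatrix")) counts(mat) else as.matrix(mat)
  freq <- colMeans(cnt > 0)
  full <- runNMDS(dissimilarityMatrix(cnt, index), k = k,
                  nStarts = nStarts, seed = seed)
  ax1 <- ordScores(full)[, 1]
  res <- lapply(thresholds, function(th) {
    keep <- names(freq)[freq > th]
    if (length(keep) < 3)
      stop("fewer than 3 species occur in more than ",
           round(100 * th), "% of units")
    sub <- cnt[, keep, drop = FALSE]
    fit <- runNMDS(dissimilarityMatrix(sub, index), k = k,
                   nStarts = nStarts, seed = seed)
    sc <- ordScores(fit)[, 1]
    shared <- intersect(names(ax1), names(sc))
    r <- abs(stats::cor(ax1[shared], sc[shared]))
    data.frame(threshold = th, nSpecies = length(keep), r = r, r2 = r^2)
  })
  do.call(rbind, res)
}
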
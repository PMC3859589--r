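# Pairwise (dis)similarity indices and the seedling-versus-initial-trees
# compositional divergence comparison.

checkPair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (any(x < 0) || any(y < 0)) stop("negative abundances")
  if (sum(x) == 0 && sum(y) == 0)
    stop("dissimilarity undefined for two all-zero vectors")
}

#' Ruzicka (abundance-based Jaccard) dissimilarity
#'
#' \deqn{d = 1 - \sum_i \min(x_i, y_i) / \sum_i \max(x_i, y_i)}
#' On presence/absence (0/1) vectors this reduces exactly to the classical
#' Jaccard dissimilarity.
#'
#' @param x,y non-negative abundance vectors of equal length.
#' @return dissimilarity in [0, 1].
#' @export
ruzicka <- function(x, y) {
  checkPair(x, y)
  1 - sum(pmin(x, y)) / sum(pmax(x, y))
}

#' Presence/absence Jaccard dissimilarity
#'
#' \deqn{d = 1 - |A \cap B| / |A \cup B|} on the supports of the two
#' vectors; identical to [ruzicka()] applied to 0/1-truncated vectors.
#'
#' @inheritParams ruzicka
#' @return dissimilarity in [0, 1].
#' @export
jaccardPresence <- function(x, y) ruzicka(as.numeric(x > 0), as.numeric(y > 0))

#' Morisita-Horn dissimilarity
#'
#' Alternative abundance-based index, provided for sensitivity checks and
#' excluded from the default reports.
#'
#' @inheritParams ruzicka
#' @return dissimilarity in [0, 1].
#' @export
morisitaHorn <- function(x, y) {
  checkPair(x, y)
  if (sum(x) == 0 || sum(y) == 0) return(1)
  px <- x / sum(x); py <- y / sum(y)
  1 - 2 * sum(px * py) / (sum(px^2) + sum(py^2))
}

#' Chao-Jaccard abundance-based similarity estimator
#'
#' Estimates the Jaccard similarity of two assemblages from raw counts,
#' correcting for unseen shared species, so the estimate is far less biased
#' by unequal sample sizes than raw indices. With totals \eqn{n}, \eqn{m}
#' and shared-species counts \eqn{x_i}, \eqn{y_i}:
#' \deqn{\hat U = \sum x_i/n + \frac{m-1}{m} \frac{f_{+1}}{2 f_{+2}}
#'   \sum_{y_i = 1} x_i/n}
#' where \eqn{f_{+1}}, \eqn{f_{+2}} count shared species occurring as
#' singletons/doubletons in the second sample; \eqn{\hat V} is the mirror
#' image; both are capped at 1 and the estimator is
#' \eqn{\hat U \hat V / (\hat U + \hat V - \hat U \hat V)}.
#' When a correction denominator has \eqn{f_{+2} = 0} it is replaced by
#' \eqn{2(f_{+2} + 1)}, the usual bias-correction convention.
#'
#' @param x,y raw (unnormalized) count vectors of equal length.
#' @param corrected apply the unseen-shared-species correction terms
#'   (default); \code{FALSE} gives the plug-in \eqn{U = \sum x_i/n} version
#'   for sensitivity checks.
#' @return estimated similarity in [0, 1]; 0 when no species is shared.
#' @export
chaoJaccard <- function(x, y, corrected = TRUE) {
  checkPair(x, y)
  n <- sum(x); m <- sum(y)
  if (n == 0 || m == 0) stop("zero-total sample")
  shared <- x > 0 & y > 0
  if (!any(shared)) return(0)
  xs <- x[shared]; ys <- y[shared]
  U <- sum(xs) / n
  V <- sum(ys) / m
  if (corrected) {
    fp1 <- sum(ys == 1); fp2 <- sum(ys == 2)
    fq1 <- sum(xs == 1); fq2 <- sum(xs == 2)
    U <- U + (m - 1) / m * fp1 / (2 * if (fp2 == 0) fp2 + 1 else fp2) *
      sum(xs[ys == 1]) / n
    V <- V + (n - 1) / n * fq1 / (2 * if (fq2 == 0) fq2 + 1 else fq2) *
      sum(ys[xs == 1]) / m
  }
  U <- min(U, 1); V <- min(V, 1)
  U * V / (U + V - U * V)
}

#' Pairwise dissimilarity matrix among sampling units
#'
#' @param mat an [AbundanceMatrix-class] or unit x species matrix.
#' @param index one of \code{"ruzicka"}, \code{"jaccard"} (presence/absence),
#'   \code{"chao"} (1 - Chao-Jaccard similarity), \code{"morisita"}.
#' @param ... passed to the pairwise index (e.g. \code{corrected}).
#' @return a [DissimilarityMatrix-class]. Units without any individuals
#'   (e.g. sites too young to hold stems of the stratum) have no defined
#'   dissimilarity and are dropped with a warning.
#' @export
dissimilarityMatrix <- function(mat, index = c("ruzicka", "jaccard",
                                               "chao", "morisita"), ...) {
  index <- match.arg(index)
  m <- if (is(mat, "AbundanceMatrix")) counts(mat) else as.matrix(mat)
  empty <- rowSums(m) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " unit(s) without individuals: ",
            paste(rownames(m)[empty], collapse = ", "))
    m <- m[!empty, , drop = FALSE]
  }
  f <- switch(index,
    ruzicka  = ruzicka,
    jaccard  = jaccardPresence,
    chao     = function(x, y, ...) 1 - chaoJaccard(x, y, ...),
    morisita = morisitaHorn)
  n <- nrow(m)
  v <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        v[i, j] <- v[j, i] <- f(m[i, ], m[j, ], ...)
      }
    }
  }
  new("DissimilarityMatrix", values = v, indexName = index)
}

#' Divergence of seedling assemblages from the initial tree community
#'
#' Compares, per stand-basal-area class, the canopy-species composition of
#' the seedling layer with the composition of the larger stems (>= 1 cm) of
#' the youngest stands (SBA-1): every cross pair (seedling unit in class k)
#' x (stem unit in SBA-1) is scored with the Chao-Jaccard abundance
#' estimator and summarized as a mean with a 95 percent normal-theory
#' confidence interval across pairs. Only species that can reach at least
#' 5 cm diameter (maximum-DBH class mid-value >= \code{minDbhmaxMidCm})
#' enter the comparison. A declining mean across classes indicates
#' landscape-scale successional turnover of the canopy flora.
#'
#' @param seedlingMat seedling-stratum [AbundanceMatrix-class] (site level).
#' @param stemMat >= 1 cm stems [AbundanceMatrix-class] (site level).
#' @param scheme SBA [ClassScheme-class] over the sites.
#' @param traits trait table with \code{species_code} and
#'   \code{dbhmax_mid_cm}.
#' @param referenceClass label of the reference class (default the first).
#' @param minDbhmaxMidCm canopy filter on the class mid-value; the default
#'   7.5 keeps species of maximum-DBH class 5-10 cm and above.
#' @param ciMethod \code{"normal"} (mean +/- 1.96 SE) or \code{"bootstrap"}
#'   (percentile, 999 draws).
#' @param seed RNG seed for the bootstrap.
#' @return data.frame: \code{class}, \code{mean}, \code{ciLow},
#'   \code{ciHigh}, \code{nPairs}.
#' @export
seedlingDivergence <- function(seedlingMat, stemMat, scheme, traits,
                               referenceClass = scheme@labels[1],
                               minDbhmaxMidCm = 7.5,
                               ciMethod = c("normal", "bootstrap"),
                               seed = 1L) {
  ciMethod <- match.arg(ciMethod)
  canopy <- traits$species_code[traits$dbhmax_mid_cm >= minDbhmaxMidCm]
  sm <- counts(seedlingMat)[, intersect(colnames(counts(seedlingMat)), canopy),
                            drop = FALSE]
  tm <- counts(stemMat)[, intersect(colnames(counts(stemMat)), canopy),
                        drop = FALSE]
  allsp <- union(colnames(sm), colnames(tm))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(allsp),
                  dimnames = list(rownames(m), allsp))
    out[, colnames(m)] <- m
    out
  }
  sm <- pad(sm); tm <- pad(tm)
  cls <- classOf(scheme, rownames(sm))
  refUnits <- rownames(tm)[classOf(scheme, rownames(tm)) == referenceClass &
                             rowSums(tm) > 0]
  if (!length(refUnits)) stop("empty reference class ", referenceClass)
  res <- lapply(scheme@labels, function(k) {
    su <- rownames(sm)[cls == k & rowSums(sm) > 0]
    if (!length(su)) stop("no seedling assemblages in class ", k)
    pairs <- expand.grid(s = su, r = refUnits, stringsAsFactors = FALSE)
    sims <- mapply(function(s, r) chaoJaccard(sm[s, ], tm[r, ]),
                   pairs$s, pairs$r)
    mu <- mean(sims)
    if (ciMethod == "normal") {
      se <- stats::sd(sims) / sqrt(length(sims))
      ci <- mu + c(-1.96, 1.96) * se
    } else {
      set.seed(seed)
      bs <- vapply(seq_len(999), function(i)
        mean(sample(sims, replace = TRUE)), numeric(1))
      ci <- stats::quantile(bs, c(0.025, 0.975), names = FALSE)
    }
    data.frame(class = k, mean = mu, ciLow = ci[1], ciHigh = ci[2],
               nPairs = length(sims))
  })
  do.call(rbind, res)
}
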
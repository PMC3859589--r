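# Hill-number diversity, exact individual-based rarefaction, sample-based
# accumulation, and resampled metacommunity (gamma) diversity.

#' Hill number (effective number of species) of order q
#'
#' \deqn{^qD = (\sum_i p_i^q)^{1/(1-q)}} for relative abundances
#' \eqn{p_i}. The order q tunes the sensitivity to common versus rare
#' species: q = 0 counts species, q = 1 is the exponential of Shannon
#' entropy (computed by its closed-form limit, never by numerical approach
#' to 1), and q = 2 the inverse Simpson concentration. A community of n
#' equally common species has \eqn{^qD = n} for every q.
#'
#' @param counts non-negative abundance vector (zeros are ignored).
#' @param q non-negative order(s); vectorized over q.
#' @return effective number of species, one value per q.
#' @export
hillNumber <- function(counts, q = c(0, 1, 2)) {
  if (any(counts < 0)) stop("negative counts")
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero abundance vector")
  if (any(q < 0)) stop("q must be non-negative")
  p <- counts / sum(counts)
  vapply(q, function(qi) {
    if (qi == 0) as.numeric(length(p))
    else if (qi == 1) exp(-sum(p * log(p)))
    else sum(p^qi)^(1 / (1 - qi))
  }, numeric(1))
}

#' Exact rarefied species richness
#'
#' Expected number of species in a random subsample of n individuals, by
#' the exact hypergeometric formula
#' \deqn{E[S_n] = \sum_i \left[1 - \binom{N - N_i}{n} / \binom{N}{n}\right]}
#' evaluated in log space so large inventories do not overflow.
#'
#' @param counts non-negative integer abundance vector.
#' @param n subsample size, \code{1 <= n <= sum(counts)}.
#' @return expected species number.
#' @export
rarefiedRichness <- function(counts, n) {
  if (any(counts < 0)) stop("negative counts")
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (n <= 0) stop("n must be positive")
  if (n > N) stop("n exceeds the ", N, " individuals available")
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Resampled metacommunity (gamma) diversity
#'
#' Pools the counts of a uniform random subset of sites (without
#' replacement, by default 12 sites, 1000 times), evaluates the Hill number
#' of the pooled assemblage, and summarizes the resampling distribution by
#' its mean and 0.025/0.975 empirical quantiles (type-7 linear
#' interpolation). This makes gamma diversity comparable across classes
#' holding different numbers of sites.
#'
#' @param mat an [AbundanceMatrix-class] (or bare unit x species matrix).
#' @param subsampleSize sites pooled per draw.
#' @param iterations number of draws.
#' @param q Hill order.
#' @param seed RNG seed.
#' @param replace sample sites with replacement instead (non-default).
#' @return a [ResampledGamma-class].
#' @export
resampledGamma <- function(mat, subsampleSize = 12, iterations = 1000,
                           q = 0, seed = 1L, replace = FALSE) {
  m <- if (is(mat, "AbundanceMatrix")) counts(mat) else as.matrix(mat)
  if (subsampleSize > nrow(m))
    stop("subsampleSize exceeds the ", nrow(m), " units available")
  set.seed(seed)
  vals <- vapply(seq_len(iterations), function(i) {
    rows <- sample.int(nrow(m), subsampleSize, replace = replace)
    hillNumber(colSums(m[rows, , drop = FALSE]), q)
  }, numeric(1))
  qs <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
  new("ResampledGamma", q = as.numeric(q),
      subsampleSize = as.integer(subsampleSize),
      iterations = as.integer(iterations),
      mean = mean(vals), ciLow = qs[1], ciHigh = qs[2], values = vals)
}

#' Sample-based species accumulation curve
#'
#' Expected species number against the number of sites pooled. The
#' \code{"exact"} method uses the analytic sample-based rarefaction formula
#' \deqn{E[S(m)] = \sum_s \left[1 - \binom{M - M_s}{m} / \binom{M}{m}\right]}
#' over species occurrence counts \eqn{M_s} out of M sites; \code{"random"}
#' averages cumulative richness over random site orderings.
#'
#' @param mat an [AbundanceMatrix-class] or unit x species matrix.
#' @param method \code{"exact"} or \code{"random"}.
#' @param iterations orderings for \code{method = "random"}.
#' @param seed RNG seed (random method).
#' @return data.frame with \code{sites} and \code{richness}, non-decreasing.
#' @export
accumulationCurve <- function(mat, method = c("exact", "random"),
                              iterations = 100, seed = 1L) {
  method <- match.arg(method)
  m <- if (is(mat, "AbundanceMatrix")) counts(mat) else as.matrix(mat)
  M <- nrow(m)
  if (M < 1) stop("need at least one unit")
  occ <- colSums(m > 0)
  rich <- if (method == "exact") {
    vapply(seq_len(M), function(k)
      sum(1 - exp(lchoose(M - occ, k) - lchoose(M, k))), numeric(1))
  } else {
    set.seed(seed)
    acc <- matrix(0, iterations, M)
    for (i in seq_len(iterations)) {
      ord <- sample.int(M)
      seen <- rep(FALSE, ncol(m))
      for (k in seq_len(M)) {
        seen <- seen | m[ord[k], ] > 0
        acc[i, k] <- sum(seen)
      }
    }
    colMeans(acc)
  }
  data.frame(sites = seq_len(M), richness = rich)
}

#' Site-level Hill diversity table
#'
#' Convenience wrapper: Hill numbers of every unit of an abundance matrix,
#' in tidy long format.
#'
#' @param mat an [AbundanceMatrix-class].
#' @param q Hill orders.
#' @return data.frame with \code{unit}, \code{q}, \code{value}.
#' @export
alphaDiversity <- function(mat, q = c(0, 1, 2)) {
  m <- if (is(mat, "AbundanceMatrix")) counts(mat) else as.matrix(mat)
  rows <- rownames(m)
  res <- do.call(rbind, lapply(rows, function(u) {
    x <- m[u, ]
    if (sum(x) == 0)
      return(data.frame(unit = u, q = q, value = NA_real_))
    data.frame(unit = u, q = q, value = hillNumber(x, q))
  }))
  rownames(res) <- NULL
  res
}
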
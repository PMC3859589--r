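# Shared fixtures and independent oracles used across the suite.

# minimal hand-written stem table: one valid sapling, tree and liana
toyStems <- function() {
  data.frame(
    site_id = c("A", "A", "B"),
    plot_id = c("upper", "lower", "upper"),
    species_code = c("sp1", "sp2", "sp3"),
    stratum = c("sapling", "tree", "liana"),
    diameter_cm = c(2.0, 7.1, 1.3),
    life_form = c("tree", "tree", "liana"),
    stringsAsFactors = FALSE)
}

toySites <- function() {
  data.frame(site_id = c("A", "B"), age_y = c(5, 20),
             sba_m2ha = c(8, 25), x_m = c(0, 100), y_m = c(0, 0),
             stringsAsFactors = FALSE)
}

# independent transcription of the abundance-based Chao-Jaccard estimator,
# written directly from the published formulas (bias-corrected form; the
# f+2 = 0 denominator replaced by 2(f+2 + 1))
oracleChaoJaccard <- function(x, y) {
  sh <- which(x > 0 & y > 0)
  if (!length(sh)) return(0)
  n <- sum(x); m <- sum(y)
  U <- sum(x[sh]) / n
  V <- sum(y[sh]) / m
  f1y <- sum(y[sh] == 1); f2y <- sum(y[sh] == 2)
  f1x <- sum(x[sh] == 1); f2x <- sum(x[sh] == 2)
  U <- U + (m - 1) / m * f1y / (2 * max(f2y, 1)) * sum(x[sh][y[sh] == 1]) / n
  V <- V + (n - 1) / n * f1x / (2 * max(f2x, 1)) * sum(y[sh][x[sh] == 1]) / m
  U <- min(U, 1); V <- min(V, 1)
  U * V / (U + V - U * V)
}

# random labelled dissimilarity matrix from points in the plane
randomDistMatrix <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n), n, 2)
  m <- as.matrix(dist(x))
  dimnames(m) <- list(paste0("u", seq_len(n)), paste0("u", seq_len(n)))
  m
}

# all permutations of 1..n (for exhaustive-enumeration oracles)
oracleAllPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracleAllPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos)
    t(apply(sub, 1, function(p) append(p, n, after = pos - 1)))))
}

# labelled random abundance matrix
randomCommunity <- function(nUnits, nSpecies, lambda = 2, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(nUnits * nSpecies, lambda), nUnits, nSpecies,
              dimnames = list(paste0("u", seq_len(nUnits)),
                              paste0("s", seq_len(nSpecies))))
  m[, colSums(m) > 0, drop = FALSE]
}
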
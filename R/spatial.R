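# Mantel test, Mantel correlogram, and one-factor distance-based
# (permutational) MANOVA. All permutation p-values use the +1 convention
# p = (1 + #{perm >= obs}) / (1 + n_perm); exhaustive modes enumerate every
# non-identity relabeling, which makes p equal to the proportion of all n!
# relabelings (identity included) reaching the observed statistic.

pairIndices <- function(n) {
  lt <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(i = lt[, 1], j = lt[, 2])
}

allPermutations <- function(n) {
  if (n > 8) stop("exhaustive enumeration limited to n <= 8")
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (s in sub) {
    for (pos in seq_len(n)) {
      k <- k + 1L
      out[[k]] <- append(s, n, after = pos - 1L)
    }
  }
  out
}

checkAligned <- function(m1, m2) {
  if (!identical(rownames(m1), rownames(m2)))
    stop("dissimilarity matrices do not share unit order")
}

#' Mantel test between two distance matrices
#'
#' Pearson product-moment correlation between the lower-triangle entries of
#' two distance matrices; the null distribution is obtained by permuting
#' rows and columns of the second matrix simultaneously. One-sided upper
#' p-value with the +1 convention.
#'
#' @param dSpecies,dGeo aligned [DissimilarityMatrix-class] objects (or
#'   square matrices / dist).
#' @param permutations number of random permutations (default 999).
#' @param seed RNG seed.
#' @param exact enumerate all relabelings instead (n <= 8); the p-value
#'   then equals the exhaustive proportion over all n! relabelings.
#' @return a [PermutationTestResult-class].
#' @export
mantelTest <- function(dSpecies, dGeo, permutations = 999, seed = 1L,
                       exact = FALSE) {
  m1 <- asDistInput(dSpecies); m2 <- asDistInput(dGeo)
  checkAligned(m1, m2)
  n <- nrow(m1)
  if (n < 4) stop("need at least 4 units")
  px <- pairIndices(n)
  v1 <- m1[cbind(px$i, px$j)]
  robs <- stats::cor(v1, m2[cbind(px$i, px$j)])
  if (exact) {
    perms <- allPermutations(n)
    stats_ <- vapply(perms, function(p)
      stats::cor(v1, m2[cbind(p[px$i], p[px$j])]), numeric(1))
    idty <- vapply(perms, function(p) all(p == seq_len(n)), logical(1))
    nperm <- length(perms) - 1L
    count <- sum(stats_[!idty] >= robs)
  } else {
    set.seed(seed)
    nperm <- as.integer(permutations)
    count <- 0L
    for (b in seq_len(nperm)) {
      p <- sample.int(n)
      if (stats::cor(v1, m2[cbind(p[px$i], p[px$j])]) >= robs)
        count <- count + 1L
    }
  }
  new("PermutationTestResult", statName = "Mantel r", statistic = robs,
      permutations = nperm, pValue = (1 + count) / (1 + nperm),
      seed = if (exact) NA_real_ else as.numeric(seed),
      details = list(n = n))
}

#' Mantel correlogram
#'
#' Splits the geographic pair distances into classes (Sturges' rule by
#' default) and computes, per class, a Mantel statistic between the species
#' dissimilarities and the class-membership indicator, signed so that a
#' positive value means sites of that class are compositionally more
#' similar than average (positive spatial correlation). Significance per
#' class is a one-sided permutation test for positive correlation, with
#' progressive Holm correction across classes.
#'
#' @param dSpecies [DissimilarityMatrix-class] (or square matrix).
#' @param coords two-column matrix of planar coordinates (metres), rows
#'   aligned with \code{dSpecies}.
#' @param breaks optional distance-class break vector; default Sturges.
#' @param permutations,seed permutation settings.
#' @return data.frame: class midpoint, number of pairs, Mantel r, raw and
#'   progressively Holm-corrected one-sided p-values. Classes without pairs
#'   are dropped with a warning.
#' @export
mantelCorrelogram <- function(dSpecies, coords, breaks = NULL,
                              permutations = 999, seed = 1L) {
  m <- asDistInput(dSpecies)
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(m)) stop("coords misaligned with matrix")
  n <- nrow(m)
  px <- pairIndices(n)
  vd <- m[cbind(px$i, px$j)]
  geo <- as.matrix(stats::dist(coords))
  vg <- geo[cbind(px$i, px$j)]
  if (is.null(breaks)) {
    if (diff(range(vg)) < 1e-9) {
      breaks <- c(min(vg) - 1e-9, max(vg) + 1e-9)
    } else {
      ncl <- ceiling(log2(length(vg))) + 1
      breaks <- seq(min(vg), max(vg), length.out = ncl + 1)
    }
  }
  cls <- cut(vg, breaks, include.lowest = TRUE)
  keep <- table(cls) > 0
  if (any(!keep)) warning("dropping empty distance class(es)")
  labs <- levels(cls)[keep]
  ind <- vapply(labs, function(l) as.numeric(cls == l),
                numeric(length(vd)))
  # a class holding every pair gives a constant indicator: r undefined
  usable <- apply(ind, 2, stats::sd) > 0
  robs <- rep(NA_real_, length(labs))
  robs[usable] <- -as.numeric(stats::cor(vd, ind[, usable, drop = FALSE]))
  set.seed(seed)
  count <- integer(length(labs))
  for (b in seq_len(permutations)) {
    p <- sample.int(n)
    rp <- rep(-Inf, length(labs))
    rp[usable] <- -as.numeric(
      stats::cor(m[cbind(p[px$i], p[px$j])], ind[, usable, drop = FALSE]))
    count <- count + (!is.na(robs) & rp >= robs)
  }
  praw <- ifelse(is.na(robs), NA_real_, (1 + count) / (1 + permutations))
  pholm <- vapply(seq_along(praw), function(k)
    stats::p.adjust(praw[seq_len(k)], "holm")[k], numeric(1))
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  data.frame(class = labs, midpoint = mids[keep],
             nPairs = as.integer(table(cls)[keep]),
             r = robs, pRaw = praw, pHolm = pholm,
             row.names = NULL)
}

#' One-factor permutational MANOVA (distance-based)
#'
#' Partitions the total sum of squared dissimilarities among and within
#' groups via the Gower-centred inner-product matrix
#' \eqn{G = -\frac{1}{2} J D^{(2)} J}: the model sum of squares is
#' \eqn{tr(HGH)} for the hat matrix of the group design, giving
#' pseudo-F = (SS_between/df_b) / (SS_within/df_w) and
#' R2 = SS_between/SS_total. Significance is assessed by permuting group
#' labels. On Euclidean distances of one-dimensional data this reproduces
#' the classical one-way ANOVA F exactly.
#'
#' @param d a [DissimilarityMatrix-class] (or square matrix / dist).
#' @param groups group labels, aligned with the units.
#' @param permutations,seed permutation settings.
#' @param coding \code{"categorical"} (df = k - 1) or \code{"linear"}
#'   (ordered classes scored 1..k as a single numeric term, df = 1).
#' @param exact enumerate all label permutations (n <= 8).
#' @return a [PermutationTestResult-class]; \code{details} holds R2, df and
#'   the sums of squares.
#' @export
permanovaTest <- function(d, groups, permutations = 999, seed = 1L,
                          coding = c("categorical", "linear"),
                          exact = FALSE) {
  coding <- match.arg(coding)
  m <- asDistInput(d)
  n <- nrow(m)
  if (length(groups) != n) stop("groups misaligned with matrix")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (coding == "categorical" && any(tab < 2))
    stop("singleton group(s): ", paste(names(tab)[tab < 2], collapse = ", "))
  A <- -0.5 * m^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  x <- if (coding == "categorical") factor(groups)
       else as.numeric(factor(groups, levels = sort(unique(groups))))
  X <- stats::model.matrix(~x)
  H <- X %*% solve(crossprod(X), t(X))
  dfB <- qr(X)$rank - 1L
  dfW <- n - qr(X)$rank
  ssT <- sum(diag(G))
  ssB <- sum(H * G)   # tr(HG), H idempotent symmetric
  ssW <- ssT - ssB
  Fobs <- (ssB / dfB) / (ssW / dfW)
  statPerm <- function(p) {
    Gp <- G[p, p]
    ssb <- sum(H * Gp)
    (ssb / dfB) / ((ssT - ssb) / dfW)
  }
  if (exact) {
    perms <- allPermutations(n)
    idty <- vapply(perms, function(p) all(p == seq_len(n)), logical(1))
    stats_ <- vapply(perms[!idty], statPerm, numeric(1))
    nperm <- length(stats_)
    count <- sum(stats_ >= Fobs)
    seedOut <- NA_real_
  } else {
    set.seed(seed)
    nperm <- as.integer(permutations)
    count <- 0L
    for (b in seq_len(nperm)) {
      if (statPerm(sample.int(n)) >= Fobs) count <- count + 1L
    }
    seedOut <- as.numeric(seed)
  }
  new("PermutationTestResult", statName = "pseudo-F", statistic = Fobs,
      permutations = as.integer(nperm),
      pValue = (1 + count) / (1 + nperm), seed = seedOut,
      details = list(R2 = ssB / ssT, df = c(dfB, dfW),
                     SS = c(between = ssB, within = ssW, total = ssT)))
}
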
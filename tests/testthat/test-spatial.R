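test_that("Mantel statistic and p-value behave at the extremes", {
  d <- randomDistMatrix(10, seed = 1)
  r <- mantelTest(d, d, permutations = 999, seed = 2)
  expect_equal(r@statistic, 1)
  expect_equal(pValue(r), 1 / 1000)      # minimum attainable with +1 rule
  # +1 convention lower bound and seed reproducibility
  d2 <- randomDistMatrix(10, seed = 5)
  p1 <- pValue(mantelTest(d, d2, permutations = 99, seed = 3))
  p2 <- pValue(mantelTest(d, d2, permutations = 99, seed = 3))
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  bad <- d2
  rownames(bad) <- colnames(bad) <- paste0("x", 1:10)
  expect_error(mantelTest(d, bad), "unit order")
})

test_that("Mantel r is invariant to shifting all off-diagonal entries", {
  d1 <- randomDistMatrix(8, seed = 11)
  d2 <- randomDistMatrix(8, seed = 12)
  shifted <- d2 + 5
  diag(shifted) <- 0
  expect_equal(mantelTest(d1, d2, 9, seed = 1)@statistic,
               mantelTest(d1, shifted, 9, seed = 1)@statistic)
})

test_that("exhaustive Mantel p equals the full-enumeration proportion", {
  d1 <- randomDistMatrix(5, seed = 21)
  d2 <- randomDistMatrix(5, seed = 22)
  res <- mantelTest(d1, d2, exact = TRUE)
  perms <- oracleAllPerms(5)
  lt <- lower.tri(d1)
  v1 <- d1[lt]
  robs <- cor(v1, d2[lt])
  stats <- apply(perms, 1, function(p) cor(v1, (d2[p, p])[lt]))
  expect_equal(pValue(res), mean(stats >= robs))
  expect_equal(res@permutations, factorial(5) - 1L)
})

test_that("PERMANOVA partitions variance correctly at the extremes", {
  # two internally identical groups, positive between-group distance
  m <- matrix(0, 6, 6, dimnames = list(paste0("u", 1:6), paste0("u", 1:6)))
  m[1:3, 4:6] <- 1; m[4:6, 1:3] <- 1
  pv <- permanovaTest(m, rep(c("A", "B"), each = 3), 99, seed = 1)
  expect_equal(pv@details$R2, 1, tolerance = 1e-12)
  expect_gt(pv@statistic, 1e10)   # SS_within is zero up to rounding
  expect_error(permanovaTest(m, c("A", rep("B", 5)), 9), "singleton")
  expect_error(permanovaTest(m, rep("A", 6), 9), "2 groups")
})

test_that("PERMANOVA on Euclidean 1-D distances equals classical ANOVA", {
  set.seed(33)
  for (i in 1:5) {
    y <- rnorm(15)
    g <- sample(rep(letters[1:3], 5))
    d <- as.matrix(dist(y))
    dimnames(d) <- list(paste0("u", 1:15), paste0("u", 1:15))
    pv <- permanovaTest(d, g, permutations = 19, seed = i)
    expect_equal(pv@statistic, anova(lm(y ~ g))$`F value`[1],
                 tolerance = 1e-12)
    expect_equal(pv@details$df, c(2, 12))
  }
})

test_that("PERMANOVA agrees with adonis2 and supports linear coding", {
  m <- randomCommunity(12, 10, seed = 41)
  d <- as.matrix(dissimilarityMatrix(m, "ruzicka"))
  g <- rep(c("c1", "c2", "c3"), each = 4)
  pv <- permanovaTest(d, g, permutations = 99, seed = 1)
  ad <- vegan::adonis2(as.dist(d) ~ g, permutations = 99)
  expect_equal(pv@statistic, ad$F[1], tolerance = 1e-10)
  expect_equal(pv@details$R2, ad$R2[1], tolerance = 1e-10)
  lin <- permanovaTest(d, g, permutations = 99, seed = 1,
                       coding = "linear")
  expect_equal(lin@details$df[1], 1)
})

test_that("exhaustive PERMANOVA p equals the 20-split enumeration", {
  set.seed(43)
  y <- rnorm(6)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("u", 1:6), paste0("u", 1:6))
  g <- rep(c("A", "B"), each = 3)
  res <- permanovaTest(d, g, exact = TRUE)
  # independent oracle: pair-sum formula over the 20 distinct label splits
  Fsplit <- function(lab) {
    n <- 6
    sst <- sum(d[lower.tri(d)]^2) / n
    ssw <- sum(vapply(unique(lab), function(k) {
      idx <- lab == k
      sum((d[idx, idx])[lower.tri(d[idx, idx])]^2) / sum(idx)
    }, numeric(1)))
    ((sst - ssw) / 1) / (ssw / (n - 2))
  }
  splits <- combn(6, 3)
  Fs <- apply(splits, 2, function(ix) {
    lab <- rep("B", 6); lab[ix] <- "A"; Fsplit(lab)
  })
  expect_equal(pValue(res), mean(Fs >= Fsplit(g) - 1e-12))
})

test_that("the correlogram flags short-range structure and nothing else", {
  pool <- speciesPool(nSpecies = 120, seed = 2)
  sim <- simulateMetacommunity(
    pool, landscapeParams(spatialKernel = TRUE, kernelRangeM = 250),
    seed = 6)
  m <- buildAbundanceMatrix(sim$stems, c("sapling", "tree", "liana"),
                            "site", minDiameterCm = 1, sites = sim$sites)
  d <- suppressWarnings(dissimilarityMatrix(m, "ruzicka"))
  co <- as.matrix(sim$sites[, c("x_m", "y_m")])
  rownames(co) <- sim$sites$site_id
  cg <- mantelCorrelogram(d, co[rownames(as.matrix(d)), ],
                          permutations = 499, seed = 3)
  short <- cg$midpoint < 500
  expect_gt(cg$r[1], 0)
  expect_lt(cg$pHolm[1], 0.05)
  # no significant positive correlation at long range
  expect_true(all(cg$pHolm[cg$midpoint > 1200] > 0.05, na.rm = TRUE))

  # without any spatial kernel, nothing should light up
  sim0 <- simulateMetacommunity(pool, landscapeParams(), seed = 6)
  m0 <- buildAbundanceMatrix(sim0$stems, c("sapling", "tree", "liana"),
                             "site", minDiameterCm = 1, sites = sim0$sites)
  d0 <- suppressWarnings(dissimilarityMatrix(m0, "ruzicka"))
  co0 <- as.matrix(sim0$sites[, c("x_m", "y_m")])
  rownames(co0) <- sim0$sites$site_id
  cg0 <- mantelCorrelogram(d0, co0[rownames(as.matrix(d0)), ],
                           permutations = 499, seed = 3)
  expect_true(all(cg0$pHolm > 0.05, na.rm = TRUE))
})

test_that("degenerate geometries collapse to a single distance class", {
  # equilateral triangle in the plane plus centre trick: use 3 equidistant
  co <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2), c(0.5, sqrt(3) / 6))
  d <- randomDistMatrix(3, seed = 51)
  cg <- mantelCorrelogram(d, co[1:3, ], permutations = 9, seed = 1)
  expect_equal(nrow(cg), 1)
  expect_true(is.na(cg$r[1]))
})
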
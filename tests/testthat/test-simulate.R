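test_that("the generator is deterministic under its seeds", {
  a <- simulateMetacommunity(speciesPool(nSpecies = 50, seed = 2),
                             landscapeParams(sitesPerBand = 3), seed = 9)
  b <- simulateMetacommunity(speciesPool(nSpecies = 50, seed = 2),
                             landscapeParams(sitesPerBand = 3), seed = 9)
  expect_identical(a$stems, b$stems)
  expect_identical(a$sites, b$sites)
  n1 <- simulateNullMetacommunity(seed = 5)
  n2 <- simulateNullMetacommunity(seed = 5)
  expect_identical(n1$stems, n2$stems)
})

test_that("every emitted record satisfies the census invariants", {
  sim <- simulateScenario("paper-like", seed = 7)
  expect_equal(nrow(validateStems(sim$stems)$rejected), 0)
  nl <- simulateNullMetacommunity(seed = 7)
  expect_equal(nrow(validateStems(nl$stems)$rejected), 0)
  # two plots per site, ages within the configured range
  expect_true(all(sim$sites$age_y >= 2 & sim$sites$age_y <= 32))
  expect_true(all(sim$stems$plot_id %in% c("upper", "lower")))
  # diameters never exceed the species maximum
  mid <- sim$traits$dbhmax_mid_cm[match(sim$stems$species_code,
                                        sim$traits$species_code)]
  ok <- !is.na(sim$stems$diameter_cm)
  expect_true(all(sim$stems$diameter_cm[ok] <= 0.95 * mid[ok] + 1e-9))
})

test_that("degenerate parameters are rejected loudly", {
  pool <- speciesPool(nSpecies = 5, seed = 1)
  pool$colonization_rate[] <- 0
  expect_error(simulateMetacommunity(pool), "degenerate")
  expect_error(simulateNullMetacommunity(meanAbundance = 0), "degenerate")
})

test_that("pioneers decline between young and old stands", {
  # pioneer-only pool: short lifespans + closed-canopy regeneration failure
  # must outweigh 15x longer colonization at age 30
  pool <- speciesPool(nSpecies = 40, pioneerFraction = 1, seed = 3)
  lsc <- landscapeParams(ageBands = list(c(2), c(30)), sitesPerBand = 4)
  counts <- vapply(1:20, function(s) {
    sim <- simulateMetacommunity(pool, lsc, seed = s)
    n <- table(factor(sim$stems$site_id, levels = sim$sites$site_id))
    c(mean(n[sim$sites$age_y == 2]), mean(n[sim$sites$age_y == 30]))
  }, numeric(2))
  expect_lt(mean(counts[2, ]), mean(counts[1, ]))
})

test_that("tree species density increases with stand age", {
  rc <- vapply(1:10, function(s) {
    sim <- simulateScenario("paper-like", seed = s)
    tm <- buildAbundanceMatrix(sim$stems, "tree", "site", sites = sim$sites)
    ages <- setNames(sim$sites$age_y, sim$sites$site_id)
    cor(rowSums(counts(tm) > 0), ages[sampleUnits(tm)],
        method = "spearman")
  }, numeric(1))
  expect_true(all(rc > 0.5))
})

test_that("doubling one species' colonization rate raises its landscape F1", {
  pool <- speciesPool(nSpecies = 60, seed = 5)
  target <- order(pool$colonization_rate)[30]
  sp <- pool$species_code[target]
  occup <- function(p, s) {
    sim <- simulateMetacommunity(p, landscapeParams(sitesPerBand = 8),
                                 seed = s)
    m <- buildAbundanceMatrix(sim$stems, c("sapling", "tree", "liana"),
                              "plot", minDiameterCm = 1)
    if (!sp %in% speciesNames(m)) 0 else mean(counts(m)[, sp] > 0)
  }
  boosted <- pool
  boosted$colonization_rate[target] <- 2 * boosted$colonization_rate[target]
  f1base <- mean(vapply(1:10, function(s) occup(pool, s), numeric(1)))
  f1boost <- mean(vapply(1:10, function(s) occup(boosted, s), numeric(1)))
  expect_gt(f1boost, f1base)
})

test_that("turning the niche axis off collapses the young-old contrast", {
  excess <- function(pool, seed) {
    lsc <- landscapeParams(ageBands = list(2:5, 25:32), sitesPerBand = 8)
    sim <- simulateMetacommunity(pool, lsc, seed = seed)
    m <- buildAbundanceMatrix(sim$stems, c("sapling", "tree", "liana"),
                              "site", minDiameterCm = 1, sites = sim$sites)
    d <- as.matrix(suppressWarnings(dissimilarityMatrix(m, "chao")))
    ag <- setNames(sim$sites$age_y, sim$sites$site_id)[rownames(d)]
    y <- ag <= 5; o <- ag >= 25
    mean(d[y, o]) - (mean(d[y, y][upper.tri(d[y, y])]) +
                       mean(d[o, o][upper.tri(d[o, o])])) / 2
  }
  pOn <- speciesPool(nSpecies = 80, seed = 9)
  pOff <- pOn
  pOff$shade_tolerance[] <- 1   # everything establishes anywhere
  pOff$longevity_y[] <- 1e9     # nothing dies
  eOn <- mean(vapply(1:5, function(s) excess(pOn, s), numeric(1)))
  eOff <- mean(vapply(1:5, function(s) excess(pOff, s), numeric(1)))
  expect_gt(eOn, 0.05)          # niche on: real successional contrast
  expect_lt(abs(eOff), 0.05)    # niche off: contrast at the null level
})

test_that("the null generator carries no structure the tests could detect", {
  nl <- simulateNullMetacommunity(nSites = 25, seed = 11)
  m <- buildAbundanceMatrix(nl$stems, "tree", "site")
  expect_equal(sort(sampleUnits(m)), sort(nl$sites$site_id))
  # no age dependence of richness (single realization, weak check)
  ages <- setNames(nl$sites$age_y, nl$sites$site_id)
  r <- cor(rowSums(counts(m) > 0), ages[sampleUnits(m)])
  expect_lt(abs(r), 0.6)
})
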
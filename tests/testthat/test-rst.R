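# fixture: two sites per age class, explicit plots, tree/shrub species with
# known maximum-size classes
rstStems <- function() {
  data.frame(
    site_id = rep(c("y1", "o1"), each = 4),
    plot_id = rep(c("upper", "upper", "lower", "lower"), 2),
    species_code = c("big", "small", "big", "palm1",
                     "big", "small", "big", "palm1"),
    stratum = c("sapling", "sapling", "tree", "tree",
                "tree", "sapling", "tree", "tree"),
    diameter_cm = c(2, 1.2, 10, 9, 12, 2.8, 20, 11),
    life_form = c("tree", "shrub", "tree", "palm",
                  "tree", "shrub", "tree", "palm"),
    stringsAsFactors = FALSE)
}

rstTraits <- function() {
  assignDbhmaxClass(data.frame(
    species_code = c("big", "small", "palm1"),
    life_form = c("tree", "shrub", "palm"),
    dbhmax_class = c("20-40", "1-5", "10-20"),
    stringsAsFactors = FALSE))
}

rstScheme <- function() {
  assignClasses(data.frame(site_id = c("y1", "o1"), age_y = c(4, 25)),
                "age")
}

test_that("maximum-size classification follows expert label then observation", {
  tr <- assignDbhmaxClass(data.frame(
    species_code = c("a", "b", "c", "d"),
    life_form = "tree",
    dbhmax_class = c(NA, NA, "40-80", NA),
    observed_max_cm = c(35, 5, 22, NA)))
  # observed 35 -> 20-40 with mid 30; observed exactly 5 is lower-inclusive
  expect_equal(tr$dbhmax_class[1:2], c("20-40", "5-10"))
  expect_equal(tr$dbhmax_mid_cm[1:2], c(30, 7.5))
  # expert label wins over the observed 22
  expect_equal(tr$dbhmax_mid_cm[3], 60)
  # neither source: unclassified, reported
  expect_true(is.na(tr$dbhmax_class[4]))
  expect_equal(dbhmaxMidValues()[["1-5"]], 3)
  expect_equal(dbhmaxMidValues(openClassMid = 100)[[">80"]], 100)
  expect_error(assignDbhmaxClass(data.frame(
    species_code = "x", life_form = "tree", dbhmax_class = "5-15")),
    "unknown maximum-DBH")
})

test_that("the RST filter applies threshold arithmetic per plot", {
  # DBH 10 with mid-value 30 qualifies at p = 0.30 (10 >= 9)
  above <- speciesAboveRST(rstStems(), rstTraits(), 0.30, rstScheme())
  expect_true("big" %in% above[["2-7 y"]])   # tree of 10 cm in y1
  expect_true("big" %in% above[["18-32 y"]])
  # the 1-5 cm class has mid 3: bar 0.9 cm, nearly every measured stem passes
  expect_true("small" %in% above[["2-7 y"]])
  # palms are out of scope for the tree/shrub analysis
  expect_false(any(grepl("palm", unlist(above))))
  # rarity variant: "big" qualifies in 2 plots of o1 but 1 plot of y1
  multi <- speciesAboveRST(rstStems(), rstTraits(), 0.30, rstScheme(),
                           minPlots = 2)
  expect_false("big" %in% multi[["2-7 y"]])
  expect_true("big" %in% multi[["18-32 y"]])
  expect_error(speciesAboveRST(rstStems(), rstTraits(), 1.2, rstScheme()),
               "\\(0, 1\\]")
})

test_that("seedlings never qualify for a relative size threshold", {
  st <- rstStems()
  st$stratum[1] <- "seedling"; st$diameter_cm[1] <- NA
  above <- speciesAboveRST(st, rstTraits(), 0.001, rstScheme())
  # the seedling record cannot carry 'big' in y1's upper plot
  multi <- speciesAboveRST(st, rstTraits(), 0.3, rstScheme(), minPlots = 2)
  expect_false("big" %in% multi[["2-7 y"]])
})

test_that("raising the threshold never adds species (set inclusion)", {
  sim <- simulateScenario("paper-like", seed = 8)
  traits <- assignDbhmaxClass(sim$traits)
  scheme <- assignClasses(sim$sites, "age")
  prev <- NULL
  for (p in c(0.05, 0.1, 0.3, 0.6, 1)) {
    cur <- speciesAboveRST(sim$stems, traits, p, scheme)
    if (!is.null(prev))
      for (k in names(cur)) expect_true(all(cur[[k]] %in% prev[[k]]))
    prev <- cur
  }
})

test_that("the effective-diversity summary reproduces hand counts", {
  # printed toy table: 10 tree species, exactly 4 with a stem at or above
  # 30% of their class mid-value
  spp <- sprintf("t%02d", 1:10)
  # qualifiers: class 20-40 (bar 9 cm) at 10 cm; non-qualifiers: 20-40 at
  # 8 cm and 40-80 (bar 18 cm) at 17 cm -- all census-legal trees
  dia <- c(rep(10, 4), rep(8, 3), rep(17, 3))
  stems <- data.frame(
    site_id = "s1", plot_id = "upper", species_code = spp,
    stratum = "tree", diameter_cm = dia, life_form = "tree")
  traits <- assignDbhmaxClass(data.frame(
    species_code = spp, life_form = "tree",
    dbhmax_class = c(rep("20-40", 7), rep("40-80", 3))))
  scheme <- assignClasses(data.frame(site_id = "s1", age_y = 5), "age",
                          boundaries = c(2, 8))
  eff <- effectiveGammaSummary(stems, traits, scheme, thresholds = 0.30)
  row <- eff$summary[eff$summary$age_class == "2-7 y", ]
  expect_equal(row$n_species_total, 10)
  expect_equal(row$n_above_rst30, 4)
  expect_equal(row$reduction_rst30_pct, 60)
  # per-maximum-size-class species counts partition the total
  brk <- eff$breakdown[eff$breakdown$age_class == "2-7 y", ]
  expect_equal(sum(brk$n_species), 10)
  expect_equal(sum(brk$n_above_rst30), 4)
})

test_that("a vanishing threshold recovers total diversity", {
  sim <- simulateScenario("paper-like", seed = 9)
  traits <- assignDbhmaxClass(sim$traits)
  scheme <- assignClasses(sim$sites, "age")
  eff <- effectiveGammaSummary(sim$stems, traits, scheme,
                               thresholds = c(0.001, 0.3),
                               includeSeedlings = FALSE)
  expect_equal(eff$summary$n_above_rst00,
               eff$summary$n_species_total)
  expect_true(all(eff$summary$n_above_rst30 <=
                    eff$summary$n_above_rst00))
  expect_true(all(eff$summary$n_above_multiplot <=
                    eff$summary$n_above_rst30))
})
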
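test_that("stem validation enforces the census protocol", {
  chk <- validateStems(toyStems())
  expect_equal(nrow(chk$valid), 3)
  expect_equal(nrow(chk$rejected), 0)

  bad <- toyStems()
  bad$diameter_cm[2] <- 3.0  # a "tree" below the 5 cm census limit
  chk <- validateStems(bad)
  expect_equal(nrow(chk$valid), 2)
  expect_match(chk$rejected$reason, "tree DBH below 5 cm")

  # liana stratum reserved for climbers; climbing seedlings are fine
  mix <- data.frame(site_id = "A", plot_id = "upper",
                    species_code = c("x", "y"),
                    stratum = c("liana", "seedling"),
                    diameter_cm = c(2, NA), life_form = c("tree", "liana"))
  chk <- validateStems(mix)
  expect_equal(chk$valid$stratum, "seedling")
  expect_match(chk$rejected$reason, "climbing life form")

  expect_error(validateStems(toyStems()[, -4]), "required column")
})

test_that("stem tables round-trip through CSV loss-free", {
  sim <- simulateScenario("paper-like", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  writeStemTable(sim$stems, path)
  back <- loadStemTable(path)
  expect_equal(nrow(back), nrow(sim$stems))
  expect_equal(nrow(attr(back, "rejected")), 0)
  attr(back, "rejected") <- NULL
  got <- back[order(back$site_id, back$plot_id, back$species_code,
                    back$stratum, back$diameter_cm), ]
  want <- sim$stems[order(sim$stems$site_id, sim$stems$plot_id,
                          sim$stems$species_code, sim$stems$stratum,
                          sim$stems$diameter_cm), ]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("loadStemTable applies dialects and reports rejects", {
  df <- toyStems()
  names(df) <- c("site", "plot", "sp", "layer", "dbh", "form")
  df$dbh[1] <- 0.2  # sapling below 1 cm: must be rejected, not dropped
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  expect_message(
    stems <- loadStemTable(path, dialect = c(
      site_id = "site", plot_id = "plot", species_code = "sp",
      stratum = "layer", diameter_cm = "dbh", life_form = "form")),
    "1 stem record")
  expect_equal(nrow(stems), 2)
  expect_equal(nrow(attr(stems, "rejected")), 1)
  expect_error(loadStemTable(path, dialect = c(site_id = "nope")),
               "absent")
})

test_that("site classification uses the stated interval conventions", {
  sites <- data.frame(site_id = sprintf("s%d", 1:5),
                      age_y = c(2, 7, 8, 17, 32),
                      sba_m2ha = c(5, 15, 11, 20, 29))
  sba <- assignClasses(sites, "sba", c(0, 11, 20, 30))
  # 15 falls in SBA-2; 11 exactly is lower-inclusive into SBA-2; 20 in SBA-3
  expect_equal(unname(membership(sba)[c("s2", "s3", "s4")]),
               c("SBA-2", "SBA-2", "SBA-3"))
  age <- assignClasses(sites, "age")
  # age labels are both-ends inclusive on integers: 7 -> "2-7 y"
  expect_equal(unname(membership(age)),
               c("2-7 y", "2-7 y", "8-17 y", "8-17 y", "18-32 y"))
  # partition: every site in exactly one class
  expect_equal(sum(classSizes(age)), nrow(sites))
  expect_false(anyNA(membership(age)))

  out <- sites; out$sba_m2ha[1] <- 35
  expect_error(assignClasses(out, "sba", c(0, 11, 20, 30)), "s1")
})

test_that("abundance matrices pool plots additively and filter by diameter", {
  stems <- data.frame(
    site_id = "A", plot_id = c("upper", "upper", "upper", "lower", "lower"),
    species_code = c("a", "a", "a", "a", "b"),
    stratum = "tree", diameter_cm = c(6, 7, 8, 9, 10), life_form = "tree")
  site <- buildAbundanceMatrix(stems, "tree", "site")
  expect_equal(as.vector(counts(site)), c(4, 1))
  plot <- buildAbundanceMatrix(stems, "tree", "plot")
  expect_equal(unname(colSums(counts(plot))), unname(colSums(counts(site))))
  # site-level row equals the sum of its two plot-level rows
  expect_equal(unname(counts(site)["A", ]),
               unname(colSums(counts(plot))))

  mixed <- rbind(stems, toyStems())
  only5 <- buildAbundanceMatrix(mixed, c("sapling", "tree", "liana"),
                                "site", minDiameterCm = 5)
  kept <- mixed$species_code[mixed$diameter_cm >= 5 &
                               !is.na(mixed$diameter_cm)]
  expect_setequal(speciesNames(only5), unique(kept))
})

test_that("matrix construction matches a brute-force tally and is idempotent", {
  sim <- simulateScenario("paper-like", seed = 4)
  mat <- buildAbundanceMatrix(sim$stems, c("sapling", "tree", "liana"),
                              "plot", minDiameterCm = 1)
  sub <- sim$stems[sim$stems$stratum %in% c("sapling", "tree", "liana") &
                     !is.na(sim$stems$diameter_cm) &
                     sim$stems$diameter_cm >= 1, ]
  for (u in sample(sampleUnits(mat), 5)) {
    parts <- strsplit(u, ":")[[1]]
    rows <- sub$site_id == parts[1] & sub$plot_id == parts[2]
    expect_equal(sum(counts(mat)[u, ]), sum(rows))
    tallied <- table(sub$species_code[rows])
    expect_equal(unname(counts(mat)[u, names(tallied)]),
                 as.vector(tallied))
  }
  # site matrix = sum of its plot matrices, exact integer equality
  site <- buildAbundanceMatrix(sim$stems, c("sapling", "tree", "liana"),
                               "site", minDiameterCm = 1)
  pooled <- rowsum(counts(mat), unitData(mat)$site_id)
  expect_equal(counts(site)[rownames(pooled), colnames(counts(mat))],
               pooled[, colnames(counts(mat))])
  # applying the same filter twice changes nothing
  again <- buildAbundanceMatrix(
    sim$stems[sim$stems$diameter_cm >= 1 & !is.na(sim$stems$diameter_cm), ],
    c("sapling", "tree", "liana"), "plot", minDiameterCm = 1)
  expect_identical(counts(again), counts(mat))
})

test_that("stand basal area accounts for the half-plot sapling census", {
  # one 10 cm tree per site-plot-pair: pi * 0.05^2 m2 over 0.2 ha
  stems <- data.frame(site_id = "A", plot_id = "upper",
                      species_code = "a", stratum = "tree",
                      diameter_cm = 10, life_form = "tree")
  expect_equal(unname(siteBasalArea(stems)["A"]),
               pi * 0.05^2 / 0.2)
  # an identical sapling counts double (censused on half the area)
  sap <- within(stems, { stratum <- "sapling"; diameter_cm <- 4 })
  expect_equal(unname(siteBasalArea(sap)["A"]),
               pi * 0.02^2 / 0.1)
  # liana exclusion flag
  li <- within(stems, { stratum <- "liana"; life_form <- "liana" })
  expect_equal(unname(siteBasalArea(li, includeLianas = FALSE)["A"]), 0)
})

test_that("empty filters warn and AbundanceMatrix validity holds", {
  expect_warning(m <- buildAbundanceMatrix(toyStems(), "seedling", "site"),
                 "no stems")
  expect_equal(ncol(counts(m)), 0)
  expect_error(
    new("AbundanceMatrix",
        counts = matrix(c(1, -1), 1, 2,
                        dimnames = list("u", c("a", "b"))),
        stratum = "tree", unitLevel = "site", minDiameterCm = 5,
        sampledAreaM2 = c(u = 1000),
        unitData = data.frame(row.names = "u")),
    "non-negative")
})
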
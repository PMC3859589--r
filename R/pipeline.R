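# End-to-end chronosequence analysis from one configuration: simulate (or
# load) -> classify -> diversity -> similarity -> ordination -> spatial ->
# regressions -> frequencies -> conservation, with a manifest of content
# hashes for reproducibility.

#' Default pipeline configuration
#'
#' Returns the configuration list [runPipeline()] consumes. Either
#' \code{scenario} names a bundled generator scenario, or \code{paths}
#' gives the stem/site/trait files to load. Every stochastic stage carries
#' an explicit seed; [runPipeline()] refuses configurations where one is
#' missing.
#'
#' @param scenario \code{"paper-like"}, \code{"null"}, or \code{NULL} when
#'   loading files.
#' @param paths list with \code{stems}, \code{sites}, \code{traits} file
#'   paths (used when \code{scenario} is NULL).
#' @param seed master seed; stage seeds are derived from it.
#' @return configuration list.
#' @export
pipelineConfig <- function(scenario = "paper-like", paths = NULL,
                           seed = 1L) {
  list(
    scenario = scenario,
    paths = paths,
    sbaBoundaries = c(0, 11, 20, Inf),
    ageBoundaries = c(2, 8, 18, 33),
    rstThresholds = c(0.10, 0.30),
    gammaSubsampleSize = 12,
    gammaIterations = 200,
    nmdsK = 2,
    nmdsStarts = 10,
    permutations = 999,
    hillOrders = c(0, 1, 2),
    seeds = list(simulate = seed, diversity = seed + 1L,
                 ordination = seed + 2L, spatial = seed + 3L)
  )
}

#' Run the full chronosequence analysis
#'
#' Executes every stage of the landscape succession analysis from one
#' configuration and writes a report bundle: tidy CSV tables per stage, a
#' JSON summary echoing every threshold and boundary used, the
#' configuration itself, and a manifest listing each output file with its
#' MD5 content hash (identical configuration and seeds reproduce identical
#' hashes for the deterministic stages). Any stage error halts the run
#' with a stage-named message; outputs written up to that point are kept
#' next to a \code{FAILED} marker naming the stage.
#'
#' @param config configuration list from [pipelineConfig()] (or a YAML
#'   file path).
#' @param outDir output directory (created; must be empty or absent).
#' @return invisibly, the manifest data.frame.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  needSeeds <- c("simulate", "diversity", "ordination", "spatial")
  have <- names(config$seeds)
  if (is.null(config$seeds) || !all(needSeeds %in% have))
    stop("configuration error: missing seed(s) for stochastic stage(s): ",
         paste(setdiff(needSeeds, have), collapse = ", "))
  if (dir.exists(outDir) && length(list.files(outDir)))
    stop("output directory is not empty: ", outDir)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(outDir, "config.yaml"))
  written <- character()
  emit <- function(df, name) {
    p <- file.path(outDir, name)
    utils::write.csv(df, p, row.names = FALSE)
    written <<- c(written, p)
  }
  stage <- "input"
  res <- tryCatch({
    # ---- input ----
    if (!is.null(config$scenario)) {
      sim <- simulateScenario(config$scenario,
                              seed = config$seeds$simulate)
      stems <- sim$stems; sites <- sim$sites; traits <- sim$traits
    } else {
      stems <- loadStemTable(config$paths$stems)
      sites <- loadSiteTable(config$paths$sites)
      traits <- loadTraitTable(config$paths$traits)
    }
    if (!"sba_m2ha" %in% names(sites) || anyNA(sites$sba_m2ha)) {
      ba <- siteBasalArea(stems)
      sites$sba_m2ha <- ba[sites$site_id]
    }
    traits <- assignDbhmaxClass(traits)
    emit(stems, "stems.csv"); emit(sites, "sites.csv")
    emit(traits, "traits.csv")

    stage <- "classify"
    sbaScheme <- assignClasses(sites, "sba", config$sbaBoundaries)
    ageScheme <- assignClasses(sites, "age", config$ageBoundaries)

    stage <- "matrices"
    mats <- list(
      seedling = buildAbundanceMatrix(stems, "seedling", "site",
                                      sites = sites),
      sapling = buildAbundanceMatrix(stems, "sapling", "site",
                                     sites = sites),
      tree = buildAbundanceMatrix(stems, "tree", "site", sites = sites),
      liana = buildAbundanceMatrix(stems, "liana", "site", sites = sites))
    stemsPlot <- buildAbundanceMatrix(
      stems, c("sapling", "tree", "liana"), "plot", minDiameterCm = 1,
      sites = sites)
    stemsSite <- buildAbundanceMatrix(
      stems, c("sapling", "tree", "liana"), "site", minDiameterCm = 1,
      sites = sites)

    stage <- "diversity"
    alpha <- do.call(rbind, lapply(names(mats), function(g) {
      df <- alphaDiversity(mats[[g]], config$hillOrders)
      df$group <- g
      df
    }))
    emit(alpha, "alpha_diversity.csv")
    gam <- do.call(rbind, lapply(names(mats), function(g) {
      do.call(rbind, lapply(sbaScheme@labels, function(k) {
        units <- names(membership(sbaScheme))[membership(sbaScheme) == k]
        sub <- subsetAbundance(mats[[g]], units = units)
        do.call(rbind, lapply(config$hillOrders, function(q) {
          rg <- resampledGamma(sub,
                  subsampleSize = min(config$gammaSubsampleSize,
                                      length(units)),
                  iterations = config$gammaIterations, q = q,
                  seed = config$seeds$diversity)
          data.frame(group = g, class = k, q = q, mean = rg@mean,
                     ciLow = rg@ciLow, ciHigh = rg@ciHigh)
        }))
      }))
    }))
    emit(gam, "gamma_diversity.csv")

    stage <- "ordination"
    ages <- stats::setNames(sites$age_y, sites$site_id)
    sbas <- stats::setNames(sites$sba_m2ha, sites$site_id)
    ordFits <- lapply(names(mats), function(g) {
      d <- dissimilarityMatrix(mats[[g]], "ruzicka")
      runNMDS(d, k = config$nmdsK, nStarts = config$nmdsStarts,
              seed = config$seeds$ordination, ageCovariate = ages)
    })
    names(ordFits) <- names(mats)
    scoresDf <- do.call(rbind, lapply(names(mats), function(g) {
      sc <- ordScores(ordFits[[g]])
      data.frame(group = g, unit = rownames(sc), sc, row.names = NULL,
                 stress = ordFits[[g]]@stress)
    }))
    emit(scoresDf, "nmds_scores.csv")

    stage <- "regressions"
    fitRows <- list()
    addFit <- function(response, group, predictor, sel) {
      b <- sel$best
      fitRows[[length(fitRows) + 1L]] <<- data.frame(
        response = response, group = group, predictor = predictor,
        model = b@family, r2 = round(b@r2, 2),
        p = signif(b@pValue, 3))
    }
    for (g in names(mats)) {
      al <- alpha[alpha$group == g, ]
      for (q in config$hillOrders) {
        y <- stats::setNames(al$value[al$q == q], al$unit[al$q == q])
        y <- y[!is.na(y)]
        for (pred in c("age", "sba")) {
          xv <- if (pred == "age") ages[names(y)] else sbas[names(y)]
          addFit(sprintf("D%g", q), g, pred,
                 selectSuccessionModel(xv, y))
        }
      }
      for (pred in c("age", "sba")) {
        xv <- if (pred == "age") ages else sbas
        addFit("composition", g, pred,
               axisRegression(ordFits[[g]], xv))
      }
    }
    emit(do.call(rbind, fitRows), "succession_fits.csv")

    stage <- "spatial"
    coords <- as.matrix(sites[, c("x_m", "y_m")])
    rownames(coords) <- sites$site_id
    spatialRows <- list()
    for (g in names(mats)) {
      d <- dissimilarityMatrix(mats[[g]], "ruzicka")
      geo <- as.matrix(stats::dist(coords[rownames(as.matrix(d)), ]))
      mt <- mantelTest(d, geo, permutations = config$permutations,
                       seed = config$seeds$spatial)
      pv <- permanovaTest(d, classOf(sbaScheme, rownames(as.matrix(d))),
                          permutations = config$permutations,
                          seed = config$seeds$spatial)
      spatialRows[[g]] <- data.frame(
        group = g, mantel_r = mt@statistic, mantel_p = mt@pValue,
        permanova_F = pv@statistic, permanova_R2 = pv@details$R2,
        permanova_p = pv@pValue)
    }
    emit(do.call(rbind, spatialRows), "spatial_tests.csv")

    stage <- "divergence"
    div <- seedlingDivergence(mats$seedling, stemsSite, sbaScheme, traits)
    emit(div, "seedling_divergence.csv")

    stage <- "frequency"
    freq <- occurrenceFrequencies(stemsPlot, sbaScheme)
    emit(freq, "landscape_frequencies.csv")
    turn <- do.call(rbind, lapply(
      utils::combn(sbaScheme@labels, 2, simplify = FALSE),
      function(pr) classTurnover(freq, pr[1], pr[2])))
    emit(turn, "class_turnover.csv")
    rf <- do.call(rbind, lapply(sbaScheme@labels, function(k) {
      r <- rankFrequencyCurve(freq, k)
      data.frame(class = k, slope = r$slope,
                 nSpecies = nrow(r$curve))
    }))
    emit(rf, "rank_frequency_slopes.csv")

    stage <- "conservation"
    eff <- effectiveGammaSummary(stems, traits, ageScheme,
                                 thresholds = config$rstThresholds)
    emit(eff$summary, "effective_diversity.csv")
    emit(eff$breakdown, "effective_diversity_breakdown.csv")

    stage <- "summary"
    jsonlite::write_json(
      list(sbaBoundaries = config$sbaBoundaries,
           ageBoundaries = config$ageBoundaries,
           rstThresholds = config$rstThresholds,
           hillOrders = config$hillOrders,
           permutations = config$permutations,
           seeds = config$seeds,
           classSizes = list(
             sba = as.list(table(membership(sbaScheme))),
             age = as.list(table(membership(ageScheme))))),
      file.path(outDir, "summary.json"), auto_unbox = TRUE, digits = NA)
    written <- c(written, file.path(outDir, "summary.json"))
    TRUE
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  files <- sort(c(written, file.path(outDir, "config.yaml")))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.csv(manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
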
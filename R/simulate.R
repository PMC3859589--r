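# Synthetic metacommunity generator. Encodes the two assembly axes the
# chronosequence analysis is designed to detect -- species-specific
# colonization rates (dispersal limitation) and light-dependent
# establishment (the successional niche) -- plus a structureless null
# generator for permutation-test calibration.

#' Species pool parameters for the metacommunity generator
#'
#' Draws per-species demographic parameters. Pioneers combine high
#' colonization rates, low shade tolerance, short lifespans and fast growth;
#' non-pioneers the reverse. Maximum-diameter classes are drawn with
#' life-form-dependent weights so shrubs are small-statured and canopy trees
#' dominate the large classes.
#'
#' @param nSpecies number of species in the regional pool.
#' @param pioneerFraction fraction of pioneer species.
#' @param colonizationMedian median per-plot, per-year arrival rate of a
#'   non-pioneer species.
#' @param colonizationSdLog log-scale sd of colonization rates across
#'   species (dispersal limitation: rates differ by orders of magnitude).
#' @param pioneerBoost multiplier on pioneer colonization rates.
#' @param seed RNG seed.
#' @return data.frame with one row per species: \code{species_code},
#'   \code{life_form}, \code{pioneer}, \code{colonization_rate},
#'   \code{shade_tolerance}, \code{longevity_y}, \code{growth_cm_y},
#'   \code{dbhmax_class}, \code{dbhmax_mid_cm}.
#' @export
speciesPool <- function(nSpecies = 300, pioneerFraction = 0.25,
                        colonizationMedian = 0.02, colonizationSdLog = 1.2,
                        pioneerBoost = 8, seed = 1L) {
  stopifnot(nSpecies >= 1, colonizationMedian > 0)
  set.seed(seed)
  lf <- sample(c("tree", "shrub", "palm", "liana", "other"), nSpecies,
               replace = TRUE, prob = c(0.46, 0.25, 0.05, 0.22, 0.02))
  pioneer <- stats::runif(nSpecies) < pioneerFraction
  colrate <- stats::rlnorm(nSpecies, log(colonizationMedian),
                           colonizationSdLog)
  colrate[pioneer] <- colrate[pioneer] * pioneerBoost
  # disjoint tolerance ranges guarantee pioneers sit below the pool median
  tol <- ifelse(pioneer, stats::runif(nSpecies, 0.02, 0.35),
                stats::runif(nSpecies, 0.40, 0.95))
  longev <- ifelse(pioneer, stats::runif(nSpecies, 6, 15),
                   stats::runif(nSpecies, 30, 120))
  classProbs <- rbind(
    tree   = c(0.00, 0.10, 0.20, 0.30, 0.30, 0.10),
    shrub  = c(0.30, 0.40, 0.30, 0.00, 0.00, 0.00),
    palm   = c(0.00, 0.20, 0.50, 0.30, 0.00, 0.00),
    liana  = c(0.20, 0.40, 0.30, 0.10, 0.00, 0.00),
    other  = c(0.40, 0.40, 0.20, 0.00, 0.00, 0.00))
  pioneerProbs <- c(0.10, 0.30, 0.30, 0.25, 0.05, 0.00)
  cls <- vapply(seq_len(nSpecies), function(i) {
    p <- if (pioneer[i]) pioneerProbs else classProbs[lf[i], ]
    sample.int(6L, 1L, prob = p)
  }, integer(1))
  mids <- dbhmaxMidValues()
  growth <- stats::rlnorm(nSpecies, log(0.45), 0.35) *
    (mids[cls] / 15)^0.3 * ifelse(pioneer, 2.2, 1)
  data.frame(
    species_code = sprintf("sp%03d", seq_len(nSpecies)),
    life_form = lf, pioneer = pioneer,
    colonization_rate = colrate, shade_tolerance = tol,
    longevity_y = longev, growth_cm_y = growth,
    dbhmax_class = names(mids)[cls], dbhmax_mid_cm = unname(mids[cls]),
    stringsAsFactors = FALSE)
}

#' Landscape parameters for the metacommunity generator
#'
#' Chronosequence layout: sites are drawn in equal numbers from three age
#' bands (so the age classes downstream are balanced), placed uniformly on a
#' square extent, and given a saturating stand-basal-area trajectory with
#' lognormal site-to-site noise. Understory light declines exponentially
#' with stand basal area, \code{light = 100 exp(-k SBA)}; the default decay
#' \code{k = 0.086} puts light near 7 percent at SBA 30 m2/ha.
#'
#' @param ageBands list of integer age vectors, one per band.
#' @param sitesPerBand sites drawn from each band.
#' @param sbaMax,sbaHalfSatY asymptote (m2/ha) and half-saturation age (y)
#'   of the SBA-age curve.
#' @param sbaNoiseSd log-scale sd of site deviations from the curve.
#' @param lightDecayK exponential light-extinction coefficient per m2/ha.
#' @param spatialExtentM side of the square landscape, metres.
#' @param spatialKernel add a short-range spatial colonization kernel
#'   (one random source point per species, exponential decay) to create
#'   distance decay of similarity; off by default.
#' @param kernelRangeM e-folding range of the kernel, metres.
#' @param lightReqMaxPct light requirement (percent of full light) of a
#'   fully intolerant species; a species establishes only where understory
#'   light exceeds \code{lightReqMaxPct * (1 - shade_tolerance)}, so
#'   pioneers stop regenerating once the canopy closes.
#' @return parameter list.
#' @export
landscapeParams <- function(ageBands = list(2:7, 8:17, 18:32),
                            sitesPerBand = 15,
                            sbaMax = 33, sbaHalfSatY = 11,
                            sbaNoiseSd = 0.25, lightDecayK = 0.086,
                            spatialExtentM = 2000,
                            spatialKernel = FALSE, kernelRangeM = 250,
                            lightReqMaxPct = 30) {
  stopifnot(sitesPerBand >= 1, length(ageBands) >= 1, sbaMax > 0)
  list(ageBands = ageBands, sitesPerBand = sitesPerBand, sbaMax = sbaMax,
       sbaHalfSatY = sbaHalfSatY, sbaNoiseSd = sbaNoiseSd,
       lightDecayK = lightDecayK, spatialExtentM = spatialExtentM,
       spatialKernel = spatialKernel, kernelRangeM = kernelRangeM,
       lightReqMaxPct = lightReqMaxPct)
}

sbaCurve <- function(age, landscape, siteEffect = 1)
  landscape$sbaMax * age / (age + landscape$sbaHalfSatY) * siteEffect

lightPct <- function(sba, k) 100 * exp(-k * sba)

#' Simulate a successional metacommunity
#'
#' Generates a stem inventory with the statistical structure the
#' chronosequence analysis assumes. For a site of age T, each species
#' accumulates colonization events as a Poisson process (rate = its
#' colonization rate, per plot-year); each arrival establishes with
#' probability \code{shade_tolerance^(1 - light/100)} evaluated at the
#' stand's light level when it arrived, and only where that light exceeds
#' the species' regeneration light requirement
#' (\code{lightReqMaxPct * (1 - shade_tolerance)}). Early arrivals under
#' full light thus establish almost surely regardless of tolerance, while
#' shade-intolerant pioneers stop regenerating once the canopy closes --
#' the successional-niche axis. Survivors of an exponential mortality hazard
#' \code{1/longevity} grow at their species rate, capped at 95 percent of
#' their maximum diameter, and are emitted as stem records with the stratum
#' inferred from diameter and life form. Saplings are thinned by one half
#' (half-plot census); establishments of the last two years still below
#' 1 cm become the seedling stratum.
#'
#' @param pool species pool from [speciesPool()].
#' @param landscape parameters from [landscapeParams()].
#' @param seed RNG seed for the landscape realization; together with the
#'   pool it fully determines the output.
#' @param seedlingWindowY recency window (years) for seedling emission.
#' @return list with data.frames \code{stems}, \code{sites}, \code{traits}
#'   (the loadable file contents) plus the \code{pool} and
#'   \code{landscape} used.
#' @export
simulateMetacommunity <- function(pool, landscape = landscapeParams(),
                                  seed = 1L, seedlingWindowY = 2) {
  if (all(pool$colonization_rate <= 0))
    stop("degenerate species pool: all colonization rates are zero")
  set.seed(seed)
  nSites <- landscape$sitesPerBand * length(landscape$ageBands)
  ages <- unlist(lapply(landscape$ageBands, function(b)
    b[sample.int(length(b), landscape$sitesPerBand, replace = TRUE)]))
  siteIds <- sprintf("S%02d", seq_len(nSites))
  xy <- matrix(stats::runif(2 * nSites, 0, landscape$spatialExtentM),
               ncol = 2, dimnames = list(siteIds, c("x", "y")))
  siteEffect <- stats::rlnorm(nSites, 0, landscape$sbaNoiseSd)
  sbaNow <- sbaCurve(ages, landscape, siteEffect)

  S <- nrow(pool)
  mult <- matrix(1, nSites, S)
  if (isTRUE(landscape$spatialKernel)) {
    src <- matrix(stats::runif(2 * S, 0, landscape$spatialExtentM), ncol = 2)
    dist2src <- sqrt(outer(xy[, 1], src[, 1], "-")^2 +
                     outer(xy[, 2], src[, 2], "-")^2)
    mult <- exp(-dist2src / landscape$kernelRangeM)
    mult <- sweep(mult, 2, colMeans(mult), "/")  # preserve landscape totals
  }

  plots <- c("upper", "lower")
  out <- vector("list", nSites * 2L)
  idx <- 0L
  for (j in seq_len(nSites)) {
    T <- ages[j]
    for (p in plots) {
      idx <- idx + 1L
      nArr <- stats::rpois(S, pool$colonization_rate * mult[j, ] * T)
      tot <- sum(nArr)
      if (tot == 0L) next
      sp <- rep.int(seq_len(S), nArr)
      aAge <- stats::runif(tot, 0, T)            # stand age at arrival
      light <- lightPct(sbaCurve(aAge, landscape, siteEffect[j]),
                        landscape$lightDecayK)
      # regeneration niche: establishment requires the understory light to
      # exceed the species' light requirement (high for intolerant
      # pioneers), then succeeds with probability tol^(1 - light/100)
      tol <- pool$shade_tolerance[sp]
      pEst <- ifelse(light >= landscape$lightReqMaxPct * (1 - tol),
                     tol^(1 - light / 100), 0)
      est <- stats::runif(tot) < pEst
      res <- T - aAge                            # residence time
      surv <- stats::runif(tot) < exp(-res / pool$longevity_y[sp])
      keep <- est & surv
      sp <- sp[keep]; res <- res[keep]
      # round before classifying so stored diameters honour the stratum
      # boundaries (4.999 cm must not become a 5.00 cm "sapling")
      d <- round(pmin(pool$growth_cm_y[sp] * res,
                      0.95 * pool$dbhmax_mid_cm[sp]), 2)
      lf <- pool$life_form[sp]
      strat <- rep(NA_character_, length(sp))
      strat[lf == "liana" & d >= 1] <- "liana"
      strat[lf != "liana" & d >= 5] <- "tree"
      strat[lf != "liana" & d >= 1 & d < 5] <- "sapling"
      strat[d < 1 & res <= seedlingWindowY] <- "seedling"
      ok <- !is.na(strat)
      # half-plot sapling census
      ok[strat == "sapling" & !is.na(strat)] <-
        ok[strat == "sapling" & !is.na(strat)] &
        stats::runif(sum(strat == "sapling", na.rm = TRUE)) < 0.5
      if (!any(ok)) next
      out[[idx]] <- data.frame(
        site_id = siteIds[j], plot_id = p,
        species_code = pool$species_code[sp[ok]],
        stratum = strat[ok],
        diameter_cm = ifelse(strat[ok] == "seedling", NA_real_, d[ok]),
        life_form = lf[ok], stringsAsFactors = FALSE)
    }
  }
  stems <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(stems) <- NULL
  sites <- data.frame(
    site_id = siteIds, age_y = ages, sba_m2ha = round(sbaNow, 2),
    x_m = round(xy[, 1], 1), y_m = round(xy[, 2], 1),
    light_pct = round(lightPct(sbaNow, landscape$lightDecayK), 2),
    stringsAsFactors = FALSE)
  traits <- pool[, c("species_code", "life_form", "dbhmax_class",
                     "dbhmax_mid_cm")]
  list(stems = stems, sites = sites, traits = traits,
       pool = pool, landscape = landscape)
}

#' Simulate a structureless null metacommunity
#'
#' Counts are i.i.d. Poisson across sites with species-specific means --
#' no age, stand-structure or spatial dependence of any kind. Used to
#' calibrate the type-I error of the permutation tests.
#'
#' @param nSites number of sites (2 plots each).
#' @param nSpecies species pool size.
#' @param meanAbundance median of the per-site species means.
#' @param spatialExtentM landscape side, metres.
#' @param seed RNG seed.
#' @return list of \code{stems}, \code{sites}, \code{traits} data.frames.
#' @export
simulateNullMetacommunity <- function(nSites = 30, nSpecies = 40,
                                      meanAbundance = 3,
                                      spatialExtentM = 2000, seed = 1L) {
  stopifnot(nSites >= 2, nSpecies >= 1)
  if (meanAbundance <= 0)
    stop("degenerate null parameters: meanAbundance must be positive")
  set.seed(seed)
  siteIds <- sprintf("N%02d", seq_len(nSites))
  mu <- stats::rlnorm(nSpecies, log(meanAbundance), 0.8)
  cnt <- matrix(stats::rpois(nSites * nSpecies, rep(mu, each = nSites)),
                nSites, nSpecies)
  tot <- sum(cnt)
  sp <- rep(rep(sprintf("sp%03d", seq_len(nSpecies)), each = nSites)[cnt > 0],
            cnt[cnt > 0])
  site <- rep(rep(siteIds, nSpecies)[cnt > 0], cnt[cnt > 0])
  stems <- data.frame(
    site_id = site,
    plot_id = sample(c("upper", "lower"), tot, replace = TRUE),
    species_code = sp, stratum = "tree",
    diameter_cm = round(stats::runif(tot, 5, 20), 2),
    life_form = "tree", stringsAsFactors = FALSE)
  sites <- data.frame(
    site_id = siteIds,
    age_y = sample(2:32, nSites, replace = TRUE),
    sba_m2ha = round(stats::runif(nSites, 1, 29.9), 2),
    x_m = round(stats::runif(nSites, 0, spatialExtentM), 1),
    y_m = round(stats::runif(nSites, 0, spatialExtentM), 1),
    stringsAsFactors = FALSE)
  traits <- data.frame(
    species_code = sprintf("sp%03d", seq_len(nSpecies)),
    life_form = "tree", dbhmax_class = "20-40", dbhmax_mid_cm = 30,
    stringsAsFactors = FALSE)
  list(stems = stems, sites = sites, traits = traits)
}

#' Bundled generator scenarios
#'
#' \code{"paper-like"} reproduces the qualitative successional regime the
#' analysis targets (45 sites in three balanced age bands, a several-hundred
#' species pool with pioneers and dispersal limitation); \code{"null"} is
#' the structureless calibration scenario.
#'
#' @param name scenario name.
#' @param seed master seed; the pool and landscape seeds are derived from it.
#' @return for \code{"paper-like"}, the [simulateMetacommunity()] output;
#'   for \code{"null"}, the [simulateNullMetacommunity()] output.
#' @export
simulateScenario <- function(name = c("paper-like", "null"), seed = 1L) {
  name <- match.arg(name)
  if (name == "paper-like") {
    simulateMetacommunity(speciesPool(seed = seed + 1000L),
                          landscapeParams(), seed = seed)
  } else {
    simulateNullMetacommunity(seed = seed)
  }
}
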
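# Maximum-size classification and relative-size-threshold (RST) effective
# diversity: the number of species with at least one individual above a
# fraction of its species maximum diameter, used as a proxy for the number
# of species reaching reproductive size in young forests.

DBHMAX_LABELS <- c("1-5", "5-10", "10-20", "20-40", "40-80", ">80")
DBHMAX_EDGES <- c(1, 5, 10, 20, 40, 80, Inf)

#' Mid-values of the maximum-DBH classes
#'
#' Classes 1-5, 5-10, 10-20, 20-40, 40-80 cm take their interval
#' mid-values (3, 7.5, 15, 30, 60); the open-topped >80 cm class has no
#' defined mid-value and defaults to 120 cm (1.5 x its lower bound),
#' configurable.
#'
#' @param openClassMid mid-value assigned to the >80 cm class.
#' @return named numeric vector of class mid-values (cm).
#' @export
dbhmaxMidValues <- function(openClassMid = 120) {
  c("1-5" = 3, "5-10" = 7.5, "10-20" = 15, "20-40" = 30, "40-80" = 60,
    ">80" = openClassMid)
}

#' Assign species to maximum-DBH classes
#'
#' An expert class label (column \code{dbhmax_class}) wins when provided;
#' otherwise the class is the interval containing the observed maximum
#' diameter (column \code{observed_max_cm}; intervals lower-inclusive, so
#' an observed maximum of exactly 5 cm falls in 5-10). Species with
#' neither source are flagged unclassified (NA class) and their count
#' reported; they are excluded from RST analyses.
#'
#' @param traits data.frame with \code{species_code}, \code{life_form} and
#'   \code{dbhmax_class} and/or \code{observed_max_cm}.
#' @param openClassMid mid-value for the >80 cm class.
#' @return the trait table with validated \code{dbhmax_class} and
#'   \code{dbhmax_mid_cm} columns.
#' @export
assignDbhmaxClass <- function(traits, openClassMid = 120) {
  mids <- dbhmaxMidValues(openClassMid)
  cls <- rep(NA_character_, nrow(traits))
  if ("dbhmax_class" %in% names(traits)) {
    lab <- as.character(traits$dbhmax_class)
    bad <- !is.na(lab) & !lab %in% DBHMAX_LABELS
    if (any(bad))
      stop("unknown maximum-DBH class label(s): ",
           paste(unique(lab[bad]), collapse = ", "))
    cls <- lab
  }
  if ("observed_max_cm" %in% names(traits)) {
    obs <- traits$observed_max_cm
    need <- is.na(cls) & !is.na(obs)
    idx <- pmax(findInterval(obs[need], DBHMAX_EDGES), 1L)
    cls[need] <- DBHMAX_LABELS[idx]
  }
  if (anyNA(cls))
    message(sum(is.na(cls)),
            " species unclassified (no expert label, no observed maximum)")
  traits$dbhmax_class <- cls
  traits$dbhmax_mid_cm <- unname(mids[cls])
  traits
}

rstScope <- function(stems, traits, lifeForms = c("tree", "shrub")) {
  tr <- traits[!is.na(traits$dbhmax_class) &
                 traits$life_form %in% lifeForms, ]
  st <- stems[stems$species_code %in% tr$species_code, , drop = FALSE]
  list(stems = st, traits = tr)
}

#' Species with individuals above a relative size threshold, per age class
#'
#' A species qualifies in an age class when it has at least one individual
#' with DBH >= \code{p} times its maximum-DBH class mid-value, in at least
#' \code{minPlots} distinct plots of the class. Only tree and shrub species
#' are considered (lianas and palms excluded); seedlings carry no diameter
#' and never qualify. \code{minPlots = 2} implements the rarity variant
#' that discounts species qualifying in a single plot.
#'
#' @param stems validated stem data.frame.
#' @param traits trait table processed by [assignDbhmaxClass()].
#' @param p relative size threshold in (0, 1].
#' @param scheme age [ClassScheme-class].
#' @param minPlots minimum number of distinct qualifying plots.
#' @return named list: per age class, the character vector of qualifying
#'   species codes.
#' @export
speciesAboveRST <- function(stems, traits, p, scheme, minPlots = 1) {
  if (p <= 0 || p > 1) stop("relative size threshold must lie in (0, 1]")
  sc <- rstScope(stems, traits)
  st <- sc$stems
  mid <- sc$traits$dbhmax_mid_cm[match(st$species_code,
                                       sc$traits$species_code)]
  qual <- !is.na(st$diameter_cm) & st$diameter_cm >= p * mid
  st <- st[qual, , drop = FALSE]
  cls <- classOf(scheme, st$site_id)
  plot <- paste(st$site_id, st$plot_id, sep = ":")
  out <- lapply(scheme@labels, function(k) {
    sub <- cls == k
    if (!any(sub)) return(character())
    nplots <- tapply(plot[sub], st$species_code[sub],
                     function(z) length(unique(z)))
    sort(names(nplots)[nplots >= minPlots])
  })
  names(out) <- scheme@labels
  out
}

#' Effective gamma-diversity summary per age class
#'
#' For each age class of pooled plots: the total number of tree and shrub
#' species, the number with at least one individual above each relative
#' size threshold (plus the more-than-one-plot rarity variant at the
#' highest threshold), the percentage reduction (reported to the integer
#' percent), and the species/stem breakdown across the six maximum-DBH
#' classes.
#'
#' @param stems validated stem data.frame.
#' @param traits trait table processed by [assignDbhmaxClass()].
#' @param scheme age [ClassScheme-class].
#' @param thresholds relative size thresholds (default 0.10 and 0.30).
#' @param includeSeedlings count seedling-only occurrences towards the
#'   class species totals (default TRUE).
#' @return list with \code{summary} (one row per age class) and
#'   \code{breakdown} (per age class x maximum-DBH class species and stem
#'   counts, with per-threshold qualifying species counts).
#' @export
effectiveGammaSummary <- function(stems, traits, scheme,
                                  thresholds = c(0.10, 0.30),
                                  includeSeedlings = TRUE) {
  thresholds <- sort(thresholds)
  sc <- rstScope(stems, traits)
  st <- sc$stems
  if (!includeSeedlings) st <- st[st$stratum != "seedling", , drop = FALSE]
  cls <- classOf(scheme, st$site_id)
  above <- lapply(thresholds, function(p)
    speciesAboveRST(stems, traits, p, scheme))
  names(above) <- sprintf("rst%02d", round(100 * thresholds))
  pmax_ <- thresholds[length(thresholds)]
  multi <- speciesAboveRST(stems, traits, pmax_, scheme, minPlots = 2)
  trCls <- sc$traits$dbhmax_class[match(st$species_code,
                                        sc$traits$species_code)]
  sumRows <- list(); brkRows <- list()
  for (k in scheme@labels) {
    sub <- cls == k
    if (!any(sub)) stop("age class ", k, " contains no stems")
    spp <- sort(unique(st$species_code[sub]))
    row <- data.frame(age_class = k, n_species_total = length(spp))
    for (nm in names(above)) {
      nAb <- length(intersect(above[[nm]][[k]], spp))
      row[[paste0("n_above_", nm)]] <- nAb
      row[[paste0("reduction_", nm, "_pct")]] <-
        round(100 * (1 - nAb / length(spp)))
    }
    row$n_above_multiplot <- length(intersect(multi[[k]], spp))
    sumRows[[k]] <- row
    for (dc in DBHMAX_LABELS) {
      inCls <- sub & trCls == dc
      sppD <- sort(unique(st$species_code[inCls]))
      br <- data.frame(age_class = k, dbhmax_class = dc,
                       n_species = length(sppD),
                       n_stems = sum(inCls & st$stratum != "seedling"))
      for (nm in names(above))
        br[[paste0("n_above_", nm)]] <-
          length(intersect(above[[nm]][[k]], sppD))
      brkRows[[paste(k, dc)]] <- br
    }
  }
  list(summary = do.call(rbind, c(sumRows, make.row.names = FALSE)),
       breakdown = do.call(rbind, c(brkRows, make.row.names = FALSE)))
}
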
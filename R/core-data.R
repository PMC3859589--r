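# Stem-inventory data model: reading/writing stem, site and trait tables,
# site classification, and construction of unit x species abundance matrices.

STRATA <- c("seedling", "sapling", "tree", "liana")
LIFE_FORMS <- c("tree", "shrub", "palm", "liana", "other")

# census area (m^2) per plot for each stratum: seedlings in 20 1x1 m
# subplots, saplings in one half plot, trees and lianas in the full
# 20 x 50 m plot
STRATUM_AREA_M2 <- c(seedling = 20, sapling = 500, tree = 1000, liana = 1000)

STEM_COLUMNS <- c("site_id", "plot_id", "species_code", "stratum",
                  "diameter_cm", "life_form")

#' Validate stem records against the census protocol
#'
#' Checks each row of a stem table against the inventory invariants:
#' saplings have 1 <= DBH < 5 cm, trees DBH >= 5 cm, lianas DBH >= 1 cm,
#' seedlings carry no diameter, and the liana stratum is reserved for
#' climbing life forms (liana-species seedlings are legitimate).
#'
#' @param stems data.frame with columns \code{site_id}, \code{plot_id},
#'   \code{species_code}, \code{stratum}, \code{diameter_cm},
#'   \code{life_form}.
#' @return list with elements \code{valid} (clean rows) and \code{rejected}
#'   (offending rows plus a \code{reason} column).
#' @export
validateStems <- function(stems) {
  missing <- setdiff(STEM_COLUMNS, names(stems))
  if (length(missing))
    stop("stem table lacks required column(s): ",
         paste(missing, collapse = ", "))
  stems <- as.data.frame(stems)[STEM_COLUMNS]
  d <- suppressWarnings(as.numeric(stems$diameter_cm))
  reason <- rep(NA_character_, nrow(stems))
  flag <- function(bad, why) reason[bad & is.na(reason)] <<- why
  flag(!stems$stratum %in% STRATA, "unknown stratum")
  flag(!stems$life_form %in% LIFE_FORMS, "unknown life form")
  flag(stems$stratum == "sapling" & (is.na(d) | d < 1 | d >= 5),
       "sapling DBH outside [1, 5) cm")
  flag(stems$stratum == "tree" & (is.na(d) | d < 5),
       "tree DBH below 5 cm")
  flag(stems$stratum == "liana" & (is.na(d) | d < 1),
       "liana diameter below 1 cm")
  flag(stems$stratum == "liana" & stems$life_form != "liana",
       "liana stratum requires climbing life form")
  flag(stems$life_form == "liana" &
         !stems$stratum %in% c("liana", "seedling"),
       "climbing life form outside liana/seedling strata")
  bad <- !is.na(reason)
  rejected <- stems[bad, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[bad]
  list(valid = stems[!bad, , drop = FALSE], rejected = rejected)
}

#' Read a stem inventory table
#'
#' Reads a delimited text file with one row per censused individual,
#' optionally renaming columns through a dialect map, validates every row,
#' and reports (not silently drops) rejected rows via the
#' \code{"rejected"} attribute and a message.
#'
#' @param path CSV (or TSV) file with a header.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g.
#'   \code{c(species_code = "sp", diameter_cm = "dbh")}.
#' @param dropUnknown drop rows whose species code matches
#'   \code{unknownCodes}; morphospecies codes are always retained.
#' @param unknownCodes species codes treated as unidentifiable.
#' @return validated stem data.frame; attribute \code{"rejected"} holds the
#'   rows that failed validation with reasons.
#' @export
loadStemTable <- function(path, dialect = NULL, dropUnknown = TRUE,
                          unknownCodes = c("unknown", "UNKNOWN", "indet")) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    hit <- match(dialect, names(raw))
    if (anyNA(hit))
      stop("dialect names columns absent from the file: ",
           paste(dialect[is.na(hit)], collapse = ", "))
    names(raw)[hit] <- names(dialect)
  }
  missing <- setdiff(STEM_COLUMNS, names(raw))
  if (length(missing))
    stop("stem table lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (dropUnknown) raw <- raw[!raw$species_code %in% unknownCodes, ,
                              drop = FALSE]
  chk <- validateStems(raw)
  if (nrow(chk$rejected))
    message(nrow(chk$rejected), " stem record(s) rejected during validation")
  stems <- chk$valid
  rownames(stems) <- NULL
  attr(stems, "rejected") <- chk$rejected
  stems
}

#' Write a stem table to CSV
#'
#' Counterpart of [loadStemTable()]; the written file round-trips loss-free.
#'
#' @param stems validated stem data.frame.
#' @param path output file path.
#' @export
writeStemTable <- function(stems, path) {
  utils::write.csv(stems[STEM_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a site metadata table
#'
#' @param path delimited file with columns \code{site_id}, \code{age_y},
#'   and optionally \code{sba_m2ha}, \code{x_m}, \code{y_m},
#'   \code{light_pct}.
#' @param dialect optional canonical -> file column-name map.
#' @return validated data.frame.
#' @export
loadSiteTable <- function(path, dialect = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  sites <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  if (!is.null(dialect)) {
    hit <- match(dialect, names(sites))
    names(sites)[hit[!is.na(hit)]] <- names(dialect)[!is.na(hit)]
  }
  if (!all(c("site_id", "age_y") %in% names(sites)))
    stop("site table needs at least site_id and age_y")
  if (any(sites$age_y <= 0)) stop("site ages must be positive")
  if (anyDuplicated(sites$site_id)) stop("duplicated site ids")
  sites
}

#' Read a species trait table
#'
#' @param path delimited file with \code{species_code}, \code{life_form} and
#'   \code{dbhmax_class} and/or \code{observed_max_cm}.
#' @return data.frame, ready for [assignDbhmaxClass()].
#' @export
loadTraitTable <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tr <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("species_code", "life_form") %in% names(tr)))
    stop("trait table needs species_code and life_form")
  tr
}

#' Classify sites into stand-basal-area or age classes
#'
#' Partitions the chronosequence sites along a successional axis. SBA uses
#' half-open intervals \code{[b_i, b_{i+1})} so a site at exactly 11 m2/ha
#' falls in SBA-2. Age boundaries are also half-open on the supplied edges,
#' which on integer ages reproduces the conventional both-ends-inclusive
#' labels: edges \code{c(2, 8, 18, 33)} give classes "2-7 y", "8-17 y",
#' "18-32 y".
#'
#' @param sites site data.frame (needs \code{site_id} plus \code{sba_m2ha}
#'   or \code{age_y}).
#' @param kind \code{"sba"} or \code{"age"}.
#' @param boundaries strictly increasing interval edges; defaults to
#'   \code{c(0, 11, 20, 30)} for SBA and \code{c(2, 8, 18, 33)} for age.
#' @param labels optional class labels; default "SBA-1"... for SBA and
#'   "2-7 y"-style labels for age.
#' @return a [ClassScheme-class].
#' @export
assignClasses <- function(sites, kind = c("sba", "age"),
                          boundaries = NULL, labels = NULL) {
  kind <- match.arg(kind)
  if (is.null(boundaries))
    boundaries <- if (kind == "sba") c(0, 11, 20, 30) else c(2, 8, 18, 33)
  if (is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  value <- switch(kind, sba = sites$sba_m2ha, age = sites$age_y)
  if (is.null(value))
    stop("site table lacks the ", if (kind == "sba") "sba_m2ha" else "age_y",
         " column")
  idx <- findInterval(value, boundaries)
  out <- idx < 1L | idx >= length(boundaries)
  if (any(out))
    stop("site(s) outside all class intervals: ",
         paste(sites$site_id[out], collapse = ", "))
  if (is.null(labels)) {
    labels <- if (kind == "sba") {
      paste0("SBA-", seq_len(length(boundaries) - 1L))
    } else {
      sprintf("%d-%d y", boundaries[-length(boundaries)],
              boundaries[-1L] - 1L)
    }
  }
  if (length(labels) != length(boundaries) - 1L)
    stop("need one label per interval")
  m <- labels[idx]
  names(m) <- sites$site_id
  new("ClassScheme", kind = kind, boundaries = as.numeric(boundaries),
      labels = labels, membership = m)
}

#' Class label of given sites
#'
#' @param scheme a [ClassScheme-class].
#' @param siteIds site identifiers.
#' @return character vector of class labels.
#' @export
classOf <- function(scheme, siteIds) {
  lab <- scheme@membership[as.character(siteIds)]
  if (anyNA(lab))
    stop("site(s) not in scheme: ",
         paste(unique(siteIds[is.na(lab)]), collapse = ", "))
  unname(lab)
}

#' Build a unit x species abundance matrix for a stratum
#'
#' Tallies stems passing the stratum and minimum-diameter filters per
#' sampling unit. Site-level matrices pool the two plots of each site (the
#' default for most analyses); plot-level matrices are used for
#' landscape-scale frequency analyses. All units present in \code{stems}
#' (before filtering) are kept as rows so matrices from different strata
#' align; species absent after filtering are dropped.
#'
#' @param stems validated stem data.frame.
#' @param stratum one or more of \code{"seedling"}, \code{"sapling"},
#'   \code{"tree"}, \code{"liana"} (pooled when several).
#' @param unitLevel \code{"site"} (pool plot pairs) or \code{"plot"}.
#' @param minDiameterCm optional diameter filter; stems without a diameter
#'   (seedlings) are excluded by any diameter filter.
#' @param sites optional site table; carried into \code{unitData}.
#' @return an [AbundanceMatrix-class].
#' @export
buildAbundanceMatrix <- function(stems, stratum,
                                 unitLevel = c("site", "plot"),
                                 minDiameterCm = NULL, sites = NULL) {
  unitLevel <- match.arg(unitLevel)
  stopifnot(all(stratum %in% STRATA))
  unit_all <- if (unitLevel == "site") as.character(stems$site_id) else
    paste(stems$site_id, stems$plot_id, sep = ":")
  units <- sort(unique(unit_all))
  keep <- stems$stratum %in% stratum
  if (!is.null(minDiameterCm))
    keep <- keep & !is.na(stems$diameter_cm) &
      stems$diameter_cm >= minDiameterCm
  if (!any(keep))
    warning("no stems pass the stratum/diameter filter; empty matrix")
  sub <- stems[keep, , drop = FALSE]
  species <- sort(unique(sub$species_code))
  m <- matrix(0L, length(units), length(species),
              dimnames = list(units, species))
  if (nrow(sub)) {
    tab <- table(factor(if (unitLevel == "site") as.character(sub$site_id)
                        else paste(sub$site_id, sub$plot_id, sep = ":"),
                        levels = units),
                 factor(sub$species_code, levels = species))
    m[] <- as.integer(tab)
  }
  # census area per unit: plot-level area of the stratum, doubled for sites
  # (two plots each); pooled strata use the full plot area
  areaPlot <- if (length(stratum) > 1L) 1000 else STRATUM_AREA_M2[[stratum]]
  area <- rep(if (unitLevel == "site") 2 * areaPlot else areaPlot,
              length(units))
  names(area) <- units
  ud <- data.frame(row.names = units)
  if (unitLevel == "plot") {
    ud$site_id <- sub("^(.*):[^:]*$", "\\1", units)
  } else {
    ud$site_id <- units
  }
  if (!is.null(sites)) {
    j <- match(ud$site_id, sites$site_id)
    for (cl in setdiff(names(sites), "site_id")) ud[[cl]] <- sites[[cl]][j]
  }
  new("AbundanceMatrix", counts = m, stratum = stratum,
      unitLevel = unitLevel,
      minDiameterCm = if (is.null(minDiameterCm)) NA_real_
                      else as.numeric(minDiameterCm),
      sampledAreaM2 = area, unitData = ud)
}

#' Subset an AbundanceMatrix to a set of species or units
#'
#' Species columns left all-zero by a unit subset are dropped, preserving
#' the container invariant.
#'
#' @param mat an [AbundanceMatrix-class].
#' @param species optional species codes to keep.
#' @param units optional unit ids to keep.
#' @export
subsetAbundance <- function(mat, species = NULL, units = NULL) {
  m <- mat@counts
  if (!is.null(units)) {
    bad <- setdiff(units, rownames(m))
    if (length(bad)) stop("unknown unit(s): ", paste(bad, collapse = ", "))
    m <- m[units, , drop = FALSE]
  }
  if (!is.null(species)) m <- m[, intersect(colnames(m), species), drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  new("AbundanceMatrix", counts = m, stratum = mat@stratum,
      unitLevel = mat@unitLevel, minDiameterCm = mat@minDiameterCm,
      sampledAreaM2 = mat@sampledAreaM2[rownames(m)],
      unitData = mat@unitData[rownames(m), , drop = FALSE])
}

#' Stand basal area per site
#'
#' Computes, for sites lacking a measured value, stand basal area as the
#' summed cross-sectional area of all stems >= 1 cm DBH (saplings, trees
#' and, by default, lianas) scaled to m2 per hectare using the sampled area
#' of each stratum (saplings are censused on half the plot area).
#'
#' @param stems validated stem data.frame.
#' @param includeLianas count lianas towards basal area (default TRUE).
#' @return named numeric vector, m2/ha per site.
#' @export
siteBasalArea <- function(stems, includeLianas = TRUE) {
  strata <- c("sapling", "tree", if (includeLianas) "liana")
  sub <- stems[stems$stratum %in% strata & !is.na(stems$diameter_cm), ,
               drop = FALSE]
  # per-site sampled area: two plots
  haPerStem <- 2 * STRATUM_AREA_M2[sub$stratum] / 1e4
  ba <- pi * (sub$diameter_cm / 200)^2 / haPerStem  # cm -> m radius
  out <- tapply(ba, factor(as.character(sub$site_id),
                           levels = sort(unique(as.character(stems$site_id)))),
                sum, default = 0)
  res <- as.numeric(out)
  names(res) <- names(out)
  res
}

#' Write an AbundanceMatrix as wide CSV plus JSON sidecar
#'
#' @param mat an [AbundanceMatrix-class].
#' @param path CSV path; the sidecar gets the same path with a
#'   \code{.json} extension.
#' @export
writeAbundanceMatrix <- function(mat, path) {
  df <- data.frame(unit = rownames(mat@counts), mat@counts,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  side <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(stratum = mat@stratum, unitLevel = mat@unitLevel,
         minDiameterCm = mat@minDiameterCm,
         sampledAreaM2 = as.list(mat@sampledAreaM2)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
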
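# Landscape-scale frequencies of occurrence (F1, F5%), between-class
# species turnover, and rank-frequency curves.

#' Landscape frequencies of occurrence per class
#'
#' For each species and site class, computes from a plot-level abundance
#' matrix of stems >= 1 cm (all life forms): \code{f1_pct}, the percentage
#' of the class's plots holding at least one individual, and
#' \code{f5_pct}, the percentage of plots where the species holds at least
#' 5 percent of all individuals >= 1 cm (boundary inclusive). The plot --
#' not the site -- is the frequency unit.
#'
#' @param mat plot-level [AbundanceMatrix-class] (units are plots;
#'   \code{unitData} must carry \code{site_id}).
#' @param scheme [ClassScheme-class] over the parent sites.
#' @param dominanceShare relative-abundance cutoff for F5 (default 0.05).
#' @return data.frame: \code{species}, \code{class}, \code{f1_pct},
#'   \code{f5_pct}.
#' @export
occurrenceFrequencies <- function(mat, scheme, dominanceShare = 0.05) {
  if (mat@unitLevel != "plot")
    stop("frequencies are defined over plots; build the matrix with ",
         "unitLevel = 'plot'")
  cnt <- counts(mat)
  cls <- classOf(scheme, unitData(mat)$site_id)
  tot <- rowSums(cnt)
  rel <- cnt / ifelse(tot == 0, 1, tot)
  res <- lapply(scheme@labels, function(k) {
    rows <- cls == k
    if (!any(rows)) stop("class ", k, " contains no plots")
    np <- sum(rows)
    data.frame(
      species = colnames(cnt),
      class = k,
      f1_pct = 100 * colSums(cnt[rows, , drop = FALSE] > 0) / np,
      f5_pct = 100 * colSums(rel[rows, , drop = FALSE] >=
                               dominanceShare) / np,
      row.names = NULL)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Species turnover between two classes
#'
#' Percentage of the species present (F1 > 0) in one class that are absent
#' from the other, in both directions.
#'
#' @param freq output of [occurrenceFrequencies()].
#' @param classA,classB class labels.
#' @return data.frame with two rows: species of A absent from B, and
#'   species of B absent from A (swapping the arguments swaps the rows).
#' @export
classTurnover <- function(freq, classA, classB) {
  present <- function(k) {
    s <- freq$species[freq$class == k & freq$f1_pct > 0]
    if (!length(s)) stop("class ", k, " holds no species")
    s
  }
  sA <- present(classA); sB <- present(classB)
  data.frame(
    from = c(classA, classB), absentIn = c(classB, classA),
    nSpecies = c(length(sA), length(sB)),
    nAbsent = c(length(setdiff(sA, sB)), length(setdiff(sB, sA))),
    pctAbsent = c(100 * length(setdiff(sA, sB)) / length(sA),
                  100 * length(setdiff(sB, sA)) / length(sB)))
}

#' Rank-frequency curve of a class
#'
#' Species present in the class sorted by descending F1 (ties broken
#' alphabetically, so the ordering is deterministic), plus a slope summary:
#' the linear slope of F1 on rank fitted over the top decile of ranks (at
#' least two, truncated at the last nonzero rank). The head of the curve is
#' where dominance concentrates, so its slope tracks how evenly the most
#' widespread species are distributed; shallower (less negative) slopes
#' indicate a more even distribution of landscape frequencies.
#'
#' @param freq output of [occurrenceFrequencies()].
#' @param class class label.
#' @return list with \code{curve} (rank, species, f1_pct) and \code{slope}.
#' @export
rankFrequencyCurve <- function(freq, class) {
  sub <- freq[freq$class == class & freq$f1_pct > 0, ]
  if (!nrow(sub)) stop("class ", class, " holds no species")
  ord <- order(-sub$f1_pct, sub$species)
  curve <- data.frame(rank = seq_len(nrow(sub)),
                      species = sub$species[ord],
                      f1_pct = sub$f1_pct[ord])
  upto <- min(nrow(curve), max(2L, ceiling(0.1 * nrow(curve))))
  seg <- curve[seq_len(upto), ]
  slope <- if (nrow(seg) < 2) 0
           else unname(stats::coef(stats::lm(f1_pct ~ rank, seg))[2])
  list(curve = curve, slope = slope)
}
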
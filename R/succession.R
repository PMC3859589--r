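# Linear, power and exponential regressions of community metrics on
# successional predictors, with the max-significant-R2 selection rule.

newFit <- function(family, a, b, r2, p, n, nDropped = 0L)
  new("SuccessionFit", family = family, a = a, b = b,
      r2 = r2, pValue = p, n = as.integer(n), nDropped = as.integer(nDropped))

responseScaleStats <- function(y, yhat, nPar = 2L) {
  n <- length(y)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 0 else max(0, 1 - sse / sst)
  Fst <- if (sse == 0) Inf else ((sst - sse) / (nPar - 1)) / (sse / (n - nPar))
  p <- stats::pf(Fst, nPar - 1, n - nPar, lower.tail = FALSE)
  list(r2 = r2, p = p)
}

#' Fit one succession regression family
#'
#' Linear \eqn{y = a + bx} by least squares; power \eqn{y = a x^b} and
#' exponential \eqn{y = a e^{bx}} by nonlinear least squares initialized
#' from the corresponding log-space linear fit (set
#' \code{fitMode = "loglog"} to keep the log-space coefficients instead).
#' The coefficient of determination is always computed on the response
#' scale, so R2 is comparable across families; significance is the F-test
#' of the fitted model against the intercept-only model. The power family
#' requires positive predictors; non-positive responses are excluded from
#' the power/exponential fits (their count is recorded in the result, no
#' offset is added).
#'
#' @param x predictor (age in years, stand basal area in m2/ha, or light
#'   in percent).
#' @param y response (diversity, ordination score, ...).
#' @param family \code{"linear"}, \code{"power"} or \code{"exponential"}.
#' @param fitMode \code{"nls"} (default) or \code{"loglog"}.
#' @return a [SuccessionFit-class].
#' @export
fitSuccessionModel <- function(x, y,
                               family = c("linear", "power", "exponential"),
                               fitMode = c("nls", "loglog")) {
  family <- match.arg(family)
  fitMode <- match.arg(fitMode)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 observations")
  if (family == "linear") {
    fit <- stats::lm(y ~ x)
    st <- responseScaleStats(y, stats::fitted(fit))
    return(newFit("linear", unname(stats::coef(fit)[1]),
                  unname(stats::coef(fit)[2]), st$r2, st$p, length(x)))
  }
  if (family == "power" && any(x <= 0))
    stop("power family requires a strictly positive predictor")
  drop <- y <= 0
  nDropped <- sum(drop)
  if (nDropped)
    message(nDropped, " non-positive response value(s) excluded from the ",
            family, " fit")
  x <- x[!drop]; y <- y[!drop]
  if (length(x) < 4) stop("fewer than 4 usable observations after ",
                          "excluding non-positive responses")
  init <- if (family == "power") stats::lm(log(y) ~ log(x))
          else stats::lm(log(y) ~ x)
  a0 <- exp(unname(stats::coef(init)[1])); b0 <- unname(stats::coef(init)[2])
  yhat0 <- if (family == "power") a0 * x^b0 else a0 * exp(b0 * x)
  if (fitMode == "loglog") {
    st <- responseScaleStats(y, yhat0)
    return(newFit(family, a0, b0, st$r2, st$p, length(x), nDropped))
  }
  # an (essentially) exact log-space fit leaves nls nothing to improve and
  # trips its zero-residual guard; keep the closed-form solution
  if (sum((y - yhat0)^2) <= 1e-12 * max(sum((y - mean(y))^2), 1e-12)) {
    st <- responseScaleStats(y, yhat0)
    return(newFit(family, a0, b0, st$r2, st$p, length(x), nDropped))
  }
  form <- if (family == "power") y ~ a * x^b else y ~ a * exp(b * x)
  nl <- tryCatch(
    stats::nls(form, data = data.frame(x = x, y = y),
               start = list(a = a0, b = b0),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e)
      stop("nonlinear fit failed to converge (log-space initialization: a = ",
           signif(a0, 4), ", b = ", signif(b0, 4), "): ",
           conditionMessage(e)))
  cf <- stats::coef(nl)
  st <- responseScaleStats(y, stats::fitted(nl))
  newFit(family, unname(cf["a"]), unname(cf["b"]), st$r2, st$p,
         length(x), nDropped)
}

#' Fit all regression families and select the best
#'
#' Fits every applicable family and selects the one with the highest
#' response-scale R2 among fits significant at \code{alpha}; when none is
#' significant the selection carries the family marker \code{"ns"}. The
#' power family is skipped (with a note in the output) when the predictor
#' contains non-positive values.
#'
#' @param x,y as in [fitSuccessionModel()].
#' @param families candidate families.
#' @param alpha significance level for admission (default 0.05).
#' @param fitMode passed through.
#' @return list with \code{best} (a [SuccessionFit-class]) and \code{fits}
#'   (all successful fits, named by family).
#' @export
selectSuccessionModel <- function(x, y,
                                  families = c("linear", "power",
                                               "exponential"),
                                  alpha = 0.05,
                                  fitMode = c("nls", "loglog")) {
  fitMode <- match.arg(fitMode)
  fits <- list()
  for (fam in families) {
    f <- tryCatch(suppressMessages(
      fitSuccessionModel(x, y, fam, fitMode)), error = function(e) NULL)
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (!length(fits)) stop("no family could be fitted")
  sig <- Filter(function(f) !is.na(f@pValue) && f@pValue <= alpha, fits)
  best <- if (length(sig)) {
    sig[[which.max(vapply(sig, function(f) f@r2, numeric(1)))]]
  } else {
    newFit("ns", NA_real_, NA_real_, NA_real_, NA_real_,
           length(x))
  }
  list(best = best, fits = fits)
}
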
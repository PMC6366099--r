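#' Likelihood-ratio test for 24 h rhythmicity
#'
#' `Lambda = 2 (logLik_rhythmic - logLik_null)`, clipped at zero, compared
#' to the upper tail of a chi-squared distribution with `df` degrees of
#' freedom (default 2: the rhythmic model frees the shared variance and
#' its lengthscale). Because the null pins a variance to the boundary of
#' the parameter space, the naive chi-squared reference is conservative; a
#' permutation-calibrated p-value is available through
#' [testRhythmicity()].
#'
#' @param fitRhythmic,fitNull \linkS4class{GPFit} objects for the same
#'   series.
#' @param alpha significance level (default the conventional 5%).
#' @param df chi-squared degrees of freedom (default 2).
#' @return one-row data.frame: `lr_stat`, `df`, `p_value`, `rhythmic`,
#'   `converged`.
#' @export
lrTest <- function(fitRhythmic, fitNull, alpha = 0.05, df = 2) {
  stopifnot(methods::is(fitRhythmic, "GPFit"), methods::is(fitNull, "GPFit"))
  if (fitRhythmic@kind != "rhythmic" || fitNull@kind != "null")
    stop("lrTest expects (rhythmic fit, null fit) in that order")
  if (!fitRhythmic@converged || !fitNull@converged)
    return(data.frame(lr_stat = NA_real_, df = df, p_value = NA_real_,
                      rhythmic = NA, converged = FALSE))
  lam <- max(0, 2 * (fitRhythmic@logLik - fitNull@logLik))
  p <- pchisq(lam, df = df, lower.tail = FALSE)
  data.frame(lr_stat = lam, df = df, p_value = p, rhythmic = p <= alpha,
             converged = TRUE)
}

#' Full rhythmicity analysis of one analyte in one group
#'
#' Stacks the series, fits null and rhythmic hierarchical GP models,
#' applies the likelihood-ratio test, and (for significant analytes)
#' extracts the posterior shared curve and its acrophase.
#'
#' @param x a normalized \linkS4class{RhythmExperiment}.
#' @param analyte,group analyte name and group label.
#' @param alpha significance level.
#' @param df chi-squared degrees of freedom.
#' @param period rhythm period in hours.
#' @param gridRes posterior grid resolution in hours.
#' @param permute replace the chi-squared p-value by a permutation
#'   p-value (clock times shuffled within each subject, `nPerm`
#'   permutations, deterministic given `permSeed`).
#' @param nPerm,permSeed permutation count and seed.
#' @return list: `result` (one-row data.frame with analyte, group,
#'   lr_stat, df, p_value, rhythmic, acrophase), `fits`, `posterior`
#'   (`NULL` unless rhythmic).
#' @export
testRhythmicity <- function(x, analyte, group, alpha = 0.05, df = 2,
                            period = 24, gridRes = 0.1, permute = FALSE,
                            nPerm = 999, permSeed = 1) {
  series <- stackSeries(x, analyte, group)
  fits <- fitRhythmModels(series, period = period)
  res <- lrTest(fits$rhythmic, fits$null, alpha = alpha, df = df)
  if (permute && isTRUE(res$converged)) {
    res$p_value <- .permutationP(series, res$lr_stat, nPerm = nPerm,
                                 seed = permSeed, period = period)
    res$rhythmic <- res$p_value <= alpha
  }
  out <- cbind(data.frame(analyte = analyte, group = group), res,
               data.frame(acrophase = NA_real_))
  posterior <- NULL
  if (isTRUE(res$rhythmic)) {
    posterior <- posteriorSharedCurve(series, fits$rhythmic,
                                      gridRes = gridRes)
    out$acrophase <- tryCatch(estimateAcrophase(posterior),
                              error = function(e) NA_real_)
  }
  list(result = out, fits = fits, posterior = posterior)
}

## permutation calibration of the LR statistic: shuffle observation times
## within each subject (breaking any shared phase relation while keeping
## each subject's marginal distribution), refit both models
.permutationP <- function(series, lrObs, nPerm, seed, period) {
  if (!is.finite(lrObs)) return(NA_real_)
  count <- 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (b in seq_len(nPerm)) {
    tp <- series@t
    for (s in seq_len(series@nSubjects)) {
      idx <- which(series@subjectIdx == s)
      tp[idx] <- tp[sample(idx)]
    }
    sp <- series
    sp@t <- tp
    fb <- fitRhythmModels(sp, period = period)
    if (fb$null@converged && fb$rhythmic@converged) {
      lamb <- max(0, 2 * (fb$rhythmic@logLik - fb$null@logLik))
      if (lamb >= lrObs) count <- count + 1L
    }
  }
  (1 + count) / (nPerm + 1)
}

#' Classify gain or loss of rhythmicity between groups
#'
#' A pure truth table on the two within-group p-values at level `alpha`:
#' significant in both groups, only in the disease group (gain), only in
#' the control group (loss), or in neither.
#'
#' @param pControl,pDisease vectors of p-values for the control (healthy)
#'   and disease (RA/CIA) groups.
#' @param alpha significance level.
#' @return factor with levels `rhythmic_in_both`, `gained_in_RA`,
#'   `lost_in_RA`, `not_rhythmic` (`NA` where either p is `NA`).
#' @export
classifyGain <- function(pControl, pDisease, alpha = 0.05) {
  stopifnot(length(pControl) == length(pDisease))
  ok <- !is.na(pControl) & !is.na(pDisease)
  if (any(c(pControl[ok], pDisease[ok]) < 0 | c(pControl[ok], pDisease[ok]) > 1))
    stop("p-values must lie in [0, 1]")
  h <- pControl <= alpha
  r <- pDisease <= alpha
  out <- ifelse(h & r, "rhythmic_in_both",
         ifelse(!h & r, "gained_in_RA",
         ifelse(h & !r, "lost_in_RA", "not_rhythmic")))
  factor(out, levels = c("rhythmic_in_both", "gained_in_RA", "lost_in_RA",
                         "not_rhythmic"))
}

#' Per-class rhythmicity summary for one group
#'
#' Bins analytes into ceramide structural classes (NS, NDS, AS, ADS via
#' the nomenclature parser) or `"other"` for non-ceramides, and counts
#' detected and rhythmic species per class. Acrophases of the rhythmic
#' species are attached per class.
#'
#' @param results data.frame for a single group with columns `analyte`,
#'   `rhythmic`, `acrophase` (as produced by [runPipeline()] or
#'   [testRhythmicity()]).
#' @return data.frame with columns `class`, `n_detected`, `n_rhythmic`
#'   and attribute `"acrophases"` (named list of peak-hour vectors).
#' @export
summarizeByClass <- function(results) {
  stopifnot(all(c("analyte", "rhythmic") %in% names(results)))
  cls <- vapply(results$analyte, function(a) {
    p <- parseCeramideName(a, lenient = TRUE)
    if (is.na(p$class_code)) "other" else p$class_code
  }, character(1))
  lev <- c("NS", "NDS", "AS", "ADS", "other")
  cls <- factor(cls, levels = lev)
  rhythmic <- !is.na(results$rhythmic) & results$rhythmic
  out <- data.frame(
    class = lev,
    n_detected = as.integer(table(cls)),
    n_rhythmic = as.integer(table(cls[rhythmic])))
  acr <- if ("acrophase" %in% names(results))
    lapply(split(results$acrophase[rhythmic], cls[rhythmic]),
           function(v) v[!is.na(v)])
  else setNames(rep(list(numeric(0)), length(lev)), lev)
  attr(out, "acrophases") <- acr
  out
}

#' Modal acrophase bin
#'
#' Histogram peak of a set of acrophases under fixed-width clock-hour
#' binning (ties broken by the earliest bin).
#'
#' @param acrophases vector of peak hours in `[0, 24)`.
#' @param binWidth bin width in hours.
#' @return left edge (hour) of the modal bin, or `NA` if empty.
#' @export
modalAcrophaseBin <- function(acrophases, binWidth = 1) {
  acrophases <- acrophases[!is.na(acrophases)]
  if (length(acrophases) == 0) return(NA_real_)
  edges <- seq(0, 24, by = binWidth)
  counts <- table(cut(acrophases %% 24, breaks = edges, right = FALSE,
                      include.lowest = TRUE))
  edges[which.max(counts)]
}

#' Circular distance between two clock hours
#'
#' @param a,b hours; recycled.
#' @param period cycle length in hours.
#' @return shortest-way distance in hours, in `[0, period/2]`.
#' @export
circularDistance <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}
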
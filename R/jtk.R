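#' JTK-style nonparametric rhythm test
#'
#' A simplified JTK-CYCLE-type detector for balanced, evenly sampled
#' designs: the data are correlated (Kendall's tau) against cosine
#' templates `cos(2 pi (t - phi) / period)` over a grid of candidate
#' acrophases `phi`; each template's p-value is the one-sided (positive
#' concordance) tail, exact when there are no ties and otherwise a
#' seeded permutation tail; the family p-value Bonferroni-corrects the
#' minimum over templates. The best phase is the argmin-p template,
#' earliest on ties.
#'
#' @param times sampling times in hours (replicates per timepoint
#'   allowed; at least 4 distinct timepoints).
#' @param values measurements aligned with `times`.
#' @param period rhythm period in hours.
#' @param phaseStep spacing of the candidate-phase grid in hours;
#'   defaults to the sampling interval.
#' @param nPerm permutations for the tie fallback.
#' @param seed seed for the permutation fallback.
#' @return list: `best_phase_h`, `tau` (at the best phase), `p_value`
#'   (family-corrected), and `phases` (per-template data.frame). A
#'   constant series yields an `NA` result rather than an error.
#' @export
jtkTest <- function(times, values, period = 24, phaseStep = NULL,
                    nPerm = 1000, seed = 1) {
  stopifnot(length(times) == length(values))
  ok <- is.finite(times) & !is.na(values)
  times <- times[ok]; values <- values[ok]
  if (length(unique(times %% period)) < 4)
    stop("jtkTest needs at least 4 distinct timepoints within one period")
  if (diff(range(values)) < 1e-12)
    return(list(best_phase_h = NA_real_, tau = NA_real_,
                p_value = NA_real_, phases = NULL))
  if (is.null(phaseStep)) {
    ut <- sort(unique(times %% period))
    phaseStep <- min(diff(ut))
  }
  phases <- seq(0, period - phaseStep / 2, by = phaseStep)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  permIdx <- NULL
  nullCache <- new.env(parent = emptyenv())
  res <- lapply(phases, function(phi) {
    ## rounding zaps floating-point residue (cos at quarter periods is
    ## O(1e-16), not 0), which would silently break template ties
    tmpl <- round(cos(2 * pi * (times - phi) / period), 12)
    tau <- suppressWarnings(cor(values, tmpl, method = "kendall"))
    ties <- anyDuplicated(values) > 0 || anyDuplicated(round(tmpl, 12)) > 0
    if (!ties) {
      p <- suppressWarnings(
        cor.test(values, tmpl, method = "kendall",
                 alternative = "greater", exact = TRUE)$p.value)
    } else {
      ## permutation null of tau; the distribution depends on the two
      ## vectors' value multisets only, so templates sharing a multiset
      ## (all phases on an evenly sampled grid) share one null
      key <- paste(sort(round(tmpl, 9)), collapse = ",")
      if (is.null(nullCache[[key]])) {
        if (is.null(permIdx))
          permIdx <<- replicate(nPerm, sample.int(length(values)))
        nullCache[[key]] <- apply(permIdx, 2, function(ix)
          suppressWarnings(cor(values[ix], tmpl, method = "kendall")))
      }
      p <- (1 + sum(nullCache[[key]] >= tau - 1e-12)) / (nPerm + 1)
    }
    data.frame(phase = phi, tau = tau, p = p)
  })
  tab <- do.call(rbind, res)
  best <- which.min(tab$p)                     # earliest phase on ties
  list(best_phase_h = tab$phase[best], tau = tab$tau[best],
       p_value = min(1, tab$p[best] * nrow(tab)), phases = tab)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment across analytes
#' (delegates to [stats::p.adjust()]).
#'
#' @param p vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, each `>=` the raw p and `<= 1`.
#' @export
adjustBH <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' JTK screen across all analytes of one group
#'
#' Pools the group's subjects as replicates per timepoint (times reduced
#' modulo the period) and applies [jtkTest()] per analyte, with BH
#' adjustment across analytes.
#'
#' @param x a \linkS4class{RhythmExperiment}.
#' @param group group label.
#' @param period,phaseStep,nPerm,seed passed to [jtkTest()].
#' @return data.frame: `analyte`, `best_phase_h`, `tau`, `p_value`,
#'   `p_adj`.
#' @export
jtkScreen <- function(x, group, period = 24, phaseStep = NULL,
                      nPerm = 1000, seed = 1) {
  rows <- lapply(analytes(x), function(a) {
    series <- tryCatch(stackSeries(x, a, group), error = function(e) NULL)
    if (is.null(series))
      return(data.frame(analyte = a, best_phase_h = NA_real_,
                        tau = NA_real_, p_value = NA_real_))
    r <- jtkTest(series@t %% period, series@y, period = period,
                 phaseStep = phaseStep, nPerm = nPerm, seed = seed)
    data.frame(analyte = a, best_phase_h = r$best_phase_h, tau = r$tau,
               p_value = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjustBH(out$p_value)
  out
}
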
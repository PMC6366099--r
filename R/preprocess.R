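#' Per-subject-per-analyte standardization
#'
#' Centres and scales every (subject, analyte) stratum of observed values
#' to mean 0 and sample SD 1 (n-1 denominator). Missing cells are left
#' untouched. Strata with zero variance cannot be standardized; they are
#' excluded from rhythm analysis (values set to `NA`, the stratum recorded
#' in [excludedStrata()]) rather than jittered, and a warning is issued.
#' Idempotent on already-normalized data.
#'
#' @param object a \linkS4class{RhythmExperiment}.
#' @param ... unused.
#' @return the normalized \linkS4class{RhythmExperiment}.
#' @importFrom BiocGenerics normalize
#' @export
#' @aliases normalize
setMethod("normalize", "RhythmExperiment", function(object, ...) {
  m <- SummarizedExperiment::assay(object, "value")
  cd <- SummarizedExperiment::colData(object)
  excl <- S4Vectors::metadata(object)$excluded
  nBefore <- nrow(excl)
  for (s in unique(cd$subject)) {
    cols <- which(cd$subject == s)
    for (i in seq_len(nrow(m))) {
      v <- m[i, cols]
      obs <- !is.na(v)
      if (sum(obs) < 2) next
      sdev <- sd(v[obs])
      if (!is.finite(sdev) || sdev < 1e-12) {
        m[i, cols] <- NA_real_
        excl <- rbind(excl, data.frame(subject = s,
                                       analyte = rownames(m)[i],
                                       reason = "constant stratum"))
        next
      }
      m[i, cols][obs] <- (v[obs] - mean(v[obs])) / sdev
    }
  }
  SummarizedExperiment::assay(object, "value") <- m
  S4Vectors::metadata(object)$excluded <- excl
  S4Vectors::metadata(object)$normalized <- TRUE
  nNew <- nrow(excl) - nBefore
  if (nNew > 0) {
    object <- .appendLog(object, sprintf(
      "normalize: %d constant (subject, analyte) strata excluded", nNew))
    warning(sprintf("%d constant (subject, analyte) strata excluded from rhythm analysis",
                    nNew), call. = FALSE)
  }
  object <- .appendLog(object, "normalize: per (subject, analyte) mean 0 / SD 1")
  object
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic imputation of missing cells
#'
#' Fills each missing value of a (subject, analyte) stratum by linear
#' interpolation of the subject's observed values against time; values
#' missing at a boundary time carry the nearest observed value. Single
#' imputation, fully deterministic given the input. Subjects retaining
#' fewer than 2 observed visits (timepoints with any observed analyte)
#' are dropped with a warning.
#'
#' @param x a \linkS4class{RhythmExperiment}.
#' @param ... unused.
#' @return the imputed \linkS4class{RhythmExperiment}; imputed cells are
#'   recorded in the `"imputed"` logical assay.
#' @export
setMethod("imputeMissing", "RhythmExperiment", function(x, ...) {
  m <- SummarizedExperiment::assay(x, "value")
  cd <- SummarizedExperiment::colData(x)
  ## drop subjects with < 2 visits carrying any observation
  keep <- rep(TRUE, ncol(m))
  for (s in unique(cd$subject)) {
    cols <- which(cd$subject == s)
    nVisits <- sum(colSums(!is.na(m[, cols, drop = FALSE])) > 0)
    if (nVisits < 2) {
      keep[cols] <- FALSE
      warning("subject '", s, "' dropped: fewer than 2 observed visits",
              call. = FALSE)
      x <- .appendLog(x, paste0("impute: subject '", s, "' dropped (<2 visits)"))
    }
  }
  if (!all(keep)) {
    x <- x[, keep]
    m <- SummarizedExperiment::assay(x, "value")
    cd <- SummarizedExperiment::colData(x)
  }
  imputed <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  for (s in unique(cd$subject)) {
    cols <- which(cd$subject == s)
    ts <- cd$time_h[cols]
    ord <- order(ts)
    for (i in seq_len(nrow(m))) {
      v <- m[i, cols]
      obs <- !is.na(v)
      if (all(obs) || sum(obs) == 0) next
      if (sum(obs) == 1) {
        fill <- v[obs]
      } else {
        fill <- approx(ts[obs], v[obs], xout = ts, rule = 2)$y
      }
      imputed[i, cols][!obs] <- TRUE
      v[!obs] <- if (length(fill) == 1) fill else fill[!obs]
      m[i, cols] <- v
    }
  }
  SummarizedExperiment::assay(x, "value") <- m
  SummarizedExperiment::assays(x)$imputed <- imputed
  S4Vectors::metadata(x)$imputedFlag <- TRUE
  nImp <- sum(imputed)
  .appendLog(x, sprintf("impute: %d cells filled by linear-in-time interpolation",
                        nImp))
})

#' Stack one analyte's observations in one group
#'
#' Collects all observed (non-`NA`) values of one analyte across the
#' subjects of one group into an \linkS4class{AnalyteSeries}, canonically
#' ordered by subject then time, so that any input ordering yields an
#' identical series.
#'
#' @param x a \linkS4class{RhythmExperiment}.
#' @param analyte analyte name.
#' @param group group label.
#' @param ... unused.
#' @return An \linkS4class{AnalyteSeries}.
#' @export
setMethod("stackSeries", "RhythmExperiment", function(x, analyte, group, ...) {
  if (!analyte %in% rownames(x)) stop("analyte '", analyte, "' not found")
  cd <- SummarizedExperiment::colData(x)
  cols <- which(as.character(cd$group) == group)
  if (length(cols) == 0) stop("group '", group, "' not found")
  v <- SummarizedExperiment::assay(x, "value")[analyte, cols]
  subj <- cd$subject[cols]
  t <- cd$time_h[cols]
  obs <- !is.na(v)
  if (sum(obs) == 0)
    stop("no observed values for analyte '", analyte, "' in group '",
         group, "'")
  subj <- subj[obs]; t <- t[obs]; v <- v[obs]
  ord <- order(subj, t)
  subj <- subj[ord]; t <- t[ord]; v <- as.numeric(v[ord])
  lev <- unique(subj)
  methods::new("AnalyteSeries", analyte = analyte, group = group,
               t = t, y = v, subjectIdx = match(subj, lev),
               nSubjects = length(lev), subjectLevels = lev)
})
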
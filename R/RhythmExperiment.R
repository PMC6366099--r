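#' Build a RhythmExperiment from a tidy long table
#'
#' @param table data.frame with columns `subject`, `group`, `time_h`,
#'   `analyte`, `value` (`NA` for missing cells). `time_h` must already be
#'   unwrapped hours in `[0, 48)`.
#' @param truth optional ground-truth data.frame (from the simulator),
#'   stored as metadata only.
#' @param groupLevels optional explicit ordering of the group factor
#'   (control group first); defaults to order of first appearance.
#' @return A \linkS4class{RhythmExperiment}.
#' @export
RhythmExperiment <- function(table, truth = NULL, groupLevels = NULL) {
  need <- c("subject", "group", "time_h", "analyte", "value")
  miss <- setdiff(need, colnames(table))
  if (length(miss) > 0)
    stop("long table is missing column(s): ", paste(miss, collapse = ", "))
  table$subject <- as.character(table$subject)
  table$analyte <- as.character(table$analyte)
  key <- paste(table$subject, table$time_h, table$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf(
      "duplicate (subject, time_h, analyte) key at row %d: (%s, %s, %s)",
      i, table$subject[i], format(table$time_h[i]), table$analyte[i]))
  }
  if (is.null(groupLevels))
    groupLevels <- unique(as.character(table$group))
  ana <- unique(table$analyte)
  samp <- unique(table[, c("subject", "group", "time_h")])
  samp <- samp[order(match(as.character(samp$group), groupLevels),
                     samp$subject, samp$time_h), , drop = FALSE]
  sid <- paste(samp$subject, samp$time_h, sep = "@")
  m <- matrix(NA_real_, nrow = length(ana), ncol = nrow(samp),
              dimnames = list(ana, sid))
  ri <- match(table$analyte, ana)
  ci <- match(paste(table$subject, table$time_h, sep = "@"), sid)
  m[cbind(ri, ci)] <- table$value
  cd <- S4Vectors::DataFrame(
    subject = samp$subject,
    group = factor(as.character(samp$group), levels = groupLevels),
    time_h = samp$time_h,
    row.names = sid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(value = m), colData = cd)
  out <- methods::new("RhythmExperiment", se)
  S4Vectors::metadata(out)$truth <- truth
  S4Vectors::metadata(out)$log <- character(0)
  S4Vectors::metadata(out)$excluded <-
    data.frame(subject = character(0), analyte = character(0),
               reason = character(0))
  S4Vectors::metadata(out)$normalized <- FALSE
  S4Vectors::metadata(out)$imputedFlag <- FALSE
  methods::validObject(out)
  out
}

.appendLog <- function(x, msg) {
  S4Vectors::metadata(x)$log <- c(S4Vectors::metadata(x)$log, msg)
  x
}

#' Tidy long-format view of a RhythmExperiment
#'
#' @param x a RhythmExperiment.
#' @param dropMissing drop rows whose value is `NA`.
#' @return data.frame with columns subject, group, time_h, analyte, value.
#' @export
setMethod("longTable", "RhythmExperiment", function(x, dropMissing = FALSE) {
  cd <- SummarizedExperiment::colData(x)
  m <- SummarizedExperiment::assay(x, "value")
  out <- data.frame(
    subject = rep(cd$subject, each = nrow(m)),
    group = rep(as.character(cd$group), each = nrow(m)),
    time_h = rep(cd$time_h, each = nrow(m)),
    analyte = rep(rownames(m), times = ncol(m)),
    value = as.vector(m),
    stringsAsFactors = FALSE)
  out <- out[order(out$group, out$subject, out$time_h, out$analyte), ,
             drop = FALSE]
  rownames(out) <- NULL
  if (dropMissing) out <- out[!is.na(out$value), , drop = FALSE]
  out
})

#' @rdname groundTruth
#' @param x a RhythmExperiment.
#' @export
setMethod("groundTruth", "RhythmExperiment", function(x)
  S4Vectors::metadata(x)$truth)

#' @rdname runLog
#' @param x a RhythmExperiment.
#' @export
setMethod("runLog", "RhythmExperiment", function(x)
  S4Vectors::metadata(x)$log)

#' @rdname excludedStrata
#' @param x a RhythmExperiment.
#' @export
setMethod("excludedStrata", "RhythmExperiment", function(x)
  S4Vectors::metadata(x)$excluded)

#' @rdname analytes
#' @param x a RhythmExperiment.
#' @export
setMethod("analytes", "RhythmExperiment", function(x) rownames(x))

#' @rdname subjects
#' @param x a RhythmExperiment.
#' @export
setMethod("subjects", "RhythmExperiment", function(x)
  unique(SummarizedExperiment::colData(x)$subject))

setMethod("show", "RhythmExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("RhythmExperiment:", nrow(object), "analytes,",
      length(unique(cd$subject)), "subjects,",
      length(unique(cd$time_h)), "timepoints\n")
  tab <- table(cd$group[!duplicated(cd$subject)])
  cat("  groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
  cat("  normalized:", S4Vectors::metadata(object)$normalized,
      "| imputed:", S4Vectors::metadata(object)$imputedFlag,
      "| missing cells:",
      sum(is.na(SummarizedExperiment::assay(object, "value"))), "\n")
  if (!is.null(S4Vectors::metadata(object)$truth))
    cat("  simulation ground truth attached (metadata)\n")
})

setMethod("show", "KernelParams", function(object) {
  cat(sprintf(paste0(
    "KernelParams: shared periodic s2=%.4g ell=%.4g T=%g h | ",
    "subject Matern32 s2=%.4g ell=%.4g h | noise s2=%.4g\n"),
    object@sigma2p, object@ellp, object@period,
    object@sigma2m, object@ellm, object@sigma2n))
})

setMethod("show", "AnalyteSeries", function(object) {
  cat(sprintf("AnalyteSeries '%s' [%s]: %d observations from %d subjects\n",
              object@analyte, object@group, length(object@y),
              object@nSubjects))
})

setMethod("show", "GPFit", function(object) {
  cat(sprintf("GPFit (%s): log marginal likelihood %.4f, converged %s (%d starts)\n",
              object@kind, object@logLik, object@converged, object@nRestarts))
  methods::show(object@params)
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig: %d subjects/group x %d times, %d analytes\n",
    "  groups %s/%s, rhythmic fractions %.2f/%.2f, mode '%s'\n",
    "  amplitude %.2f, subject dev sd %.2f (ell %.1f h), noise sd %.2f, ",
    "missing %.3f, seed %d\n"),
    object@nSubjectsPerGroup, length(object@sampleTimes), object@nAnalytes,
    object@groupLabels[1], object@groupLabels[2],
    object@fractionRhythmic[1], object@fractionRhythmic[2],
    object@signalMode, object@amplitude, object@subjectDevSd,
    object@subjectDevLengthscale, object@noiseSd, object@missingRate,
    object@seed))
})
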
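.defaultDialect <- function() {
  list(subject = "subject", group = "group", time = "time_h",
       analyte = "analyte", value = "value", sep = ",")
}

#' Read a tidy long-format measurement table
#'
#' Expects columns for subject, group, clock time, analyte and value
#' (names configurable through a dialect list or YAML file). Clock times
#' may be decimal hours or `"HH:MM"` strings; within each subject, times
#' are taken in file order and unwrapped across midnight, so a time that
#' steps backwards (e.g. `"00:00"` following `"18:00"`) is shifted into
#' the second day (`[24, 48)`).
#'
#' @param path CSV/TSV file path.
#' @param dialect named list overriding column names and `sep`, or the
#'   path of a YAML file holding such a list.
#' @param groupLevels optional explicit group ordering (control first).
#' @return A \linkS4class{RhythmExperiment}.
#' @export
readLongTable <- function(path, dialect = NULL, groupLevels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dd <- .defaultDialect()
  if (is.character(dialect) && length(dialect) == 1)
    dialect <- yaml::read_yaml(dialect)
  dd[names(dialect)] <- dialect
  raw <- read.csv(path, sep = dd$sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  need <- c(dd$subject, dd$group, dd$time, dd$analyte, dd$value)
  miss <- setdiff(need, colnames(raw))
  if (length(miss) > 0)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  tab <- data.frame(subject = as.character(raw[[dd$subject]]),
                    group = as.character(raw[[dd$group]]),
                    time_raw = raw[[dd$time]],
                    analyte = as.character(raw[[dd$analyte]]),
                    value = suppressWarnings(as.numeric(raw[[dd$value]])),
                    stringsAsFactors = FALSE)
  tab$time_h <- .parseClockTimes(tab$time_raw)
  ## unwrap across midnight, per subject, in file order
  for (s in unique(tab$subject)) {
    idx <- which(tab$subject == s)
    tt <- tab$time_h[idx]
    ut <- tt[!duplicated(tt)]
    if (length(ut) > 1) {
      off <- cumsum(c(0, diff(ut) < 0)) * 24
      if (any(off > 24)) stop("times of subject '", s,
                              "' wrap more than one midnight")
      tab$time_h[idx] <- tt + off[match(tt, ut)]
    }
  }
  tab$time_raw <- NULL
  RhythmExperiment(tab, groupLevels = groupLevels)
}

.parseClockTimes <- function(x) {
  if (is.numeric(x)) {
    if (any(!is.finite(x))) stop("non-finite time at row ",
                                 which(!is.finite(x))[1])
    return(as.numeric(x))
  }
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  hm <- grepl("^\\s*\\d{1,2}:\\d{2}\\s*$", x)
  if (any(hm)) {
    parts <- strsplit(trimws(x[hm]), ":", fixed = TRUE)
    out[hm] <- vapply(parts, function(p)
      as.numeric(p[1]) + as.numeric(p[2]) / 60, numeric(1))
  }
  bad <- which(is.na(out))
  if (length(bad) > 0)
    stop("unparseable time '", x[bad[1]], "' at row ", bad[1])
  out
}

#' Write a RhythmExperiment as a tidy CSV
#'
#' Columns `subject, group, time_h, analyte, value`; numeric values are
#' written with 17 significant digits so that a write/read round trip is
#' bit-identical for finite values. Missing cells are written as `NA`.
#'
#' @param x a \linkS4class{RhythmExperiment}.
#' @param path output file.
#' @export
writeLongTable <- function(x, path) {
  tab <- longTable(x)
  tab$time_h <- sprintf("%.17g", tab$time_h)
  tab$value <- ifelse(is.na(tab$value), "NA", sprintf("%.17g", tab$value))
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulated dataset to plain-text files
#'
#' Writes `data.csv` (tidy long table), `truth.csv` (per-analyte,
#' per-group ground truth) and `config.yaml` into a directory.
#'
#' @param x a simulated \linkS4class{RhythmExperiment}.
#' @param dir output directory (created if needed).
#' @param config the \linkS4class{SimulationConfig} used, or `NULL`.
#' @return `dir`, invisibly.
#' @export
exportDataset <- function(x, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLongTable(x, file.path(dir, "data.csv"))
  tr <- groundTruth(x)
  if (!is.null(tr))
    write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(config))
    yaml::write_yaml(.configAsList(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

.configAsList <- function(config) {
  list(nSubjectsPerGroup = config@nSubjectsPerGroup,
       sampleTimes = config@sampleTimes,
       nAnalytes = config@nAnalytes,
       fractionRhythmic = as.list(setNames(config@fractionRhythmic,
                                           config@groupLabels)),
       amplitude = config@amplitude,
       acrophases = if (length(config@acrophases) == 0) "random"
                    else config@acrophases,
       signalMode = config@signalMode,
       subjectDevSd = config@subjectDevSd,
       subjectDevLengthscale = config@subjectDevLengthscale,
       noiseSd = config@noiseSd,
       missingRate = config@missingRate,
       groupLabels = config@groupLabels,
       seed = config@seed)
}
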
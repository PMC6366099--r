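#' Stack one analyte's observations in one group
#'
#' @param x a data container (see the method for
#'   \linkS4class{RhythmExperiment}).
#' @param analyte analyte name.
#' @param group group label.
#' @param ... passed to methods.
#' @export
setGeneric("stackSeries", function(x, analyte, group, ...)
  standardGeneric("stackSeries"))

#' Deterministically impute missing cells
#'
#' @param x a data container.
#' @param ... passed to methods.
#' @export
setGeneric("imputeMissing", function(x, ...) standardGeneric("imputeMissing"))

#' Tidy long-format view of a dataset
#'
#' @param x a data container.
#' @param ... passed to methods.
#' @export
setGeneric("longTable", function(x, ...) standardGeneric("longTable"))

#' Simulation ground truth attached to a dataset
#'
#' @param x a data container.
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' Run log of preprocessing actions
#'
#' @param x a data container.
#' @export
setGeneric("runLog", function(x) standardGeneric("runLog"))

#' Strata excluded from rhythm analysis
#'
#' @param x a data container.
#' @export
setGeneric("excludedStrata", function(x) standardGeneric("excludedStrata"))

#' Analyte names of a dataset
#'
#' @param x a data container.
#' @export
setGeneric("analytes", function(x) standardGeneric("analytes"))

#' Subject identifiers of a dataset
#'
#' @param x a data container.
#' @export
setGeneric("subjects", function(x) standardGeneric("subjects"))
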
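#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats approx cor cor.test optim pchisq p.adjust rnorm runif
#'   sd setNames
#' @importFrom utils read.csv write.csv head
NULL

#' RhythmExperiment: multi-subject lipid time-series container
#'
#' Extends \linkS4class{SummarizedExperiment}. Rows are analytes (lipid
#' species), columns are samples (one subject at one clock time). `colData`
#' carries `subject`, `group` and `time_h` (hours since midnight of the
#' admission day; second-day times are unwrapped into `[24, 48)` so that
#' periodicity is handled by the model, never by folding the data). The
#' `"value"` assay holds (possibly normalized) concentrations with `NA` for
#' missing cells.
#'
#' Metadata slots used by the pipeline: `truth` (simulation ground truth,
#' kept out of the assay so analysis code cannot peek), `excluded`
#' (constant strata removed from rhythm analysis), `imputed` (cells filled
#' by the deterministic imputer), `log` (run log lines), and the
#' `normalized` / `imputedFlag` stage markers.
#'
#' @export
setClass("RhythmExperiment", contains = "SummarizedExperiment")

setValidity("RhythmExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("subject", "group", "time_h")
  miss <- setdiff(need, colnames(cd))
  if (length(miss) > 0)
    return(paste0("colData is missing column(s): ", paste(miss, collapse = ", ")))
  if (!"value" %in% SummarizedExperiment::assayNames(object))
    return("assay 'value' is required")
  t <- cd$time_h
  if (!is.numeric(t) || any(!is.finite(t)))
    return("time_h must be finite numeric hours")
  if (any(t < 0 | t >= 48))
    return("time_h must lie in [0, 48) after unwrapping")
  key <- paste(cd$subject, t, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (subject, time_h) sample")
  g <- tapply(as.character(cd$group), as.character(cd$subject),
              function(x) length(unique(x)))
  if (any(g > 1))
    return("each subject must belong to exactly one group")
  TRUE
})

#' Simulation configuration for the synthetic lipidome generator
#'
#' Holds the study-design parameters the generator emulates: two groups of
#' subjects sampled at a handful of clock times across one day, a panel of
#' lipid analytes of which a per-group fraction carries a shared 24 h
#' rhythmic component, subject-specific smooth deviations (Matern 3/2),
#' i.i.d. Gaussian noise, and sporadic missingness.
#'
#' @slot nSubjectsPerGroup subjects per group.
#' @slot sampleTimes clock times in hours, strictly increasing, in `[0, 48)`
#'   (times past midnight unwrapped by +24).
#' @slot nAnalytes number of analytes in the panel.
#' @slot fractionRhythmic length-2 proportion of rhythmic analytes per group
#'   (control group first).
#' @slot amplitude SD of the shared rhythmic component on the normalized
#'   scale (the cosinor curve is `amplitude * sqrt(2) * cos(...)` so its SD
#'   over a cycle equals `amplitude`).
#' @slot acrophases per-analyte peak hour in `[0, 24)`, recycled; length 0
#'   means "random" (uniform per analyte and group).
#' @slot signalMode `"cosinor"` (deterministic cosine; known truth for
#'   recovery tests) or `"gp"` (draw the shared curve from the periodic GP,
#'   faithful to the analysis model).
#' @slot subjectDevSd,subjectDevLengthscale SD (normalized units) and
#'   lengthscale (hours) of the subject-level Matern 3/2 deviations.
#' @slot noiseSd SD of the observation noise, > 0.
#' @slot missingRate probability a cell is flagged missing, in `[0, 1)`.
#' @slot groupLabels two group names, control first.
#' @slot seed integer master seed; per-analyte substreams are derived
#'   deterministically from (seed, analyte index).
#' @export
setClass("SimulationConfig", representation(
  nSubjectsPerGroup = "integer",
  sampleTimes = "numeric",
  nAnalytes = "integer",
  fractionRhythmic = "numeric",
  amplitude = "numeric",
  acrophases = "numeric",
  signalMode = "character",
  subjectDevSd = "numeric",
  subjectDevLengthscale = "numeric",
  noiseSd = "numeric",
  missingRate = "numeric",
  groupLabels = "character",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  chk <- function(cond, msg) if (!cond) msg else NULL
  errs <- c(
    chk(length(object@nSubjectsPerGroup) == 1 && object@nSubjectsPerGroup >= 1,
        "nSubjectsPerGroup: must be a positive integer"),
    chk(length(object@sampleTimes) >= 2, "sampleTimes: need at least 2 times"),
    chk(all(is.finite(object@sampleTimes)) &&
          all(object@sampleTimes >= 0 & object@sampleTimes < 48),
        "sampleTimes: must lie in [0, 48) after unwrapping"),
    chk(all(diff(object@sampleTimes) > 0),
        "sampleTimes: must be strictly increasing"),
    chk(length(object@nAnalytes) == 1 && object@nAnalytes >= 1,
        "nAnalytes: must be a positive integer"),
    chk(length(object@fractionRhythmic) == 2 &&
          all(object@fractionRhythmic >= 0 & object@fractionRhythmic <= 1),
        "fractionRhythmic: two proportions in [0, 1]"),
    chk(length(object@amplitude) == 1 && object@amplitude >= 0,
        "amplitude: must be >= 0"),
    chk(length(object@acrophases) == 0 ||
          all(object@acrophases >= 0 & object@acrophases < 24),
        "acrophases: peak hours must lie in [0, 24)"),
    chk(object@signalMode %in% c("cosinor", "gp"),
        "signalMode: must be 'cosinor' or 'gp'"),
    chk(object@subjectDevSd >= 0, "subjectDevSd: must be >= 0"),
    chk(object@subjectDevLengthscale > 0,
        "subjectDevLengthscale: must be > 0 hours"),
    chk(object@noiseSd > 0, "noiseSd: must be > 0"),
    chk(object@missingRate >= 0 && object@missingRate < 1,
        "missingRate: must lie in [0, 1)"),
    chk(length(object@groupLabels) == 2 &&
          !anyDuplicated(object@groupLabels),
        "groupLabels: two distinct labels required"),
    chk(length(object@seed) == 1 && !is.na(object@seed),
        "seed: must be a single integer")
  )
  if (length(errs) > 0) errs else TRUE
})

#' Hyperparameters of the hierarchical Gaussian-process model
#'
#' The model for one analyte in one group is
#' `y_si(t) = g(t) + f_s(t) + e`, with `g` a shared periodic GP
#' (exp-sine-squared kernel, variance `sigma2p`, warp lengthscale `ellp`,
#' period `period` = 24 h), `f_s` a per-subject Matern 3/2 GP (variance
#' `sigma2m`, lengthscale `ellm` hours) and `e` i.i.d. Gaussian noise
#' (variance `sigma2n`). All variances are on the normalized
#' (unit-variance) concentration scale. The period is fixed, not estimated:
#' five samples per subject cannot identify a period, and the hypothesis
#' under test is 24 h rhythmicity specifically.
#'
#' @export
setClass("KernelParams", representation(
  sigma2p = "numeric", ellp = "numeric", period = "numeric",
  sigma2m = "numeric", ellm = "numeric", sigma2n = "numeric"
))

setValidity("KernelParams", function(object) {
  one <- function(x) length(x) == 1 && is.finite(x)
  chk <- function(cond, msg) if (!cond) msg else NULL
  errs <- c(
    chk(one(object@sigma2p) && object@sigma2p >= 0, "sigma2p: must be >= 0"),
    chk(one(object@ellp) && object@ellp > 0, "ellp: must be > 0"),
    chk(one(object@period) && object@period > 0, "period: must be > 0 hours"),
    chk(one(object@sigma2m) && object@sigma2m >= 0, "sigma2m: must be >= 0"),
    chk(one(object@ellm) && object@ellm > 0, "ellm: must be > 0 hours"),
    chk(one(object@sigma2n) && object@sigma2n > 0, "sigma2n: must be > 0")
  )
  if (length(errs) > 0) errs else TRUE
})

#' Stacked observations of one analyte in one group
#'
#' All observed values of one analyte across the subjects of one group,
#' stacked into aligned vectors: times `t` (hours), normalized values `y`,
#' and 1-based `subjectIdx` into `subjectLevels`. This is the joint
#' observation vector over which the hierarchical covariance is assembled.
#'
#' @export
setClass("AnalyteSeries", representation(
  analyte = "character", group = "character",
  t = "numeric", y = "numeric", subjectIdx = "integer",
  nSubjects = "integer", subjectLevels = "character"
))

setValidity("AnalyteSeries", function(object) {
  n <- length(object@t)
  chk <- function(cond, msg) if (!cond) msg else NULL
  errs <- c(
    chk(length(object@y) == n && length(object@subjectIdx) == n,
        "t, y and subjectIdx must have equal length"),
    chk(n == 0 || all(object@subjectIdx >= 1 &
                        object@subjectIdx <= object@nSubjects),
        "subjectIdx out of range"),
    chk(all(is.finite(object@t)) && all(is.finite(object@y)),
        "t and y must be finite"),
    chk(length(object@subjectLevels) == object@nSubjects,
        "subjectLevels must have nSubjects entries")
  )
  if (length(errs) > 0) errs else TRUE
})

#' Maximum-likelihood fit of one model for one analyte series
#'
#' `kind` is `"rhythmic"` (shared periodic component included; free
#' hyperparameters sigma2p, ellp, sigma2m, ellm, sigma2n) or `"null"`
#' (sigma2p fixed at 0, ellp not a free parameter). `logLik` is the
#' maximized log marginal likelihood; `trace` records every restart's
#' converged objective so optimizer behaviour is auditable.
#'
#' @export
setClass("GPFit", representation(
  params = "KernelParams",
  logLik = "numeric",
  kind = "character",
  converged = "logical",
  nRestarts = "integer",
  trace = "data.frame"
))

setValidity("GPFit", function(object) {
  if (!object@kind %in% c("rhythmic", "null"))
    return("kind must be 'rhythmic' or 'null'")
  if (object@converged && !is.finite(object@logLik))
    return("logLik must be finite when converged")
  TRUE
})
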
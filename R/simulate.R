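#' Simulation configuration constructor
#'
#' Defaults emulate the clinical study design: two groups (healthy
#' controls and RA patients) of 10 subjects each, serum sampled 5 times at
#' 6-hour intervals starting at 18:00 (so times 18, 24, 30, 36, 42 h after
#' unwrapping across midnight), a panel of 116 lipid analytes spanning
#' ceramide, eicosanoid and endocannabinoid classes, and sporadic
#' missingness at the "one broken vial" level.
#'
#' @param nSubjectsPerGroup subjects per group.
#' @param sampleTimes explicit clock times in hours (unwrapped, strictly
#'   increasing, in `[0, 48)`); or `NULL` to build
#'   `sampleStart + sampleInterval * (0:(nSamples-1))`.
#' @param sampleStart,sampleInterval,nSamples schedule triple used when
#'   `sampleTimes` is `NULL`.
#' @param nAnalytes panel size.
#' @param fractionRhythmic length-2 proportions of rhythmic analytes
#'   (control group first). The defaults reflect a disease-driven gain of
#'   rhythmicity: a modest rhythmic fraction in controls, a larger one in
#'   the disease group.
#' @param amplitude SD of the shared rhythmic component (normalized
#'   units).
#' @param acrophases `"random"`, or per-analyte peak hours in `[0, 24)`
#'   (recycled across analytes; shared between groups).
#' @param signalMode `"cosinor"` (deterministic
#'   `amplitude * sqrt(2) * cos(2 pi (t - acrophase) / 24)`, exact known
#'   truth) or `"gp"` (shared curve drawn from the periodic GP with
#'   variance `amplitude^2`, faithful to the analysis model but with
#'   random phase).
#' @param subjectDevSd,subjectDevLengthscale Matern 3/2 subject-deviation
#'   SD and lengthscale (hours).
#' @param noiseSd observation-noise SD.
#' @param missingRate probability each cell is missing.
#' @param groupLabels two labels, control first.
#' @param seed master integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @export
SimulationConfig <- function(nSubjectsPerGroup = 10, sampleTimes = NULL,
                             sampleStart = 18, sampleInterval = 6,
                             nSamples = 5, nAnalytes = 116,
                             fractionRhythmic = c(0.10, 0.30),
                             amplitude = 1, acrophases = "random",
                             signalMode = c("cosinor", "gp"),
                             subjectDevSd = 0.5,
                             subjectDevLengthscale = 6, noiseSd = 1,
                             missingRate = 0.01,
                             groupLabels = c("healthy", "RA"), seed = 1) {
  signalMode <- match.arg(signalMode)
  if (is.null(sampleTimes))
    sampleTimes <- sampleStart + sampleInterval * (0:(nSamples - 1))
  acro <- if (identical(acrophases, "random")) numeric(0)
          else as.numeric(acrophases)
  methods::new("SimulationConfig",
               nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
               sampleTimes = as.numeric(sampleTimes),
               nAnalytes = as.integer(nAnalytes),
               fractionRhythmic = as.numeric(fractionRhythmic),
               amplitude = as.numeric(amplitude), acrophases = acro,
               signalMode = signalMode,
               subjectDevSd = as.numeric(subjectDevSd),
               subjectDevLengthscale = as.numeric(subjectDevLengthscale),
               noiseSd = as.numeric(noiseSd),
               missingRate = as.numeric(missingRate),
               groupLabels = as.character(groupLabels),
               seed = as.integer(seed))
}

## deterministic analyte panel: ceramide-majority, plus eicosanoid and
## endocannabinoid names, mirroring a targeted serum lipidomics panel
.makeAnalyteNames <- function(n) {
  faClass <- c("N", "A")
  base <- c("DS", "S")
  faC <- c(16, 18, 20, 22, 24, 25, 26, 29)
  baseC <- c(16, 18, 20)
  cer <- character(0)
  for (fc in faClass) for (b in base) for (a in faC) for (bc in baseC)
    cer <- c(cer, sprintf("CER[%s(%d)%s(%d)]", fc, a, b, bc))
  eico <- c("9-HODE", "13-HODE", "9-HOTrE", "13-HOTrE", "12(13)-EpOME",
            "9(10)-EpOME", "5-HETE", "12-HETE", "15-HETE", "20-HETE",
            "PGE2", "PGD2", "PGF2a", "6-keto-PGF1a", "TXB2", "LTB4",
            "LXA4", "14-HDHA", "17-HDHA", "18-HEPE", "EKODE", "9-oxoODE",
            "13-oxoODE", "15-deoxy-PGJ2")
  endo <- c("AEA", "2-AG", "PEA", "OEA", "LEA", "SEA", "DHEA", "2-LG")
  nCer <- min(length(cer), ceiling(n * 0.72))
  rest <- n - nCer
  nEico <- min(length(eico), ceiling(rest * 0.75))
  nEndo <- rest - nEico
  pool <- c(cer[seq_len(nCer)], eico[seq_len(nEico)])
  if (nEndo > 0) {
    extra <- rep(endo, length.out = nEndo)
    dup <- duplicated(extra)
    extra[dup] <- paste0(extra[dup], "_", cumsum(dup)[dup] + 1)
    pool <- c(pool, extra)
  }
  if (length(pool) < n)
    pool <- c(pool, sprintf("lipid_%03d", seq_len(n - length(pool))))
  pool[seq_len(n)]
}

## one draw of a zero-mean GP at times t with covariance K (+ jitter)
.drawGP <- function(t, K) {
  L <- .jitterChol(K)$L
  as.vector(t(L) %*% rnorm(length(t)))
}

## internal: draw the shared periodic-GP curve (exposed for model-
## faithfulness tests of the generator)
.drawPeriodicGP <- function(t, sigma2, ell = 1, period = 24) {
  .drawGP(t, .kPeriodic(outer(t, t, "-"), sigma2, ell, period))
}

## substream seed for analyte j, derived deterministically from the
## master seed so per-analyte streams are reproducible independent of
## evaluation order; kept inside 32-bit integer range
.substreamSeed <- function(seed, j) {
  as.integer((as.numeric(seed) * 100003 + j * 7919) %% 2147483647)
}

#' Simulate a two-group lipidomics time-series dataset
#'
#' Samples from the generative counterpart of the hierarchical GP model:
#' per rhythmic analyte and group a shared 24 h component (deterministic
#' cosine or a periodic-GP draw, per `signalMode`), plus an independent
#' Matern 3/2 deviation per subject, plus i.i.d. Gaussian noise; a
#' `missingRate` fraction of cells is flagged missing (`NA`). Ground
#' truth (rhythmic flag, acrophase, amplitude per analyte and group) is
#' attached as metadata only, never as data columns.
#'
#' Regenerating with the same seed is bit-identical; per-analyte
#' substreams are derived deterministically from (seed, analyte index).
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{RhythmExperiment} with `groundTruth()` attached.
#' @export
simulateLipidome <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  methods::validObject(config)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  nS <- config@nSubjectsPerGroup
  times <- config@sampleTimes
  nT <- length(times)
  nA <- config@nAnalytes
  groups <- config@groupLabels
  ana <- .makeAnalyteNames(nA)
  subj <- lapply(seq_along(groups), function(g)
    sprintf("%s_%02d", groups[g], seq_len(nS)))

  ## design-level draws (rhythmic sets, acrophases) from the master seed
  set.seed(config@seed)
  rhythmicSet <- lapply(seq_along(groups), function(g) {
    k <- round(config@fractionRhythmic[g] * nA)
    sort(sample.int(nA, k))
  })
  acro <- if (length(config@acrophases) > 0)
    rep_len(config@acrophases, nA)
  else round(runif(nA, 0, 24), 1) %% 24

  Kmat <- .kMatern32(abs(outer(times, times, "-")),
                     config@subjectDevSd^2, config@subjectDevLengthscale)
  value <- matrix(NA_real_, nA, nS * nT * length(groups))
  truth <- vector("list", length(groups))

  colSubject <- unlist(lapply(seq_along(groups), function(g)
    rep(subj[[g]], each = nT)))
  colGroup <- rep(groups, each = nS * nT)
  colTime <- rep(times, nS * length(groups))

  for (j in seq_len(nA)) {
    set.seed(.substreamSeed(config@seed, j))
    row <- numeric(0)
    for (g in seq_along(groups)) {
      isRhythmic <- j %in% rhythmicSet[[g]]
      shared <- numeric(nT)
      if (isRhythmic && config@amplitude > 0) {
        shared <- if (config@signalMode == "cosinor")
          config@amplitude * sqrt(2) *
            cos(2 * pi * (times - acro[j]) / 24)
        else
          .drawPeriodicGP(times, config@amplitude^2)
      }
      for (s in seq_len(nS)) {
        dev <- if (config@subjectDevSd > 0) .drawGP(times, Kmat)
               else numeric(nT)
        eps <- rnorm(nT, 0, config@noiseSd)
        row <- c(row, shared + dev + eps)
      }
    }
    if (config@missingRate > 0) {
      mis <- runif(length(row)) < config@missingRate
      row[mis] <- NA_real_
    }
    value[j, ] <- row
  }

  truth <- do.call(rbind, lapply(seq_along(groups), function(g)
    data.frame(analyte = ana, group = groups[g],
               rhythmic = seq_len(nA) %in% rhythmicSet[[g]],
               acrophase = ifelse(seq_len(nA) %in% rhythmicSet[[g]],
                                  acro, NA_real_),
               amplitude = ifelse(seq_len(nA) %in% rhythmicSet[[g]],
                                  config@amplitude, 0),
               stringsAsFactors = FALSE)))

  tab <- data.frame(subject = rep(colSubject, each = nA),
                    group = rep(colGroup, each = nA),
                    time_h = rep(colTime, each = nA),
                    analyte = rep(ana, times = length(colSubject)),
                    value = as.vector(value),
                    stringsAsFactors = FALSE)
  RhythmExperiment(tab, truth = truth, groupLevels = groups)
}

#' Simulate a dataset with no rhythmic component
#'
#' As [simulateLipidome()] with both rhythmic fractions forced to zero;
#' subject deviations and noise are retained. Used for size calibration
#' of the rhythmicity test.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{RhythmExperiment}.
#' @export
makeNullDataset <- function(config) {
  stopifnot(methods::is(config, "SimulationConfig"))
  config@fractionRhythmic <- c(0, 0)
  simulateLipidome(config)
}
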
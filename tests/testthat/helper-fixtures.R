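# fixtures are built in code; nothing is read from disk

makeSeries <- function(t, y, subjectIdx, analyte = "test", group = "g") {
  lev <- paste0("s", seq_len(max(subjectIdx)))
  methods::new("AnalyteSeries", analyte = analyte, group = group,
               t = as.numeric(t), y = as.numeric(y),
               subjectIdx = as.integer(subjectIdx),
               nSubjects = as.integer(max(subjectIdx)), subjectLevels = lev)
}

randomSeries <- function(n, nSubjects = 4, seed = 1) {
  set.seed(seed)
  makeSeries(t = runif(n, 0, 48), y = rnorm(n),
             subjectIdx = sample.int(nSubjects, n, replace = TRUE))
}

randomParams <- function(seed = 1) {
  set.seed(seed)
  KernelParams(sigma2p = runif(1, 0.01, 2), ellp = runif(1, 0.2, 3),
               sigma2m = runif(1, 0.01, 2), ellm = runif(1, 0.5, 30),
               sigma2n = runif(1, 0.05, 2))
}

manualFit <- function(params, logLik = 0, kind = "rhythmic") {
  methods::new("GPFit", params = params, logLik = logLik, kind = kind,
               converged = TRUE, nRestarts = 1L,
               trace = data.frame(start = 1L, objective = -logLik,
                                  convergence = 0L))
}

toyLongTable <- function() {
  expand.grid(subject = c("a1", "a2", "b1", "b2"),
              time_h = c(0, 6, 12, 18, 24),
              analyte = c("L1", "L2"),
              stringsAsFactors = FALSE) |>
    transform(group = ifelse(startsWith(subject, "a"), "ctrl", "dis"),
              value = seq_len(40) / 7)
}

smallSim <- function(..., seed = 1) {
  simulateLipidome(SimulationConfig(..., seed = seed))
}
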
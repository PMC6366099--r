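test_that("simulated datasets have the study-design dimensions", {
  x <- smallSim(nAnalytes = 3, seed = 5)
  tab <- longTable(x)
  # 10 subjects x 5 samples -> 50 rows per analyte per group
  one <- tab[tab$analyte == analytes(x)[1] & tab$group == "healthy", ]
  expect_equal(nrow(one), 50)
  expect_equal(nrow(tab), 2 * 10 * 5 * 3)
  # default schedule: 18:00 then 6-hourly, unwrapped across midnight
  expect_equal(sort(unique(tab$time_h)), c(18, 24, 30, 36, 42))
})

test_that("the generator is bit-identical under a fixed seed", {
  a <- smallSim(nAnalytes = 4, seed = 42)
  b <- smallSim(nAnalytes = 4, seed = 42)
  expect_identical(longTable(a), longTable(b))
  expect_identical(groundTruth(a), groundTruth(b))
  c <- smallSim(nAnalytes = 4, seed = 43)
  expect_false(identical(longTable(a)$value, longTable(c)$value))
})

test_that("ground truth lives in metadata, not in the data columns", {
  x <- smallSim(nAnalytes = 2, seed = 1)
  expect_identical(colnames(longTable(x)),
                   c("subject", "group", "time_h", "analyte", "value"))
  tr <- groundTruth(x)
  expect_true(all(c("analyte", "group", "rhythmic", "acrophase",
                    "amplitude") %in% colnames(tr)))
})

test_that("a degenerate config yields pure i.i.d. Gaussian noise", {
  cfg <- SimulationConfig(nAnalytes = 60, amplitude = 0, subjectDevSd = 0,
                          noiseSd = 1.5, missingRate = 0, seed = 8)
  x <- simulateLipidome(cfg)
  v <- longTable(x)$value             # 6000 draws
  expect_lt(abs(mean(v)), 3 * 1.5 / sqrt(length(v)))
  expect_lt(abs(sd(v) - 1.5), 3 * 1.5 / sqrt(2 * length(v)))
})

test_that("null data without subject deviations show no serial correlation", {
  # adjacent-timepoint correlation measured across the many (subject,
  # analyte) strata is consistent with white noise (the within-stratum
  # lag-1 estimate is too biased at 5 points to be informative)
  cfg <- SimulationConfig(nAnalytes = 40, subjectDevSd = 0,
                          missingRate = 0, seed = 9)
  x <- makeNullDataset(cfg)
  tab <- longTable(x)
  tab <- tab[order(tab$analyte, tab$subject, tab$time_h), ]
  V <- matrix(tab$value, nrow = 5)       # timepoints x strata
  for (j in 1:4) {
    r <- cor(V[j, ], V[j + 1, ])
    expect_lt(abs(r), 4 / sqrt(ncol(V)))
  }
})

test_that("null datasets carry no rhythmic analytes in the ground truth", {
  x <- makeNullDataset(SimulationConfig(nAnalytes = 7, seed = 2))
  expect_equal(sum(groundTruth(x)$rhythmic), 0)
})

test_that("the default 116-analyte panel uses field nomenclature", {
  x <- smallSim(seed = 3)              # default nAnalytes = 116
  expect_equal(nrow(x), 116)
  cls <- vapply(analytes(x), function(a)
    parseCeramideName(a, lenient = TRUE)$class_code, character(1))
  nCer <- sum(!is.na(cls))
  expect_gt(nCer, 50)                  # ceramide-majority panel
  expect_true(all(cls[!is.na(cls)] %in% c("NS", "NDS", "AS", "ADS")))
  expect_true("9-HODE" %in% analytes(x))
  expect_false(anyDuplicated(analytes(x)) > 0)
})

test_that("missingness frequency is compatible with the configured rate", {
  cfg <- SimulationConfig(nAnalytes = 50, missingRate = 0.05, seed = 12)
  x <- simulateLipidome(cfg)
  v <- longTable(x)$value
  phat <- mean(is.na(v))
  se <- sqrt(0.05 * 0.95 / length(v))
  expect_lt(abs(phat - 0.05), 3 * se)
})

test_that("gp-mode shared draws reproduce the periodic kernel covariance", {
  tt <- c(18, 24, 30, 36, 42)
  K <- periodicKernel(tt, tt, KernelParams(sigma2p = 1, ellp = 1))
  set.seed(99)
  draws <- t(replicate(4000, LipidRhythm:::.drawPeriodicGP(tt, 1, 1, 24)))
  Khat <- crossprod(sweep(draws, 2, colMeans(draws))) / (nrow(draws) - 1)
  se <- sqrt((outer(diag(K), diag(K)) + K^2) / nrow(draws))
  expect_true(all(abs(Khat - K) <= 3.5 * se))
})

test_that("cosinor mode injects the exact acrophase and amplitude", {
  cfg <- SimulationConfig(nAnalytes = 1, fractionRhythmic = c(1, 1),
                          amplitude = 2, acrophases = 23, subjectDevSd = 0,
                          noiseSd = 1e-9, missingRate = 0, seed = 4)
  x <- simulateLipidome(cfg)
  s <- stackSeries(x, analytes(x)[1], "RA")
  expect_equal(s@y, 2 * sqrt(2) * cos(2 * pi * (s@t - 23) / 24),
               tolerance = 1e-6)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(SimulationConfig(nSubjectsPerGroup = 0), "nSubjectsPerGroup")
  expect_error(SimulationConfig(missingRate = 1), "missingRate")
  expect_error(SimulationConfig(noiseSd = 0), "noiseSd")
  expect_error(SimulationConfig(fractionRhythmic = c(0.5, 1.2)),
               "fractionRhythmic")
  expect_error(SimulationConfig(sampleTimes = c(6, 6, 12)), "sampleTimes")
  expect_error(SimulationConfig(acrophases = 25), "acrophases")
})

test_that("exportDataset writes data, truth and config side files", {
  dir <- withr::local_tempdir()
  cfg <- SimulationConfig(nAnalytes = 2, seed = 6)
  x <- simulateLipidome(cfg)
  exportDataset(x, dir, cfg)
  expect_true(all(file.exists(file.path(dir, c("data.csv", "truth.csv",
                                               "config.yaml")))))
  cfgBack <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_equal(cfgBack$noiseSd, 1)
  expect_equal(cfgBack$seed, 6)
})
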
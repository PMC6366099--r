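test_that("the LR statistic and chi-squared p behave as Wilks prescribes", {
  p <- KernelParams()
  f0 <- manualFit(p, logLik = -50, kind = "null")
  f1same <- manualFit(p, logLik = -50, kind = "rhythmic")
  r <- lrTest(f1same, f0)
  expect_equal(r$lr_stat, 0)
  expect_equal(r$p_value, 1)
  expect_false(r$rhythmic)
  # delta logLik = 3 -> Lambda = 6; chi2_2 upper tail there is exp(-3)
  f1 <- manualFit(p, logLik = -47, kind = "rhythmic")
  r2 <- lrTest(f1, f0, alpha = 0.05)
  expect_equal(r2$lr_stat, 6)
  expect_equal(r2$p_value, exp(-3), tolerance = 1e-12)
  expect_true(r2$rhythmic)
  # a rhythmic optimum numerically below the null clips at zero
  fbelow <- manualFit(p, logLik = -50.0001, kind = "rhythmic")
  expect_equal(lrTest(fbelow, f0)$lr_stat, 0)
  expect_error(lrTest(f0, f1), "order")
})

test_that("unconverged fits yield an inconclusive, flagged result", {
  p <- KernelParams()
  bad <- methods::new("GPFit", params = p, logLik = -Inf, kind = "rhythmic",
                      converged = FALSE, nRestarts = 5L,
                      trace = data.frame())
  r <- lrTest(bad, manualFit(p, -50, "null"))
  expect_false(r$converged)
  expect_true(is.na(r$p_value))
})

test_that("acrophase is the earliest argmax of the posterior mean", {
  grid <- seq(0, 23.9, by = 0.1)
  mk <- function(m) structure(data.frame(grid_t = grid, mean = m, sd = 0),
                              class = c("PosteriorCurve", "data.frame"))
  expect_equal(estimateAcrophase(mk(cos(2 * pi * (grid - 23) / 24))), 23)
  expect_equal(estimateAcrophase(mk(cos(2 * pi * grid / 24))), 0)
  expect_error(estimateAcrophase(mk(rep(1, length(grid)))), "undefined")
})

test_that("gain classification follows the two-test truth table", {
  expect_equal(as.character(classifyGain(0.20, 0.01)), "gained_in_RA")
  expect_equal(as.character(classifyGain(0.01, 0.01)), "rhythmic_in_both")
  expect_equal(as.character(classifyGain(0.01, 0.20)), "lost_in_RA")
  expect_equal(as.character(classifyGain(0.20, 0.20)), "not_rhythmic")
  # boundary: p = alpha counts as significant
  expect_equal(as.character(classifyGain(0.05, 0.051, alpha = 0.05)),
               "lost_in_RA")
  expect_error(classifyGain(1.2, 0.5), "0, 1")
})

test_that("gain classification is exhaustive and mutually exclusive", {
  set.seed(13)
  ph <- runif(500); pr <- runif(500)
  cls <- classifyGain(ph, pr, alpha = 0.3)
  expect_false(any(is.na(cls)))
  expect_equal(sum(table(cls)), 500)
  # every cell of the truth table is a single category
  expect_equal(length(unique(cls[ph <= 0.3 & pr <= 0.3])), 1)
  expect_equal(length(unique(cls[ph > 0.3 & pr <= 0.3])), 1)
})

test_that("class summaries count detected and rhythmic species coherently", {
  res <- data.frame(
    analyte = c(sprintf("CER[N(%d)DS(18)]", c(16, 18, 20, 22, 24, 26)),
                sprintf("CER[A(%d)DS(18)]", c(16, 18)),
                "CER[N(24)S(16)]", "CER[A(20)S(18)]"),
    rhythmic = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE,
                 TRUE, FALSE, FALSE, FALSE),
    acrophase = c(6.0, 6.1, 18.0, NA, NA, NA, 23.0, NA, NA, NA))
  s <- summarizeByClass(res)
  expect_equal(s$n_detected[s$class == "NDS"], 6)
  expect_equal(s$n_rhythmic[s$class == "NDS"], 3)
  expect_equal(s$n_rhythmic[s$class == "ADS"], 1)
  expect_equal(sum(s$n_detected), nrow(res))
  expect_equal(sum(s$n_rhythmic), 4)
  acr <- attr(s, "acrophases")
  expect_equal(modalAcrophaseBin(acr$NDS, binWidth = 1), 6)
  # empty rhythmic set: all-zero counts, no error
  res0 <- transform(res, rhythmic = FALSE, acrophase = NA_real_)
  s0 <- summarizeByClass(res0)
  expect_equal(sum(s0$n_rhythmic), 0)
  # non-ceramides fall into 'other'
  resO <- data.frame(analyte = c("9-HODE", "AEA"), rhythmic = c(TRUE, FALSE),
                     acrophase = c(18, NA))
  expect_equal(summarizeByClass(resO)$n_detected[5], 2)
})

test_that("circular distance respects the 24 h wrap", {
  expect_equal(circularDistance(23, 1), 2)
  expect_equal(circularDistance(0, 12), 12)
  expect_equal(circularDistance(6, 6), 0)
  expect_equal(circularDistance(c(1, 23), c(23, 1)), c(2, 2))
})

test_that("permutation calibration returns a valid, larger-tail p", {
  cfg <- SimulationConfig(nAnalytes = 1, fractionRhythmic = c(0, 1),
                          amplitude = 2, missingRate = 0, seed = 71)
  x <- normalize(simulateLipidome(cfg))
  r <- testRhythmicity(x, analytes(x)[1], "RA", permute = TRUE, nPerm = 19,
                       permSeed = 5)
  expect_true(r$result$p_value >= 1 / 20 - 1e-12)
  expect_true(r$result$p_value <= 1)
})
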
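test_that("log marginal likelihood matches closed forms at n = 1", {
  s1 <- makeSeries(t = 0, y = 0, subjectIdx = 1)
  p <- KernelParams(sigma2p = 0, ellp = 1, sigma2m = 0, ellm = 6,
                    sigma2n = 1)
  expect_equal(logMarginalLikelihood(s1, p, includeShared = FALSE),
               -0.5 * log(2 * pi), tolerance = 1e-6)
  v <- 0.37; y1 <- 1.4
  s2 <- makeSeries(t = 0, y = y1, subjectIdx = 1)
  p2 <- KernelParams(sigma2p = 0, ellp = 1, sigma2m = 0, ellm = 6,
                     sigma2n = v)
  expect_equal(logMarginalLikelihood(s2, p2, includeShared = FALSE),
               -0.5 * log(2 * pi * v) - y1^2 / (2 * v), tolerance = 1e-6)
})

test_that("Cholesky likelihood equals dense inverse/determinant evaluation", {
  for (i in 1:50) {
    set.seed(i)
    n <- sample(5:40, 1)
    s <- randomSeries(n, nSubjects = sample(2:6, 1), seed = i)
    p <- randomParams(seed = i + 500)
    ll <- logMarginalLikelihood(s, p)
    K <- jointCovariance(s, p)
    K <- K + diag(1e-8 * mean(diag(K)), n)   # same deterministic jitter
    ref <- -0.5 * drop(t(s@y) %*% solve(K) %*% s@y) -
      0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
      n / 2 * log(2 * pi)
    expect_equal(ll, ref, tolerance = 1e-6)
  }
})

test_that("likelihood is invariant to stacking order and subject relabeling", {
  s <- randomSeries(24, nSubjects = 4, seed = 9)
  p <- randomParams(seed = 10)
  ll <- logMarginalLikelihood(s, p)
  set.seed(11)
  perm <- sample.int(24)
  sp <- makeSeries(s@t[perm], s@y[perm], s@subjectIdx[perm])
  expect_equal(logMarginalLikelihood(sp, p), ll, tolerance = 1e-9)
  relab <- c(3L, 1L, 4L, 2L)
  sr <- makeSeries(s@t, s@y, relab[s@subjectIdx])
  expect_equal(logMarginalLikelihood(sr, p), ll, tolerance = 1e-9)
})

test_that("analytic gradient of the objective matches finite differences", {
  s <- randomSeries(20, nSubjects = 4, seed = 21)
  for (kind in c("null", "rhythmic")) {
    obj <- LipidRhythm:::.nllFactory(s, kind, 24)
    th <- log(if (kind == "rhythmic") c(0.4, 1.1, 0.6, 9, 0.8)
              else c(0.6, 9, 0.8))
    g <- obj$gr(th)
    gn <- vapply(seq_along(th), function(i) {
      e <- 1e-6; tp <- th; tm <- th
      tp[i] <- th[i] + e; tm[i] <- th[i] - e
      (obj$fn(tp) - obj$fn(tm)) / (2 * e)
    }, numeric(1))
    expect_equal(g, gn, tolerance = 1e-5)
  }
})

test_that("ML recovers the total noise-level variance on i.i.d. data", {
  # with 6-hourly sampling a Matern with a ~2 h lengthscale is
  # indistinguishable from white noise, so only the sum of the noise and
  # subject-deviation variances is identified on i.i.d. data
  set.seed(77)
  s <- makeSeries(t = rep(c(18, 24, 30, 36, 42), 40), y = rnorm(200),
                  subjectIdx = rep(1:40, each = 5))
  fit <- fitML(s, "null")
  expect_true(fit@converged)
  tot <- fit@params@sigma2n + fit@params@sigma2m
  expect_gt(tot, 0.8)
  expect_lt(tot, 1.2)
})

test_that("constant-zero series pins variances at the lower bound", {
  s <- makeSeries(t = rep(c(0, 6, 12, 18), 3), y = rep(0, 12),
                  subjectIdx = rep(1:3, each = 4))
  fit <- fitML(s, "null")
  expect_true(fit@converged)
  expect_lt(fit@params@sigma2n, 1e-5)
})

test_that("shared variance is detected in most cosinor simulations", {
  hits <- 0
  for (i in 1:50) {
    cfg <- SimulationConfig(nSubjectsPerGroup = 20, nAnalytes = 1,
                            fractionRhythmic = c(0, 1), amplitude = 1,
                            missingRate = 0, seed = 4000 + i)
    x <- normalize(simulateLipidome(cfg))
    s <- stackSeries(x, analytes(x)[1], "RA")
    fit <- fitML(s, "rhythmic", nullFit = fitML(s, "null"))
    if (fit@converged && fit@params@sigma2p > 0.1) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("estimated shared variance grows with the simulated amplitude", {
  med <- vapply(c(0.5, 1, 2), function(amp) {
    s2 <- vapply(1:50, function(i) {
      cfg <- SimulationConfig(nAnalytes = 1, fractionRhythmic = c(0, 1),
                              amplitude = amp, missingRate = 0,
                              seed = 5000 + i)
      x <- normalize(simulateLipidome(cfg))
      s <- stackSeries(x, analytes(x)[1], "RA")
      fitML(s, "rhythmic", nullFit = fitML(s, "null"))@params@sigma2p
    }, numeric(1))
    median(s2)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("posterior shared curve behaves at the limits", {
  # prior dominates as sigma2p -> 0
  s <- makeSeries(t = rep(c(0, 8, 16), 2), y = rnorm(6) + 1,
                  subjectIdx = rep(1:2, each = 3))
  fit0 <- manualFit(KernelParams(sigma2p = 1e-12, ellp = 1, sigma2m = 0.5,
                                 ellm = 6, sigma2n = 1))
  pc0 <- posteriorSharedCurve(s, fit0)
  expect_lt(max(abs(pc0$mean)), 1e-5)
  expect_lt(max(pc0$sd), 1e-5)
  # near-noise-free single subject: posterior interpolates the data
  tt <- seq(0, 22, by = 2)
  yy <- sqrt(2) * cos(2 * pi * (tt - 5) / 24)
  s1 <- makeSeries(tt, yy, rep(1, length(tt)))
  fit1 <- manualFit(KernelParams(sigma2p = 1, ellp = 1, sigma2m = 1e-6,
                                 ellm = 6, sigma2n = 1e-6))
  pc1 <- posteriorSharedCurve(s1, fit1)
  at <- vapply(tt, function(t0) pc1$mean[which.min(abs(pc1$grid_t - t0))],
               numeric(1))
  expect_lt(max(abs(at - yy)), 0.01)
  # far from all observations (in kernel distance) the sd reverts to the prior
  s2 <- makeSeries(c(0, 0.2, 0.4), c(0.1, 0, -0.1), c(1, 1, 1))
  fit2 <- manualFit(KernelParams(sigma2p = 0.9, ellp = 0.15, sigma2m = 1e-6,
                                 ellm = 6, sigma2n = 0.5))
  pc2 <- posteriorSharedCurve(s2, fit2)
  sd12 <- pc2$sd[which.min(abs(pc2$grid_t - 12))]
  expect_equal(sd12, sqrt(0.9), tolerance = 1e-3)
  # pointwise variance never exceeds the prior variance
  expect_true(all(pc2$sd^2 <= 0.9 + 1e-8))
})

test_that("posterior curve requires a converged rhythmic fit", {
  s <- makeSeries(c(0, 6, 12), c(0, 1, 0), c(1, 1, 1))
  nullFit <- manualFit(KernelParams(sigma2p = 0, ellp = 1, sigma2m = 1,
                                    ellm = 6, sigma2n = 1), kind = "null")
  expect_error(posteriorSharedCurve(s, nullFit), "rhythmic")
})

test_that("fitted rhythmic likelihood never falls below the null", {
  for (i in 1:10) {
    cfg <- SimulationConfig(nAnalytes = 1, fractionRhythmic = c(0, 0),
                            missingRate = 0, seed = 6000 + i)
    x <- normalize(makeNullDataset(cfg))
    s <- stackSeries(x, analytes(x)[1], "healthy")
    f <- fitRhythmModels(s)
    expect_gte(f$rhythmic@logLik - f$null@logLik, -1e-6)
  }
})
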
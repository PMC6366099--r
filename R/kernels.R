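#' Kernel parameter constructor
#'
#' @param sigma2p,ellp,period shared periodic component: variance,
#'   dimensionless warp lengthscale, period in hours (fixed at 24 by
#'   default and not estimated).
#' @param sigma2m,ellm subject-level Matern 3/2 component: variance and
#'   lengthscale in hours.
#' @param sigma2n observation-noise variance.
#' @return A \linkS4class{KernelParams}.
#' @export
KernelParams <- function(sigma2p = 1, ellp = 1, period = 24,
                         sigma2m = 1, ellm = 6, sigma2n = 1) {
  methods::new("KernelParams", sigma2p = as.numeric(sigma2p),
               ellp = as.numeric(ellp), period = as.numeric(period),
               sigma2m = as.numeric(sigma2m), ellm = as.numeric(ellm),
               sigma2n = as.numeric(sigma2n))
}

## plain-numeric kernel cores, shared by the public API, the covariance
## assembly and the simulator
.kPeriodic <- function(d, sigma2, ell, period) {
  sigma2 * exp(-2 * sin(pi * d / period)^2 / ell^2)
}

.kMatern32 <- function(r, sigma2, ell) {
  a <- sqrt(3) * r / ell
  sigma2 * (1 + a) * exp(-a)
}

#' Exp-sine-squared (periodic) covariance
#'
#' `k(t, t') = sigma2p * exp(-2 sin^2(pi (t - t') / T) / ellp^2)`, exactly
#' `T`-periodic in the lag. This is the covariance of the shared rhythmic
#' component.
#'
#' @param t1,t2 vectors of times in hours (`t2` defaults to `t1`).
#' @param params a \linkS4class{KernelParams}.
#' @return `length(t1) x length(t2)` covariance matrix.
#' @export
periodicKernel <- function(t1, t2 = t1, params = KernelParams()) {
  stopifnot(methods::is(params, "KernelParams"))
  methods::validObject(params)
  .kPeriodic(outer(t1, t2, "-"), params@sigma2p, params@ellp, params@period)
}

#' Matern 3/2 covariance
#'
#' `k(r) = sigma2m * (1 + sqrt(3) r / ellm) * exp(-sqrt(3) r / ellm)` with
#' `r = |t - t'|`; the covariance of the once-differentiable
#' subject-deviation process.
#'
#' @inheritParams periodicKernel
#' @return `length(t1) x length(t2)` covariance matrix.
#' @export
matern32Kernel <- function(t1, t2 = t1, params = KernelParams()) {
  stopifnot(methods::is(params, "KernelParams"))
  methods::validObject(params)
  .kMatern32(abs(outer(t1, t2, "-")), params@sigma2m, params@ellm)
}

#' Joint covariance of a stacked analyte series
#'
#' Assembles the hierarchical covariance over all stacked observations:
#' the shared periodic kernel couples every pair of observations
#' (optional, via `includeShared`), the Matern 3/2 kernel applies only
#' within a subject (block structure), and the noise variance sits on the
#' diagonal.
#'
#' @param series an \linkS4class{AnalyteSeries}.
#' @param params a \linkS4class{KernelParams}.
#' @param includeShared include the shared periodic component (the
#'   rhythmic model); `FALSE` gives the null model's covariance.
#' @return symmetric covariance matrix of dimension `length(series@t)`.
#' @export
jointCovariance <- function(series, params, includeShared = TRUE) {
  stopifnot(methods::is(series, "AnalyteSeries"),
            methods::is(params, "KernelParams"))
  if (length(series@t) == 0) stop("empty series")
  d <- outer(series@t, series@t, "-")
  sameSubj <- outer(series@subjectIdx, series@subjectIdx, "==")
  K <- .kMatern32(abs(d), params@sigma2m, params@ellm) * sameSubj
  if (includeShared)
    K <- K + .kPeriodic(d, params@sigma2p, params@ellp, params@period)
  diag(K) <- diag(K) + params@sigma2n
  if (any(!is.finite(K))) stop("non-finite entries in joint covariance")
  K
}

## diagonal jitter: 1e-8 x mean diagonal, escalated x10 on factorization
## failure (data are on the unit-variance scale, so this never moves a
## likelihood materially)
.jitterChol <- function(K, what = "covariance") {
  mj <- 1e-8 * mean(diag(K))
  for (j in mj * 10^(0:6)) {
    L <- tryCatch(chol(K + diag(j, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = j))
  }
  stop("Cholesky factorization failed after jitter escalation for ", what)
}
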
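#' Posterior mean and SD of the shared rhythmic component
#'
#' Standard GP conditional of the shared periodic component `g` given the
#' stacked observations: `mean = K_g* K^-1 y`,
#' `var = k(t*, t*) - K_g* K^-1 K_g*'`, where `K_g*` couples the
#' prediction grid to every observation through the periodic kernel only.
#' Reported on a fixed-resolution clock-hour grid over `[0, 24)`; both
#' mean and SD are exactly 24 h-periodic because the kernel is.
#'
#' @param series the fitted \linkS4class{AnalyteSeries}.
#' @param fit a converged rhythmic \linkS4class{GPFit}.
#' @param gridRes grid resolution in hours (default 0.1).
#' @return data.frame of class `"PosteriorCurve"` with columns `grid_t`,
#'   `mean`, `sd`.
#' @export
posteriorSharedCurve <- function(series, fit, gridRes = 0.1) {
  stopifnot(methods::is(series, "AnalyteSeries"), methods::is(fit, "GPFit"))
  if (fit@kind != "rhythmic")
    stop("posterior of the shared component requires a rhythmic fit ",
         "(the null model has no shared component)")
  if (!fit@converged) stop("fit did not converge")
  p <- fit@params
  grid <- seq(0, p@period - gridRes / 2, by = gridRes)
  K <- jointCovariance(series, p, includeShared = TRUE)
  fc <- .jitterChol(K)
  L <- fc$L
  Kstar <- .kPeriodic(outer(grid, series@t, "-"), p@sigma2p, p@ellp, p@period)
  alpha <- backsolve(L, forwardsolve(t(L), series@y))
  mean <- as.vector(Kstar %*% alpha)
  ## var_i = sigma2p - k_i K^-1 k_i'
  V <- forwardsolve(t(L), t(Kstar))          # solves t(L) V = Kstar'
  var <- pmax(0, p@sigma2p - colSums(V^2))
  out <- data.frame(grid_t = grid, mean = mean, sd = sqrt(var))
  class(out) <- c("PosteriorCurve", "data.frame")
  out
}

#' Acrophase (peak clock time) of a posterior curve
#'
#' The argmax of the posterior mean over the prediction grid; ties are
#' broken by the earliest hour. Errors when the curve is flat (acrophase
#' undefined).
#'
#' @param curve a `PosteriorCurve` from [posteriorSharedCurve()].
#' @return peak hour in `[0, 24)`.
#' @export
estimateAcrophase <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("grid_t", "mean") %in% names(curve)))
  m <- curve$mean
  if (diff(range(m)) < 1e-9)
    stop("acrophase undefined: posterior mean is constant")
  curve$grid_t[which.max(m)]
}
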
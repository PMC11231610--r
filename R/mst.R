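# Microscale thermophoresis: Fnorm extraction from fluorescence traces and
# the 1:1 binding-isotherm fit for KD with a 68 percent confidence range.

#' Fnorm from an MST fluorescence trace
#'
#' Ratio of the mean fluorescence in the cold window (before the IR laser
#' switches on) to the mean in the hot window centred at the evaluation
#' time after heating starts. Window definitions follow common practice:
#' cold = the last \code{coldWindowS} seconds before \code{irOnS}, hot = a
#' \code{hotWindowS}-wide window centred at \code{irOnS + tEndS}.
#'
#' @param timeS time axis (s).
#' @param fluorescence fluorescence counts, same length.
#' @param tEndS evaluation time after heating start (s, default 1.5).
#' @param irOnS time at which the IR laser switches on (s, default 0).
#' @param coldWindowS,hotWindowS window widths (s).
#' @return dimensionless Fnorm.
#' @examples
#' t <- seq(-2, 3, by = 0.01)
#' f <- ifelse(t < 0, 1, 0.9)
#' fnormFromTrace(t, f)   # 1/0.9
#' @export
fnormFromTrace <- function(timeS, fluorescence, tEndS = 1.5, irOnS = 0,
                           coldWindowS = 1, hotWindowS = 0.2) {
  stopifnot(length(timeS) == length(fluorescence))
  cold <- timeS >= irOnS - coldWindowS & timeS < irOnS
  hot <- timeS >= irOnS + tEndS - hotWindowS / 2 &
    timeS <= irOnS + tEndS + hotWindowS / 2
  if (!any(cold) || !any(hot)) {
    stop("trace-format error: trace must span the pre-heating baseline and the evaluation time")
  }
  mean(fluorescence[cold]) / mean(fluorescence[hot])
}

#' Bound ligand fraction for 1:1 binding at finite ligand concentration
#'
#' Exact quadratic solution of the 1:1 isotherm,
#' \deqn{f = \frac{c_P + L_0 + K_D - \sqrt{(c_P + L_0 + K_D)^2 - 4 c_P L_0}}{2 L_0},}
#' monotone in the protein concentration and respecting ligand
#' conservation. In the limit \eqn{L_0 \to 0} this degenerates to the
#' hyperbola \eqn{c_P / (c_P + K_D)}, which is returned for \code{L0UM = 0}.
#'
#' @param cProteinUM protein concentration(s), uM.
#' @param kdUM dissociation constant, uM.
#' @param L0UM total labelled-ligand concentration, uM.
#' @return bound fraction(s) in [0, 1].
#' @export
boundFraction1to1 <- function(cProteinUM, kdUM, L0UM) {
  stopifnot(all(cProteinUM >= 0), kdUM >= 0, L0UM >= 0)
  if (L0UM == 0) {
    return(ifelse(cProteinUM + kdUM == 0, 0, cProteinUM / (cProteinUM + kdUM)))
  }
  s <- cProteinUM + L0UM + kdUM
  pmin(pmax((s - sqrt(s^2 - 4 * cProteinUM * L0UM)) / (2 * L0UM), 0), 1)
}

#' Fit the 1:1 MST isotherm for KD
#'
#' Averages replicates per concentration, weights by the replicate standard
#' deviation where available, and fits
#' \code{response = base + amp * boundFraction1to1(cP, KD, L0)} by
#' Levenberg-Marquardt least squares with the baseline and amplitude as
#' nuisance parameters (so the fit is invariant to affine transformations
#' of the raw Fnorm). KD is parameterized on the log scale; the 68 percent
#' confidence range comes from the parameter covariance.
#'
#' @param series an \linkS4class{MstSeries}.
#' @return list with \code{KD_uM}, \code{ciLow_uM}, \code{ciHigh_uM}
#'   (68 percent), \code{confidencePct} (half-range as percent of KD),
#'   \code{base}, \code{amp}, \code{fitted} (per averaged point),
#'   \code{cProteinUM} and \code{plateauWarning}. When the highest
#'   concentration cannot identify the plateau the interval is widened and
#'   flagged.
#' @export
fitKdMst <- function(series) {
  stopifnot(is(series, "MstSeries"))
  cp <- series@cProteinUM
  y <- series@response
  agg <- stats::aggregate(y, by = list(cp = cp), FUN = mean)
  sdv <- stats::aggregate(y, by = list(cp = cp), FUN = stats::sd)$x
  n <- stats::aggregate(y, by = list(cp = cp), FUN = length)$x
  cc <- agg$cp
  yy <- agg$x
  # pool the replicate scatter into one noise level: with duplicate
  # measurements the per-concentration SD has a single degree of freedom
  # and weighting by it is far noisier than assuming homoscedastic error
  sdPool <- sqrt(mean(sdv^2, na.rm = TRUE))
  if (!is.finite(sdPool) || sdPool == 0) sdPool <- 1
  w <- sqrt(n) / sdPool
  L0 <- series@ligandConcNM / 1000  # nM -> uM

  resid <- function(p) {
    kd <- exp(p[1])
    f <- boundFraction1to1(cc, kd, L0)
    w * (yy - (p[2] + p[3] * f))
  }
  span <- max(yy) - min(yy)
  p0 <- c(log(stats::median(cc)), min(yy), if (span > 0) span else 1)
  fit <- minpack.lm::nls.lm(par = p0, fn = resid,
                            control = minpack.lm::nls.lm.control(maxiter = 300))
  kd <- exp(fit$par[1])
  covm <- tryCatch({
    s2 <- sum(fit$fvec^2) / max(1, length(yy) - 3)
    solve(fit$hessian) * s2
  }, error = function(e) matrix(NA_real_, 3, 3))
  sdLogKd <- sqrt(abs(covm[1, 1]))
  plateauWarning <- FALSE
  if (max(cc) < kd) {
    plateauWarning <- TRUE
    sdLogKd <- 2 * sdLogKd   # widened interval
    warning("plateau unidentifiable: highest concentration below the fitted KD; confidence range widened")
  }
  ciLow <- kd * exp(-sdLogKd)
  ciHigh <- kd * exp(sdLogKd)
  list(KD_uM = kd, ciLow_uM = ciLow, ciHigh_uM = ciHigh,
       confidencePct = 100 * (exp(sdLogKd) - 1),
       base = fit$par[2], amp = fit$par[3],
       fitted = fit$par[2] + fit$par[3] * boundFraction1to1(cc, kd, L0),
       cProteinUM = cc, plateauWarning = plateauWarning)
}
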
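# Multi-component spectral decomposition: fit a spectrum as a weighted sum
# of simulated component spectra and report fractions with RMSD-based
# uncertainties.
#
# Conventions: spectra are double-integral-normalized before fitting, so the
# experimental amplitude is absorbed into one global scale factor; an
# additive linear baseline (offset + slope) is fitted jointly with the
# weights. The nonnegative weight solve uses pracma::lsqnonneg with the
# baseline columns entered as +/- pairs (free sign).

.designMatrix <- function(spectrum, components, engine = "auto",
                          overrides = NULL) {
  B <- fieldAxis(spectrum)
  sapply(seq_along(components), function(i) {
    comp <- components[[i]]
    if (!is.null(overrides)) {
      ov <- overrides[[i]]
      if (!is.null(ov$tauC)) comp@tauC <- ov$tauC
      if (!is.null(ov$Azz)) comp@ATensor[3] <- ov$Azz
    }
    simulateComponent(comp, B, spectrum@mwFreqGHz, engine = engine)
  })
}

.solveWeights <- function(y, X, Bc) {
  base <- cbind(1, Bc)
  A <- cbind(X, base, -base)
  sol <- pracma::lsqnonneg(A, y)
  coefs <- sol$x
  k <- ncol(X)
  w <- coefs[1:k]
  bl <- base %*% (coefs[(k + 1):(k + 2)] - coefs[(k + 3):(k + 4)])
  fit <- as.numeric(X %*% w + bl)
  list(w = w, baseline = as.numeric(bl), fitted = fit,
       resid = y - fit)
}

#' Fit component weights to a measured or synthetic spectrum
#'
#' Solves for nonnegative component amplitudes (plus a linear baseline and a
#' global scale) by least squares, then reports fractions via the
#' double-integral shares of the fitted components. Optionally performs a
#' bounded nonlinear refinement (+/- 15 percent) of tau_c and/or A'zz of
#' each component around their library values, wrapping the linear solve.
#'
#' @param spectrum a \linkS4class{SpectrumTrace}.
#' @param components non-empty list of \linkS4class{SpinComponent}s (the
#'   component library); simulated on the spectrum's axis.
#' @param refine one of "none", "tau_c", "Azz", "both".
#' @param engine forward-engine selection, see
#'   \code{\link{simulateComponent}}.
#' @return a \linkS4class{DecompositionResult}. A degeneracy warning with
#'   the condition number is emitted if two components are numerically
#'   indistinguishable on this axis; the ambiguous weight then goes to the
#'   smallest-tau_c component.
#' @export
fitWeights <- function(spectrum, components,
                       refine = c("none", "tau_c", "Azz", "both"),
                       engine = "auto") {
  refine <- match.arg(refine)
  if (length(components) == 0) stop("component library is empty")
  if (length(components) > 3) stop("at most three components are supported")
  B <- fieldAxis(spectrum)
  y <- intensity(spectrum)
  # amplitude convention: one global scale factor absorbs the experimental
  # amplitude (peak-to-peak is robust where the double integral of a noisy
  # trace is not); fractions are double-integral shares and scale-invariant
  scale <- max(y) - min(y)
  if (!is.finite(scale) || scale <= 0) {
    stop("empty-spectrum error: zero peak-to-peak amplitude")
  }
  y <- y / scale
  Bc <- (B - mean(B)) / (max(B) - min(B))

  evalRss <- function(overrides) {
    X <- .designMatrix(spectrum, components, engine, overrides)
    s <- .solveWeights(y, X, Bc)
    list(rss = sum(s$resid^2), X = X, sol = s)
  }

  overrides <- NULL
  refined <- list()
  if (refine != "none") {
    doTau <- refine %in% c("tau_c", "both")
    doAzz <- refine %in% c("Azz", "both")
    k <- length(components)
    # parameters as multipliers in [0.85, 1.15] of the library values
    npar <- (doTau + doAzz) * k
    par0 <- rep(1, npar)
    obj <- function(p) {
      ov <- lapply(seq_len(k), function(i) {
        o <- list()
        j <- 0
        if (doTau) { o$tauC <- components[[i]]@tauC * p[i]; j <- k }
        if (doAzz) o$Azz <- components[[i]]@ATensor[3] * p[j + i]
        o
      })
      evalRss(ov)$rss
    }
    opt <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = rep(0.85, npar), upper = rep(1.15, npar),
                        control = list(maxit = 60, factr = 1e10))
    p <- opt$par
    overrides <- lapply(seq_len(k), function(i) {
      o <- list()
      j <- 0
      if (doTau) { o$tauC <- components[[i]]@tauC * p[i]; j <- k }
      if (doAzz) o$Azz <- components[[i]]@ATensor[3] * p[j + i]
      o
    })
    refined <- overrides
  }

  res <- evalRss(overrides)
  X <- res$X
  sol <- res$sol

  # degeneracy diagnostics on the normalized component columns
  Xn <- sweep(X, 2, sqrt(colSums(X^2)), "/")
  cond <- tryCatch(kappa(Xn, exact = TRUE), error = function(e) Inf)
  if (cond > 1e6) {
    warning(sprintf("degeneracy warning: component design condition number %.3g; ambiguous weight assigned to the smallest-tau_c component", cond))
    # push weight shared by indistinguishable pairs onto the faster component
    taus <- vapply(components, tauC, numeric(1))
    cors <- crossprod(Xn)
    for (i in seq_len(ncol(X))) for (j in seq_len(ncol(X))) {
      if (i < j && cors[i, j] > 1 - 1e-9) {
        fast <- if (taus[i] <= taus[j]) i else j
        slow <- if (taus[i] <= taus[j]) j else i
        sol$w[fast] <- sol$w[fast] + sol$w[slow]
        sol$w[slow] <- 0
      }
    }
  }

  # fractions from the double integrals of the fitted, scaled components
  scaled <- sweep(X, 2, sol$w, "*")
  fractions <- fractionsFromDoubleIntegrals(
    lapply(seq_len(ncol(scaled)), function(i) scaled[, i]), B)
  labels <- vapply(components, componentLabel, character(1))
  names(fractions) <- labels

  resid <- sol$resid
  pp <- max(y) - min(y)
  rmsd <- 100 * sqrt(mean(resid^2)) / pp
  errs <- pmin(pmax(rep(rmsd / 100, length(fractions)), 0), 1)
  names(errs) <- labels

  new("DecompositionResult",
      weights = fractions, weightErrors = errs,
      refinedParams = refined, rmsdPct = rmsd,
      fittedTrace = sol$fitted * scale, baseline = sol$baseline * scale,
      conditionNumber = cond)
}

#' Component fractions from double integrals
#'
#' Fractions are the double-integral shares of the fitted component traces;
#' by construction they are invariant to a rescaling of any component trace
#' together with its weight, and they equal the solver weights when the
#' components are unit-spins normalized.
#'
#' @param traces list of fitted (scaled) component intensity vectors on a
#'   common axis.
#' @param fieldMT the common field axis (mT).
#' @return numeric vector of fractions summing to 1.
#' @export
fractionsFromDoubleIntegrals <- function(traces, fieldMT) {
  dis <- vapply(traces, function(tr) doubleIntegral(fieldMT, tr), numeric(1))
  tot <- sum(dis)
  if (!is.finite(tot) || tot <= 0) {
    stop("empty-spectrum error: total double integral is not positive")
  }
  dis / tot
}

#' Weights with plus/minus absolute errors from the fit RMSD
#'
#' Applies the reporting rule Phi +/- RMSD percent: the fit RMSD (percent of
#' peak-to-peak amplitude) is attached to every component fraction as an
#' absolute error, clipped so that Phi +/- error stays within [0, 1].
#'
#' @param result a \linkS4class{DecompositionResult}.
#' @return data.frame with columns component, phi, error, lower, upper.
#' @export
phiUncertainty <- function(result) {
  stopifnot(is(result, "DecompositionResult"))
  phi <- result@weights
  err <- rep(result@rmsdPct / 100, length(phi))
  data.frame(
    component = names(phi),
    phi = as.numeric(phi),
    error = err,
    lower = pmax(phi - err, 0),
    upper = pmin(phi + err, 1),
    row.names = NULL
  )
}

#' Export decomposition results as a one-row data.frame
#'
#' One row per spectrum with fractions, errors, RMSD and any refined
#' parameters; suitable for accumulation into the results-table CSV.
#'
#' @param result a \linkS4class{DecompositionResult}.
#' @param meta optional named list prepended as columns (e.g. protein
#'   concentration, temperature).
#' @return data.frame with a single row.
#' @export
decompositionRow <- function(result, meta = list()) {
  w <- result@weights
  out <- c(meta,
           as.list(stats::setNames(as.numeric(w), paste0("phi_", names(w)))),
           as.list(stats::setNames(as.numeric(result@weightErrors),
                                   paste0("err_", names(w)))),
           list(rmsd_pct = result@rmsdPct))
  as.data.frame(out)
}

#' Double integral of the fitted (noise-free) model trace
#'
#' Raw double integrals of measured traces are dominated by low-frequency
#' noise accumulation; integrating the fitted model with its baseline
#' removed recovers the spin count of the signal alone, which is the
#' quantity temperature-series normalization needs.
#'
#' @param result a \linkS4class{DecompositionResult}.
#' @param fieldMT the field axis the result was fitted on.
#' @return scalar double integral of the baseline-free fitted trace.
#' @export
fittedDoubleIntegral <- function(result, fieldMT) {
  doubleIntegral(fieldMT, result@fittedTrace - result@baseline)
}
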
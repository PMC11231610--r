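#' @import methods
NULL

#' SpinComponent: one nitroxide spectral species
#'
#' Describes a single S = 1/2, I = 1 (14N) nitroxide species by its magnetic
#' tensors, rotational dynamics and residual broadenings. Isotropic means
#' (\code{giso}, \code{aiso}) are always derived from the tensors, never
#' stored separately.
#'
#' @slot label character, one of \code{"free"}, \code{"intermediate"},
#'   \code{"strong"}.
#' @slot gTensor numeric(3), principal g values (gxx, gyy, gzz).
#' @slot ATensor numeric(3), principal hyperfine values in MHz.
#' @slot tauC rotational correlation time in ns (> 0).
#' @slot lwGauss Gaussian peak-to-peak broadening in mT (>= 0).
#' @slot lwLorentz Lorentzian peak-to-peak broadening in mT (>= 0).
#' @slot exchangeFreq Heisenberg exchange frequency in MHz (>= 0).
#' @slot eulerDeg numeric(3), tilt (alpha, beta, gamma) of the hyperfine
#'   frame relative to the g frame, degrees.
#' @export
setClass("SpinComponent",
  representation(
    label = "character",
    gTensor = "numeric",
    ATensor = "numeric",
    tauC = "numeric",
    lwGauss = "numeric",
    lwLorentz = "numeric",
    exchangeFreq = "numeric",
    eulerDeg = "numeric"
  ),
  prototype(
    label = "free",
    gTensor = c(2.0083, 2.0061, 2.0022),
    ATensor = c(15.5, 15.5, 101.3),
    tauC = 0.1,
    lwGauss = 0,
    lwLorentz = 0,
    exchangeFreq = 0,
    eulerDeg = c(0, 0, 0)
  )
)

setValidity("SpinComponent", function(object) {
  msg <- character()
  if (!object@label %in% c("free", "intermediate", "strong")) {
    msg <- c(msg, "label must be one of 'free', 'intermediate', 'strong'")
  }
  if (length(object@gTensor) != 3 || any(!is.finite(object@gTensor)) ||
      any(object@gTensor <= 0)) {
    msg <- c(msg, "gTensor must be three positive finite values")
  }
  if (length(object@ATensor) != 3 || any(!is.finite(object@ATensor))) {
    msg <- c(msg, "ATensor must be three finite values (MHz)")
  }
  if (length(object@tauC) != 1 || !is.finite(object@tauC) || object@tauC <= 0) {
    msg <- c(msg, "tauC must be a single positive value (ns)")
  }
  if (object@lwGauss < 0 || object@lwLorentz < 0) {
    msg <- c(msg, "linewidths must be >= 0")
  }
  if (object@exchangeFreq < 0) msg <- c(msg, "exchangeFreq must be >= 0")
  if (length(object@eulerDeg) != 3 || any(!is.finite(object@eulerDeg))) {
    msg <- c(msg, "eulerDeg must be three finite angles")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpinComponent
#'
#' @param label component label ("free", "intermediate" or "strong").
#' @param gTensor three principal g values.
#' @param ATensor three principal hyperfine values (MHz).
#' @param tauC rotational correlation time (ns).
#' @param lwGauss,lwLorentz residual Gaussian / Lorentzian peak-to-peak
#'   broadening (mT).
#' @param exchangeFreq Heisenberg exchange frequency (MHz), applied as a
#'   uniform extra Lorentzian broadening.
#' @param eulerDeg hyperfine-frame tilt angles (alpha, beta, gamma), degrees.
#' @return a validated \linkS4class{SpinComponent}.
#' @examples
#' sc <- spinComponent("free", tauC = 0.1, lwGauss = 0.13)
#' gIso(sc); aIso(sc)
#' @export
spinComponent <- function(label = "free",
                          gTensor = c(2.0083, 2.0061, 2.0022),
                          ATensor = c(15.5, 15.5, 101.3),
                          tauC = 0.1, lwGauss = 0, lwLorentz = 0,
                          exchangeFreq = 0, eulerDeg = c(0, 0, 0)) {
  new("SpinComponent", label = label, gTensor = as.numeric(gTensor),
      ATensor = as.numeric(ATensor), tauC = as.numeric(tauC),
      lwGauss = as.numeric(lwGauss), lwLorentz = as.numeric(lwLorentz),
      exchangeFreq = as.numeric(exchangeFreq),
      eulerDeg = as.numeric(eulerDeg))
}

#' SpectrumTrace: a first-derivative CW EPR spectrum
#'
#' @slot fieldMT strictly increasing magnetic-field axis (mT), >= 64 points.
#' @slot intensity first-derivative amplitudes (arbitrary units).
#' @slot mwFreqGHz microwave frequency (GHz).
#' @slot temperatureK sample temperature (K).
#' @slot meta list with acquisition metadata (protein id/concentration,
#'   ligand id/concentration, ...).
#' @export
setClass("SpectrumTrace",
  representation(
    fieldMT = "numeric",
    intensity = "numeric",
    mwFreqGHz = "numeric",
    temperatureK = "numeric",
    meta = "list"
  ),
  prototype(mwFreqGHz = 9.47, temperatureK = 310.15, meta = list())
)

setValidity("SpectrumTrace", function(object) {
  msg <- character()
  if (length(object@fieldMT) < 64) msg <- c(msg, "need >= 64 field points")
  if (length(object@fieldMT) != length(object@intensity)) {
    msg <- c(msg, "field and intensity must have the same length")
  }
  if (any(diff(object@fieldMT) <= 0)) {
    msg <- c(msg, "field axis must be strictly increasing")
  }
  if (any(!is.finite(object@fieldMT)) || any(!is.finite(object@intensity))) {
    msg <- c(msg, "non-finite values in trace")
  }
  if (object@mwFreqGHz <= 0) msg <- c(msg, "microwave frequency must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumTrace
#' @param fieldMT field axis (mT).
#' @param intensity derivative amplitudes.
#' @param mwFreqGHz microwave frequency (GHz).
#' @param temperatureK temperature (K).
#' @param meta metadata list.
#' @return a \linkS4class{SpectrumTrace}.
#' @export
spectrumTrace <- function(fieldMT, intensity, mwFreqGHz = 9.47,
                          temperatureK = 310.15, meta = list()) {
  new("SpectrumTrace", fieldMT = as.numeric(fieldMT),
      intensity = as.numeric(intensity), mwFreqGHz = mwFreqGHz,
      temperatureK = temperatureK, meta = meta)
}

#' DecompositionResult: fitted component weights for one spectrum
#'
#' @slot weights named fractions (free, intermediate, strong), sum to 1.
#' @slot weightErrors absolute uncertainties on the weights (RMSD rule).
#' @slot refinedParams list of per-component refined parameters (may be
#'   empty when no refinement was requested).
#' @slot rmsdPct fit root-mean-square deviation as percent of the spectrum's
#'   peak-to-peak amplitude.
#' @slot fittedTrace model spectrum on the input axis.
#' @slot baseline fitted additive baseline (offset + slope) on the axis.
#' @slot conditionNumber condition number of the component design matrix.
#' @export
setClass("DecompositionResult",
  representation(
    weights = "numeric",
    weightErrors = "numeric",
    refinedParams = "list",
    rmsdPct = "numeric",
    fittedTrace = "numeric",
    baseline = "numeric",
    conditionNumber = "numeric"
  )
)

setValidity("DecompositionResult", function(object) {
  msg <- character()
  if (any(object@weights < -1e-9)) msg <- c(msg, "weights must be >= 0")
  if (abs(sum(object@weights) - 1) > 1e-6) {
    msg <- c(msg, "weights must sum to 1 within 1e-6")
  }
  if (object@rmsdPct < 0) msg <- c(msg, "rmsdPct must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CurveFit: a fitted binding-curve model
#'
#' @slot model one of "hill", "bihill", "bidoseresp", "double_boltzmann".
#' @slot params named parameter estimates.
#' @slot paramErrors named standard errors.
#' @slot covariance parameter covariance matrix.
#' @slot rss residual sum of squares.
#' @slot r2 coefficient of determination.
#' @slot xRange concentration range of the fitted data (uM).
#' @export
setClass("CurveFit",
  representation(
    model = "character",
    params = "numeric",
    paramErrors = "numeric",
    covariance = "matrix",
    rss = "numeric",
    r2 = "numeric",
    xRange = "numeric"
  )
)

#' MstSeries: a microscale thermophoresis dose-response series
#'
#' @slot cProteinUM protein concentrations (uM).
#' @slot response raw Fnorm or bound-fraction values.
#' @slot replicate replicate identifiers (same length as points).
#' @slot ligandConcNM labelled-ligand concentration (nM), fixed.
#' @slot tEndS evaluation time after heating start (s).
#' @export
setClass("MstSeries",
  representation(
    cProteinUM = "numeric",
    response = "numeric",
    replicate = "integer",
    ligandConcNM = "numeric",
    tEndS = "numeric"
  ),
  prototype(ligandConcNM = 80, tEndS = 1.5)
)

setValidity("MstSeries", function(object) {
  msg <- character()
  if (length(object@cProteinUM) != length(object@response)) {
    msg <- c(msg, "concentration and response lengths differ")
  }
  if (length(unique(object@cProteinUM)) < 6) {
    msg <- c(msg, "need >= 6 distinct concentrations for fitting")
  }
  if (object@ligandConcNM <= 0) msg <- c(msg, "ligand concentration must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an MstSeries
#' @param cProteinUM protein concentrations (uM).
#' @param response Fnorm or normalized bound fraction per point.
#' @param replicate optional replicate ids (defaults to 1).
#' @param ligandConcNM fixed labelled-ligand concentration (nM).
#' @param tEndS evaluation time (s).
#' @return an \linkS4class{MstSeries}.
#' @export
mstSeries <- function(cProteinUM, response, replicate = NULL,
                      ligandConcNM = 80, tEndS = 1.5) {
  if (is.null(replicate)) replicate <- rep(1L, length(cProteinUM))
  new("MstSeries", cProteinUM = as.numeric(cProteinUM),
      response = as.numeric(response), replicate = as.integer(replicate),
      ligandConcNM = ligandConcNM, tEndS = tEndS)
}

#' TempSeriesResult: assembled temperature-dependent fractions
#'
#' @slot table data.frame with columns temperatureK, phiFree, phiIntermediate,
#'   phiStrong, totalDI, analyzed (logical; frozen-solution rows are retained
#'   but flagged FALSE).
#' @slot tIntermediateMax interpolated temperature (K) of the maximum of the
#'   intermediate fraction (NA when not computed).
#' @slot classification one of "release", "trap_destroy", "dynamics_only",
#'   or "" before classification.
#' @slot evidence list of per-rule diagnostics.
#' @export
setClass("TempSeriesResult",
  representation(
    table = "data.frame",
    tIntermediateMax = "numeric",
    classification = "character",
    evidence = "list"
  ),
  prototype(tIntermediateMax = NA_real_, classification = "", evidence = list())
)
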
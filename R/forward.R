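# Forward simulation of first-derivative CW EPR spectra for S = 1/2, I = 1
# nitroxides in fast and slow rotational-motion regimes.
#
# The fast engine is the standard motional-narrowing (Redfield/Kivelson)
# three-line model: Lorentzian derivative lines at the isotropic resonance
# positions with mI-dependent widths A + B*mI + C*mI^2 computed from the g-
# and hyperfine-tensor anisotropies, B0 and tau_c.
#
# The slow engine is a partial-anisotropy-averaging lineshape: the residual
# (motionally unaveraged) fraction S(tau_c) of the tensor anisotropy is kept
# and powder-averaged over orientations, while the averaged fraction (1 - S)
# contributes motional Lorentzian broadening through the same Redfield
# coefficients. S(tau_c) = tau_c^2 / (tau_c^2 + tau_0^2) with tau_0 = 3 ns
# interpolates smoothly between the fast-motion limit (S -> 0) and the rigid
# powder limit (S -> 1), where the outer splitting converges to 2*A'zz.

.TAU0_NS <- 3            # anisotropy-averaging crossover time, ns
.FAST_SLOW_THRESHOLD <- 0.5   # ns, engine = "auto" switch
.RIGID_BASE_WIDTH <- 0.12     # mT, residual homogeneous width in the rigid limit
.WIDTH_FLOOR <- 0.02          # mT, numerical floor so powder sticks stay resolved

.orderS <- function(tauCNs) tauCNs^2 / (tauCNs^2 + .TAU0_NS^2)

# per-session cache of unit-normalized component simulations (the same
# library components are simulated on the same axis thousands of times in
# decomposition sweeps)
.simCache <- new.env(parent = emptyenv())

.componentKey <- function(component, fieldMT, mwFreqGHz, engine) {
  paste(component@label,
        paste(signif(c(component@gTensor, component@ATensor, component@tauC,
                       component@lwGauss, component@lwLorentz,
                       component@exchangeFreq, component@eulerDeg), 12),
              collapse = ","),
        length(fieldMT), signif(range(fieldMT), 12)[1],
        signif(range(fieldMT), 12)[2], signif(mwFreqGHz, 12), engine,
        sep = "|")
}

#' Fast-motion resonance field positions of a nitroxide triplet
#'
#' First-order positions of the three 14N hyperfine lines (mI = +1, 0, -1)
#' in the motional-narrowing limit: the centre line sits at
#' \eqn{B_0 = h\nu/(g_{iso}\mu_B)} and the mI = +/-1 lines are displaced by
#' -/+ aiso converted to field units.
#'
#' @param giso isotropic g value (> 0).
#' @param aiso isotropic hyperfine coupling (MHz).
#' @param mwFreqGHz microwave frequency (GHz, > 0).
#' @return numeric(3) of field positions in mT, sorted ascending.
#' @examples
#' resonancePositionsFast(2.0060, 44.1, 9.4)
#' @export
resonancePositionsFast <- function(giso, aiso, mwFreqGHz) {
  if (!is.finite(giso) || giso <= 0 || !is.finite(mwFreqGHz) || mwFreqGHz <= 0) {
    stop("invalid-parameter: giso and microwave frequency must be positive")
  }
  B0 <- centreField(giso, mwFreqGHz)
  aMT <- mhzToMilliTesla(aiso, giso)
  sort(B0 - c(+1, 0, -1) * aMT)
}

# Redfield linewidth coefficients (rad/s) for isotropic Brownian tumbling.
# Returns list(A, B, C) of the motional contribution to 1/T2(mI).
.redfieldCoefficients <- function(gTensor, ATensor, B0mT, tauCNs) {
  giso <- mean(gTensor)
  tau <- tauCNs * 1e-9
  B0 <- B0mT * 1e-3
  # axial measures of the anisotropies
  dGamma <- (.BOHR_MAGNETON / .HBAR) * (gTensor[3] - (gTensor[1] + gTensor[2]) / 2)
  b <- (4 * pi / 3) * (ATensor[3] - (ATensor[1] + ATensor[2]) / 2) * 1e6
  we <- .gammaE(giso) * B0
  j0 <- tau
  je <- tau / (1 + we^2 * tau^2)
  list(
    A = (4 / 45) * (dGamma * B0)^2 * (3 * j0 + 7 * je) / 7 + (b^2 / 20) * (3 * j0 + 7 * je) / 10,
    B = (4 / 15) * b * dGamma * B0 * (j0 + (3 / 4) * je) / 1.75,
    C = (b^2 / 8) * (j0 - (1 / 8) * je) / 1.125
  )
}

# convert a homogeneous rate 1/T2 (rad/s) to a peak-to-peak width in mT
.rateToPPmT <- function(rate, giso) {
  (2 / sqrt(3)) * rate / .gammaE(giso) * 1e3
}

# exchange frequency (MHz) -> extra Lorentzian pp width (mT)
.exchangeWidth <- function(exchangeFreqMHz, giso) {
  .rateToPPmT(2 * pi * exchangeFreqMHz * 1e6, giso)
}

#' Fast-motion peak-to-peak linewidths for the three hyperfine lines
#'
#' Motional-narrowing widths \eqn{\Delta B(m_I) = A + B m_I + C m_I^2}
#' computed from the tensor anisotropies, the centre field and tau_c, plus
#' the component's residual Lorentzian and exchange broadenings. Widths are
#' peak-to-peak of the derivative Lorentzian, in mT.
#'
#' @param component a \linkS4class{SpinComponent}.
#' @param B0mT centre field in mT.
#' @return named numeric(3) of widths for mI = +1, 0, -1 (all > 0). A
#'   warning flags tau_c beyond the fast-regime validity (> 1 ns); the slow
#'   engine should be used there.
#' @export
fastMotionLinewidths <- function(component, B0mT) {
  stopifnot(is(component, "SpinComponent"))
  if (component@tauC > 1) {
    warning("tau_c beyond fast-regime validity; use the slow engine")
  }
  co <- .redfieldCoefficients(component@gTensor, component@ATensor, B0mT,
                              component@tauC)
  giso <- gIso(component)
  mI <- c(1, 0, -1)
  motional <- .rateToPPmT(co$A + co$B * mI + co$C * mI^2, giso)
  w <- component@lwLorentz + .exchangeWidth(component@exchangeFreq, giso) +
    pmax(motional, 0) + .WIDTH_FLOOR
  names(w) <- c("mI+1", "mI0", "mI-1")
  w
}

# rotation matrix for ZYZ Euler angles in degrees (g frame -> A frame)
.eulerMatrix <- function(eulerDeg) {
  a <- eulerDeg[1] * pi / 180
  b <- eulerDeg[2] * pi / 180
  g <- eulerDeg[3] * pi / 180
  Rz1 <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz2 <- matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3, 3)
  Rz2 %*% Ry %*% Rz1
}

# orientation grid over the sphere: Gauss-Legendre in cos(beta), uniform phi
.orientationGrid <- function(nBeta = 60, nPhi = 36) {
  gl <- pracma::gaussLegendre(nBeta, -1, 1)
  phi <- seq(0, 2 * pi, length.out = nPhi + 1)[-(nPhi + 1)]
  ct <- rep(gl$x, times = nPhi)
  wt <- rep(gl$w, times = nPhi) / (2 * nPhi)   # weights sum to 1
  ph <- rep(phi, each = nBeta)
  st <- sqrt(pmax(0, 1 - ct^2))
  list(n = cbind(st * cos(ph), st * sin(ph), ct), w = wt)
}

# fast engine: three derivative Lorentzians + Gaussian convolution
.simulateFast <- function(component, fieldMT, mwFreqGHz) {
  giso <- gIso(component)
  pos <- resonancePositionsFast(giso, aIso(component), mwFreqGHz)
  # ascending field order corresponds to mI = +1, 0, -1 for a positive aiso
  widths <- fastMotionLinewidths(component, centreField(giso, mwFreqGHz))
  dB <- .gridStep(fieldMT)
  y <- numeric(length(fieldMT))
  for (i in 1:3) {
    y <- y + .dLorentzBinned(fieldMT, pos[i], widths[i], dB) / 3
  }
  y
}

# slow engine: partial-anisotropy-averaged powder lineshape
.simulateSlow <- function(component, fieldMT, mwFreqGHz,
                          nBeta = 60, nPhi = 36) {
  S <- .orderS(component@tauC)
  giso <- gIso(component)
  aiso <- aIso(component)
  gEff <- giso + S * (component@gTensor - giso)
  AEff <- aiso + S * (component@ATensor - aiso)
  grid <- .orientationGrid(nBeta, nPhi)
  n <- grid$n
  # direction cosines in the hyperfine frame (tilted by the Euler angles)
  m <- n %*% t(.eulerMatrix(component@eulerDeg))
  gOri <- sqrt(n[, 1]^2 * gEff[1]^2 + n[, 2]^2 * gEff[2]^2 + n[, 3]^2 * gEff[3]^2)
  AOri <- sqrt(m[, 1]^2 * AEff[1]^2 + m[, 2]^2 * AEff[2]^2 + m[, 3]^2 * AEff[3]^2)
  # residual motional broadening through the averaged anisotropy fraction
  co <- .redfieldCoefficients(component@gTensor, component@ATensor,
                              centreField(giso, mwFreqGHz), component@tauC)
  dB <- .gridStep(fieldMT)
  pad <- 0.25 * (max(fieldMT) - min(fieldMT))
  work <- seq(min(fieldMT) - pad, max(fieldMT) + pad, by = dB)
  absn <- numeric(length(work))
  exch <- .exchangeWidth(component@exchangeFreq, giso)
  for (mI in c(1, 0, -1)) {
    Bres <- centreField(gOri, mwFreqGHz) - mI * mhzToMilliTesla(AOri, gOri)
    stick <- .linearBin(work, Bres, grid$w)
    motional <- .rateToPPmT(co$A + co$B * mI + co$C * mI^2, giso)
    wpp <- component@lwLorentz + exch + (1 - S) * max(motional, 0) +
      S * .RIGID_BASE_WIDTH + .WIDTH_FLOOR
    # unit-mass absorption Lorentzian kernel: convolving the orientation
    # sticks with it conserves the absorption area exactly, and the
    # derivative is taken numerically afterwards
    gam <- sqrt(3) * wpp / 2
    nk <- max(3L, ceiling(25 * wpp / dB))
    xk <- seq(-nk, nk) * dB
    kern <- 1 / (xk^2 + gam^2)
    kern <- kern / sum(kern)
    absn <- absn + .convolveUniform(stick, kern) / 3
  }
  y <- numeric(length(work))
  y[2:(length(work) - 1)] <- (absn[3:length(work)] -
                                absn[1:(length(work) - 2)]) / (2 * dB)
  idx <- round((fieldMT - work[1]) / dB) + 1L
  y[idx] / dB  # per-bin mass -> density
}

# truncation diagnostic: fraction of absorption mass in the outermost
# edgeFrac of the window, and whether the absorption returns to baseline at
# the high-field edge (it does not when the pattern is cut off)
.edgeMass <- function(fieldMT, y, edgeFrac = 0.02) {
  absn <- .cumtrapz(fieldMT, y)
  tot <- .trapz(fieldMT, abs(absn))
  if (tot <= 0 || max(abs(absn)) == 0) return(1)
  span <- max(fieldMT) - min(fieldMT)
  lo <- fieldMT <= min(fieldMT) + edgeFrac * span
  hi <- fieldMT >= max(fieldMT) - edgeFrac * span
  edges <- (.trapz(fieldMT[lo], abs(absn[lo])) +
              .trapz(fieldMT[hi], abs(absn[hi]))) / tot
  endFrac <- abs(absn[length(absn)]) / max(abs(absn))
  max(edges, endFrac / 3)
}

#' Simulate the first-derivative spectrum of a single component
#'
#' Dispatches between the fast-motion and the slow-motion engine by tau_c
#' (threshold 0.5 ns in \code{engine = "auto"}). Gaussian residual
#' broadening and, optionally, sinusoidal field modulation are applied as
#' unit-area post-convolutions, so the double integral is conserved.
#'
#' @param component a \linkS4class{SpinComponent}.
#' @param fieldMT uniform, strictly increasing field axis (mT) covering the
#'   spectrum.
#' @param mwFreqGHz microwave frequency (GHz).
#' @param engine "auto", "fast" or "slow".
#' @param normalize "unit-spins" (double integral scaled to 1) or "none".
#' @param modAmpMT optional field-modulation amplitude (mT); 0 disables the
#'   pseudo-modulation convolution (the default, the 0.1 mT experimental
#'   modulation being small against the linewidths).
#' @param edgeTol maximal tolerated fraction of absorption mass in the
#'   outermost 2 percent of the window before a truncation error is raised.
#'   The default (0.05) accommodates the slight clipping of rigid-limit
#'   powder wings on the standard 10 mT acquisition window while still
#'   catching grossly truncated spectra.
#' @return intensity vector on \code{fieldMT}.
#' @examples
#' B <- seq(332.5, 342.5, length.out = 1024)
#' y <- simulateComponent(spinComponent("free", tauC = 0.1, lwGauss = 0.13), B, 9.4)
#' @export
simulateComponent <- function(component, fieldMT, mwFreqGHz = 9.47,
                              engine = c("auto", "fast", "slow"),
                              normalize = c("unit-spins", "none"),
                              modAmpMT = 0, edgeTol = 0.05) {
  engine <- match.arg(engine)
  normalize <- match.arg(normalize)
  stopifnot(is(component, "SpinComponent"))
  if (engine == "auto") {
    engine <- if (component@tauC <= .FAST_SLOW_THRESHOLD) "fast" else "slow"
  }
  useCache <- normalize == "unit-spins" && modAmpMT == 0
  if (useCache) {
    key <- .componentKey(component, fieldMT, mwFreqGHz, engine)
    hit <- .simCache[[key]]
    if (!is.null(hit)) return(hit)
  }
  y <- if (engine == "fast") {
    .simulateFast(component, fieldMT, mwFreqGHz)
  } else {
    .simulateSlow(component, fieldMT, mwFreqGHz)
  }
  dB <- .gridStep(fieldMT)
  if (component@lwGauss > 0) {
    y <- .convolveUniform(y, .gaussianKernel(component@lwGauss, dB))
  }
  if (modAmpMT > 0) {
    y <- .convolveUniform(y, .modulationKernel(modAmpMT, dB))
  }
  if (.edgeMass(fieldMT, y) > edgeTol) {
    stop("window error: spectral weight at the field-window edges exceeds tolerance")
  }
  if (normalize == "unit-spins") {
    di <- doubleIntegral(fieldMT, y)
    if (!is.finite(di) || di <= 0) stop("window error: non-positive double integral")
    y <- y / di
  }
  if (useCache) .simCache[[key]] <- y
  y
}

#' Outer-extrema splitting of a derivative spectrum
#'
#' Field separation between the lowest-field significant local maximum and
#' the highest-field significant local minimum of a derivative trace. In
#' the rigid limit of a nitroxide this converges to \eqn{2 A'_{zz}} in
#' field units, the classic read-out of the z hyperfine extent.
#'
#' @param fieldMT field axis (mT).
#' @param intensity derivative amplitudes.
#' @param prominence minimal amplitude of an extremum, as a fraction of the
#'   global maximum absolute amplitude (default 0.05).
#' @return separation in mT.
#' @export
outerExtremaSplitting <- function(fieldMT, intensity, prominence = 0.05) {
  th <- prominence * max(abs(intensity))
  n <- length(intensity)
  i <- 2:(n - 1)
  isMax <- intensity[i] > intensity[i - 1] & intensity[i] >= intensity[i + 1] &
    intensity[i] > th
  isMin <- intensity[i] < intensity[i - 1] & intensity[i] <= intensity[i + 1] &
    intensity[i] < -th
  if (!any(isMax) || !any(isMin)) stop("no significant extrema found")
  lowMax <- fieldMT[i[isMax][1]]
  highMin <- fieldMT[rev(i[isMin])[1]]
  highMin - lowMax
}

# arcsine field distribution of a sinusoidal modulation of amplitude a (pp)
.modulationKernel <- function(modAmpMT, dB) {
  half <- modAmpMT / 2
  nk <- max(1L, floor(half / dB))
  x <- seq(-nk, nk) * dB
  k <- 1 / sqrt(pmax(half^2 - x^2, (0.5 * dB)^2))
  k / sum(k)
}

#' Simulate a weighted three-state mixture spectrum
#'
#' The mixture is the weight-linear superposition of unit-spins-normalized
#' single-component spectra, mirroring how measured spectra decompose into
#' free, intermediately bound and strongly bound species.
#'
#' @param components list of \linkS4class{SpinComponent}s.
#' @param weights nonnegative fractions summing to 1 (within 1e-9).
#' @param fieldMT field axis (mT).
#' @param mwFreqGHz microwave frequency (GHz).
#' @param temperatureK stored in the trace metadata.
#' @param meta metadata list for the resulting trace.
#' @param engine forwarded to \code{\link{simulateComponent}}.
#' @return a \linkS4class{SpectrumTrace}.
#' @export
simulateMixture <- function(components, weights, fieldMT, mwFreqGHz = 9.47,
                            temperatureK = 310.15, meta = list(),
                            engine = "auto") {
  if (length(components) != length(weights)) {
    stop("components and weights must have the same length")
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-9) {
    stop(sprintf("normalization error: weights must be >= 0 and sum to 1 (sum = %.12g)",
                 sum(weights)))
  }
  y <- numeric(length(fieldMT))
  for (i in seq_along(components)) {
    if (weights[i] > 0) {
      y <- y + weights[i] *
        simulateComponent(components[[i]], fieldMT, mwFreqGHz, engine = engine)
    }
  }
  spectrumTrace(fieldMT, y, mwFreqGHz = mwFreqGHz, temperatureK = temperatureK,
                meta = meta)
}
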
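# Small numerical helpers shared by the simulation and fitting code.

# trapezoidal integral of y over x
.trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# cumulative trapezoidal integral, anchored at 0 on the left
.cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2))
}

#' Double integral of a first-derivative spectrum
#'
#' Integrates a derivative-mode EPR trace twice over its field window. The
#' result is proportional to the number of contributing spins and is the
#' weighting used when component fractions are read off a decomposition.
#'
#' @param fieldMT field axis in mT, strictly increasing.
#' @param intensity first-derivative amplitudes.
#' @return scalar double integral (arbitrary units x mT^2).
#' @export
doubleIntegral <- function(fieldMT, intensity) {
  absorption <- .cumtrapz(fieldMT, intensity)
  .trapz(fieldMT, absorption)
}

# convolve a trace with a unit-area kernel sampled on the same (uniform) grid,
# zero-padded FFT convolution; kernel is centred
.convolveUniform <- function(y, kernel) {
  n <- length(y)
  m <- length(kernel)
  nfft <- stats::nextn(n + m, 2)
  ypad <- c(y, numeric(nfft - n))
  kpad <- c(kernel, numeric(nfft - m))
  conv <- Re(stats::fft(stats::fft(ypad) * stats::fft(kpad), inverse = TRUE)) / nfft
  shift <- (m - 1) %/% 2
  conv[(1 + shift):(n + shift)]
}

# unit-area Gaussian kernel with peak-to-peak derivative width wpp (mT) on a
# uniform grid of step dB; sigma = wpp / 2 for the first-derivative convention
.gaussianKernel <- function(wpp, dB, halfwidthSigmas = 6) {
  sigma <- wpp / 2
  nk <- max(1L, ceiling(halfwidthSigmas * sigma / dB))
  x <- seq(-nk, nk) * dB
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# first-derivative Lorentzian line, unit absorption area, pp width wpp (mT).
# For a Lorentzian with HWHM g the derivative extrema are at +-g/sqrt(3),
# so wpp = 2*g/sqrt(3)  =>  g = sqrt(3) * wpp / 2
.dLorentz <- function(B, B0, wpp) {
  g <- sqrt(3) * wpp / 2
  x <- B - B0
  -2 * g * x / (pi * (x^2 + g^2)^2)
}

# bin-averaged derivative Lorentzian: exact mean of L'(B) over each grid
# bin, i.e. the difference quotient of the absorption L(B) = (g/pi)/(x^2+g^2).
# Keeps the first integral of sharp lines exact on coarse grids.
.dLorentzBinned <- function(B, B0, wpp, dB) {
  g <- sqrt(3) * wpp / 2
  L <- function(x) (g / pi) / ((x - B0)^2 + g^2)
  (L(B + dB / 2) - L(B - dB / 2)) / dB
}

# uniform-grid check
.gridStep <- function(x) {
  d <- diff(x)
  if (any(d <= 0)) stop("field axis must be strictly increasing")
  mean(d)
}

# deposit weights onto a uniform grid with linear (first-order) binning
.linearBin <- function(grid, positions, weights) {
  dB <- grid[2] - grid[1]
  acc <- numeric(length(grid))
  idx <- (positions - grid[1]) / dB
  lo <- floor(idx)
  frac <- idx - lo
  keep <- lo >= 0 & lo <= length(grid) - 2
  lo <- lo[keep]; frac <- frac[keep]; w <- weights[keep]
  if (length(lo)) {
    acc_lo <- tapply(w * (1 - frac), lo, sum)
    acc_hi <- tapply(w * frac, lo + 1, sum)
    acc[as.integer(names(acc_lo)) + 1L] <- acc[as.integer(names(acc_lo)) + 1L] + acc_lo
    acc[as.integer(names(acc_hi)) + 1L] <- acc[as.integer(names(acc_hi)) + 1L] + acc_hi
  }
  acc
}
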
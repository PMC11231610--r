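# Physical constants (CODATA 2018) and unit conversions used throughout.
# Magnetic fields are in mT, hyperfine couplings in MHz, frequencies in GHz,
# correlation times in ns, temperatures in K, concentrations in uM.

.PLANCK_H <- 6.62607015e-34      # J s
.BOHR_MAGNETON <- 9.2740100783e-24  # J / T
.HBAR <- .PLANCK_H / (2 * pi)
.GAS_CONSTANT <- 8.314           # J / (mol K), convention used in report tables

#' Convert a frequency in MHz to a field offset in mT at a given g value
#'
#' A hyperfine coupling of \eqn{a} MHz corresponds to a field-domain
#' splitting of \eqn{a \cdot h / (g \mu_B)} when the spectrum is swept in
#' field at fixed microwave frequency.
#'
#' @param mhz frequency in MHz.
#' @param g dimensionless g value (> 0).
#' @return field offset in mT.
#' @export
mhzToMilliTesla <- function(mhz, g) {
  if (any(!is.finite(g)) || any(g <= 0)) {
    stop("invalid-parameter: g must be positive and finite")
  }
  mhz * .PLANCK_H * 1e6 / (g * .BOHR_MAGNETON) * 1e3
}

#' Centre resonance field for a given g value and microwave frequency
#'
#' @param g dimensionless g value.
#' @param mwFreqGHz microwave frequency in GHz.
#' @return field in mT where \eqn{h\nu = g \mu_B B}.
#' @export
centreField <- function(g, mwFreqGHz) {
  if (any(g <= 0) || any(mwFreqGHz <= 0)) {
    stop("invalid-parameter: g and microwave frequency must be positive")
  }
  .PLANCK_H * mwFreqGHz * 1e9 / (g * .BOHR_MAGNETON) * 1e3
}

# electron gyromagnetic ratio at g, rad / (s T)
.gammaE <- function(g) g * .BOHR_MAGNETON / .HBAR
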
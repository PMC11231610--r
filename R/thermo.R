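# Mass-action and van't Hoff binding thermodynamics: convert component
# fractions into concentrations, equilibrium constants and Gibbs energies
# for the transitions F-T, F-I, F-S and I-S, with first-order error
# propagation.
#
# All transitions use the same 1:1 mass-action form
#   KD = [P_free][L_free] / [PL],  [PL] = Phi_bound * cL,
#   [P_free] = cP - [PL]
# and the van't Hoff relation Delta G = -R T ln KA. The intermediate-to-
# strong transition is a dimensionless population ratio K_IS = [S]/[I].
# EPR-derived tables are evaluated at 310.15 K (37 C); MST-derived
# quantities at 295.15 K (22 C) - the temperature that reproduces the
# printed MST Gibbs energies even though MST was measured at 25 C (flagged
# here for users).

#' State concentrations from component fractions
#'
#' \eqn{[x] = \Phi_x \cdot c_{L,total}}: each spectral fraction times the
#' total ligand concentration.
#'
#' @param phi named fractions (free, intermediate, strong) summing to 1.
#' @param cLigandUM total ligand concentration (uM).
#' @return named numeric of concentrations (uM); sums to \code{cLigandUM}.
#' @examples
#' concentrationsFromFractions(c(free = 0.27, intermediate = 0.55, strong = 0.18), 20)
#' @export
concentrationsFromFractions <- function(phi, cLigandUM) {
  stopifnot(cLigandUM >= 0, all(phi >= 0))
  phi * cLigandUM
}

#' Dissociation constant from a bound fraction (1:1 mass action)
#'
#' @param cProteinUM total protein concentration (uM).
#' @param cLigandUM total ligand concentration (uM).
#' @param phiBound bound fraction of the ligand, strictly between 0 and
#'   \code{min(1, cProteinUM / cLigandUM)}.
#' @return KD in uM.
#' @examples
#' kdFromMassAction(20, 20, 0.722)  # 2.14 uM
#' @export
kdFromMassAction <- function(cProteinUM, cLigandUM, phiBound) {
  if (phiBound <= 0) stop("no-binding error: KD undefined for phi_bound = 0")
  if (phiBound >= min(1, cProteinUM / cLigandUM)) {
    stop("stoichiometry error: bound fraction exceeds available protein or ligand")
  }
  pl <- phiBound * cLigandUM
  (cProteinUM - pl) * (cLigandUM - pl) / pl
}

#' Bound fraction from a dissociation constant (inverse of the mass action)
#'
#' Exact quadratic root of the 1:1 binding equation lying in [0, 1];
#' round-trips with \code{\link{kdFromMassAction}} to high precision.
#'
#' @param cProteinUM total protein concentration (uM).
#' @param cLigandUM total ligand concentration (uM).
#' @param kdUM dissociation constant (uM).
#' @return bound fraction of the ligand.
#' @export
phiFromKd <- function(cProteinUM, cLigandUM, kdUM) {
  if (cLigandUM <= 0) return(0)
  s <- cProteinUM + cLigandUM + kdUM
  pl <- (s - sqrt(s^2 - 4 * cProteinUM * cLigandUM)) / 2
  pl / cLigandUM
}

#' Gibbs energy of association from an equilibrium constant
#'
#' van't Hoff relation \eqn{\Delta G = -R T \ln K_A} in kJ/mol, with
#' R = 8.314 J/(mol K). Applies equally to a molar association constant
#' (1/KD in M) and to a dimensionless population ratio.
#'
#' @param KA association constant (M^-1) or dimensionless ratio, > 0.
#' @param temperatureK temperature (K), > 0.
#' @return Gibbs energy in kJ/mol (negative for KA > 1).
#' @examples
#' gibbsFromK(1 / 3.5e-6, 295.15)  # -30.8 kJ/mol
#' @export
gibbsFromK <- function(KA, temperatureK) {
  if (any(KA <= 0)) stop("domain error: KA must be positive")
  if (any(temperatureK <= 0)) stop("domain error: temperature must be positive")
  -.GAS_CONSTANT * temperatureK * log(KA) / 1000
}

#' Equilibrium constants and Gibbs energies for all three-state transitions
#'
#' Builds the four transitions from one binding point: F-T (total bound,
#' from Phi_I + Phi_S), F-I and F-S (each via the same 1:1 mass action),
#' and I-S as the dimensionless ratio [S]/[I]. Transitions whose component
#' is absent are marked undefined (NA), mirroring report tables where such
#' fields cannot be calculated. For I-S the Gibbs energy is reported along
#' two routes: directly from K_IS and as the chain difference
#' dG(F-S) - dG(F-I); the two need not agree when the three fractions do
#' not share one consistent mass-action scheme, so both are kept.
#'
#' @param cProteinUM total protein concentration (uM).
#' @param cLigandUM total ligand concentration (uM).
#' @param phi named fractions (free, intermediate, strong).
#' @param temperatureK temperature for the Gibbs energies (K); 310.15 K for
#'   EPR-derived tables.
#' @param phiError optional absolute error on the fractions (scalar,
#'   RMSD-rule); propagated to all derived quantities when given.
#' @return data.frame with one row per transition (F-T, F-I, F-S, I-S) and
#'   columns KD_uM, KA_perM, lnKA, dG_kJ_mol (+ errors when requested,
#'   and dG_chain_kJ_mol for the I-S row).
#' @export
equilibriumConstantsThreeState <- function(cProteinUM, cLigandUM, phi,
                                           temperatureK = 310.15,
                                           phiError = NULL) {
  need <- c("free", "intermediate", "strong")
  if (!all(need %in% names(phi))) {
    stop("phi must be named with 'free', 'intermediate', 'strong'")
  }
  phiI <- phi[["intermediate"]]
  phiS <- phi[["strong"]]
  if (phiI == 0 && phiS > 0) {
    stop("K_IS undefined error: zero intermediate with nonzero strong component")
  }
  phis <- c("F-T" = phiI + phiS, "F-I" = phiI, "F-S" = phiS)

  rows <- lapply(names(phis), function(tr) {
    p <- phis[[tr]]
    if (p <= 0 || p >= min(1, cProteinUM / cLigandUM)) {
      return(data.frame(transition = tr, KD_uM = NA_real_, KA_perM = NA_real_,
                        lnKA = NA_real_, dG_kJ_mol = NA_real_))
    }
    kd <- kdFromMassAction(cProteinUM, cLigandUM, p)
    ka <- 1 / (kd * 1e-6)
    data.frame(transition = tr, KD_uM = kd, KA_perM = ka, lnKA = log(ka),
               dG_kJ_mol = gibbsFromK(ka, temperatureK))
  })
  tab <- do.call(rbind, rows)

  kIS <- if (phiI > 0) phiS / phiI else NA_real_
  dgIS <- if (!is.na(kIS) && kIS > 0) gibbsFromK(kIS, temperatureK) else NA_real_
  isRow <- data.frame(transition = "I-S", KD_uM = NA_real_,
                      KA_perM = NA_real_,
                      lnKA = if (!is.na(kIS) && kIS > 0) log(kIS) else NA_real_,
                      dG_kJ_mol = dgIS)
  tab <- rbind(tab, isRow)
  tab$K_IS <- c(NA, NA, NA, kIS)
  tab$dG_chain_kJ_mol <- c(NA, NA, NA,
                           tab$dG_kJ_mol[3] - tab$dG_kJ_mol[2])

  if (!is.null(phiError)) {
    err <- propagateErrors(cProteinUM, cLigandUM, phi, phiError, temperatureK)
    tab <- merge(tab, err, by = "transition", sort = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' First-order error propagation from fraction errors to thermo quantities
#'
#' Propagates an absolute fraction error through the mass-action and
#' van't Hoff chain: \eqn{\sigma_{KD} = |dKD/d\Phi| \sigma_\Phi},
#' \eqn{\sigma_{lnKA} = \sigma_{KD}/KD},
#' \eqn{\sigma_{\Delta G} = R T \sigma_{lnKA}/1000}. For the I-S ratio the
#' two fraction errors combine in quadrature.
#'
#' @param cProteinUM,cLigandUM total concentrations (uM).
#' @param phi named fractions (free, intermediate, strong).
#' @param phiError absolute error applied to each fraction.
#' @param temperatureK temperature (K).
#' @return data.frame with transition, sd_KD_uM, sd_lnKA, sd_dG_kJ_mol.
#' @export
propagateErrors <- function(cProteinUM, cLigandUM, phi, phiError,
                            temperatureK = 310.15) {
  phiI <- phi[["intermediate"]]
  phiS <- phi[["strong"]]
  phis <- c("F-T" = phiI + phiS, "F-I" = phiI, "F-S" = phiS)
  rows <- lapply(names(phis), function(tr) {
    p <- phis[[tr]]
    if (p <= 0 || p >= min(1, cProteinUM / cLigandUM)) {
      return(data.frame(transition = tr, sd_KD_uM = NA_real_,
                        sd_lnKA = NA_real_, sd_dG_kJ_mol = NA_real_))
    }
    x <- p * cLigandUM                       # bound ligand, uM
    kd <- kdFromMassAction(cProteinUM, cLigandUM, p)
    # KD(x) = cP*cL/x - (cP + cL) + x  =>  dKD/dx = 1 - cP*cL/x^2
    dKDdPhi <- abs((1 - cProteinUM * cLigandUM / x^2) * cLigandUM)
    sdKD <- dKDdPhi * phiError
    sdLn <- sdKD / kd
    data.frame(transition = tr, sd_KD_uM = sdKD, sd_lnKA = sdLn,
               sd_dG_kJ_mol = .GAS_CONSTANT * temperatureK * sdLn / 1000)
  })
  tab <- do.call(rbind, rows)
  sdIS <- if (phiI > 0 && phiS > 0) {
    k <- phiS / phiI
    sdK <- k * sqrt((phiError / phiS)^2 + (phiError / phiI)^2)
    c(sdK, sdK / k, .GAS_CONSTANT * temperatureK * (sdK / k) / 1000)
  } else rep(NA_real_, 3)
  rbind(tab, data.frame(transition = "I-S", sd_KD_uM = sdIS[1],
                        sd_lnKA = sdIS[2], sd_dG_kJ_mol = sdIS[3]))
}

#' MST-style thermodynamic chain from a dissociation constant
#'
#' Reproduces the report layout KD -> KA (uM^-1 and M^-1) -> lnKA -> dG at
#' a given temperature, with first-order error propagation from an
#' absolute KD error.
#'
#' @param kdUM dissociation constant (uM).
#' @param temperatureK temperature (K); 295.15 K for MST-derived rows.
#' @param kdErrUM optional absolute KD error (uM).
#' @return one-row data.frame with KD_uM, KA_perUM, KA_perM, lnKA,
#'   dG_kJ_mol (and sd_ columns when an error is given).
#' @export
thermoChainFromKd <- function(kdUM, temperatureK = 295.15, kdErrUM = NULL) {
  stopifnot(kdUM > 0)
  ka <- 1 / (kdUM * 1e-6)
  out <- data.frame(KD_uM = kdUM, KA_perUM = 1 / kdUM, KA_perM = ka,
                    lnKA = log(ka),
                    dG_kJ_mol = gibbsFromK(ka, temperatureK))
  if (!is.null(kdErrUM)) {
    sdLn <- kdErrUM / kdUM
    out$sd_KA_perM <- ka * sdLn
    out$sd_lnKA <- sdLn
    out$sd_dG_kJ_mol <- .GAS_CONSTANT * temperatureK * sdLn / 1000
  }
  out
}
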
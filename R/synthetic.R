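# Synthetic ground-truth generator: three-state binding fractions with
# mass-action concentration dependence and van't Hoff temperature
# dependence, rendered into noisy spectra through the same forward model
# the decomposition fits. Presets echo the qualitative behaviours of the
# three isoforms (steep high-affinity binding, weak binding, sub-unity
# plateau) and the two high-temperature narratives (ligand release vs
# trap-and-destruction of the radical).

#' Ground-truth parameters for the synthetic generator
#'
#' The three-state truth model: free ligand binds with a 1:1 mass-action
#' constant \code{K_I} (uM, dissociation, referenced to 310.15 K) into the
#' intermediate state, and bound ligand partitions between strong and
#' intermediate with the dimensionless ratio \code{K_IS} = [S]/[I]. The
#' total-bound equilibrium then follows an effective dissociation constant
#' \code{K_I / (1 + K_IS)}. Temperature enters through van't Hoff
#' enthalpies \code{dH_I} (association F->I) and \code{dH_IS} (I->S), both
#' kJ/mol, anchored at 310.15 K.
#'
#' @param K_I free-intermediate dissociation constant at 310.15 K (uM).
#' @param K_IS strong/intermediate population ratio at 310.15 K.
#' @param plateau maximal total-bound fraction (0, 1].
#' @param dH_I van't Hoff enthalpy of the association F->I (kJ/mol).
#' @param dH_IS van't Hoff enthalpy of I->S (kJ/mol).
#' @param noiseSnr signal-to-noise ratio of generated spectra
#'   (peak-to-peak amplitude / noise SD); \code{Inf} for noiseless.
#' @param seed integer seed; fixed seed means byte-identical datasets.
#' @param preset one of "fabp3_like", "fabp4_like", "fabp5_like",
#'   "release", "destroy", "flat"; presets fill all other arguments unless
#'   they are overridden explicitly.
#' @param protein,probe which packaged component library renders the
#'   spectra.
#' @return list of class "truthParams".
#' @export
truthParams <- function(K_I = 2.6, K_IS = 0.33, plateau = 1,
                        dH_I = -50, dH_IS = -60, noiseSnr = Inf,
                        seed = 1L,
                        preset = c("fabp3_like", "fabp4_like", "fabp5_like",
                                   "release", "destroy", "flat"),
                        protein = NULL, probe = "5-DSA") {
  preset <- match.arg(preset)
  p <- switch(preset,
    fabp3_like = list(K_I = 2.6, K_IS = 0.33, plateau = 1.0,
                      dH_I = -110, dH_IS = -40, protein = "FABP3"),
    fabp4_like = list(K_I = 12.5, K_IS = 0.22, plateau = 0.97,
                      dH_I = -110, dH_IS = -40, protein = "FABP4"),
    fabp5_like = list(K_I = 2.9, K_IS = 0.45, plateau = 0.948,
                      dH_I = -18, dH_IS = -40, protein = "FABP5"),
    release = list(K_I = 2.6, K_IS = 0.33, plateau = 1.0,
                   dH_I = -110, dH_IS = -40, protein = "FABP3"),
    destroy = list(K_I = 2.6, K_IS = 0.33, plateau = 1.0,
                   dH_I = -18, dH_IS = -40, protein = "FABP5"),
    flat = list(K_I = 2.6, K_IS = 0.33, plateau = 1.0,
                dH_I = 0, dH_IS = 0, protein = "FABP3")
  )
  cl <- as.list(match.call())[-1]
  for (nm in c("K_I", "K_IS", "plateau", "dH_I", "dH_IS")) {
    if (nm %in% names(cl)) p[[nm]] <- get(nm)
  }
  if (!is.null(protein)) p$protein <- protein
  stopifnot(p$K_I > 0, p$K_IS >= 0, p$plateau > 0, p$plateau <= 1)
  structure(list(K_I = p$K_I, K_IS = p$K_IS, plateau = p$plateau,
                 dH_I = p$dH_I, dH_IS = p$dH_IS, noiseSnr = noiseSnr,
                 seed = as.integer(seed), preset = preset,
                 protein = p$protein, probe = probe),
            class = "truthParams")
}

# van't Hoff-shifted constants at temperature T (anchor 310.15 K)
.truthConstantsAtT <- function(params, temperatureK) {
  Tref <- 310.15
  R <- .GAS_CONSTANT
  # association K_A scales as exp(-dH/R * (1/T - 1/Tref)); K_I is a
  # dissociation constant, so it scales inversely
  shiftI <- exp(-(params$dH_I * 1000 / R) * (1 / temperatureK - 1 / Tref))
  shiftIS <- exp(-(params$dH_IS * 1000 / R) * (1 / temperatureK - 1 / Tref))
  list(K_I = params$K_I / shiftI, K_IS = params$K_IS * shiftIS)
}

#' Ground-truth fractions at one condition
#'
#' Solves the 1:1 mass action for total bound ligand with the effective
#' dissociation constant \code{K_I / (1 + K_IS)} (exact quadratic root),
#' scales by the plateau, and splits bound into strong/intermediate by
#' \code{K_IS}. Deterministic.
#'
#' @param cProteinUM protein concentration (uM).
#' @param cLigandUM ligand concentration (uM).
#' @param params a \code{\link{truthParams}} object.
#' @param temperatureK temperature (K); defaults to the 310.15 K anchor.
#' @return named fractions (free, intermediate, strong) summing to 1.
#' @export
truthFractions <- function(cProteinUM, cLigandUM, params,
                           temperatureK = 310.15) {
  k <- .truthConstantsAtT(params, temperatureK)
  kdEff <- k$K_I / (1 + k$K_IS)
  phiB <- params$plateau * phiFromKd(cProteinUM, cLigandUM, kdEff)
  phiS <- phiB * k$K_IS / (1 + k$K_IS)
  phiI <- phiB - phiS
  c(free = 1 - phiB, intermediate = phiI, strong = phiS)
}

# render one noisy trace for given truth weights
.renderTrace <- function(weights, params, fieldMT, mwFreqGHz, temperatureK,
                         cProteinUM, cLigandUM, components, rng) {
  tr <- simulateMixture(components, weights, fieldMT, mwFreqGHz,
                        temperatureK = temperatureK,
                        meta = list(protein = params$protein,
                                    cProteinUM = cProteinUM,
                                    ligand = params$probe,
                                    cLigandUM = cLigandUM))
  if (is.finite(params$noiseSnr)) {
    pp <- max(tr@intensity) - min(tr@intensity)
    tr@intensity <- tr@intensity +
      stats::rnorm(length(tr@intensity), 0, pp / params$noiseSnr)
  }
  tr
}

#' Synthetic concentration series
#'
#' Generates the default acquisition grid (protein 200, 100, 50, 35, 25,
#' 20, 15, 10 and 5 uM at fixed 20 uM ligand) plus a protein-free
#' reference, rendering each truth mixture through the packaged component
#' library with additive white Gaussian noise at the requested SNR.
#'
#' @param params a \code{\link{truthParams}} object (its seed drives the
#'   noise).
#' @param cPGridUM protein concentrations (uM).
#' @param cLigandUM ligand concentration (uM, default 20).
#' @param fieldMT field axis.
#' @param mwFreqGHz microwave frequency (GHz).
#' @param temperatureK temperature (K).
#' @return list with one element per condition (including cP = 0), each a
#'   list(cProteinUM, cLigandUM, truth, trace).
#' @export
synthConcentrationSeries <- function(params,
                                     cPGridUM = c(200, 100, 50, 35, 25, 20,
                                                  15, 10, 5),
                                     cLigandUM = 20,
                                     fieldMT = defaultFieldAxis(),
                                     mwFreqGHz = 9.47,
                                     temperatureK = 310.15) {
  stopifnot(inherits(params, "truthParams"), length(cPGridUM) > 0)
  components <- fabpComponents(params$protein, params$probe)
  grid <- c(cPGridUM, 0)
  old <- globalenv()$.Random.seed
  set.seed(params$seed)
  out <- lapply(grid, function(cp) {
    w <- if (cp > 0) truthFractions(cp, cLigandUM, params, temperatureK) else
      c(free = 1, intermediate = 0, strong = 0)
    list(cProteinUM = cp, cLigandUM = cLigandUM, truth = w,
         trace = .renderTrace(w, params, fieldMT, mwFreqGHz, temperatureK,
                              cp, cLigandUM, components))
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Synthetic temperature series
#'
#' Renders truth fractions over a temperature grid with van't Hoff
#' temperature dependence; for default parameters the intermediate
#' fraction passes through an interior maximum near physiological
#' temperature. The "destroy" preset additionally decays the total
#' spectral intensity above 328 K (radical loss in the denaturing
#' protein), while "release" uses a strongly exothermic association so
#' the free fraction rises at high temperature.
#'
#' @param params a \code{\link{truthParams}} object.
#' @param TGridK sorted temperature grid (K).
#' @param cProteinUM,cLigandUM concentrations (uM).
#' @param fieldMT field axis; \code{mwFreqGHz} microwave frequency.
#' @return list per temperature: list(temperatureK, truth, integralScale,
#'   trace).
#' @export
synthTemperatureSeries <- function(params,
                                   TGridK = seq(273.15, 363.15, by = 5),
                                   cProteinUM = 100, cLigandUM = 20,
                                   fieldMT = defaultFieldAxis(),
                                   mwFreqGHz = 9.47) {
  stopifnot(inherits(params, "truthParams"), !is.unsorted(TGridK))
  components <- fabpComponents(params$protein, params$probe)
  old <- globalenv()$.Random.seed
  set.seed(params$seed + 1L)
  out <- lapply(TGridK, function(Tk) {
    w <- truthFractions(cProteinUM, cLigandUM, params, Tk)
    scale <- if (params$preset == "destroy" && Tk > 328.15) {
      max(0.3, 1 - 0.02 * (Tk - 328.15))
    } else 1
    tr <- .renderTrace(w, params, fieldMT, mwFreqGHz, Tk, cProteinUM,
                       cLigandUM, components)
    tr@intensity <- tr@intensity * scale
    list(temperatureK = Tk, truth = w, integralScale = scale, trace = tr)
  })
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Synthetic MST dose-response series
#'
#' A 12-point twofold dilution from 200 uM protein at 80 nM labelled
#' ligand, duplicated, with an affine Fnorm transform and additive
#' Gaussian noise.
#'
#' @param kdUM true dissociation constant (uM).
#' @param noiseSd noise SD on the bound-fraction scale.
#' @param seed integer seed.
#' @param nDilutions number of twofold dilutions (default 12).
#' @param topUM highest protein concentration (uM).
#' @param ligandConcNM labelled-ligand concentration (nM).
#' @param base,amp affine transform applied to the bound fraction.
#' @param replicates number of replicates per concentration.
#' @return an \linkS4class{MstSeries}.
#' @export
synthMstSeries <- function(kdUM = 3.5, noiseSd = 0, seed = 1L,
                           nDilutions = 12, topUM = 200, ligandConcNM = 80,
                           base = 0.85, amp = 0.25, replicates = 2) {
  cp <- topUM / 2^(0:(nDilutions - 1))
  cp <- rep(cp, each = replicates)
  f <- boundFraction1to1(cp, kdUM, ligandConcNM / 1000)
  old <- globalenv()$.Random.seed
  set.seed(seed)
  y <- base + amp * f + stats::rnorm(length(f), 0, noiseSd)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  mstSeries(cp, y, replicate = rep(seq_len(replicates), times = nDilutions),
            ligandConcNM = ligandConcNM)
}
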
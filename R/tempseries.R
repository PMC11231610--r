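# Temperature-series assembly and high-temperature classification: collect
# per-temperature component fractions, locate the interior maximum of the
# intermediate state, and decide between gradual ligand release, trap-and-
# destruction (radical signal loss inside the denaturing protein), and
# dynamics-only behaviour.

.DEFAULT_TEMP_THRESHOLDS <- list(
  releaseRise = 0.15,    # Phi_free rise 323.15 K -> max T for "release"
  destroyRise = 0.10,    # Phi_free rise must stay below this for "trap_destroy"
  integralKeep = 0.70,   # total DI must stay above this fraction for "release"
  integralDestroy = 0.50 # total DI below this fraction flags signal loss
)

#' Assemble a temperature series from per-temperature decompositions
#'
#' Rows are sorted by temperature and duplicate temperatures are averaged.
#' The total double integral is normalized to its value at the lowest
#' analyzed temperature at or above 273.15 K; frozen-solution rows below
#' 273.15 K (powder-type spectra, low signal-to-noise) are retained in the
#' table but flagged as not analyzed.
#'
#' @param entries list of lists with elements \code{temperatureK},
#'   \code{result} (a \linkS4class{DecompositionResult}) and
#'   \code{totalDI} (raw double integral of the spectrum).
#' @return a \linkS4class{TempSeriesResult} with the assembled table.
#' @export
buildTemperatureSeries <- function(entries) {
  rows <- do.call(rbind, lapply(entries, function(e) {
    w <- componentWeights(e$result)
    data.frame(temperatureK = e$temperatureK,
               phiFree = w[["free"]],
               phiIntermediate = w[["intermediate"]],
               phiStrong = w[["strong"]],
               totalDI = e$totalDI)
  }))
  # average duplicates, sort
  rows <- stats::aggregate(rows[-1], by = list(temperatureK = rows$temperatureK),
                           FUN = mean)
  rows <- rows[order(rows$temperatureK), ]
  rows$analyzed <- rows$temperatureK >= 273.15
  if (sum(rows$analyzed) < 4) {
    stop("insufficient-series error: need at least 4 analyzable temperatures")
  }
  ref <- rows$totalDI[rows$analyzed][1]
  rows$totalDI <- rows$totalDI / ref
  rownames(rows) <- NULL
  new("TempSeriesResult", table = rows)
}

#' Temperature of the intermediate-component maximum
#'
#' Finds the grid maximum of Phi_intermediate over analyzed rows and
#' refines it by quadratic interpolation through the maximum and its two
#' grid neighbours. An interior maximum near physiological temperature is
#' the expected signature of the loosely attached state.
#'
#' @param series a \linkS4class{TempSeriesResult}.
#' @return the input series with \code{tIntermediateMax} set; the evidence
#'   list carries the grid window used. A maximum at the series edge
#'   triggers an edge warning and no interpolation; exact ties are broken
#'   towards the lower temperature and flagged.
#' @export
intermediateMaximum <- function(series) {
  stopifnot(is(series, "TempSeriesResult"))
  tab <- series@table[series@table$analyzed, ]
  phi <- tab$phiIntermediate
  if (diff(range(phi)) == 0) stop("Phi_intermediate column is constant")
  imax <- which(phi == max(phi))
  tie <- length(imax) > 1
  i <- imax[1]   # lower-temperature tie-break
  if (tie) warning("tie between equal maxima; returning the lower temperature")
  if (i == 1 || i == length(phi)) {
    warning("edge warning: intermediate maximum at the series edge; no interpolation")
    series@tIntermediateMax <- tab$temperatureK[i]
    series@evidence$intermediateMax <- list(window = tab$temperatureK[i],
                                            edge = TRUE, tie = tie)
    return(series)
  }
  Tw <- tab$temperatureK[(i - 1):(i + 1)]
  yw <- phi[(i - 1):(i + 1)]
  # vertex of the parabola through the three points around the grid maximum
  num <- (Tw[2] - Tw[1])^2 * (yw[2] - yw[3]) - (Tw[2] - Tw[3])^2 * (yw[2] - yw[1])
  den <- (Tw[2] - Tw[1]) * (yw[2] - yw[3]) - (Tw[2] - Tw[3]) * (yw[2] - yw[1])
  tMax <- if (abs(den) > 0) Tw[2] - 0.5 * num / den else Tw[2]
  # clamp into the three-point window
  tMax <- min(max(tMax, Tw[1]), Tw[3])
  series@tIntermediateMax <- tMax
  series@evidence$intermediateMax <- list(window = Tw, edge = FALSE, tie = tie)
  series
}

#' Classify the high-temperature behaviour of a series
#'
#' Applies two double-integral/fraction rules: \emph{release} when the free
#' fraction rises by at least \code{releaseRise} between 323.15 K and the
#' highest temperature while the total double integral stays at or above
#' \code{integralKeep} of its low-temperature reference;
#' \emph{trap_destroy} when the total double integral falls below
#' \code{integralDestroy} of the reference with a free-fraction rise below
#' \code{destroyRise}; otherwise \emph{dynamics_only}. Because only
#' double-integral ratios and fractions enter, the classification is
#' invariant to a uniform intensity rescaling of all spectra.
#'
#' @param series a \linkS4class{TempSeriesResult} reaching at least
#'   333.15 K.
#' @param thresholds named list overriding the package defaults
#'   (releaseRise 0.15, destroyRise 0.10, integralKeep 0.70,
#'   integralDestroy 0.50).
#' @return the series with \code{classification} and \code{evidence} set.
#' @export
classifyHighT <- function(series, thresholds = list()) {
  stopifnot(is(series, "TempSeriesResult"))
  th <- utils::modifyList(.DEFAULT_TEMP_THRESHOLDS, thresholds)
  tab <- series@table[series@table$analyzed, ]
  if (max(tab$temperatureK) < 333.15) {
    stop("series must include temperatures at or above 333.15 K (60 C)")
  }
  iRef <- which.min(abs(tab$temperatureK - 323.15))
  iTop <- nrow(tab)
  rise <- tab$phiFree[iTop] - tab$phiFree[iRef]
  diTop <- tab$totalDI[iTop]
  cls <- if (rise >= th$releaseRise && diTop >= th$integralKeep) {
    "release"
  } else if (diTop < th$integralDestroy && rise < th$destroyRise) {
    "trap_destroy"
  } else {
    "dynamics_only"
  }
  series@classification <- cls
  series@evidence$classification <- list(
    freeRise = rise, integralAtMaxT = diTop,
    tRef = tab$temperatureK[iRef], tMax = tab$temperatureK[iTop],
    thresholds = th)
  series
}
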
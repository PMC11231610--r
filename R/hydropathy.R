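# Kyte-Doolittle hydropathy and Zimmermann polarity over protein sequences:
# whole-sequence totals and sliding-window profiles (ProtScale-style, linear
# weights).

.KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

.ZIMMERMAN_POLARITY <- c(
  A = 0.00, R = 52.00, N = 3.38, D = 49.70, C = 1.48, Q = 3.53, E = 49.90,
  G = 0.00, H = 51.60, I = 0.13, L = 0.13, K = 49.50, M = 1.43, F = 0.35,
  P = 1.58, S = 1.67, T = 1.66, W = 2.10, Y = 1.61, V = 0.13
)

#' Residue scale lookup
#'
#' @param name "kyte_doolittle" (hydropathy; positive = hydrophobic) or
#'   "zimmermann_polarity".
#' @return named numeric over the 20 canonical residues.
#' @export
hydropathyScale <- function(name = c("kyte_doolittle", "zimmermann_polarity")) {
  name <- match.arg(name)
  switch(name, kyte_doolittle = .KYTE_DOOLITTLE,
         zimmermann_polarity = .ZIMMERMAN_POLARITY)
}

.checkResidues <- function(residues) {
  ok <- names(.KYTE_DOOLITTLE)
  chars <- strsplit(toupper(residues), "")[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop(sprintf("validation error: illegal residue '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  chars
}

#' Total scale index of a sequence
#'
#' Sum of the per-residue scale values over the whole sequence (the
#' whole-protein hydropathy or polarity figure). The empty sequence gives
#' 0; concatenation is additive.
#'
#' @param residues one-letter amino-acid string (upper or lower case).
#' @param scale a named scale from \code{\link{hydropathyScale}} or a scale
#'   name.
#' @return scalar total index.
#' @examples
#' totalIndex("GA")  # -0.4 + 1.8
#' @export
totalIndex <- function(residues, scale = "kyte_doolittle") {
  if (is.character(scale) && length(scale) == 1) scale <- hydropathyScale(scale)
  if (nchar(residues) == 0) return(0)
  chars <- .checkResidues(residues)
  sum(scale[chars])
}

#' Sliding-window scale profile of a sequence
#'
#' Centred moving average of the per-residue scale values with an odd
#' window and linear (uniform) weights; window 1 reproduces the raw
#' per-residue values. The output has length \code{nchar - window + 1},
#' positions refer to the window centres.
#'
#' @param residues one-letter amino-acid string.
#' @param scale scale vector or name as in \code{\link{totalIndex}}.
#' @param window odd positive integer, at most the sequence length.
#' @return data.frame with columns position (centre, 1-based) and value.
#' @export
windowProfile <- function(residues, scale = "kyte_doolittle", window = 9) {
  if (is.character(scale) && length(scale) == 1) scale <- hydropathyScale(scale)
  n <- nchar(residues)
  if (window %% 2 == 0 || window < 1 || window > n) {
    stop("parameter error: window must be odd, positive and <= sequence length")
  }
  chars <- .checkResidues(residues)
  vals <- as.numeric(scale[chars])
  half <- (window - 1) / 2
  prof <- stats::filter(vals, rep(1 / window, window), sides = 2)
  keep <- (half + 1):(n - half)
  data.frame(position = keep, value = as.numeric(prof[keep]))
}
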
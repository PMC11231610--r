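# Generics and accessor methods for the core classes.

#' Isotropic g value of a component
#' @param object a \linkS4class{SpinComponent}.
#' @return mean of the g-tensor principal values.
#' @export
setGeneric("gIso", function(object) standardGeneric("gIso"))

#' @rdname gIso
#' @export
setMethod("gIso", "SpinComponent", function(object) mean(object@gTensor))

#' Isotropic hyperfine coupling of a component (MHz)
#' @param object a \linkS4class{SpinComponent}.
#' @return mean of the hyperfine principal values, MHz.
#' @export
setGeneric("aIso", function(object) standardGeneric("aIso"))

#' @rdname aIso
#' @export
setMethod("aIso", "SpinComponent", function(object) mean(object@ATensor))

#' Rotational correlation time (ns)
#' @param object a \linkS4class{SpinComponent}.
#' @return tau_c in ns.
#' @export
setGeneric("tauC", function(object) standardGeneric("tauC"))

#' @rdname tauC
#' @export
setMethod("tauC", "SpinComponent", function(object) object@tauC)

#' Component label
#' @param object a \linkS4class{SpinComponent}.
#' @return the label string.
#' @export
setGeneric("componentLabel", function(object) standardGeneric("componentLabel"))

#' @rdname componentLabel
#' @export
setMethod("componentLabel", "SpinComponent", function(object) object@label)

#' Field axis of a spectrum (mT)
#' @param object a \linkS4class{SpectrumTrace}.
#' @return numeric field axis.
#' @export
setGeneric("fieldAxis", function(object) standardGeneric("fieldAxis"))

#' @rdname fieldAxis
#' @export
setMethod("fieldAxis", "SpectrumTrace", function(object) object@fieldMT)

#' Intensity of a spectrum
#' @param object a \linkS4class{SpectrumTrace}.
#' @return numeric derivative amplitudes.
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname intensity
#' @export
setMethod("intensity", "SpectrumTrace", function(object) object@intensity)

#' Component weights of a decomposition
#' @param object a \linkS4class{DecompositionResult}.
#' @return named fractions summing to 1.
#' @export
setGeneric("componentWeights", function(object) standardGeneric("componentWeights"))

#' @rdname componentWeights
#' @export
setMethod("componentWeights", "DecompositionResult", function(object) object@weights)

#' Fit RMSD as percent of peak-to-peak amplitude
#' @param object a \linkS4class{DecompositionResult}.
#' @return scalar percent RMSD.
#' @export
setGeneric("rmsdPct", function(object) standardGeneric("rmsdPct"))

#' @rdname rmsdPct
#' @export
setMethod("rmsdPct", "DecompositionResult", function(object) object@rmsdPct)

setMethod("show", "SpinComponent", function(object) {
  cat(sprintf("SpinComponent '%s': giso = %.5f, aiso = %.2f MHz, tau_c = %g ns\n",
              object@label, gIso(object), aIso(object), object@tauC))
  cat(sprintf("  g = (%.4f, %.4f, %.4f); A' = (%.1f, %.1f, %.1f) MHz\n",
              object@gTensor[1], object@gTensor[2], object@gTensor[3],
              object@ATensor[1], object@ATensor[2], object@ATensor[3]))
  cat(sprintf("  lw (G/L) = %.3f/%.3f mT; exchange = %.1f MHz; euler = (%g, %g, %g) deg\n",
              object@lwGauss, object@lwLorentz, object@exchangeFreq,
              object@eulerDeg[1], object@eulerDeg[2], object@eulerDeg[3]))
})

setMethod("show", "SpectrumTrace", function(object) {
  cat(sprintf("SpectrumTrace: %d points, %.2f-%.2f mT, %.3f GHz, %.2f K\n",
              length(object@fieldMT), min(object@fieldMT), max(object@fieldMT),
              object@mwFreqGHz, object@temperatureK))
  if (length(object@meta)) {
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "DecompositionResult", function(object) {
  w <- object@weights
  e <- object@weightErrors
  cat("DecompositionResult:\n")
  for (i in seq_along(w)) {
    cat(sprintf("  Phi_%s = %.4f +/- %.4f\n", names(w)[i], w[i], e[i]))
  }
  cat(sprintf("  RMSD = %.2f%% of peak-to-peak amplitude\n", object@rmsdPct))
})

setMethod("show", "CurveFit", function(object) {
  cat(sprintf("CurveFit (%s): RSS = %.4g, R2 = %.4f\n", object@model,
              object@rss, object@r2))
  p <- object@params; e <- object@paramErrors
  for (i in seq_along(p)) {
    cat(sprintf("  %s = %.4g +/- %.2g\n", names(p)[i], p[i], e[i]))
  }
})

setMethod("show", "TempSeriesResult", function(object) {
  cat(sprintf("TempSeriesResult: %d temperatures (%d analyzed)\n",
              nrow(object@table), sum(object@table$analyzed)))
  if (!is.na(object@tIntermediateMax)) {
    cat(sprintf("  intermediate maximum at %.1f K\n", object@tIntermediateMax))
  }
  if (nzchar(object@classification)) {
    cat(sprintf("  high-T classification: %s\n", object@classification))
  }
})

setMethod("show", "MstSeries", function(object) {
  cat(sprintf("MstSeries: %d points, %d distinct concentrations, L0 = %g nM, t_end = %g s\n",
              length(object@cProteinUM), length(unique(object@cProteinUM)),
              object@ligandConcNM, object@tEndS))
})
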
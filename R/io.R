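# File input/output: spectrum CSV (two columns field_mT,intensity), an
# optional JCAMP-DX reader for instrument exports, FASTA sequences via
# Biostrings, and table/JSON writers for results.

#' Read a spectrum from a two-column CSV
#'
#' Expects a header row \code{field_mT,intensity}; extra metadata may be
#' supplied through \code{meta}. A descending field axis is sorted with a
#' warning; malformed rows raise a parse error naming the line.
#'
#' @param path CSV file path.
#' @param mwFreqGHz,temperatureK,meta acquisition metadata attached to the
#'   trace.
#' @return a \linkS4class{SpectrumTrace}.
#' @export
readSpectrumCsv <- function(path, mwFreqGHz = 9.47, temperatureK = 310.15,
                            meta = list()) {
  raw <- utils::read.csv(path, colClasses = "character")
  if (ncol(raw) < 2) stop("parse error: expected two columns (field_mT,intensity)")
  field <- suppressWarnings(as.numeric(raw[[1]]))
  inten <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(field) | is.na(inten))
  if (length(bad)) {
    stop(sprintf("parse error: non-numeric cell at data line %d of %s",
                 bad[1], path))
  }
  if (is.unsorted(field)) {
    if (is.unsorted(rev(field))) {
      o <- order(field)
    } else {
      o <- rev(seq_along(field))
    }
    warning("field axis not increasing; sorting")
    field <- field[o]
    inten <- inten[o]
  }
  spectrumTrace(field, inten, mwFreqGHz = mwFreqGHz,
                temperatureK = temperatureK, meta = meta)
}

#' Write a spectrum to the two-column CSV layout
#'
#' @param trace a \linkS4class{SpectrumTrace}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSpectrumCsv <- function(trace, path) {
  utils::write.csv(data.frame(field_mT = fieldAxis(trace),
                              intensity = intensity(trace)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum from a JCAMP-DX file (minimal EPR dialect)
#'
#' Supports AFFN-encoded \code{##XYDATA=(X++(Y..Y))} blocks with FIRSTX,
#' LASTX (or DELTAX), NPOINTS and optional YFACTOR/XFACTOR. On any parse
#' failure the function warns and returns \code{NULL} so callers can
#' degrade to the CSV path.
#'
#' @param path JCAMP-DX file path.
#' @param ... forwarded metadata, see \code{\link{readSpectrumCsv}}.
#' @return a \linkS4class{SpectrumTrace}, or NULL on parse failure.
#' @export
readSpectrumJcamp <- function(path, ...) {
  tryCatch({
    lines <- readLines(path, warn = FALSE)
    getNum <- function(key) {
      hit <- grep(paste0("^##", key, "="), lines, value = TRUE)
      if (!length(hit)) return(NA_real_)
      as.numeric(sub(paste0("^##", key, "="), "", hit[1]))
    }
    firstx <- getNum("FIRSTX")
    lastx <- getNum("LASTX")
    deltax <- getNum("DELTAX")
    npoints <- getNum("NPOINTS")
    yfac <- getNum("YFACTOR"); if (is.na(yfac)) yfac <- 1
    xfac <- getNum("XFACTOR"); if (is.na(xfac)) xfac <- 1
    start <- grep("^##XYDATA=", lines)
    stopifnot(length(start) == 1, !is.na(firstx), !is.na(npoints))
    end <- grep("^##END", lines)
    end <- end[end > start][1]
    block <- lines[(start + 1):(end - 1)]
    ys <- unlist(lapply(block, function(l) {
      v <- as.numeric(strsplit(trimws(l), "[ \t]+")[[1]])
      v[-1]   # first value on each line is the X of the line
    }))
    stopifnot(length(ys) == npoints)
    if (is.na(deltax)) deltax <- (lastx - firstx) / (npoints - 1)
    x <- (firstx + deltax * (0:(npoints - 1))) * xfac
    spectrumTrace(x, ys * yfac, ...)
  }, error = function(e) {
    warning("JCAMP-DX parse failure (", conditionMessage(e),
            "); falling back to the CSV path")
    NULL
  })
}

#' Read protein sequences from a FASTA file
#'
#' Wraps \code{Biostrings::readAAStringSet}; records are uppercased and
#' validated against the 20 canonical residues (an illegal character
#' raises an error with its position).
#'
#' @param path FASTA file path.
#' @return data.frame with columns id and residues, in file order.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  aa <- tryCatch(Biostrings::readAAStringSet(path),
                 error = function(e) stop("format error: ", conditionMessage(e)))
  if (length(aa) == 0) stop("format error: no FASTA records in ", path)
  res <- toupper(as.character(aa))
  for (i in seq_along(res)) .checkResidues(res[i])
  data.frame(id = sub("\\s.*$", "", names(aa)), residues = unname(res),
             stringsAsFactors = FALSE)
}

#' Export a decomposition result as JSON
#'
#' @param result a \linkS4class{DecompositionResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDecompositionJson <- function(result, path) {
  jsonlite::write_json(list(
    weights = as.list(result@weights),
    weightErrors = as.list(result@weightErrors),
    rmsdPct = result@rmsdPct,
    conditionNumber = result@conditionNumber,
    refinedParams = result@refinedParams
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
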
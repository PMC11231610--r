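# Configuration handling and the staged analysis pipeline that ties the
# modules together (also the backend of the thin command-line script in
# inst/scripts/spinbind.R).

.DEFAULT_CONFIG <- list(
  paths = list(spectraDir = NULL, outputDir = "spinbind-out"),
  analysis = list(engine = "auto", refine = "none",
                  fieldMinMT = 332.5, fieldMaxMT = 342.5, nField = 1024,
                  thresholds = list()),
  thermo = list(temperatureEprK = 310.15, temperatureMstK = 295.15,
                cLigandUM = 20),
  synth = list(preset = "fabp3_like", noiseSnr = 50),
  seed = 1L,
  logLevel = "info"
)

#' Default pipeline configuration
#'
#' All defaults match the packaged acquisition values: field window
#' 332.5-342.5 mT, ligand 20 uM, EPR thermodynamics at 310.15 K and MST
#' thermodynamics at 295.15 K.
#'
#' @return nested configuration list.
#' @export
defaultConfig <- function() .DEFAULT_CONFIG

#' Read and validate a pipeline configuration file
#'
#' YAML file merged over \code{\link{defaultConfig}}; unknown keys are
#' rejected.
#'
#' @param path YAML file path, or NULL for the defaults.
#' @return validated configuration list.
#' @export
readConfig <- function(path = NULL) {
  cfg <- .DEFAULT_CONFIG
  if (!is.null(path)) {
    if (!file.exists(path)) stop("missing input: config file ", path)
    user <- yaml::read_yaml(path)
    .checkKeys(user, cfg, "")
    cfg <- utils::modifyList(cfg, user)
  }
  cfg
}

.checkKeys <- function(user, ref, prefix) {
  for (nm in names(user)) {
    if (!nm %in% names(ref)) {
      stop("unknown configuration key: ", prefix, nm)
    }
    if (is.list(user[[nm]]) && is.list(ref[[nm]]) &&
        !identical(nm, "thresholds")) {
      .checkKeys(user[[nm]], ref[[nm]], paste0(prefix, nm, "."))
    }
  }
}

.logMsg <- function(cfg, ...) {
  if (identical(cfg$logLevel, "quiet")) return(invisible())
  message("[spinbind] ", ...)
}

#' Run one pipeline stage
#'
#' Stages: \code{synth} (write a synthetic concentration series as spectrum
#' CSVs + a truth table), \code{fit} (decompose every spectrum in the
#' spectra directory into component fractions), \code{thermo} (mass-action
#' KD/KA/dG table from the fitted fractions), \code{bindcurve} (Hill-family
#' fits of the bound fraction vs concentration), \code{tempseries}
#' (assemble + classify a synthetic temperature series), \code{mst}
#' (synthetic MST series + 1:1 KD fit), \code{hydropathy} (totals and
#' profiles for a FASTA, defaulting to the packaged fixture).
#'
#' Each stage writes CSV/JSON artifacts into the configured output
#' directory and a run log recording the seed.
#'
#' @param config configuration list from \code{\link{readConfig}}.
#' @param command stage name.
#' @param fastaPath optional FASTA input for the hydropathy stage.
#' @return invisibly, a list of the artifacts written.
#' @export
runPipeline <- function(config = defaultConfig(),
                        command = c("synth", "fit", "thermo", "bindcurve",
                                    "tempseries", "mst", "hydropathy"),
                        fastaPath = NULL) {
  command <- match.arg(command)
  outDir <- config$paths$outputDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  axis <- seq(config$analysis$fieldMinMT, config$analysis$fieldMaxMT,
              length.out = config$analysis$nField)
  artifacts <- list()
  spectraDir <- if (is.null(config$paths$spectraDir)) {
    file.path(outDir, "spectra")
  } else config$paths$spectraDir

  if (command == "synth") {
    params <- truthParams(preset = config$synth$preset,
                          noiseSnr = config$synth$noiseSnr,
                          seed = config$seed)
    series <- synthConcentrationSeries(params,
                                       cLigandUM = config$thermo$cLigandUM,
                                       fieldMT = axis)
    dir.create(spectraDir, recursive = TRUE, showWarnings = FALSE)
    truth <- do.call(rbind, lapply(series, function(s) {
      f <- file.path(spectraDir, sprintf("spectrum_cp%03d.csv", s$cProteinUM))
      writeSpectrumCsv(s$trace, f)
      data.frame(cProteinUM = s$cProteinUM, cLigandUM = s$cLigandUM,
                 t(s$truth))
    }))
    tf <- file.path(outDir, "truth.csv")
    utils::write.csv(truth, tf, row.names = FALSE)
    artifacts <- list(spectraDir = spectraDir, truth = tf)
    .logMsg(config, "synth: wrote ", length(series), " spectra (seed ",
            config$seed, ")")
  }

  if (command == "fit") {
    files <- list.files(spectraDir, pattern = "\\.csv$", full.names = TRUE)
    if (!length(files)) stop("missing inputs: no spectrum CSVs in ", spectraDir)
    params <- truthParams(preset = config$synth$preset, seed = config$seed)
    lib <- fabpComponents(params$protein, params$probe)
    rows <- lapply(files, function(f) {
      cp <- as.numeric(sub(".*cp([0-9]+)\\.csv$", "\\1", f))
      tr <- readSpectrumCsv(f)
      fit <- fitWeights(tr, lib, refine = config$analysis$refine,
                        engine = config$analysis$engine)
      decompositionRow(fit, meta = list(file = basename(f), cProteinUM = cp))
    })
    tab <- do.call(rbind, rows)
    ff <- file.path(outDir, "fractions.csv")
    utils::write.csv(tab, ff, row.names = FALSE)
    artifacts <- list(fractions = ff)
    .logMsg(config, "fit: decomposed ", nrow(tab), " spectra")
  }

  if (command == "thermo") {
    ff <- file.path(outDir, "fractions.csv")
    if (!file.exists(ff)) stop("missing inputs: run the fit stage first (", ff, ")")
    tab <- utils::read.csv(ff)
    cL <- config$thermo$cLigandUM
    rows <- lapply(which(tab$cProteinUM > 0), function(i) {
      phi <- c(free = tab$phi_free[i], intermediate = tab$phi_intermediate[i],
               strong = tab$phi_strong[i])
      th <- equilibriumConstantsThreeState(tab$cProteinUM[i], cL, phi,
                                           config$thermo$temperatureEprK,
                                           phiError = tab$rmsd_pct[i] / 100)
      cbind(cProteinUM = tab$cProteinUM[i], th)
    })
    out <- do.call(rbind, rows)
    tf <- file.path(outDir, "thermo.csv")
    utils::write.csv(out, tf, row.names = FALSE)
    artifacts <- list(thermo = tf)
    .logMsg(config, "thermo: ", nrow(out), " transition rows")
  }

  if (command == "bindcurve") {
    ff <- file.path(outDir, "fractions.csv")
    if (!file.exists(ff)) stop("missing inputs: run the fit stage first (", ff, ")")
    tab <- utils::read.csv(ff)
    tab <- tab[tab$cProteinUM > 0, ]
    phiB <- tab$phi_intermediate + tab$phi_strong
    fit <- fitBindingCurve(tab$cProteinUM, phiB,
                           sigma = pmax(tab$rmsd_pct / 100, 1e-3),
                           model = "hill")
    kd50 <- tryCatch(apparentKd(fit, 0.5), error = function(e) NA_real_)
    kd75 <- tryCatch(apparentKd(fit, 0.75), error = function(e) NA_real_)
    res <- c(as.list(fit@params), list(rss = fit@rss, r2 = fit@r2,
                                       kd50_uM = kd50, kd75_uM = kd75))
    bf <- file.path(outDir, "bindcurve.json")
    jsonlite::write_json(res, bf, auto_unbox = TRUE, digits = NA)
    artifacts <- list(bindcurve = bf)
    .logMsg(config, "bindcurve: hill K = ", signif(fit@params[["K"]], 4),
            " uM, n = ", signif(fit@params[["n"]], 3))
  }

  if (command == "tempseries") {
    params <- truthParams(preset = config$synth$preset,
                          noiseSnr = config$synth$noiseSnr,
                          seed = config$seed)
    series <- synthTemperatureSeries(params, fieldMT = axis)
    lib <- fabpComponents(params$protein, params$probe)
    entries <- lapply(series, function(s) {
      fit <- fitWeights(s$trace, lib, engine = config$analysis$engine)
      list(temperatureK = s$temperatureK, result = fit,
           totalDI = fittedDoubleIntegral(fit, fieldAxis(s$trace)))
    })
    ts <- buildTemperatureSeries(entries)
    ts <- intermediateMaximum(ts)
    ts <- classifyHighT(ts, config$analysis$thresholds)
    tf <- file.path(outDir, "tempseries.csv")
    utils::write.csv(ts@table, tf, row.names = FALSE)
    cf <- file.path(outDir, "classification.json")
    jsonlite::write_json(list(classification = ts@classification,
                              tIntermediateMaxK = ts@tIntermediateMax,
                              evidence = ts@evidence), cf,
                         auto_unbox = TRUE, digits = NA)
    artifacts <- list(table = tf, classification = cf)
    .logMsg(config, "tempseries: ", ts@classification,
            ", Phi_I max at ", round(ts@tIntermediateMax, 1), " K")
  }

  if (command == "mst") {
    series <- synthMstSeries(seed = config$seed, noiseSd = 0.01)
    fit <- fitKdMst(series)
    mf <- file.path(outDir, "mst.json")
    chain <- thermoChainFromKd(fit$KD_uM, config$thermo$temperatureMstK)
    jsonlite::write_json(c(fit[c("KD_uM", "ciLow_uM", "ciHigh_uM",
                                 "confidencePct")],
                           as.list(chain)), mf, auto_unbox = TRUE, digits = NA)
    artifacts <- list(mst = mf)
    .logMsg(config, "mst: KD = ", signif(fit$KD_uM, 4), " uM")
  }

  if (command == "hydropathy") {
    if (is.null(fastaPath)) fastaPath <- fabpSequenceFile()
    seqs <- readFastaSequences(fastaPath)
    totals <- data.frame(
      id = seqs$id,
      length = nchar(seqs$residues),
      kyteDoolittleTotal = vapply(seqs$residues, totalIndex, numeric(1)),
      zimmermannPolarityTotal = vapply(seqs$residues, totalIndex, numeric(1),
                                       scale = "zimmermann_polarity"),
      row.names = NULL)
    hf <- file.path(outDir, "hydropathy.csv")
    utils::write.csv(totals, hf, row.names = FALSE)
    artifacts <- list(hydropathy = hf)
    .logMsg(config, "hydropathy: ", nrow(totals), " sequences")
  }

  logf <- file.path(outDir, "run.log")
  cat(sprintf("%s stage=%s seed=%d\n", format(Sys.time()), command,
              config$seed), file = logf, append = TRUE)
  invisible(artifacts)
}
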
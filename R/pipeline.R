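#' Run the full pipeline from a configuration file
#'
#' Executes the stages requested in a JSON configuration: synthetic record
#' generation, wavelet + Gaussian preprocessing, QRS detection, beat
#' segmentation, class balancing, fold construction, training and
#' evaluation. Every run writes a reproducibility manifest (full config
#' snapshot, seeds, input hashes, package version, wall time) next to its
#' outputs; re-running with the same configuration produces byte-identical
#' metric files.
#'
#' The configuration document has per-stage sections; unknown keys are
#' rejected up front and all validation failures are reported at once:
#' \preformatted{
#' {
#'   "seed": 17,
#'   "outDir": "run1",
#'   "synth": {"beatsPerClass": 200, "classes": ["N","S","V","F","Q"],
#'             "snrDb": 20},
#'   "folds": {"k": 5},
#'   "train": {"epochs": 10, "learningRate": 1e-4, "batchSize": 64,
#'             "gradClipNorm": 1.0, "model": "canet", "reduced": true},
#'   "evaluate": {"heldoutPerClass": 100}
#' }
#' }
#'
#' @param configFile path to the JSON configuration, or an equivalent named
#'   list.
#' @param dryRun validate the configuration and return without computing.
#' @return invisibly, a list with the output directory, the evaluation
#'   metrics and the manifest path.
#' @export
runPipeline <- function(configFile, dryRun = FALSE) {
  cfg <- if (is.character(configFile)) {
    jsonlite::read_json(configFile, simplifyVector = TRUE)
  } else {
    configFile
  }
  problems <- character(0)
  known <- c("seed", "outDir", "synth", "folds", "train", "evaluate")
  extra <- setdiff(names(cfg), known)
  if (length(extra)) {
    problems <- c(problems, paste0("unknown section(s): ", paste(extra, collapse = ", ")))
  }
  seed <- cfg$seed %||% 1L
  if (!is.numeric(seed)) problems <- c(problems, "seed must be numeric")
  sy <- cfg$synth %||% list()
  beatsPerClass <- sy$beatsPerClass %||% 200L
  if (beatsPerClass < 1) problems <- c(problems, "synth.beatsPerClass must be >= 1")
  classes <- sy$classes %||% AAMI_CLASSES
  if (!all(classes %in% AAMI_CLASSES)) {
    problems <- c(problems, "synth.classes must be AAMI classes")
  }
  k <- (cfg$folds %||% list())$k %||% 5L
  if (k < 2) problems <- c(problems, "folds.k must be >= 2 (cross-validation needs at least two folds)")
  tr <- cfg$train %||% list()
  modelName <- tr$model %||% "canet"
  if (!modelName %in% c("canet", "rnn", "cnn", "lstm", "gru", "bilstm")) {
    problems <- c(problems, paste0("train.model '", modelName, "' unknown"))
  }
  if (beatsPerClass < k) {
    problems <- c(problems, "synth.beatsPerClass must be >= folds.k for stratification")
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "))
  }
  if (dryRun) {
    return(invisible(list(valid = TRUE)))
  }

  outDir <- cfg$outDir %||% "canet-run"
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  mkCfg <- function(reduced) if (isTRUE(reduced)) reducedModelConfig() else modelConfig()
  mcfg <- mkCfg(tr$reduced %||% TRUE)
  tcfg <- trainConfig(
    epochs = tr$epochs %||% 10L,
    learningRate = tr$learningRate %||% 1e-4,
    batchSize = tr$batchSize %||% 64L,
    gradClipNorm = tr$gradClipNorm %||% 1.0,
    seed = seed
  )

  segments <- synthBeatSet(beatsPerClass,
    classes = classes,
    snrDb = sy$snrDb %||% 20, seed = seed
  )
  factory <- function(seed) {
    if (modelName == "canet") {
      buildCanet(mcfg, seed = seed)
    } else {
      buildBaseline(modelName, mcfg, seed = seed)
    }
  }
  cv <- runCrossValidation(segments, k, factory, tcfg, seed = seed)

  ev <- cfg$evaluate %||% list()
  heldPerClass <- ev$heldoutPerClass %||% 100L
  heldout <- synthBeatSet(heldPerClass,
    classes = classes,
    snrDb = sy$snrDb %||% 20, seed = seed + 10000L
  )
  balanced <- balanceClasses(segments, seed = seed + 1L)
  finalModel <- trainModel(factory(seed), balanced, NULL, tcfg)
  ext <- externalTest(finalModel, heldout, colData(segments)$source)

  metricsOut <- list(
    crossValidation = cv$summary,
    external = list(
      overallAccuracy = ext$metrics$overallAccuracy,
      macro = as.list(ext$metrics$macro),
      perClass = ext$metrics$perClass,
      macroAuc = ext$roc$macroAuc
    )
  )
  metricsPath <- file.path(outDir, "metrics.json")
  jsonlite::write_json(metricsOut, metricsPath,
    auto_unbox = TRUE, digits = 10, dataframe = "rows"
  )
  utils::write.csv(ext$confusion, file.path(outDir, "confusion.csv"))
  saveModel(finalModel, file.path(outDir, "model.ckpt"))

  manifest <- list(
    subcommand = "pipeline",
    config = cfg,
    seed = seed,
    outputs = c("metrics.json", "confusion.csv", "model.ckpt"),
    metricsSha = unname(tools::md5sum(metricsPath)),
    packageVersion = as.character(utils::packageVersion("canet")),
    wallTimeSeconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = 10)

  invisible(list(
    outDir = outDir, metrics = metricsOut,
    manifestPath = manifestPath, metricsPath = metricsPath
  ))
}

#' End-to-end closure check on one synthetic record
#'
#' Generates an annotated record, denoises, smooths, detects R-peaks,
#' segments, and matches detected beats against the generator's ground
#' truth — the loop every stage of the package participates in.
#'
#' @param spec a [rhythmSpec()].
#' @param waveletCfg,gaussCfg,detectorCfg stage configurations.
#' @return list with the segment set, the peak-matching summary
#'   ([matchPeaks()]) and the label-attachment accuracy (fraction of
#'   detected beats whose nearest ground-truth annotation lies within
#'   50 ms).
#' @export
processRecord <- function(spec,
                          waveletCfg = waveletConfig(),
                          gaussCfg = gaussianConfig(),
                          detectorCfg = detectorConfig()) {
  gen <- generateRecord(spec)
  x <- channelSignal(gen$record)
  fs <- samplingRate(gen$record)
  den <- waveletDenoise(x, fs, waveletCfg)
  sm <- gaussianSmooth(den, fs, gaussCfg)
  peaks <- panTompkins(sm, fs, detectorCfg)
  match <- matchPeaks(peaks, gen$annotations$sampleIndex, fs)
  ## attach labels by nearest ground-truth annotation within 50 ms
  tol <- 0.05 * fs
  lab <- vapply(peaks, function(p) {
    d <- abs(gen$annotations$sampleIndex - p)
    if (min(d) <= tol) gen$annotations$aamiClass[which.min(d)] else NA_character_
  }, character(1))
  keep <- which(!is.na(lab) & length(peaks) >= 2)
  segments <- NULL
  if (length(peaks) >= 2L) {
    ann <- beatAnnotations(peaks[keep], CLASS_TO_SYMBOL[lab[keep]])
    rec <- ECGRecord(sm, fs = fs, recordId = recordId(gen$record))
    segments <- segmentBeats(rec, ann)
  }
  list(
    segments = segments, match = match,
    labelledFraction = length(keep) / max(1L, length(peaks)),
    annotations = gen$annotations, peaks = peaks
  )
}
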
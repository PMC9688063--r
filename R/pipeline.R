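#' End-to-end pipeline configuration
#'
#' All module parameters with the reference defaults: 2-20 Hz band-pass,
#' 5-s epochs, K = 4 microstates with 20 clustering restarts at tolerance
#' 1e-6 and at most 1000 iterations, 10 ranking bins, and
#' Bayesian-optimized classification with a 5-fold CV objective on an
#' 80/20 split.
#'
#' @param nPerGroup,duration,fs,noiseSd,envFreq synthetic-cohort settings
#'   (see [generatorConfig()]).
#' @param epochLength epoch length in seconds.
#' @param filterLow,filterHigh band-pass edges (Hz).
#' @param K,nRestarts,tol,maxIter modified-K-means settings.
#' @param nBins chi-square ranking bins.
#' @param budget,kFolds,testFraction,topK,protocol classification
#'   settings; `protocol` is `"subject_dependent"` or `"loso"`.
#' @param maxPeaksPerSubject GFP peaks kept per subject for the pooled
#'   clustering substrate (subsampled deterministically if more;
#'   `Inf` keeps all).
#' @param seed master seed.
#' @return A named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(nPerGroup = 14L, duration = 900, fs = 250,
                           noiseSd = 0.8, envFreq = 10, epochLength = 5,
                           filterLow = 2, filterHigh = 20, K = 4L,
                           nRestarts = 20L, tol = 1e-6, maxIter = 1000L,
                           nBins = 10L, budget = 30L, kFolds = 5L,
                           testFraction = 0.2, topK = 6L,
                           protocol = c("subject_dependent", "loso"),
                           maxPeaksPerSubject = 2000L, seed = 1L) {
  cfg <- list(nPerGroup = as.integer(nPerGroup), duration = duration,
              fs = fs, noiseSd = noiseSd, envFreq = envFreq,
              epochLength = epochLength, filterLow = filterLow,
              filterHigh = filterHigh, K = as.integer(K),
              nRestarts = as.integer(nRestarts), tol = tol,
              maxIter = as.integer(maxIter), nBins = as.integer(nBins),
              budget = as.integer(budget), kFolds = as.integer(kFolds),
              testFraction = testFraction, topK = as.integer(topK),
              protocol = match.arg(protocol),
              maxPeaksPerSubject = maxPeaksPerSubject,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from JSON
#'
#' Unknown keys are rejected; missing keys take the defaults of
#' [pipelineConfig()].
#'
#' @param path JSON file.
#' @return A `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

pipelineLog <- function(con, level, msg) {
  line <- sprintf("%s [%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                  level, msg)
  writeLines(line, con)
  invisible(line)
}

#' Run the full microstate analysis pipeline
#'
#' Executes simulate -> preprocess -> segment -> features -> rank ->
#' classify on a synthetic cohort (or on recordings read from
#' `recordingPaths`), writing all artifacts (templates, feature table,
#' ranking, univariate table, report, ground truth, log) into `outDir`.
#' Fully deterministic given the configuration seed; every artifact run
#' is reconstructible from the log header, which records the
#' configuration JSON and its MD5 hash.
#'
#' @param config a `PipelineConfig`.
#' @param outDir output directory (created if missing).
#' @param stopAfter run the pipeline only up to this stage
#'   (`"simulate"`, `"preprocess"`, `"segment"`, `"features"`, `"rank"`,
#'   `"classify"`).
#' @param recordingPaths optional character vector of EDF/CSV recordings
#'   to analyze instead of simulating a cohort (group labels must be
#'   stored in the files).
#' @return Invisible list with the computed objects (`cohort`, `epochs`,
#'   `templates`, `features`, `ranking`, `univariate`, `report`,
#'   `reportLoso` when applicable) and `artifacts` (paths).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir,
                        stopAfter = "classify", recordingPaths = NULL) {
  stages <- c("simulate", "preprocess", "segment", "features", "rank",
              "classify")
  stopAfter <- match.arg(stopAfter, stages)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(unclass(config), cfgPath, auto_unbox = TRUE,
                       digits = NA)
  logPath <- file.path(outDir, "pipeline.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  pipelineLog(logCon, "INFO", sprintf("config hash %s seed %d",
                                      unname(tools::md5sum(cfgPath)),
                                      config$seed))
  res <- list(artifacts = c(config = cfgPath, log = logPath))
  done <- function(stage) {
    pipelineLog(logCon, "INFO", sprintf("stage %s complete", stage))
    stage == stopAfter
  }
  stageError <- function(stage, e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)

  ## simulate (or read)
  tryCatch({
    if (is.null(recordingPaths)) {
      gcfg <- generatorConfig(nPerGroup = config$nPerGroup,
                              fs = config$fs, duration = config$duration,
                              envFreq = config$envFreq,
                              noiseSd = config$noiseSd, seed = config$seed)
      cohort <- generateCohort(gcfg)
      rlePerSubject <- lapply(cohort$truths, function(tr)
        data.frame(state = tr$runs$states, length = tr$runs$lengths))
      gtRuns <- do.call(rbind, Map(function(sid, df)
        cbind(subject_id = sid, df), names(rlePerSubject), rlePerSubject))
      gtPath <- file.path(outDir, "ground_truth_runs.csv")
      utils::write.csv(gtRuns, gtPath, row.names = FALSE)
      jsonlite::write_json(list(seed = config$seed,
                                nPerGroup = config$nPerGroup,
                                fs = config$fs,
                                duration = config$duration),
                           file.path(outDir, "ground_truth.json"),
                           auto_unbox = TRUE)
      res$artifacts["ground_truth"] <- gtPath
    } else {
      cohort <- list(recordings = lapply(recordingPaths, readRecording),
                     truths = NULL)
      names(cohort$recordings) <-
        vapply(cohort$recordings, subjectId, character(1))
    }
    res$cohort <- cohort
  }, error = function(e) stageError("simulate", e))
  if (done("simulate")) return(invisible(res))

  ## preprocess
  tryCatch({
    epochSets <- lapply(cohort$recordings, function(rec) {
      rec <- bandpassFilter(rec, config$filterLow, config$filterHigh)
      rec <- averageReference(rec)
      rejectOutlierEpochs(epochSignal(rec, config$epochLength))
    })
    res$epochs <- epochSets
  }, error = function(e) stageError("preprocess", e))
  if (done("preprocess")) return(invisible(res))

  ## segment: pool GFP-peak maps across all subjects, cluster, label
  tryCatch({
    peaksPerSubject <- lapply(epochSets, extractPeakMaps)
    set.seed(config$seed)
    keepPeaks <- function(pk) {
      P <- length(pk@indices)
      if (P <= config$maxPeaksPerSubject) return(pk)
      sel <- sort(sample.int(P, config$maxPeaksPerSubject))
      new("PeakSet", indices = pk@indices[sel],
          maps = pk@maps[, sel, drop = FALSE], gfp = pk@gfp[sel])
    }
    peaksPerSubject <- lapply(peaksPerSubject, keepPeaks)
    allMaps <- do.call(cbind, lapply(peaksPerSubject, peakMaps))
    allGfp <- unlist(lapply(peaksPerSubject, peakGFP), use.names = FALSE)
    pooled <- new("PeakSet", indices = seq_along(allGfp),
                  maps = allMaps, gfp = allGfp)
    km <- modifiedKMeans(pooled, K = config$K,
                         nRestarts = config$nRestarts, tol = config$tol,
                         maxIter = config$maxIter, seed = config$seed)
    templates <- km$templates
    if (config$K == 4L)
      templates <- assignCanonicalLabels(
        templates, makeTemplates(standardMontage1020()))
    pipelineLog(logCon, "INFO",
                sprintf("pooled clustering: %d peaks, GEV %.4f",
                        length(allGfp), gev(templates)))
    tplPath <- file.path(outDir, "templates.csv")
    writeTemplates(templates, tplPath)
    res$templates <- templates
    res$artifacts["templates"] <- tplPath
  }, error = function(e) stageError("segment", e))
  if (done("segment")) return(invisible(res))

  ## features
  tryCatch({
    feat <- extractFeatureTable(epochSets, templates)
    featPath <- file.path(outDir, "features.csv")
    writeFeatureTable(feat, featPath)
    res$features <- feat
    res$artifacts["features"] <- featPath
  }, error = function(e) stageError("features", e))
  if (done("features")) return(invisible(res))

  ## rank (+ univariate table)
  tryCatch({
    ranking <- chi2RankFeatures(feat, nBins = config$nBins)
    uni <- univariateTable(feat)
    rankPath <- file.path(outDir, "ranking.csv")
    uniPath <- file.path(outDir, "univariate.csv")
    utils::write.csv(ranking, rankPath, row.names = FALSE)
    utils::write.csv(uni, uniPath, row.names = FALSE)
    res$ranking <- ranking
    res$univariate <- uni
    res$artifacts["ranking"] <- rankPath
    res$artifacts["univariate"] <- uniPath
  }, error = function(e) stageError("rank", e))
  if (done("rank")) return(invisible(res))

  ## classify
  tryCatch({
    topFeatures <- ranking$feature[seq_len(config$topK)]
    if (config$protocol == "subject_dependent") {
      report <- evaluateHoldout(feat, topFeatures,
                                testFraction = config$testFraction,
                                budget = config$budget, k = config$kFolds,
                                seed = config$seed)
    } else {
      report <- leaveOneSubjectOut(feat, topFeatures,
                                   budget = config$budget,
                                   k = config$kFolds, seed = config$seed)
    }
    repPath <- file.path(outDir, "report.json")
    jsonlite::write_json(
      list(protocol = report$protocol,
           accuracy = round(report$accuracy, 4),
           auc = round(report$auc, 4),
           sensitivity = round(report$sensitivity, 4),
           specificity = round(report$specificity, 4),
           confusion = report$confusion,
           bestLearner = report$bestLearner,
           bestParams = as.list(report$bestParams),
           features = report$features,
           seed = config$seed,
           configHash = unname(tools::md5sum(cfgPath))),
      repPath, auto_unbox = TRUE, digits = NA)
    res$report <- report
    res$artifacts["report"] <- repPath
    pipelineLog(logCon, "INFO",
                sprintf("classification [%s]: accuracy %.2f%% auc %.3f",
                        report$protocol, report$accuracy, report$auc))
  }, error = function(e) stageError("classify", e))
  done("classify")
  invisible(res)
}
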
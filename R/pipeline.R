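#' @include AllClasses.R AllGenerics.R io.R
NULL

#' Default pipeline parameters
#'
#' Nested list of every stage's tunable parameters with the package's
#' documented defaults: nuclei prominence 15 on the histogram-normalized
#' DAPI channel, marker prominences 40 (pEGFR) and 100 (CHGA), 0.1-99.9
#' percentile stretch, Otsu thresholding and a 10 px minimum branch length
#' for skeletons, average-linkage clustering on 1 - r, plateau response
#' mode for forskolin and peak for carbachol, 4PL bounds on the
#' percent-inhibition scale, 30 s pH baseline / 60 s rate / 10 percent
#' plateau windows, 0.6 circularity floor and 15 px tracking gate, and the
#' rescue filter cutoffs (FDR 0.05, |log2FC| >= 1, base mean >= 10).
#'
#' @return Nested named list of defaults.
#' @export
pipelineDefaults <- function() {
  list(
    seed = 1L,
    mxif = list(
      nucleiChannel = "DAPI",
      nucleiProminence = 15,
      markerProminences = c(pEGFR = 40, CHGA = 100),
      stretchPercentiles = c(0.1, 99.9),
      thresholdMethod = "otsu",
      minBranchLength = 10,
      linkage = "average"),
    isc = list(
      forskolinMode = "plateau",
      carbacholMode = "peak",
      baselineWindow = c(-60, 0),
      responseWindow = c(0, 180),
      pl4LowerBounds = c(0, 0, -6, 0.1),
      pl4UpperBounds = c(100, 100, 6, 10)),
    ph = list(
      preWindow = 30,
      rateWindow = 60,
      plateauFraction = 0.1),
    swell = list(
      minArea = 50,
      minCircularity = 0.6,
      maxDisplacement = 15),
    rescue = list(
      fdrCutoff = 0.05,
      minAbsLog2fc = 1,
      maxFdr = 0.05,
      minBaseMean = 10))
}

.mergeConfig <- function(defaults, user, path = "") {
  for (nm in names(user)) {
    full <- if (path == "") nm else paste0(path, "$", nm)
    if (!nm %in% names(defaults))
      stop("unknown configuration key: ", full, call. = FALSE)
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- .mergeConfig(defaults[[nm]], user[[nm]], full)
    } else {
      v <- user[[nm]]
      if (is.list(v)) v <- unlist(v)
      if (!is.null(names(defaults[[nm]])) && is.null(names(v)) &&
          length(v) == length(defaults[[nm]]))
        names(v) <- names(defaults[[nm]])
      defaults[[nm]] <- v
    }
  }
  defaults
}

#' Read a pipeline configuration file
#'
#' Loads a YAML configuration, validates it against [pipelineDefaults()]
#' (unknown keys are rejected) and fills unspecified parameters with their
#' defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Nested named configuration list.
#' @export
readPipelineConfig <- function(path = NULL) {
  defaults <- pipelineDefaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path))
    stop("configuration file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  .mergeConfig(defaults, user %||% list())
}

#' Run a simulate-then-analyze pipeline
#'
#' Executes the requested stages in order against one output directory.
#' The `simulate` stage generates one dataset per modality (multiplex
#' image, dose-inhibition current traces, pH trace, swelling masks, DE
#' tables) with truth sidecars; each analysis stage reads the simulated
#' inputs from the directory and writes its result tables. A JSON manifest
#' records the package version, parameters, seed, input digests and output
#' paths; on a stage failure the manifest records the failure before the
#' error is rethrown.
#'
#' @param config Configuration list from [readPipelineConfig()] (defaults
#'   when `NULL`).
#' @param stages Character vector drawn from `"simulate"`, `"mxif"`,
#'   `"isc"`, `"ph"`, `"swell"`, `"rescue"`.
#' @param outDir Output directory.
#' @param verbose Log one line per stage (default TRUE).
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config = NULL, stages = c("simulate", "mxif",
                                                  "isc", "ph", "swell",
                                                  "rescue"),
                        outDir, verbose = TRUE) {
  if (is.null(config)) config <- pipelineDefaults()
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  log <- function(...) if (verbose) message("[enteroquant] ", ...)
  manifest <- list(
    package = as.character(utils::packageVersion("enteroquant")),
    seed = seed, parameters = config, stages = list())
  outputs <- character()

  need <- function(path) {
    if (!file.exists(path))
      stop("required input not found: ", path, call. = FALSE)
    path
  }

  runStage <- function(name, fn) {
    log("stage ", name, " start")
    rec <- list(status = "ok")
    t0 <- Sys.time()
    res <- tryCatch(fn(), error = function(e) e)
    rec$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    if (inherits(res, "error")) {
      rec$status <- "failed"
      rec$error <- conditionMessage(res)
      manifest$stages[[name]] <<- rec
      manifest$status <<- "failed"
      jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA,
                           force = TRUE)
      stop("stage '", name, "' failed: ", conditionMessage(res),
           call. = FALSE)
    }
    rec$outputs <- res
    outputs <<- c(outputs, res)
    manifest$stages[[name]] <<- rec
    log("stage ", name, " done")
  }

  for (st in stages) {
    if (st == "simulate") runStage("simulate", function() {
      p <- character()
      mx <- genMxifImage(syntheticImageConfig(
        channels = list(spotChannel("DAPI", 50, 100, 2),
                        spotChannel("CHGA", 8, 150, 2),
                        spotChannel("pEGFR", 5, 80, 2),
                        ribbonChannel("CD10", 5, 60)),
        seed = seed))
      p <- c(p, writeMultichannelImage(mx$image, outDir, "mxif"))
      writeTruth(mx$truth, file.path(outDir, "mxif_truth.yaml"))
      run <- genDoseInhibitionRun(syntheticCrofelemerConfig(seed = seed))
      p <- c(p, writeAssayTrace(run$control,
                                file.path(outDir, "isc_dose0.tsv")))
      for (k in seq_along(run$doses))
        p <- c(p, writeAssayTrace(run$traces[[k]],
                                  file.path(outDir,
                                            sprintf("isc_dose%g.tsv",
                                                    run$doses[k]))))
      writeTruth(run$truth, file.path(outDir, "isc_truth.yaml"))
      ph <- genPhTrace(syntheticPhConfig(seed = seed))
      p <- c(p, writeAssayTrace(ph$trace, file.path(outDir, "ph.tsv")))
      writeTruth(ph$truth, file.path(outDir, "ph_truth.yaml"))
      for (arm in c("agonist", "agonist_inhibitor")) {
        sw <- genSwellingSeries(syntheticSwellingConfig(
          condition = "mvid", arm = arm, seed = seed))
        p <- c(p, writeLabelMasks(sw$masks,
                                  file.path(outDir,
                                            paste0("swell_", arm, ".tif"))))
        writeTruth(sw$truth,
                   file.path(outDir, paste0("swell_", arm, "_truth.yaml")))
      }
      de <- genDeTables(syntheticDeConfig(seed = seed))
      p <- c(p, writeDeTable(de$baseline,
                             file.path(outDir, "de_baseline.tsv")))
      p <- c(p, writeDeTable(de$treatment,
                             file.path(outDir, "de_treatment.tsv")))
      writeTruth(de$truth, file.path(outDir, "de_truth.yaml"))
      p
    })
    if (st == "mxif") runStage("mxif", function() {
      img <- readMultichannelImage(need(file.path(outDir, "mxif.tif")))
      cf <- config$mxif
      fr <- cellTypeFractions(img, cf$nucleiChannel,
                              cf$markerProminences,
                              cf$nucleiProminence)
      out1 <- file.path(outDir, "mxif_fractions.tsv")
      utils::write.table(fr, out1, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      sk <- skeletonizeMarker(img, method = cf$thresholdMethod,
                              minBranchLength = cf$minBranchLength,
                              channel = "CD10")
      fs <- feretDistances(sk)
      out2 <- file.path(outDir, "mxif_feret.tsv")
      utils::write.table(feretTable(fs), out2, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      cc <- clusterCorrelation(channelCrossCorrelation(img),
                               linkage = cf$linkage)
      out3 <- file.path(outDir, "mxif_correlation.tsv")
      utils::write.table(correlationMatrix(cc), out3, sep = "\t",
                         quote = FALSE, col.names = NA)
      c(out1, out2, out3)
    })
    if (st == "isc") runStage("isc", function() {
      cf <- config$isc
      tr <- readTruth(need(file.path(outDir, "isc_truth.yaml")))
      doses <- sort(unlist(lapply(
        list.files(outDir, "^isc_dose[0-9.]+\\.tsv$"),
        function(f) as.numeric(sub("^isc_dose([0-9.]+)\\.tsv$", "\\1", f)))))
      doses <- doses[doses > 0]
      control <- readAssayTrace(need(file.path(outDir, "isc_dose0.tsv")))
      traces <- lapply(doses, function(d) {
        readAssayTrace(file.path(outDir, sprintf("isc_dose%g.tsv", d)))
      })
      dr <- measureDoseInhibition(control, traces, doses,
                                  mode = cf$forskolinMode,
                                  baselineWindow = cf$baselineWindow,
                                  responseWindow = cf$responseWindow)
      fit <- fitDoseResponse(dr$dose, dr$inhibition,
                             lowerBounds = cf$pl4LowerBounds,
                             upperBounds = cf$pl4UpperBounds)
      out <- file.path(outDir, "isc_dose_response.tsv")
      utils::write.table(
        data.frame(dose = dr$dose, inhibition = dr$inhibition,
                   ic50 = fit@ic50, ceiling = fit@ceiling,
                   floor = fit@floor, slope = fit@slope,
                   converged = fit@converged),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
    if (st == "ph") runStage("ph", function() {
      cf <- config$ph
      trace <- readAssayTrace(need(file.path(outDir, "ph.tsv")), "au")
      truth <- readTruth(need(file.path(outDir, "ph_truth.yaml")))
      cal <- fitCalibration(clampSegments(trace))
      phTrace <- signalToPh(trace, cal)
      act <- nheActivity(phTrace, truthOf(truth)$readditionTime,
                         truthOf(truth)$recoveryWindow,
                         preWindow = cf$preWindow,
                         rateWindow = cf$rateWindow,
                         plateauFraction = cf$plateauFraction)
      out <- file.path(outDir, "ph_activity.tsv")
      utils::write.table(
        data.frame(delta_ph = act@deltaPh, rate = act@rate,
                   cal_slope = cal@slope, cal_intercept = cal@intercept),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
    if (st == "swell") runStage("swell", function() {
      cf <- config$swell
      res <- lapply(c("agonist", "agonist_inhibitor"), function(arm) {
        masks <- readLabelMasks(need(file.path(
          outDir, paste0("swell_", arm, ".tif"))))
        truth <- readTruth(file.path(outDir,
                                     paste0("swell_", arm, "_truth.yaml")))
        tset <- trackObjects(masks, times = unlist(truthOf(truth)$times),
                             maxDisplacement = cf$maxDisplacement,
                             minArea = cf$minArea,
                             minCircularity = cf$minCircularity)
        diameterRatio(tset)
      })
      inh <- swellingInhibition(res[[1]], res[[2]])
      out <- file.path(outDir, "swell_summary.tsv")
      utils::write.table(
        cbind(arm = rep(c("agonist", "agonist_inhibitor"),
                        vapply(res, function(r) nrow(r@summary),
                               integer(1))),
              rbind(res[[1]]@summary, res[[2]]@summary),
              percent_inhibition = inh),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      out
    })
    if (st == "rescue") runStage("rescue", function() {
      cf <- config$rescue
      baseline <- readDeTable(need(file.path(outDir, "de_baseline.tsv")))
      treatment <- readDeTable(need(file.path(outDir, "de_treatment.tsv")))
      hits <- oppositeDirectionFilter(baseline, treatment, cf$fdrCutoff)
      ranked <- prioritizeRescueGenes(hits, cf$minAbsLog2fc, cf$maxFdr,
                                      cf$minBaseMean)
      out <- file.path(outDir, "rescue_genes.tsv")
      utils::write.table(rescueGenes(ranked), out, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out
    })
  }

  manifest$status <- "ok"
  existing <- outputs[file.exists(outputs)]
  manifest$input_digests <- as.list(tools::md5sum(existing))
  manifest$outputs <- outputs
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}
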
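#' @include AllClasses.R AllGenerics.R
NULL

#' Configuration for synthetic differential-expression tables
#'
#' Describes three simulated DE contrasts (disease vs healthy baseline,
#' disease+drug vs disease treatment, healthy+drug vs healthy) with a
#' planted set of rescue genes: genes given a significant baseline effect
#' and a significant opposite-signed treatment effect by construction.
#' Null genes draw independent uniform adjusted p values in each contrast,
#' so they pass the rescue filter only at the nominal chance rate
#' (`cutoff^2 / 2` for opposite signs).
#'
#' @param nGenes Total gene count (default 2000).
#' @param nRescue Number of planted rescue genes (default 50; must be
#'   <= `nGenes`).
#' @param rescueBaselineLfcRange Absolute baseline log2FC range for planted
#'   genes (default 1.5-4).
#' @param rescueTreatmentLfcRange Absolute treatment log2FC range for
#'   planted genes (default 1.2-3).
#' @param nullLfcSd SD of null-gene log2FC (default 0.4).
#' @param seed Integer seed.
#' @return Config list of class `"syntheticDeConfig"`.
#' @export
syntheticDeConfig <- function(nGenes = 2000, nRescue = 50,
                              rescueBaselineLfcRange = c(1.5, 4),
                              rescueTreatmentLfcRange = c(1.2, 3),
                              nullLfcSd = 0.4, seed = 1) {
  if (nRescue > nGenes)
    stop("planted count must be <= gene count", call. = FALSE)
  structure(list(nGenes = as.integer(nGenes), nRescue = as.integer(nRescue),
                 rescueBaselineLfcRange = rescueBaselineLfcRange,
                 rescueTreatmentLfcRange = rescueTreatmentLfcRange,
                 nullLfcSd = nullLfcSd, seed = as.integer(seed)),
            class = "syntheticDeConfig")
}

#' Generate three synthetic DE contrast tables with planted rescue genes
#'
#' Planted rescue genes receive opposite-signed log2 fold changes above 1.2
#' in magnitude, adjusted p values below 0.01 in both the baseline and
#' treatment contrasts, and base means of at least 50, so they satisfy the
#' rescue definition (and the default prioritization thresholds) by
#' construction; all other genes are null in both contrasts. The
#' healthy+drug contrast is generated as a pure null table.
#'
#' @param config A [syntheticDeConfig()].
#' @return List with `baseline`, `treatment`, `healthyTreatment`
#'   ([DeContrastTable-class] objects) and `truth` (planted rescue gene
#'   ids and their planted effects).
#' @export
genDeTables <- function(config) {
  stopifnot(inherits(config, "syntheticDeConfig"))
  withr::with_seed(config$seed, {
    n <- config$nGenes
    genes <- sprintf("gene%05d", seq_len(n))
    planted <- sort(sample.int(n, config$nRescue))
    isR <- seq_len(n) %in% planted

    baseLfc <- stats::rnorm(n, 0, config$nullLfcSd)
    trtLfc <- stats::rnorm(n, 0, config$nullLfcSd)
    basePadj <- stats::runif(n)
    trtPadj <- stats::runif(n)
    basemean <- stats::rlnorm(n, log(50), 1)

    if (config$nRescue > 0) {
      sgn <- ifelse(stats::runif(config$nRescue) < 0.5, -1, 1)
      bmag <- stats::runif(config$nRescue,
                           config$rescueBaselineLfcRange[1],
                           config$rescueBaselineLfcRange[2])
      tmag <- stats::runif(config$nRescue,
                           config$rescueTreatmentLfcRange[1],
                           config$rescueTreatmentLfcRange[2])
      baseLfc[planted] <- sgn * bmag
      trtLfc[planted] <- -sgn * tmag
      basePadj[planted] <- 10^stats::runif(config$nRescue, -8, -2)
      trtPadj[planted] <- 10^stats::runif(config$nRescue, -8, -2)
      basemean[planted] <- pmax(stats::rlnorm(config$nRescue,
                                              log(200), 0.5), 50)
    }

    healthyLfc <- stats::rnorm(n, 0, config$nullLfcSd)
    healthyPadj <- stats::runif(n)

    mk <- function(contrast, lfc, padj) {
      DeContrastTable(contrast,
                      data.frame(gene = genes, log2fc = lfc, padj = padj,
                                 basemean = basemean,
                                 stringsAsFactors = FALSE))
    }
    list(baseline = mk("mvid_vs_healthy", baseLfc, basePadj),
         treatment = mk("mvid_dapt_vs_mvid", trtLfc, trtPadj),
         healthyTreatment = mk("healthy_dapt_vs_healthy", healthyLfc,
                               healthyPadj),
         truth = SyntheticTruth(
           list(rescueGenes = genes[planted],
                baselineLfc = baseLfc[planted],
                treatmentLfc = trtLfc[planted]),
           config$seed, "de"))
  })
}
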
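#' @include AllClasses.R AllGenerics.R
NULL

#' Opposite-direction rescue-gene filter
#'
#' Selects genes significantly altered at baseline between disease and
#' healthy enteroids that are significantly altered in the opposite
#' direction by drug treatment: `baseline FDR < cutoff` AND `treatment FDR
#' < cutoff` AND `sign(baseline log2FC) != sign(treatment log2FC)`, with
#' zero fold changes excluded. Genes absent from either table (or with
#' missing FDR) are excluded, not imputed.
#'
#' @param baseline [DeContrastTable-class] for the disease-vs-healthy
#'   baseline contrast.
#' @param treatment [DeContrastTable-class] for the treated-disease vs
#'   disease contrast.
#' @param fdrCutoff FDR significance cutoff applied to both contrasts
#'   (default 0.05, the upstream DE engine's cutoff).
#' @return A [RescueGeneSet-class]; direction class `"down_up"` means down
#'   in disease / up with drug, `"up_down"` the converse. Base mean is taken
#'   from the baseline table.
#' @export
oppositeDirectionFilter <- function(baseline, treatment, fdrCutoff = 0.05) {
  stopifnot(is(baseline, "DeContrastTable"), is(treatment, "DeContrastTable"))
  b <- contrastData(baseline)
  t <- contrastData(treatment)
  if (nrow(b) == 0L || nrow(t) == 0L)
    stop("empty contrast table", call. = FALSE)
  m <- merge(b, t, by = "gene", suffixes = c("_b", "_t"))
  if (nrow(m) == 0L)
    stop("the two contrasts share no genes", call. = FALSE)
  sig <- !is.na(m$padj_b) & !is.na(m$padj_t) &
    m$padj_b < fdrCutoff & m$padj_t < fdrCutoff &
    m$log2fc_b != 0 & m$log2fc_t != 0 &
    sign(m$log2fc_b) != sign(m$log2fc_t)
  hit <- m[sig, , drop = FALSE]
  genes <- data.frame(
    gene = hit$gene,
    baseline_log2fc = hit$log2fc_b,
    baseline_padj = hit$padj_b,
    treatment_log2fc = hit$log2fc_t,
    treatment_padj = hit$padj_t,
    basemean = hit$basemean_b,
    direction = ifelse(hit$log2fc_b < 0, "down_up", "up_down"),
    stringsAsFactors = FALSE)
  genes <- genes[order(genes$gene), ]
  rownames(genes) <- NULL
  new("RescueGeneSet", genes = genes, fdrCutoff = fdrCutoff,
      thresholds = list())
}

#' Prioritize rescue genes
#'
#' Applies effect-size, significance and expression-level thresholds to a
#' rescue gene set and ranks the survivors: members are dropped unless
#' `|treatment log2FC| >= minAbsLog2fc`, `treatment FDR <= maxFdr` and
#' `base mean >= minBaseMean`; the remainder are ranked by descending
#' `|treatment log2FC|`, ties by ascending treatment FDR, then gene id.
#'
#' @param x A [RescueGeneSet-class].
#' @param minAbsLog2fc Minimum absolute treatment log2 fold change
#'   (default 1).
#' @param maxFdr Maximum treatment FDR (default 0.05).
#' @param minBaseMean Minimum base mean expression (default 10).
#' @return The filtered, ranked [RescueGeneSet-class] (possibly empty).
#' @export
prioritizeRescueGenes <- function(x, minAbsLog2fc = 1, maxFdr = 0.05,
                                  minBaseMean = 10) {
  stopifnot(is(x, "RescueGeneSet"))
  if (minAbsLog2fc < 0 || maxFdr < 0 || minBaseMean < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  g <- rescueGenes(x)
  keep <- abs(g$treatment_log2fc) >= minAbsLog2fc &
    g$treatment_padj <= maxFdr & g$basemean >= minBaseMean
  g <- g[keep, , drop = FALSE]
  g <- g[order(-abs(g$treatment_log2fc), g$treatment_padj, g$gene), ,
         drop = FALSE]
  rownames(g) <- NULL
  new("RescueGeneSet", genes = g, fdrCutoff = x@fdrCutoff,
      thresholds = list(minAbsLog2fc = minAbsLog2fc, maxFdr = maxFdr,
                        minBaseMean = minBaseMean))
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' Per sample, the mean target Cq is normalized to the mean housekeeping
#' Cq (`dCt = Cq_target - Cq_housekeeping`); each test sample is then
#' referenced to the control sample (`ddCt = dCt_test - dCt_reference`) and
#' expressed as the fold change `2^-ddCt`.
#'
#' @param plate A [QpcrPlate-class] with target and housekeeping wells per
#'   sample (reactions typically in triplicate; well Cq values are averaged).
#' @param referenceSample Sample id of the control/reference sample.
#' @return data.frame with one row per sample x target gene: `sample`,
#'   `gene`, `delta_ct`, `delta_delta_ct`, `fold`, `condition`.
#' @examples
#' w <- rbind(
#'   data.frame(sample = "ref", gene = "G", cq = 26, role = "target"),
#'   data.frame(sample = "ref", gene = "HK", cq = 20, role = "housekeeping"),
#'   data.frame(sample = "tst", gene = "G", cq = 24, role = "target"),
#'   data.frame(sample = "tst", gene = "HK", cq = 20, role = "housekeeping"))
#' deltaDeltaCt(QpcrPlate(w), "ref")  # fold 4 for the test sample
#' @export
deltaDeltaCt <- function(plate, referenceSample) {
  stopifnot(is(plate, "QpcrPlate"))
  w <- plate@wells
  if (!referenceSample %in% w$sample)
    stop("reference sample '", referenceSample, "' not on the plate",
         call. = FALSE)
  samples <- unique(w$sample)
  hkMean <- vapply(samples, function(s) {
    hk <- w$cq[w$sample == s & w$role == "housekeeping"]
    if (length(hk) == 0L)
      stop("no housekeeping wells for sample '", s, "'", call. = FALSE)
    mean(hk)
  }, numeric(1))
  tg <- w[w$role == "target", , drop = FALSE]
  agg <- stats::aggregate(cq ~ sample + gene, data = tg, FUN = mean)
  agg$delta_ct <- agg$cq - hkMean[agg$sample]
  refDct <- agg[agg$sample == referenceSample, c("gene", "delta_ct")]
  names(refDct)[2] <- "ref_delta_ct"
  agg <- merge(agg, refDct, by = "gene")
  agg$delta_delta_ct <- agg$delta_ct - agg$ref_delta_ct
  agg$fold <- 2^(-agg$delta_delta_ct)
  cond <- unique(w[, c("sample", "condition")])
  out <- merge(agg[, c("sample", "gene", "delta_ct", "delta_delta_ct",
                       "fold")], cond, by = "sample")
  out[order(out$gene, out$sample), ]
}
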
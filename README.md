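# enteroquant

Quantitative analysis of patient-derived intestinal enteroid assays, built
for studies of microvillus inclusion disease (MVID) — the congenital
diarrheal disorder caused by loss-of-function *MYO5B* mutations — and of
candidate rescue treatments. It is aimed at labs running the standard
enteroid assay battery (multiplex immunofluorescence, Ussing-chamber
short-circuit current, SNARF-type intracellular pH imaging, forskolin
swelling assays, bulk RNA-seq contrasts, qPCR) who want the downstream
quantification to be reproducible, parameterized and testable.

## What it computes

* **Multiplex immunofluorescence.** Nuclei and marker-positive cells are
  counted as regional maxima with *prominence* above a threshold
  (h-maxima with strict comparison: a peak `p` is counted when
  `p − merge level > h`; defaults: 15 on histogram-normalized DAPI, 40/100
  on marker channels), and reported as fractions of nuclei. Brush-border
  continuity is scored by thresholding the CD10 channel, Zhang–Suen
  skeletonization with 10 px branch pruning, and the per-skeleton maximum
  Feret caliper `max_{i,j} ‖x_i − x_j‖`. Channel co-occurrence is the
  pairwise Pearson matrix over (masked) pixels, hierarchically clustered
  on `1 − r`.
* **Short-circuit current.** Baseline-subtracted agonist responses ΔIsc
  (plateau mode for sustained cAMP responses, peak mode for Ca²⁺
  transients), inhibitor-sensitive fractions
  `100·(ΔI_ctrl − ΔI_inh)/ΔI_ctrl`, percent change between groups, and
  four-parameter logistic dose–response fits in log₁₀ dose
  `y = floor + (ceiling − floor)/(1 + 10^{s(log₁₀IC₅₀ − log₁₀d)})`
  with [0, 100] bounds on the percent-inhibition scale.
* **NHE activity from pH traces.** Affine signal→pH calibration from
  nigericin/K⁺ clamps (pH 6/7/8), ΔpH over the Na⁺ re-addition recovery
  window, initial recovery rate, and inhibitor-corrected ΔpH.
* **Enteroid swelling.** Segmentation (Otsu + hole fill + circularity
  filter), nearest-centroid tracking, equivalent-diameter ratios
  `d(t)/d(t₀)` with `d = 2√(A/π)`, and percent inhibition of the swelling
  increment `100·(R̄_ag − R̄_ag+inh)/(R̄_ag − 1)`.
* **Rescue transcriptomics.** The opposite-direction filter on DE tables
  (baseline FDR < 0.05 AND treatment FDR < 0.05 AND opposite-signed log₂
  fold changes), threshold-based prioritization and ranking, and 2^−ΔΔCt
  qPCR quantification against a housekeeping gene.
* **Synthetic data with planted truth** for every modality (seeded spot and
  ribbon images, event-shaped Isc traces with 4PL dose inhibition, pH
  clamp/recovery traces, swelling disk series, three-contrast DE tables),
  so the entire pipeline is testable without instrument data.

## Worked example

Generate a synthetic multiplex field with 50 nuclei, 10 chromogranin-A
cells and 5 brush-border fragments of 60 px, then quantify it; then simulate
a crofelemer dose–response run and fit it:

```r
library(enteroquant)

mx <- genMxifImage(syntheticImageConfig(
  channels = list(spotChannel("DAPI", 50, 100, 2),
                  spotChannel("CHGA", 10, 150, 2),
                  ribbonChannel("CD10", 5, 60)),
  seed = 7))

cellTypeFractions(mx$image, "DAPI", c(CHGA = 100))
#>   marker count nuclei fraction  flag
#> 1   CHGA    10     50      0.2 FALSE

feretDistances(skeletonizeMarker(mx$image, channel = "CD10"))
#> FeretSummary over 5 skeleton component(s)
#>   caliper (px): mean 58.18 median 58 range [ 57.28 , 59.24 ]

run <- genDoseInhibitionRun(syntheticCrofelemerConfig(seed = 7))
dr  <- measureDoseInhibition(run$control, run$traces, run$doses)
fitDoseResponse(dr$dose, dr$inhibition)
#> DoseResponseFit (4PL): IC50 = 33.38  ceiling = 79.46 % floor = 1.034 % slope = 1.09
```

All 10 marker spots and all 50 nuclei are recovered (fraction 0.20, the
planted value); the five 60 px fragments skeletonize to calipers of ~58 px
(thinning erodes roughly one pixel per end); and a single noisy run fits
IC₅₀ ≈ 33 µM and maximal inhibition ≈ 79% against planted values of 30 µM
and 80% — across 20 seeded runs the medians converge to the planted
parameters.

## Command line

A thin wrapper over the package functions supports
`simulate | mxif | isc | ph | swell | rescue | run`:

```sh
Rscript inst/scripts/enteroquant run --out out/ --seed 1
Rscript inst/scripts/enteroquant rescue \
  --baseline de_baseline.tsv --treatment de_treatment.tsv \
  --out out/ --fdr 0.05 --min-lfc 1
```

Configuration is a single YAML file (`--config`) validated against
`pipelineDefaults()`; every run writes a JSON manifest with parameters,
seed, input digests and outputs.

## Documentation

See the methods vignette (`vignettes/enteroquant-methods.Rmd`) for the
models, parameter conventions, generator design and known limitations, and
the roxygen help pages for per-function reference.
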
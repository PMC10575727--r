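---
title: "Quantifying enteroid assays: methods and design notes"
author: "enteroquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying enteroid assays: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enteroquant)
```

# Scope

Microvillus inclusion disease (MVID) is a congenital diarrheal disorder
caused by loss-of-function mutations in *MYO5B*, the motor protein that
drives apical recycling in enterocytes. Patient-derived enteroids and
enteroid monolayers make the disease epithelium experimentally accessible,
and a consistent battery of quantitative readouts has emerged around them:
multiplex immunofluorescence counts of secretory cell types, a brush-border
continuity score, transepithelial short-circuit current (Isc) analysis,
intracellular pH kinetics as a readout of Na^+^/H^+^ exchanger (NHE3)
activity, forskolin-induced swelling as a readout of fluid secretion, and a
transcriptomic filter for genes whose disease-associated expression change
is reversed by a drug.

`enteroquant` implements these readouts as reusable, tested functions with
S4 containers, plus a synthetic-data generator for every input modality.
The generators plant known ground truth (spot centers, fragment lengths,
response amplitudes, 4PL parameters, pH recovery magnitudes, rescue-gene
sets, growth factors), so every analysis function can be validated by
recovering what was planted — no microscope, voltage clamp or sequencer is
required to exercise the full pipeline.

# Multiplex immunofluorescence

## Prominence-based counting

Nuclei and marker-positive cells are counted as regional maxima that stand
out from their surroundings by more than a *prominence* threshold. The
semantics implemented in `findMaxima()` are h-maxima with strict
comparison: a regional maximum with peak value $p$ is accepted when

$$p - \ell > h,$$

where $\ell$ is the highest level at which the maximum's superlevel-set
component touches a component containing a higher peak (its *merge level*),
and $h$ is the prominence. Equal peaks are tie-broken by the smallest
linear pixel index of the peak plateau; a maximum with no higher competitor
in its connected component is measured against the component minimum, so a
perfectly flat image contains no countable maxima. Plateau maxima
contribute one point each — the plateau pixel nearest the plateau centroid.

The implementation is a single union-find sweep over pixels in decreasing
intensity order, which computes every maximum's prominence exactly (this is
the persistence pairing of the intensity surface). The test suite checks it
for exact agreement against an independent brute-force oracle that labels
superlevel sets level by level.

Counting uses the conventional prominence settings: 15 for nuclei on the
histogram-normalized DAPI channel, and per-marker values (40 for
phospho-EGFR, 100 for chromogranin A) on the raw marker channels.
`cellTypeFractions()` reports each marker count as a fraction of the
nuclei count and flags fractions above 1, which sound input should never
produce. Which marker labels tuft versus enteroendocrine cells is left to
the caller's channel naming — both channels are treated identically.

"Histogram normalization" is implemented in `normalizeHistogram()` as a
0.1–99.9 percentile contrast stretch to [0, 255]. The percentile clipping
makes the stretch robust to isolated hot pixels while preserving rank order
among unclipped pixels; counting is covariant under joint rescaling of
image and prominence, so the exact normalization convention affects results
only through the fixed prominence values.

## Brush-border continuity (skeleton Feret calipers)

The continuity of the CD10-positive brush border is scored by reducing the
thresholded marker signal to one-pixel-wide skeletons and measuring each
skeleton's maximum Feret (caliper) distance — the largest Euclidean
distance between any two member pixels. Fragmented brush borders yield many
short skeletons; continuous ones yield fewer, longer skeletons, so the mean
caliper per image increases with ribbon continuity.

`skeletonizeMarker()` uses Otsu thresholding by default (a fixed threshold
can be supplied), Zhang–Suen thinning, and pruning at a minimum branch
length of 10 pixels: spur side-branches shorter than the minimum are
removed (including the one-pixel stub left where a spur meets a straight
run by diagonal contact), and components whose total pixel count is below
the minimum are discarded as background. Skeletons are 8-connected; branch
length is measured as pixels walked along the skeleton path.
`feretDistances()` computes the exact caliper via the convex hull of each
component; the tests verify exact agreement with all-pairs brute force.

## Channel cross-correlation

`channelCrossCorrelation()` computes the Pearson correlation between every
pair of channel intensity grids over the pixels of the tissue mask (all
pixels when no mask is given — the convention adopted here, since
correlation analyses of this kind are typically run on whole
background-corrected fields). Constant channels have undefined correlation;
they are set to `NA` with a warning and must be dropped before clustering.
`clusterCorrelation()` orders channels by average-linkage hierarchical
clustering on the dissimilarity $1 - r$; average linkage is the common
default for correlation clustering and is exposed as a parameter. The
matrix is invariant to affine rescaling of any channel, which the tests
assert directly.

# Short-circuit current analysis

`deltaIsc()` measures agonist responses as the difference between a
response statistic and the mean current over a baseline window preceding
the annotated event. Two response modes are provided, reflecting canonical
secretagogue kinetics: **plateau** (mean over the final third of the
response window) for sustained cAMP-driven responses such as forskolin, and
**peak** (maximum within the response window) for transient
Ca^2+^-driven responses such as carbachol. Which statistic underlies any
given published summary is rarely stated; these defaults are a declared
convention and both modes are available everywhere. The measure is
invariant to adding a constant to the whole trace.

`sensitiveFraction()` expresses an inhibitor-sensitive component as the
percentage of the control response blocked, flagging values above 100
(inhibited response below zero). `percentChange()` is the signed relative
reduction of a test group versus a reference — used, e.g., for the SGLT1
deficit of MVID monolayers, where the phlorizin-sensitive glucose-stimulated
current is the readout.

## Dose–response fitting

`fitDoseResponse()` fits percent inhibition $y$ against dose $d$ with a
four-parameter logistic in log~10~ dose,

$$y(d) = \mathrm{floor} + \frac{\mathrm{ceiling} - \mathrm{floor}}
  {1 + 10^{\,s\,(\log_{10}\mathrm{IC}_{50} - \log_{10} d)}},$$

by Levenberg–Marquardt least squares (`minpack.lm::nlsLM`). Because the
response is on the percent-inhibition scale, the floor and ceiling are
bounded to [0, 100] by default (overrideable); the slope is started at 1
and the IC~50~ at the dose nearest half-maximal response. At least four
distinct positive doses are required; a constant response is refused as
degenerate, and optimizer failure returns a fit object flagged
non-converged with `NA` parameters rather than an error.

# Intracellular pH and NHE activity

NHE3 activity is read out as the rate and magnitude of cytosolic
re-alkalinization after Na^+^ re-addition following an acidifying Na^+^-free
period. The fluorescence signal is calibrated at the end of each experiment
with nigericin/K^+^ clamps at known pH (6, 7 and 8 by convention).

`fitCalibration()` fits pH on mean clamp signal with an affine
least-squares map. Three clamp points over two pH units cannot constrain a
sigmoidal dye response, so the affine model is the honest choice at this
design; clamp means must be strictly monotone in pH or the calibration is
rejected. `signalToPh()` applies the map elementwise and flags (but still
returns) extrapolated samples outside the calibrated signal range — note
that noise makes roughly half the samples of the extreme clamp segments
nominally "outside" the range of clamp means, so the flag marks
extrapolation, not necessarily error.

`nheActivity()` uses declared window conventions: ΔpH is the mean pH over
the final 10% of the recovery window minus the mean over the 30 s before
re-addition, and the initial rate is the least-squares slope over the first
60 s of recovery (at least 5 samples required). All three windows are
parameters. `inhibitorCorrected()` subtracts the ΔpH of a paired
NHE-inhibitor condition, flooring at zero with a flag, to isolate the
NHE-dependent component.

# Enteroid swelling

Forskolin-induced swelling is quantified as the **equivalent circular
diameter ratio** relative to the first timepoint,
$d(t)/d(t_0)$ with $d = 2\sqrt{A/\pi}$ from the object's pixel area. The
equivalent diameter is robust for near-spherical enteroids and requires no
boundary parameterization. `segmentEnteroids()` thresholds (Otsu),
hole-fills and labels each frame, discarding objects below a minimum area
(50 px²) or circularity ($4\pi A / P^2 < 0.6$ — lumen-collapsed or
irregular objects). `trackObjects()` links objects across frames by greedy
nearest-centroid matching under a 15 px displacement gate; unmatched
objects open or close tracks.

Percent inhibition of swelling is defined on the swelling *increment*:

$$100 \times \frac{\bar R_\mathrm{ag} - \bar R_\mathrm{ag+inh}}
  {\bar R_\mathrm{ag} - 1},$$

using group means of the diameter ratios. On the increment scale a
non-swelling enteroid contributes zero stimulated secretion, matching the
"percent inhibition of stimulated secretion" framing; the quantity is
undefined (an error) when the agonist arm shows no swelling. Per-enteroid
ratios are also emitted so distribution summaries (median, IQR) can be
reported either way.

# Rescue transcriptomics

The package consumes differential-expression tables (gene, log~2~ fold
change, FDR-adjusted p, base mean) from an upstream DE engine; no DE model
is fitted here, since the bespoke analysis content is downstream.
`oppositeDirectionFilter()` selects *rescue genes*: significantly altered
at baseline between disease and healthy (FDR < 0.05) **and** significantly
altered in the opposite direction by drug treatment (same cutoff — the
treatment contrast's cutoff is not separately documented in this literature,
so the filter reuses the DE engine's 0.05 by default, configurable). Zero
fold changes are excluded; genes missing from either table are excluded
rather than imputed. The healthy+drug contrast is generated and reported
but deliberately not part of the filter predicate. The filter is checked
for exact agreement against a row-by-row predicate oracle and is symmetric
under a global sign flip of both tables.

`prioritizeRescueGenes()` applies effect-size, significance and expression
thresholds (defaults $|\log_2 FC| \ge 1$, FDR ≤ 0.05, base mean ≥ 10 —
values in the literature are shown graphically rather than printed, so
these defaults are this package's choice, all configurable) and ranks by
descending $|\log_2 FC|$ of the treatment contrast, ties by ascending FDR
then gene id.

`deltaDeltaCt()` implements relative qPCR quantification: per sample,
ΔCt = mean target Cq − mean housekeeping Cq (GAPDH by role annotation);
ΔΔCt versus the reference sample; fold change $2^{-\Delta\Delta Ct}$. The
fold change is invariant to any per-sample constant Cq shift, which is the
point of housekeeping normalization.

# Synthetic data: what it emulates, and what it does not

Every generator is seeded and returns a `SyntheticTruth` alongside its
dataset; regeneration with the same seed is identical, and all datasets
round-trip through plain-text/TIFF writers and readers.

* **Images** (`genMxifImage`): isotropic Gaussian spots for nuclei and
  scattered marker-positive cells; ribbon fragments as dilated line
  segments with known endpoint-to-endpoint lengths, placed without overlap
  (bounded retries, explicit error on failure); correlated channels as an
  affine rescaling of $\rho\,z_\mathrm{ref} + \sqrt{1-\rho^2}\,\varepsilon$,
  which hits the Pearson target exactly up to the added acquisition noise.
  Noise is additive Gaussian clipped at zero (background-corrected
  intensities are non-negative), with the noise field Gaussian-blurred
  (σ = 1 px by default) because real microscope noise is band-limited by
  the point-spread function — independent pixel noise would create
  spurious high-prominence maxima that no real background-corrected image
  exhibits. Acquisition noise levels are not documented for this assay
  family; the default (sd 1 on spot amplitudes of ~100) is chosen once as
  representative of averaged, background-corrected confocal data. There is
  no optical PSF model applied to the signal itself, no photobleaching and
  no shading: passing tests show the analysis recovers structure from
  idealized geometry plus noise, not that it is robust to every real-world
  artifact.

* **Isc traces** (`genIscTrace`, `genDoseInhibitionRun`,
  `genSglt1Traces`): constant baseline plus shaped event responses —
  saturating exponential (τ = 15 s) for sustained responses, alpha-function
  (τ = 30 s) for transients. Dose-inhibition runs scale a single combined
  secretagogue event by a true 4PL curve; the default crofelemer set uses
  floor 0, **ceiling 80%, IC~50~ 30 µM**, slope 1 at six doses (1–300 µM)
  with trace noise at 5% of the 50 µA/cm² stimulated response. The default
  glucose/phlorizin protocol gives control monolayers a 20 µA/cm²
  glucose-stimulated amplitude and MVID monolayers **60% less**, with
  phlorizin fully blocking the glucose-stimulated component, 4 monolayers
  per group and 10% between-monolayer CV. These effect sizes are the study
  conditions the acceptance analysis is run at.

* **pH traces** (`genPhTrace`): Na^+^-free plateau at pH 6.6, exponential
  recovery of configurable magnitude (default 0.5 pH) and rate
  (0.02 s⁻¹), then three clamp segments at pH 6/7/8 expressed through a
  stated affine signal map (slope 0.3 per pH unit). An inhibitor flag
  scales the recovery to 10% of its magnitude.

* **Swelling series** (`genSwellingSeries`): non-overlapping disks whose
  equivalent diameter follows a per-object jittered ratio schedule;
  defaults drive the mean ratio to 1.4 at 1 h under agonist in both
  conditions, with the inhibitor arm's increment reduced by **40%
  (healthy) or 50% (MVID)**. Masks are noise-free labels: the swelling
  tests exercise segmentation, tracking and the ratio arithmetic, not
  bright-field image formation.

* **DE tables** (`genDeTables`): planted rescue genes receive
  opposite-signed fold changes (|baseline| 1.5–4, |treatment| 1.2–3),
  adjusted p below 0.01 and base mean ≥ 50 in both relevant contrasts, so
  they satisfy the rescue definition by construction; null genes draw
  independent uniform adjusted p values and pass the filter only at the
  nominal chance rate (cutoff²/2). There is no read-level simulation and
  no correlation structure between genes.

# Numerical choices and degenerate inputs

* Strict inequality for prominence (`> h`), with deterministic
  lexicographic tie-breaking of equal peaks, so integer-valued images give
  reproducible counts.
* Constant images: histogram normalization returns them unchanged with a
  warning; automatic thresholding refuses them; correlation marks them
  `NA`; the maxima counter returns zero.
* Empty skeletons and empty segmentations warn and return empty containers;
  downstream summaries (`feretDistances`) error with a pointer to the
  upstream warning rather than silently producing NaN.
* The 4PL fit bounds log~10~ IC~50~ to [−6, 6] and the slope to [0.1, 10] to
  keep the optimizer on physically sensible curves; failures are flagged,
  never fatal.
* TIFF round trips are exact to 32-bit float precision (images) and exact
  for integer label masks up to 65535.

# Problem sizes

The default study-condition analyses are deliberately modest so a full
validation run completes on a single CPU in minutes: 256×256 px synthetic
fields, 20 seeds for trace-based recoveries, 5 series per arm for swelling,
100 random 64×64 grids and 100 random skeletons for the exact-agreement
oracle checks, and 20 replicate 10⁴-gene tables for the filter oracle.

# Known limitations

* The maxima counter assumes background-corrected input; it applies no
  background model of its own, so uncorrected illumination gradients will
  inflate counts.
* Skeleton branch length is approximated by pixel count, which undercounts
  diagonal runs by up to √2; at the 10 px pruning scale this changes
  results only for branches between 8 and 10 px of mostly diagonal steps.
* Tracking is greedy nearest-centroid with a gate; it does not handle
  merges, splits or long occlusions.
* The affine pH calibration extrapolates linearly outside the 6–8 clamp
  range (flagged); strongly acidic excursions below pH 6 are outside the
  validated map.
* The rescue filter treats contrasts as independent tables; genes filtered
  out upstream (e.g. independent-filtering NAs) are simply absent.
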
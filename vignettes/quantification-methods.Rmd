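---
title: "Quantification methods: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantification methods: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microquant)
```

`microquant` re-implements, as tested and reusable functions, the
immunofluorescence quantification readouts used to characterize amyloid
pathology, plaque-associated neuritic damage, microglial coverage and
activation, and Tau hyperphosphorylation in aged Alzheimer's-disease mouse
models, together with the rule-based single-cell RNA-seq quality control
and marker statistics applied to sorted hippocampal immune cells, and the
novel-object-recognition discrimination index. This vignette documents the
measurement models, the parameters that matter, the numerical conventions
that make the results bit-reproducible, and the limits of what the
synthetic test bed demonstrates.

## Image measurement model

All image metrics are compositions of a small set of primitives:

* **Projections.** Plaque and Tau area fractions are measured on maximum
  z-projections; the homeostatic-marker intensity readout uses a sum
  projection. Projections accumulate in double precision.
* **Automatic thresholds.** A 256-bin equal-width histogram is built over
  the observed intensity range of the analysis region (the 8-bit
  convention of the reference implementations of both algorithms). The
  amyloid, microglia, LAMP1, CD68 and Tau channels are thresholded with
  Otsu's between-class-variance criterion; the dense-core amyloid (MeX04)
  channel uses Kapur's maximum-entropy criterion, which is better suited
  to the small, bright, heavy-tailed foreground of an amyloid-binding dye.
  Both selectors return the upper edge of the best split bin; foreground
  is strictly greater than the threshold; ties resolve to the smallest
  threshold.
* **Particle analysis.** Connected components under 8-connectivity, with
  a physical size cut-off of 50 µm² for plaques: component area is
  `pixel count x pixel_size_um^2`, so every area scales exactly with the
  square of the calibration.
* **Physical morphology.** Masks are dilated with a Euclidean disc of
  micrometre radius (25 µm to capture the peri-plaque halo where
  dystrophic neurites accumulate, 5 µm for plaque-associated microglia).
  Dilation is 2-D, applied per z-plane: the z-step of the source stacks
  is not part of the calibration model, and no claim is made about
  axial geometry (see Limitations).
* **ROI algebra.** All metrics are restricted to a polygonal anatomical
  region (subiculum, CA1). Membership is decided at pixel centres under
  the even-odd rule, with centres lying exactly on an edge counted as
  inside; this fixed convention makes every denominator deterministic.

### Thresholding scope

Thresholds are computed **per region of interest**: the histogram is
built from the ROI's pixels only, so a bright structure outside the
region cannot shift the threshold inside it. For z-stack metrics one
threshold per channel is computed from the pooled ROI histogram across
all planes and applied plane-wise (the "stack histogram" convention),
keeping plane-to-plane measurements comparable within a stack. The one
exception is the background-subtracted intensity readout, where the
threshold is computed on the whole sum projection, because its role there
is to *find the background region of the image*, not to segment within
the ROI.

A consequence of per-ROI thresholding is that a region with no intensity
contrast (blank control sections, or an ROI lying entirely inside one
structure) has no defensible threshold. Such cases are reported as
degenerate: the metric value is 0 (or missing, for ratios) and a flag is
set on the report row. Degeneracy warns rather than errors so that batch
runs over many sections complete.

### Metric definitions

* **Plaque burden**: area fraction = suprathreshold pixels / ROI pixels
  (all suprathreshold pixels, not only retained particles); count and
  mean size from particle analysis at the 50 µm² cut-off.
* **MeX04/6E10 ratio**: dense-core (maximum-entropy) foreground over
  total amyloid (Otsu) foreground, both on max projections; the MeX04
  area fraction is reported alongside.
* **Neuritic damage (LAMP1/plaque)**: per plane, the size-filtered
  plaque particles are dilated 25 µm; microglial LAMP1 is removed
  (LAMP1 AND NOT microglia) and the remainder intersected with the halo;
  the ratio divides the summed colocalized pixels by the summed
  *non-dilated* plaque pixels. The denominator counts the size-filtered
  particle pixels — the same pixels that were dilated; counting all
  suprathreshold plaque pixels instead is available via
  `denominator = "all_thresholded"`.
* **Microglial coverage**: foreground fraction of the ROI, averaged over
  planes.
* **Plaque-associated microglia**: microglia colocalized with the 5-µm
  dilation of the per-plane thresholded plaque mask, over all microglial
  pixels. The 5-µm halo is applied to the raw thresholded mask (no size
  filter), matching the definition of the fraction; with a halo below
  one pixel the metric reduces to plain overlap.
* **CD68 in microglia**: binarized CD68 AND microglia over all microglial
  pixels — the proxy for phagocytic/activated microglia.
* **Background-subtracted intensity**: the sum projection's
  sub-threshold region defines the background level; the background mean
  is subtracted (clamped at zero) and averaged over suprathreshold ROI
  pixels. Restricting the final mean to suprathreshold pixels is a
  choice — it reads as "marker intensity where the marker is present";
  the whole-ROI mean is available via `suprathreshold_only = FALSE`.
* **Tau epitope ratio**: phospho-epitope area fraction over total-Tau
  area fraction (no size cut-off), both on max projections.

Undefined ratios (zero denominator) are reported as missing values with
a reason code, never as 0: coercing them to 0 would bias group means
downstream.

## Single-cell QC and marker statistics

The QC filter applies the gene-level rules first — ribosomal genes
(symbols starting `Rps`/`Rpl`, case-insensitive) and genes detected in
fewer than 3 cells are dropped — and then computes per-cell totals,
unique-feature counts and mitochondrial fractions (symbols starting
`mt-`) **on the gene-filtered matrix**. Cells are removed if they have
fewer than 200 detected features, more than 5% mitochondrial counts, or
more total transcripts than `mean + 3 SD`. The mean and SD of the
transcript cap are computed per sample/group over cells that survive the
*other* cell criteria, so a handful of grossly abnormal cells cannot
inflate the cap that is supposed to catch them; whether the original
analysis pooled samples for this step is not determinable, so per-group
is the default and is recorded in the QC report. Note that a
`mean + 3 SD` cap by construction also removes the most extreme ~0.1%
of a well-behaved cell population — that is a property of the rule, not
a defect of an implementation.

Marker detection normalizes each cell to 10,000 counts followed by
natural-log `log(1+x)` (the convention of the single-cell framework the
field uses, chosen so the log-fold-change gate of 0.25 is on the same
scale), computes the fold change as
`log(mean(expm1(A)) + 1) − log(mean(expm1(B)) + 1)`, tests only genes
with `|logFC| > 0.25` with the two-sided Wilcoxon rank-sum test (normal
approximation with tie correction, no continuity correction — the
large-sample regime of droplet data), and applies Benjamini–Hochberg
correction across the tested genes only. Because the same data decide
the gate and the test, genes whose group means differ by ~2 standard
errors can reach the significant set; with hundreds of cells per group
this affects genes near the gate, and planted 4-fold markers separate
from it by an order of magnitude.

Overrepresentation uses the upper-tail hypergeometric probability of the
observed overlap between a query list and each annotation set within a
stated universe, BH-corrected across sets.

## Behavioral index

`DI = (Tn − Tf) / (Tn + Tf)` with exclusion below 8 s of exploration.
The exclusion sentence admits two readings; the default interprets it as
*total* exploration `Tn + Tf < 8 s`, with the stricter per-object
reading available as `rule = "per_object"`. The default is a documented
choice, not an assertion about the original intent.

## Synthetic test bed

`scene_spec()`/`render_scene()` draw multi-channel scenes that emulate
the geometry the metrics were designed for: plaques as bright compact
discs (cores 6–14 µm radius at 1 µm/px) with a faint diffuse skirt out
to 1.4 R, a dense-core (MeX04) centre at 0.6 R, lobed microglial blobs
half of which are seeded on plaque rims, LAMP1 annuli concentric with
plaques, CD68 puncta inside microglia, and three sub-cut-off plaques
(radius 3 µm ≈ 28 µm² < 50 µm²) to exercise the particle filter. Default
intensities sit on a 12-bit-like scale (background 400, cores 1000).

**Noise model.** Noise is Gaussian with shot-noise scaling: the
per-pixel standard deviation is `noise_sd * sqrt(I_clean / background)`,
i.e. `noise_sd` parameterizes the background and brighter structures are
proportionally noisier, as in photon-limited confocal acquisition. A
homoscedastic Gaussian was considered and rejected: at low
signal-to-noise it gives the background the same absolute noise as the
brightest structures, which no confocal image shows, and under that
model *any* global histogram threshold collapses into the background
mode once the foreground is a few percent of the field (splitting a
pure Gaussian bulk already yields a between-class variance of
~0.64 σ², which out-competes a true foreground/background split of
small mass). Scene SNR is defined at the plaque core,
`(core − background) / sd(core)`; `noise_sd_for_snr()` inverts the
definition. Default scenes use `noise_sd = 25` (SNR ≈ 15); the recovery
properties are exercised at SNR 5.

**Count generator.** `matrix_spec()`/`sample_matrix()` draw
negative-binomial counts (size 2) around log-normal per-gene means, with
10 `mt-` genes carrying 1% of healthy expression — several standard
deviations below the 5% cap, so the planted/healthy dichotomy is sharp —
and 20 ribosomal genes. Planted failures shrink the library to 8% depth
(low-feature), inflate it 8-fold (high-count) or raise the mitochondrial
share to 25% (high-mito). Planted markers multiply a gene's mean by the
stated fold change in the second group and are drawn from genes at or
above the median baseline mean: a detection-rate contract over "markers"
presupposes transcripts that are detectable at all, as the biological
markers of interest are.

**What passing tests do and do not show.** The synthetic scenes have
piecewise-constant structures, independent pixel noise and no optical
blur, bleed-through, uneven illumination or section-to-section variance;
the count generator has no ambient RNA, doublets or batch structure.
Recovery of planted truth therefore validates the *measurement rules* —
thresholding, geometry, bookkeeping — not robustness to every real-world
artefact. Real sections additionally require the blinded, constant
acquisition settings the measurement model assumes.

## Numerical conventions and degenerate inputs

* Histograms: 256 equal-width bins over the observed range; a constant
  input yields a single populated bin and a degenerate (flagged)
  threshold with empty foreground.
* Tie-breaks: threshold selectors take the smallest optimal threshold;
  analytically tied splits (runs of empty bins) are resolved to the
  first within a 1e-10 relative tolerance of the criterion maximum,
  which keeps the vectorized implementation consistent with exhaustive
  search.
* Foreground is strictly greater than the threshold everywhere.
* The Euclidean dilation disc includes lattice offsets with
  `dx² + dy² ≤ r²` (with a 1e-9 slack so exact lattice radii are
  included); a radius of 3 px covers exactly 29 pixels.
* Constant genes get p = 1; groups smaller than 3 cells warn.
* All generators take a single integer seed and are bit-reproducible
  for a given seed.

## Problem sizes used in the checks

The bundled checks run entirely on synthetic data: 1,000 random
256-bin histograms for the threshold-oracle equivalences; 64x64
single-plane fixtures for the pixel-loop metric oracles; twenty
256x256x4 SNR-5 scenes for parameter recovery; 500-gene x 300-cell
matrices for QC fidelity; fifty 200-gene x 200-cell null replicates for
rank-sum calibration and fifty 100-cell replicates for planted-marker
power. These sizes were chosen to make the statistical assertions sharp
(binomial standard errors of a percent or less) while keeping a full
run in the tens of seconds on a laptop.

## Known limitations

* Morphology is strictly 2-D per plane; if the original macros dilated
  in 3-D, peri-plaque halos on sections with fine z-steps would differ.
* Per-ROI thresholds cannot segment regions without internal contrast;
  such regions are flagged, not guessed.
* The Wilcoxon normal approximation is inaccurate below ~10 cells per
  group (the exact-enumeration comparison in the tests quantifies the
  gap at n = 8); droplet datasets are far beyond that regime.
* Cluster labels are inputs: no clustering, dimensionality reduction,
  integration or annotation is performed here, and doublet/apoptotic
  exclusion beyond the stated thresholds is out of scope.
* The discrimination index is computed from scored exploration times;
  video tracking and scoring are upstream of this package.
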
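# microquant

Quantification pipelines for immunofluorescence readouts of amyloid,
microglial and Tau pathology in Alzheimer's-disease mouse models, with
the companion single-cell RNA-seq quality-control and marker statistics
and the novel-object-recognition discrimination index.

## Who this is for

Studies that manipulate microglia in amyloid/Tau models (e.g. CSF1R-
inhibitor depletion/repopulation paradigms) quantify their histology
with short compositions of the same primitives: automatic histogram
thresholds, particle analysis with a physical size cut-off,
micrometre-calibrated dilation, and mask colocalization algebra,
evaluated inside hand-drawn anatomical regions (subiculum, CA1). Those
compositions usually live in one-off image-analysis macros.
`microquant` provides them as tested R functions over calibrated image
stacks, plus the rule-based single-cell QC that typically accompanies
such studies, so every readout is reproducible and testable without the
microscope.

## The measurements

For a plaque channel thresholded by Otsu's criterion (maximum
between-class variance σ²_B = ω₀ω₁(μ₀−μ₁)² over all splits of a 256-bin
histogram; the MeX04 dense-core channel uses Kapur's maximum-entropy
criterion instead):

* plaque **area fraction** = suprathreshold px / ROI px; **count** and
  **mean size** from 8-connected particles ≥ 50 µm²;
* **LAMP1/plaque ratio** (dystrophic neurites): size-filtered plaques
  dilated 25 µm, intersected with non-microglial LAMP1, divided by the
  non-dilated plaque pixels;
* **plaque-associated microglia** = |microglia ∧ dilate(plaque, 5 µm)| /
  |microglia|; **coverage** = microglial foreground fraction;
  **CD68-in-microglia** = |CD68 ∧ microglia| / |microglia|;
* **background-subtracted intensity** of homeostatic markers (P2RY12)
  from sum projections;
* **phospho-Tau / total-Tau** area-fraction ratios.

Single-cell: genes in < 3 cells and ribosomal genes are excluded; cells
with < 200 features, > mean + 3 SD transcripts, or > 5% mitochondrial
counts are removed; markers are Wilcoxon rank-sum tests gated at
|logFC| > 0.25 with BH adjustment (padj < 0.05), on log-normalized
(10,000-scale, natural log) expression. Behavior:
DI = (Tn − Tf)/(Tn + Tf) with the 8-s exploration exclusion.

Seeded generators (`render_scene()`, `sample_matrix()`) produce
synthetic scenes and count matrices with exported ground truth, so the
whole pipeline is testable offline.

## Worked example

```r
library(microquant)

scene  <- render_scene(scene_spec(seed = 7))          # synthetic subiculum field
region <- rect_roi(1, 256, 1, 256, "subiculum")

plaque_burden(scene$stacks$plaque_6e10, region)
#> $area_fraction 0.0419   $count 8   $mean_size_um2 333   $flag ""
scene$truth$area_fraction; scene$truth$count; scene$truth$mean_size_um2
#> 0.04191589   8   332.875

neuritic_damage_ratio(scene$stacks$plaque_6e10, scene$stacks$lamp1,
                      scene$stacks$microglia, region)$ratio
#> 1.234322
plaque_associated_microglia(scene$stacks$plaque_6e10,
                            scene$stacks$microglia, region)$fraction
#> 0.4735216
```

The measured plaque burden (4.19% of the region, 8 plaques, mean size
333 µm²) matches the generator's geometric truth exactly at this noise
level; the LAMP1/plaque ratio of 1.23 says the non-microglial LAMP1
inside the 25-µm peri-plaque halos covers 1.23x the plaque area itself,
and 47% of microglial pixels lie within 5 µm of a plaque.

```r
sm <- sample_matrix(matrix_spec(n_low_feature = 10, n_markers = 2, seed = 7))
qc <- qc_filter(sm$matrix)
qc$report
#>            criterion removed
#>       ribosomal_gene      20
#>   low_detection_gene       0
#>     low_feature_cell      10      <- exactly the 10 planted cells
#>      high_count_cell       0
#>       high_mito_cell       0
#>             cells_in     300
#>            cells_out     290

mk <- wilcoxon_markers(log_normalize(qc$matrix),
                       which(qc$matrix$cell_group == "plx"),
                       which(qc$matrix$cell_group == "control"))
head(mk[order(mk$p_val), c("gene", "avg_logFC", "p_val_adj")], 2)
#>       gene avg_logFC p_val_adj
#>   Gene0050     1.411  3.38e-26      <- the two planted 4-fold markers
#>   Gene0053     1.409  8.17e-24

discrimination_index(c(15, 10, 3), c(5, 10, 4))
#>   tn tf  di excluded
#> 1 15  5 0.5    FALSE
#> 2 10 10 0.0    FALSE
#> 3  3  4  NA     TRUE       <- 7 s of exploration: excluded
```

File-based pipelines (`run_quantify()`, `run_scrna()`) take YAML
configurations and write long-format CSV reports plus a run manifest;
`inst/cli/microquant.R` exposes them as `quantify-image`, `scrna-qc`,
`behavior-di`, `simulate-images` and `simulate-counts` subcommands. ROI
polygons are JSON `(y, x)` vertex lists; images are TIFF; counts are
Matrix Market triplets or dense CSV. The same QC rules can be applied
to a downloaded public count matrix (e.g. a GEO accession) via
`read_counts()` + `qc_filter()`.

See `vignettes/quantification-methods.Rmd` for the measurement models,
parameter choices and limitations.

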
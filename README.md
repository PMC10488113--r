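# myoslice

Automated viability classification and structural analysis of
cardiomyocytes in multi-channel confocal images of myocardial tissue
slices.

Cultivated heart slices contain a mixture of living and dead
cardiomyocytes. A fixable fluorophore-conjugated dextran marks dead cells
(it only enters cells whose membrane has become permeable) and is treated
as the truth standard for death; ryanodine-receptor (RyR)
immunofluorescence marks viable myocytes, which show bright RyR clusters in
a striated z-line pattern, while dying cells lose or scramble the signal.
`myoslice` implements the image-analysis chain that quantifies this — and
evaluates how well RyR positivity predicts viability — from stitched tile
scans with WGA (extracellular matrix, membranes, t-tubules), RyR, dextran,
DAPI and optional SERCA / lipofuscin channels.

## Method core

* **Thresholding.** Per channel, a box-mean (default: whole-image mean) is
  subtracted and the mask is `residual >= t` with `t = c·σ + m`, where `σ`
  is the residual standard deviation and `m` the residual histogram mode;
  `c` is 2 (DAPI), 3 (RyR), 1 (WGA), 0.5 (dextran), 2 (SERCA), 4
  (lipofuscin). The binary lipofuscin mask is subtracted from the other
  masks; masks are majority-filtered (radius 1).
* **Segmentation.** Watershed on the negated Euclidean distance map of the
  WGA mask with h-maxima suppression (`h_min_um`, default 5 µm), minimum
  segment area 100 µm², deterministic labelling.
* **Classification.** With the RyR mask dilated by 4 px and the dextran
  mask by 3 px, a segment is RyR-positive when its dilated-RyR pixel
  fraction `f_RyR ≥ 0.15` and dextran-positive when `f_dextran ≥ 0.2`,
  giving the classes live (RyR+/Dx−), dead (RyR−/Dx+), double-positive and
  double-negative.
* **Structure.** Per cell: t-system by morphological closing difference
  (ΔTT = mean distance to the nearest t-tubule; skeleton density after
  thinning), nucleus area and circularity (short/long axis of the
  equivalent ellipse), RyR density (% positive pixels, undilated) and
  spectral regularity (fraction of AC image energy at radial spatial
  frequencies 1/2.5–1/1.5 µm⁻¹).
* **Accuracy.** Dextran negativity is truth for viability and RyR tests
  *for* viable cells: TP = RyR+/Dx−, FN = RyR−/Dx−, TN = RyR−/Dx+,
  FP = RyR+/Dx+; sensitivity, specificity, PPV, NPV, threshold-sweep ROC,
  force-versus-viability regression, Welch/paired t-tests with
  Holm–Bonferroni correction.

A synthetic slice generator (`generate_slice()`) renders fiber-aligned
rod-shaped myocytes with striated RyR clusters, cytosolic dextran fills,
punctate t-tubules, DAPI nuclei, lipofuscin granules, background gradients
and Poisson–Gaussian noise, with exact per-cell ground truth — every stage
of the pipeline is validated against it. See the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

```r
library(myoslice)

spec <- example_slice_spec(n_cells = 40, seed = 7)   # compact synthetic slice
sl   <- generate_slice(spec)
px   <- sl$image$pixel_size_um

wga  <- local_threshold(sl$image$channels$WGA,     threshold_config("WGA"), px)
lipo <- local_threshold(sl$image$channels$lipofuscin,
                        threshold_config("lipofuscin"), px)
ryr  <- subtract_lipofuscin(
          local_threshold(sl$image$channels$RyR, threshold_config("RyR"), px), lipo)
dex  <- subtract_lipofuscin(
          local_threshold(sl$image$channels$dextran,
                          threshold_config("dextran"), px), lipo)

cells   <- segment_cells(wga, px)
records <- classify_cells(cells, ryr, dex)
summarize_image(records, cells, ryr, dex,
                sl$image$channels$RyR, sl$image$channels$dextran)
accuracy_from_records(records)
```

prints

```
cell_label_map: 40 cells on a 1086 x 1086 grid (0.20 um/px)
image_summary: 40 cells

           live            dead double_positive double_negative
             17              18               1               4
double-positive: 2.8% of cells, 2.3% of pixels (union-referenced)
Pearson r (RyR vs dextran): -0.151
confusion: TP=17 FN=4 TN=18 FP=1
sensitivity 81.0%  specificity 94.7%  PPV 94.44%  NPV 81.82%
```

All 40 requested cells are segmented. Seventeen segments are RyR-positive
and dextran-negative (live), eighteen dextran-positive (dead), one is
double-positive (a dying intermediate) and four are double-negative
(non-myocyte stand-ins). The two stains overlap on only 2.3% of the
stain-positive pixel union, and the negative Pearson correlation reflects
their mutual exclusion. Treating dextran as truth, RyR positivity detects
viable cells with 81% sensitivity and 95% specificity here; the four
double-negative cells are exactly the false negatives. The full pipeline
(including structural metrics, nuclei, ROC and all file artifacts) runs via
`run_pipeline(run_config(spec))`, and `inst/cli/myoslice.R` wraps it for
the shell.

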
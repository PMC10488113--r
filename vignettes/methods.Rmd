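---
title: "Methods: viability classification and structural analysis of cardiomyocytes in slice images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: viability classification and structural analysis of cardiomyocytes in slice images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Organotypic myocardial tissue slices are cultivated for days in biomimetic
chambers, and their scientific value hinges on knowing which cardiomyocytes
are still alive. A fixable fluorophore-conjugated dextran enters only cells
whose membrane has become permeable, so dextran positivity marks dead
myocytes and is treated as the truth standard for death. Ryanodine-receptor
(RyR) immunofluorescence behaves complementarily: viable myocytes show
bright RyR clusters in a striated z-line pattern, while dead and dying
myocytes lose the signal. `myoslice` implements the full image-analysis
chain that turns a multi-channel confocal tile scan — wheat germ agglutinin
(WGA) for extracellular matrix, membranes and t-tubules, RyR, dextran, DAPI
for nuclei, and optionally SERCA and a lipofuscin autofluorescence channel —
into per-cell viability calls, structural metrics and diagnostic-accuracy
summaries of the RyR stain.

## Pipeline model and assumptions

**Thresholding.** Each channel is binarised with a histogram-based local
threshold. A box-mean filter (configurable box size, default the whole
image) is subtracted from the intensities; on the residual image the
standard deviation $\sigma$ and the histogram mode $m$ (unit-width bins on
rounded residuals, ties toward the smaller value) give the threshold
$t = c\,\sigma + m$, with channel-specific multipliers $c$: 2 for DAPI, 3
for RyR, 1 for WGA, 0.5 for dextran, 2 for SERCA and 4 for lipofuscin.
Pixels with residual $\ge t$ are signal. The mode-based construction
presumes that the most common intensity is background, i.e. that dark cell
interiors (or dark background) dominate the histogram. Two points are
deliberately resolved in the package's favour where the construction is
ambiguous: $\sigma$ is computed globally on the residual (locality enters
only through the box mean; a per-box $\sigma$ is available via
`local_sigma = TRUE`), and the threshold is applied to the residual rather
than the original intensities (`threshold_on = "original"` selects the
alternative). The binary lipofuscin mask is subtracted from the signal
masks, since lipofuscin granules autofluoresce across detection bands, and
masks are then majority ("median") filtered in a $(2r{+}1)^2$ window with
reflected borders, default radius 1.

**Segmentation.** Cells are separated by a watershed transform on the
negated Euclidean distance map of the WGA mask: every basin around a
regional distance maximum is a candidate cell, and maxima whose depth above
the separating saddle is less than `h_min_um` are suppressed. Watershed
regions are intersected with the complement of the WGA mask, sub-area
regions (below `min_cell_area_um2`, default 100 µm²) are merged into the
neighbouring label with the largest contact within a 2-px reach — which
re-attaches fragments cut off by thin intracellular WGA structures — or
dropped when isolated, and labels are renumbered in raster order, making
the output deterministic.

The default `h_min_um = 5` deserves its own paragraph, because the value is
constrained from two sides. The WGA channel contains not only the
extracellular matrix but also the transverse tubules inside each cell, as
rows of puncta spaced one sarcomere period (≈1.9 µm) apart. These puncta
carve basins into the intracellular distance map whose depth reaches one
sarcomere period, and substantially more where t-tubule coverage is patchy;
an `h_min_um` below that texture scale shatters cells into sarcomere-scale
fragments. The upper constraint is loose: distinct cells are separated by a
*zero-distance* ECM ridge, so raising `h_min_um` cannot merge two cells
that the WGA mask actually separates — only a suppression depth above the
cell's own central distance maximum (half the myocyte width, ≥ 5–9 µm)
would have any further effect. Half the smallest expected myocyte width,
5 µm, therefore sits safely above the intracellular texture and below the
inter-cell scale.

**Classification.** The binary RyR mask is dilated with a disk of radius 4
px and the dextran mask with radius 3 px (disk = offsets within the
Euclidean radius). For each segment, the dilated-positive pixel count
divided by the segment pixel count gives $f_\mathrm{RyR}$ and
$f_\mathrm{dextran}$; a segment is RyR-positive when
$f_\mathrm{RyR} \ge 0.15$ and dextran-positive when
$f_\mathrm{dextran} \ge 0.2$ (boundary values count as positive). The four
combinations are the classes live, dead, double-positive and
double-negative. The undilated RyR-positive percentage is carried
separately (`raw_ryr_density`) for density-style summaries, which by
convention do not use dilation. Image-level overlap summaries are pooled
over pixels and cells, not averaged over cells; the double-positive
fractions are referenced to the union of RyR- and dextran-positive cells
(or dilated pixels restricted to labelled area).

**Structural metrics.** The t-system is recovered per cell as the
difference between the morphologically closed and the original segment,
intersected with the WGA mask; the closing radius (default 5 px = 0.5 µm at
0.1 µm pixels) must exceed half the apparent tubule width (~0.2 µm radius
after blurring by the point-spread function) and invaginations wider than
twice the radius are not recovered — a documented limitation. ΔTT is the
mean Euclidean distance from interior pixels to the nearest t-system pixel;
skeleton density divides the pixel count of the Zhang–Suen-thinned
t-system by the total cell pixels. The denominator question (interior
alone vs interior plus t-system) is resolved as interior ∪ t-system.
Nuclei are 8-connected DAPI components of at least `min_nucleus_area_um2`
(default 10 µm², an invented speckle floor); axes come from the eigenvalues
of the second central moments (equivalent-ellipse convention), and
circularity is short/long axis. RyR regularity is the fraction of a cell's
AC spectral energy with radial spatial frequency between 1/2.5 and
1/1.5 µm⁻¹, bracketing the sarcomere period: intensities are mean-subtracted
over the interior, zeroed outside, Fourier transformed in 2D and integrated
radially. Computing on raw intensities (not the mask) and radially in 2D
are package choices where 1D/2D, mask/raw and windowing were open; an
axial-1D variant is available via `method = "axial1d"`. Cells shorter than
two periods of the lower band edge are flagged not evaluable; zero AC
power scores 0.

**Statistics.** The diagnostic-accuracy convention is fixed by the biology:
dextran is truth for death, RyR tests *for* viability, so TP = RyR+/Dx−,
FN = double-negative, TN = dead, FP = double-positive; sensitivity,
specificity, PPV and NPV follow, with zero denominators flagged rather than
imputed. The ROC sweeps the RyR threshold over a grid against fixed dextran
truth on the pooled cell set. Force–viability association uses ordinary
least squares with the F-test against the constant model. Per-image
summaries report median, mean and a normal-approximation 95% CI
(mean ± 1.96·SE; a bootstrap was considered and left out as the values
reported here are means of many cells). Group comparisons use two-tailed
Welch or paired t-tests with Holm–Bonferroni correction across each family.

## The synthetic slice generator

Because no reference image data are bundled, every stage is validated
against synthetic slices with exact ground truth. The generator emulates,
per channel, the features the pipeline actually consumes:

* capsule-shaped myocytes laid out in staggered rows along a common fiber
  direction (default 8° with 2.5° per-cell jitter), separated by a
  WGA-positive ECM gap (`wga_thickness_um`, default 1.2 µm). Candidates are
  still rejection-tested pixelwise against previously placed cells, with
  the attempt budget bounded at 50 per requested cell; tissue-like packing
  density matters because the mode-based WGA threshold assumes dark
  interiors dominate the histogram, which pure uniform-position rejection
  sampling cannot achieve.
* live cells: RyR clusters (Gaussian puncta, σ 0.18 µm) on a z-line lattice
  with `sarcomere_period_um` (default 1.9 µm) axial and 0.8 µm lateral
  spacing; no cytosolic dextran.
* dead cells: homogeneous cytosolic dextran fill, RyR at background.
* double-positive cells: dextran fill plus RyR clusters displaced by
  `ryr_jitter_um` (default 0.6 µm), slightly blurred and dimmed — the
  "irregular or blurred" appearance of dying cells.
* double-negative cells: myocyte-shaped segments with neither signal,
  standing in for non-myocytes.
* t-tubules in the WGA channel as rows of PSF-blurred puncta (radius
  ~0.2 µm, spacing 0.75 µm) on a class-dependent fraction of z-lines
  (defaults 0.9 live, 0.7 dead and double-positive, 0 double-negative);
  rows of puncta rather than solid lines match the appearance of the
  t-system in 2D confocal sections and keep the thresholded WGA mask from
  forming watertight intracellular barriers.
* elliptical DAPI nuclei (one or two per cell) with class-dependent area
  and axis ratio; defaults use the published live/dead nucleus areas
  (49.4 / 44.0 µm²) and axis ratios 0.45 / 0.60 so dead-cell nuclei are
  rounder.
* sparse lipofuscin granules that bleed into the RyR and dextran channels,
  a linear background gradient of random direction, and Poisson–Gaussian
  noise (photon gain then additive read noise) on a 12-bit range [0, 4095].

Absolute signal-to-background ratios are not published for any stain; the
default amplitudes (ECM 1800, tubule 1200, RyR 1600, dextran 1000, DAPI
2500, lipofuscin 3000 over background 90) are documented assumptions chosen
to look like a well-exposed confocal scan, not calibrated values. The
generator does **not** model optical point-spread functions, tile-stitching
artifacts, photobleaching, depth effects or 3D structure, and its cells are
geometrically cleaner than real myocytes; passing the validation suite
therefore demonstrates correctness of the algorithms under the stated image
model, not performance on real tissue.

Identical `(spec, seed)` pairs reproduce output bit for bit; the generator
saves and restores the caller's RNG state.

## Problem sizes and numerical choices in the validation suite

The test suite runs the generator at 0.2 µm pixels with 40 × 14 µm cell
profiles (`example_slice_spec()`): structural features remain several
pixels wide, while a 100-cell slice fits in a ~1700² image and a 200-cell
slice in ~2400². These sizes were chosen as the package's standard compact
fixture; the generator's physical defaults (0.1 µm pixels, 60 × 18 µm
cells) match high-magnification tile scans. Oracle tests use exact brute
force (all-pairs distances, direct threshold formula, neighbourhood-count
median filter) on images up to 32². Monte-Carlo calibrations (F-test
uniformity, slope CI coverage) use 1000 draws at n = 12 slices.

Other numerical conventions: thresholds compare with ≥ so boundary pixels
are signal; watershed plateau flooding and label numbering are
deterministic (raster order); Zhang–Suen subiterations update the whole
image in parallel; equivalent-ellipse axes use population moments without
discretisation correction (validated to ±3% on a 2 µm disk); the spectral
band is inclusive at both edges; cells touching the image border are not
specially excluded by the generator-facing tests.

## Known limitations

* The t-system closing cannot recover invaginations wider than twice the
  closing radius, and the skeleton density depends mildly on tubule width
  up to the thinning scale.
* Regularity estimates leak spectral energy outside the band for short
  cells; the not-evaluable flag bounds but does not remove this effect.
* The watershed tolerates small errors by design (overflow, occasional
  splits); no manual correction exists.
* Union-referenced overlap fractions are undefined on images without any
  positive cell and are flagged, not zero-filled.
* The accuracy report pools cells without area weighting; an area-weighted
  variant of the per-image summaries is a config switch away
  (`summarize_image` operates on whatever record subset it is given).
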
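---
title: "Quantifying tetramer-stained innate-like T cells in situ: models and methods"
author: "insitucyto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tetramer-stained innate-like T cells in situ}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

NKT and MAIT cells are rare innate-like T cells that can only be
identified unambiguously in tissue sections by staining with
antigen-loaded tetramers (CD1d–α-GalCer for NKT, MR1–5-OP-RU for MAIT)
*together with* a T-cell co-stain (CD3 or TCRβ) and negative controls,
because a small number of tetramer-bright objects in any section are not
T cells at all.  Once such cells can be called reliably, the scientific
read-outs are spatial: how many cells per unit tissue area, in which
anatomical compartment, at what distance from landmark boundaries, and
how those numbers shift after in-vivo activation.

`insitucyto` implements that whole analysis chain for multi-channel
fluorescence section images, plus a synthetic-tissue generator whose
exact ground truth makes every stage testable without access to original
microscopy data.

## Cell calling model

A *tetramer object* is an 8-connected component of tetramer-channel
pixels above a threshold, kept if its area lies in
[`min_area`, `max_area`] (defaults 10–200 µm², bracketing lymphocyte
cross-sections; the size gate is a reconstruction, as no published rule
exists).  An object becomes a *specific cell* when its mean CD3/TCRβ
intensity over the object footprint exceeds the co-stain threshold, and
specific cells split into CD4⁺/CD4⁻ subsets the same way.  Object-mean
(rather than pixel-overlap) co-staining is the simplest rule consistent
with colocation-based calling; an overlap-fraction variant can be built
from the same footprint statistics.  Touching cells may merge into one
object at this stage; separating them is the job of the histo-cytometry
segmenter, not the detector.

Counts are normalised to a 0.63 mm² reference field, the conventional
reporting unit for this assay.  The default synthetic field is 1024 ×
1024 px at 0.775 µm/px ≈ 0.63 mm², so one simulated field equals one
reported field.  (The acquisition parameters commonly quoted for this
kind of imaging — 76.9 nm lateral voxels in 1024² tiles — cannot be
reconciled arithmetically with 0.63 mm² fields, so pixel size and field
size are free configuration here, with the defaults chosen to honour the
0.63 mm² normalisation unit.)

## Thresholds come from negative controls

Every analysed channel is thresholded at the `q`-quantile (default
`q = 0.999`, quantile type 7) of that channel in a negative-control
image — a section that cannot contain true signal (control-ligand
tetramer, knockout tissue, unstained channel).  The published record for
this family of analyses states only that thresholds were "set based on
negative controls"; a fixed high quantile is the deterministic,
reproducible version of that operator judgement.  The quantile
definition (linear interpolation between order statistics) is pinned so
that thresholds are bit-reproducible.

One practical consequence, visible in the simulator: if a co-stain
channel contains genuine diffuse tissue signal (CD3 across the whole
T-cell zone), its control-calibrated threshold rises above that ambient
level.  That is the desired behaviour — it is exactly what keeps
non-specific tetramer objects that merely *sit inside* the T-cell zone
from being called T cells.

For *density* quantification in the activation-series analysis we use an
explicit half-amplitude tetramer threshold instead of the q = 0.999
control threshold.  The control threshold sits barely above background,
which makes object footprints wide (≈ 5 µm beyond the cell edge); at
day-3 densities wide footprints of neighbouring cells fuse and deflate
counts by 10–20 %.  A half-maximum cutoff keeps footprints at the
physical cell boundary, where the fusion rate is below 1 %.  Both
choices are exposed; nothing in the API hard-wires either.

## Colocalization

`pearson_coloc` is the plain sample Pearson correlation over the
analysed voxel set; `costain_area` counts dual-positive voxels and
converts to µm².  The analysed set defaults to the whole mask;
`restrict = TRUE` reproduces the behaviour of threshold-based commercial
colocalization modules by keeping only voxels above threshold in at
least one channel.  Published analyses are ambiguous about which of the
two was used, so both are first-class and reported side by side.
Zero-variance channels yield `NA` rather than an error: a blank channel
is degenerate but legal input.

## Region segmentation and spatial statistics

Compartments are segmented by smoothing each lineage channel with a
Gaussian (default 10 µm), thresholding (control-calibrated or Otsu),
labelling each pixel by the strongest positive marker (ties broken by a
fixed priority, CD3 > B220 and K5 > CD205), and regularising each
compartment mask with morphological closing then opening at half the
smoothing scale.  Pixels carrying no marker default to the residual
compartment (red pulp; cortex; lymph-node medulla).  Tissue extent comes
from the DAPI channel; because a section that fills the whole field has
no background mode, the Otsu split is only trusted when the putative
background class is distinctly dimmer (< 0.6×) than the tissue class.

Per-region statistics are counts, proportions of assigned specific cells
(these sum to 1; unassigned cells are reported separately) and densities
in cells/mm².  Activation fold changes are ratios of densities between
two conditions.  Pooling count and area over ~12 fields per condition
(roughly four mice at three images each, the scale of the underlying
study design) keeps the Poisson noise on even the smallest compartment's
ratio near 8 %, which is what makes ±20 % recovery of the planted
multipliers a fair test.  The fold-change recovery experiment uses the
generator's true region map so that it measures the density-ratio
estimator in isolation; segmentation accuracy is bounded by its own
tests.

The corticomedullary junction (CMJ) is taken as the medulla-side
boundary pixels (medulla pixels 4-adjacent to cortex).  Each medullary
cell's `distance_to_cmj_um` is the Euclidean distance to the nearest
boundary pixel, computed with an exact distance transform and verified
against brute-force nearest-boundary search to sub-pixel agreement.  The
100 µm band is medullary by definition — cortical cells are excluded —
and the original hand-drawn ROI is replaced by this automatic boundary
extraction, which is a reconstruction, not a reproduction, of the manual
procedure.

Medullary voids are 8-connected components of low-K5 pixels inside the
medulla mask with area strictly greater than 5000 µm²; components
touching the mask border count (they are still inside the ROI), and no
hole-filling or smoothing is applied before measurement, since the
original script's behaviour on that point is unrecorded.  Per-mouse
aggregation is the mean of image means.

## Histo-cytometry

Nuclei are segmented from DAPI by threshold + distance-transform
watershed; `seed_min_distance` (default 4 µm) sets the neighbourhood
radius used to find watershed seeds, and fragments below
`min_nucleus_area` (8 µm²) are dropped.  Per-cell features are the mean
of every channel over the nucleus footprint (an expanded cytoplasmic
ring is deliberately not the default; whole-nucleus export matches the
DAPI-surface convention).  Gates are 2-D rectangles or closed polygons
in feature space, organised in a tree; a cell gets the first leaf (in
document order) whose entire ancestor chain it satisfies, and `misc`
otherwise, so the populations always partition the cells.  Gate
boundaries are closed (a cell exactly on an edge is inside) — pinned so
an independent point-in-polygon oracle can check the engine exactly.
`asinh` transforms with a configurable cofactor (default 150) are
available as derived features.  The specific gate geometry shipped in
`default_gate_tree()` reproduces the canonical nine-population spleen
panel (B cells, CD11b⁻/CD11b⁺ DCs, macrophages, CD4± NKT, CD4± T,
misc); the published gates themselves are unavailable, so the engine,
not the gate coordinates, is the contribution.

## The synthetic-tissue generator

The generator is the package's study-condition definition, not a tuning
knob.  Its defaults encode:

* **Spleen**: three follicles (120 µm T-cell-zone core, 160 µm outer
  B-cell-zone ring) in red pulp; 100 specific NKT cells per field split
  70/15/15 across TCZ/BCZ/RP; 75 % CD4⁺ in the TCZ and 50 % elsewhere;
  5 non-specific tetramer-bright CD3⁻ objects per field.
* **Thymus**: two 180 µm medullary lobes in cortex; 60 medullary + 5
  cortical NKT cells, 90 % of medullary cells within 100 µm of the CMJ;
  optional voids carved from the K5 stain at configured areas.
* **Lymph node**: central paracortex, follicle ring, medullary
  remainder; 20 cells per field, 70 % paracortical.
* **Optics and noise**: cells are 3.5 µm-radius discs (nuclei 2.5 µm for
  DAPI), amplitude 500 over background 100 (signal-to-background 5),
  blurred by a 1 µm Gaussian PSF; intensities then receive Poisson shot
  noise and Gaussian read noise (sd 10).  Diffuse lineage stains (B220,
  CD3, CD205 at 150; K5 at 400) fill whole compartments.
* **Packing**: cell centres obey a hard-core minimum separation
  (default 7 µm = one cell diameter; 5.5 µm in the densely packed
  histo-cytometry panel so that adjacent nuclei can abut after PSF
  blur) — cells are solid bodies and do not interpenetrate.  Counts per
  compartment remain Poisson with the configured means.

Determinism is strict: every generative stage (geometry, each
population × region, non-specific objects, voids, each channel's noise)
draws from its own seed stream derived from the base seed, so a matched
negative control — the same configuration with double-positive
populations zeroed — reproduces the geometry, the non-specific objects
and every other shared structure exactly.  Voids are carved after PSF
blur (they are two orders of magnitude larger than the PSF, so edge
softening is negligible) to keep the carved pixel area an exact ground
truth.

What the simulator deliberately does **not** model: autofluorescence
texture, vascular structures, 3-D tissue, shape variation, intensity
heterogeneity between cells, and imaging artefacts such as tile seams.
Passing tests on this generator therefore demonstrate the correctness of
the measurement chain under its stated statistical model — not
performance on real tissue, where thresholds and size gates will need
the negative controls the method is built around.

## Numerical choices

* Gaussian smoothing is a separable convolution with the truncated
  kernel renormalised at image edges (replicate-style boundary),
  implemented as banded sparse-matrix products and memoised per
  (size, σ).
* Connected components are 8-connected (pixel-adjacency graph); the
  test-suite oracle is an independent BFS flood fill.
* Unmixing solves the per-pixel least-squares system through one QR
  factorisation of the mixing matrix, then clamps negatives to zero;
  constrained NNLS is intentionally out of scope at these problem
  sizes.  Rank deficiency is rejected at matrix construction.
* Images are stored as 16-bit multi-page TIFF with an `intensity_unit`
  scale in a JSON sidecar; integer data in [0, 65535] round-trips
  bit-exactly.
* Quantiles are type 7; Otsu uses 256 levels over the observed range.
* Region-label ties go to the priority channel; overlapping sibling
  gates go to the first leaf in document order; both are documented
  determinism guarantees rather than scientific claims.

## Problem sizes used in the shipped validation

The test suite and `scripts/acceptance.R` run, per execution: 20 paired
wild-type/control spleen fields and 20 thymus fields at the full
0.63 mm² default; activation series of 10–12 fields per condition and
seed; one ~850-cell histo-cytometry section; 100 random void masks; and
50 random Pearson / 20 unmixing trials.  These sizes put every binomial
or Poisson confidence band well inside the recovery tolerances being
asserted while keeping a complete run in the minutes range on one CPU.

## Known limitations

* The CMJ boundary is extracted automatically; analyses that depend on
  operator-drawn ROIs will differ near ambiguous cortex–medulla
  interfaces.
* Merged detections are not split at the detection stage by design;
  at densities far above the defaults, count-based densities will
  undercount unless the histo-cytometry segmenter is used.
* The simulator's marker amplitudes are free parameters; no published
  per-region intensity distributions exist to calibrate them against.
* `volume_um3` and z-positions are reported as `NA` after maximum
  projection; the package does not attempt 3-D segmentation.
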
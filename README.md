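# insitucyto

Quantification of rare innate-like T cells — NKT and MAIT cells — in
multi-channel fluorescence images of lymphoid tissue sections.

These cells cannot be identified in situ by any single stain: they are
called by antigen-loaded tetramer binding (CD1d–α-GalCer for NKT,
MR1–5-OP-RU for MAIT) **co-staining** with a T-cell marker (CD3/TCRβ),
with every intensity threshold calibrated on negative controls
(control-ligand tetramer or knockout tissue).  `insitucyto` implements
the measurement chain around that principle, for people analysing
multiplexed immunofluorescence of spleen, thymus and lymph node:

* **Channel processing** — linear spectral unmixing (per-pixel least
  squares `M f = d`, negatives clamped), spillover compensation
  (`S⁻¹ x`), and negative-control threshold calibration (the
  q = 0.999 quantile of a control image, quantile type pinned).
* **Colocalization** — Pearson correlation of paired voxel intensities,
  co-stained area in µm², and two-channel voxel histograms, with an
  optional threshold-restricted analysed set.
* **Cell calling** — 8-connected tetramer-bright objects in a
  10–200 µm² size window; specific cells by footprint-mean co-stain;
  CD4⁺/CD4⁻ subsets; counts per 0.63 mm² reference field.
* **Regions** — segmentation of splenic RP/BCZ/TCZ, thymic
  cortex/medulla and lymph-node F/P/M from lineage channels; per-region
  counts, proportions, densities (cells/mm²) and activation fold
  changes; cell counts within a 100 µm medullary band of the
  corticomedullary junction (exact Euclidean distance transform);
  medullary voids (K5-free areas > 5000 µm²).
* **Histo-cytometry** — DAPI watershed segmentation, per-cell feature
  export, hierarchical 2-D gating (rectangles/polygons, closed
  boundaries, asinh-derived features), and back-mapping of gated
  populations onto tissue coordinates.
* **Synthetic tissue** — a generator producing sections with exact
  ground truth (region geometry, per-compartment Poisson cell counts,
  hard-core packing, PSF blur, Poisson + Gaussian noise, matched
  negative controls, carved voids), so every stage above is tested
  against known truth.

The methods vignette (`vignettes/insitucyto-methods.Rmd`) documents the
models, defaults, numerical choices and limitations.

## Worked example

Simulate a wild-type spleen field (0.63 mm²) with its matched negative
control, calibrate thresholds on the control, and run the analysis:

```r
library(insitucyto)

cfg  <- spleen_sim_config(seed = 7)
wt   <- generate_section(cfg)
ctrl <- generate_negative_control(cfg)

th <- calibrate_thresholds(ctrl$image, c("CD1dTet", "CD3", "CD4"))
#>   channel threshold control_id     q
#> 1 CD1dTet  146.6862    control 0.999
#> 2     CD3  299.1574    control 0.999
#> 3     CD4  144.2602    control 0.999

cells <- detect_tetramer_objects(wt$image, "CD1dTet", th)
cells <- call_specific_cells(cells, "CD3", th)
cells <- classify_cd4_subset(cells, "CD4", th)
count_per_field(cells, wt$image$meta)
#> [1] 95

regions <- segment_regions(wt$image, "spleen")
cells   <- assign_cells(cells, regions, wt$image$meta)
region_stats(cells, regions, wt$image$meta)
#>     region count proportion area_mm2 density_per_mm2
#> RP      RP    14      0.147    0.381            36.7
#> BCZ    BCZ    16      0.168    0.113           141.4
#> TCZ    TCZ    65      0.684    0.136           479.6
```

95 specific NKT cells in the field, 68 % of them in the T-cell zone —
the planted conditions were 100 cells split 70/15/15.  Among TCZ NKT
cells, 75.4 % are CD4⁺ (planted: 75 %).  The specificity contrast shows
up in the colocalization statistics:

```r
pearson_coloc(wt$image,   "CD1dTet", "CD3")   # 0.466
pearson_coloc(ctrl$image, "CD1dTet", "CD3")   # 0.011
```

The tetramer signal correlates with CD3 only where true double-positive
cells exist.  `run_pipeline()` chains all of the above (plus CMJ band
and void analysis on thymus, and gating when a gate tree is supplied)
into a run directory with a content-hash manifest;
`summarize_mice()` aggregates run directories into per-group
mean ± SEM tables ready for external statistics.  A thin CLI wrapper
lives at `inst/cli/insitucyto.R`.

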
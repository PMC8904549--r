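# Shared fixtures.  Full-field sections are expensive, so each seed is
# generated and analysed once and the (small) per-seed summaries are
# memoised for reuse across test files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  hit <- .fixtures[[key]]
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  .fixtures[[key]] <- val
  val
}

# Small multi-channel image from plain matrices.
make_image <- function(channels, pixel_size = 1) {
  m <- image_meta(pixel_size, names(channels), ncol(channels[[1]]),
                  nrow(channels[[1]]))
  multichannel_image(channels, m)
}

# Uniform background + one rendered disc in selected channels (no noise):
# a fully controlled single-object scene.
disc_image <- function(size = 64, pixel_size = 1, bg = 100, amp = 500,
                       centre = c(32, 32), radius = 3.5,
                       channels = c("Tet", "CD3"), in_channels = channels) {
  mk <- function(on) {
    m <- matrix(bg, size, size)
    if (on) {
      for (r in seq_len(size)) for (c in seq_len(size)) {
        if ((r - centre[1])^2 + (c - centre[2])^2 <= (radius / pixel_size)^2)
          m[r, c] <- m[r, c] + amp
      }
    }
    m
  }
  chs <- lapply(channels, function(ch) mk(ch %in% in_channels))
  names(chs) <- channels
  make_image(chs, pixel_size)
}

# Full default wild-type spleen field + matched control, analysed end to
# end; returns compact per-seed summaries.
spleen_eval <- function(seed) fixture(paste0("spleen_eval_", seed), {
  cfg <- spleen_sim_config(seed = seed)
  wt <- generate_section(cfg)
  ctrl <- generate_negative_control(cfg)
  th <- calibrate_thresholds(ctrl$image, c("CD1dTet", "CD3", "CD4"))
  obj <- detect_tetramer_objects(wt$image, "CD1dTet", th)
  obj <- call_specific_cells(obj, "CD3", th)
  obj <- classify_cd4_subset(obj, "CD4", th)
  spec <- obj[which(obj$costain_positive), ]
  tr <- wt$truth$cells[wt$truth$cells$specific, ]
  m <- match_to_truth(spec, tr[, c("x_um", "y_um")])
  objc <- call_specific_cells(
    detect_tetramer_objects(ctrl$image, "CD1dTet", th), "CD3", th)
  rm <- segment_regions(wt$image, "spleen")
  cells <- assign_cells(obj, rm, wt$image$meta)
  st <- region_stats(cells, rm, wt$image$meta)
  # region-assignment accuracy on the *true* region map: each detected
  # specific cell is matched to its nearest planted cell and the assigned
  # region compared with the region recorded at planting time
  cells_truthmap <- assign_cells(spec, wt$regions, wt$image$meta)
  nearest_truth <- apply(
    outer(spec$x_um, tr$x_um, "-")^2 + outer(spec$y_um, tr$y_um, "-")^2,
    1, which.min)
  assign_acc <- mean(cells_truthmap$region == tr$region[nearest_truth])
  list(seed = seed,
       recall = m$recall, precision = m$precision,
       n_truth = m$n_truth, n_detected = m$n_detected,
       control_calls = sum(objc$costain_positive),
       wt_specific = sum(obj$costain_positive),
       stats = st,
       region_agreement = mean(rm$labels == wt$regions$labels),
       assign_acc_truthmap = assign_acc,
       cd4_frac = mean(spec$subset == "CD4pos"),
       n_specific = nrow(spec),
       truth_cd4 = mean(tr$population == "NKT_CD4pos"),
       pearson_wt = as.numeric(pearson_coloc(wt$image, "CD1dTet", "CD3")),
       pearson_ctrl = as.numeric(pearson_coloc(ctrl$image, "CD1dTet", "CD3")))
})

# Full default thymus field with CMJ distances measured.
thymus_eval <- function(seed) fixture(paste0("thymus_eval_", seed), {
  cfg <- thymus_sim_config(seed = seed)
  tt <- generate_section(cfg)
  ctrl <- generate_negative_control(cfg)
  th <- calibrate_thresholds(ctrl$image, c("CD1dTet", "CD3"))
  obj <- call_specific_cells(
    detect_tetramer_objects(tt$image, "CD1dTet", th), "CD3", th)
  cells <- assign_cells(obj, tt$regions, tt$image$meta)
  bc <- cmj_band_count(cells, tt$regions, tt$image$meta)
  list(seed = seed, cells = bc$cells, boundary_xy = tt$truth$cmj_xy,
       band = bc[setdiff(names(bc), "cells")],
       pixel_size = tt$image$meta$pixel_size_xy,
       n_medulla = sum(bc$cells$costain_positive &
                         bc$cells$region == "medulla", na.rm = TRUE))
})

# One thymus field with carved voids (kept whole for void tests).
thymus_voids_fixture <- function() fixture("thymus_voids", {
  cfg <- thymus_sim_config(seed = 7, void_spec = c(8000, 3000))
  tt <- generate_section(cfg)
  list(section = tt,
       medulla = tt$regions$labels == match("medulla", tt$regions$vocab))
})

# One histo-cytometry section analysed end to end (kept whole).
histo_fixture <- function() fixture("histo", {
  hh <- generate_section(histocytometry_sim_config(seed = 11))
  labels <- segment_nuclei(hh$image)
  feats <- extract_features(labels, hh$image)
  gated <- apply_gates(feats, default_gate_tree())
  list(section = hh, labels = labels, feats = feats, gated = gated)
})

# Population-assignment accuracy of a gated histo section vs truth:
# fraction of planted cells whose nearest segmented cell (within
# `max_dist` um) carries the correct population.
histo_accuracy <- function(gated, truth, max_dist = 4) {
  dx <- outer(gated$x_um, truth$x_um, "-")
  dy <- outer(gated$y_um, truth$y_um, "-")
  d <- sqrt(dx^2 + dy^2)
  nearest <- apply(d, 2, which.min)
  found <- apply(d, 2, min) <= max_dist
  mean(found & gated$population[nearest] == truth$population)
}
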
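# Tissue-compartment segmentation and per-region spatial statistics:
# region assignment, proportions/densities, activation fold changes,
# corticomedullary-junction distance bands, and medullary voids.

# Which lineage channel marks which compartment, and the compartment used
# for pixels carrying neither marker.  Tie-breaks on degenerate voxels use
# the listed order (first wins): CD3 > B220, K5 > CD205.
region_marker_scheme <- function(tissue) {
  switch(tissue,
    spleen = list(priority = c(TCZ = "CD3", BCZ = "B220"), default = "RP"),
    thymus = list(priority = c(medulla = "K5", cortex = "CD205"),
                  default = "cortex"),
    lymph_node = list(priority = c(P = "CD3", F = "B220"), default = "M"))
}

#' Segment tissue compartments from lineage marker channels
#'
#' Each marker channel is Gaussian-smoothed at `smoothing_scale`; pixels
#' are labelled by the largest smoothed marker that exceeds its
#' threshold (spleen: B220 -> BCZ, CD3 -> TCZ, neither -> RP; thymus:
#' K5 -> medulla, CD205 -> cortex; lymph node: B220 -> F, CD3 -> P,
#' neither -> M), restricted to the DAPI-positive tissue extent.  Each
#' compartment mask is then regularised by morphological closing followed
#' by opening at half the smoothing scale.
#'
#' @param image Single-plane [multichannel_image()].
#' @param tissue `"spleen"`, `"thymus"` or `"lymph_node"`.
#' @param marker_channels Named character vector mapping region label ->
#'   channel name; defaults per tissue (spleen `c(TCZ = "CD3", BCZ =
#'   "B220")`, thymus `c(medulla = "K5", cortex = "CD205")`, lymph node
#'   `c(P = "CD3", F = "B220")`).
#' @param smoothing_scale Smoothing sigma in um (default 10).
#' @param thresholds Optional [threshold_set()] for the marker (and DAPI)
#'   channels, applied to the *smoothed* channels; channels without an
#'   entry fall back to Otsu's threshold on the smoothed channel.
#' @param dapi_channel DAPI channel defining the tissue extent, or `NULL`
#'   to treat the whole field as tissue.
#' @return A [region_map()].
#' @export
segment_regions <- function(image, tissue, marker_channels = NULL,
                            smoothing_scale = 10, thresholds = NULL,
                            dapi_channel = "DAPI") {
  tissue <- match.arg(tissue, c("spleen", "thymus", "lymph_node"))
  scheme <- region_marker_scheme(tissue)
  markers <- marker_channels %||% scheme$priority
  missing_ch <- setdiff(markers, names(image$channels))
  if (length(missing_ch))
    stop_validation("required marker channels absent: ",
                    paste(missing_ch, collapse = ", "))
  px <- image$meta$pixel_size_xy
  sigma_px <- max(smoothing_scale / px, 0.5)
  smooth <- function(ch) gaussian_smooth(get_channel(image, ch), sigma_px)
  thr_of <- function(ch, sm) {
    if (!is.null(thresholds) && ch %in% thresholds$channel)
      threshold_for(thresholds, ch) else otsu_threshold(sm)
  }

  if (!is.null(dapi_channel) && dapi_channel %in% names(image$channels)) {
    dsm <- smooth(dapi_channel)
    thr <- thr_of(dapi_channel, dsm)
    # An Otsu split is only trusted when the putative background class is
    # distinctly dimmer than the tissue class; otherwise the section
    # fills the field and everything is tissue.
    trust <- !is.null(thresholds) && dapi_channel %in% thresholds$channel
    if (!trust) {
      lo <- mean(dsm[dsm <= thr])
      hi <- mean(dsm[dsm > thr])
      trust <- is.finite(lo) && is.finite(hi) && lo < 0.6 * hi
    }
    tissue_mask <- if (trust) dsm > thr
                   else matrix(TRUE, image$meta$height, image$meta$width)
  } else {
    tissue_mask <- matrix(TRUE, image$meta$height, image$meta$width)
  }

  vocab <- region_vocabulary(tissue)
  sm <- lapply(markers, smooth)
  pos <- lapply(seq_along(markers),
                function(i) sm[[i]] > thr_of(markers[i], sm[[i]]))
  # label by argmax of positive smoothed markers; ties go to the first
  # (higher-priority) marker in the scheme order
  best <- matrix(0L, nrow(tissue_mask), ncol(tissue_mask))
  best_val <- matrix(-Inf, nrow(tissue_mask), ncol(tissue_mask))
  for (i in seq_along(markers)) {
    take <- pos[[i]] & sm[[i]] > best_val
    best[take] <- match(names(markers)[i], vocab)
    best_val[take] <- sm[[i]][take]
  }
  best[best == 0L] <- match(scheme$default, vocab)
  # regularise each non-default compartment mask
  brush <- disc_brush(smoothing_scale / px / 2)
  labels <- matrix(match(scheme$default, vocab), nrow(best), ncol(best))
  for (nm in names(markers)[rev(seq_along(markers))]) {
    code <- match(nm, vocab)
    m <- best == code
    m <- EBImage::opening(EBImage::closing(m * 1, brush), brush) > 0.5
    labels[m] <- code
  }
  labels[!tissue_mask] <- 0L
  region_map(tissue, labels)
}

#' Assign detected cells to tissue compartments
#'
#' Each cell receives the region label at its centroid pixel; cells over
#' background get `"unassigned"`.
#'
#' @param cells A [cell_table()].
#' @param regions A [region_map()] congruent with the source image.
#' @param meta The [image_meta()] of the source image (for the um -> pixel
#'   mapping).
#' @return The table with a `region` column.
#' @export
assign_cells <- function(cells, regions, meta) {
  if (!nrow(cells)) {
    cells$region <- character(0)
    return(cell_table(cells))
  }
  px <- meta$pixel_size_xy
  r <- um_to_px(cells$y_um, px, nrow(regions$labels))
  c <- um_to_px(cells$x_um, px, ncol(regions$labels))
  code <- regions$labels[cbind(r, c)]
  cells$region <- ifelse(code > 0L, regions$vocab[pmax(code, 1L)],
                         "unassigned")
  cell_table(cells)
}

#' Per-region counts, proportions and densities
#'
#' Counts specific cells per compartment; proportions are of the total
#' assigned specific cells (so they sum to 1 over regions, with
#' unassigned cells reported separately), densities are cells per mm2 of
#' compartment area.
#'
#' @param cells A [cell_table()] with a `region` column; when a
#'   `costain_positive` column is present only positive cells count.
#' @param regions The [region_map()].
#' @param meta The [image_meta()] (pixel area for region areas).
#' @return data.frame with columns `region`, `count`, `proportion`,
#'   `area_mm2`, `density_per_mm2`; one extra `unassigned` row (NA
#'   proportion/area) when applicable.
#' @export
region_stats <- function(cells, regions, meta) {
  if (!"region" %in% names(cells))
    stop_validation("cells are not assigned to regions yet")
  keep <- if ("costain_positive" %in% names(cells))
    which(cells$costain_positive) else seq_len(nrow(cells))
  reg <- cells$region[keep]
  vocab <- regions$vocab
  px_area_mm2 <- meta$pixel_size_xy^2 / 1e6
  counts <- vapply(vocab, function(v) sum(reg == v, na.rm = TRUE), 0L)
  areas <- vapply(seq_along(vocab),
                  function(i) sum(regions$labels == i) * px_area_mm2, 0)
  if (any(areas == 0 & counts > 0))
    stop_validation("cells assigned to a zero-area region")
  n_assigned <- sum(counts)
  dens <- ifelse(areas > 0, counts / areas, 0)
  out <- data.frame(region = vocab, count = as.integer(counts),
                    proportion = if (n_assigned > 0) counts / n_assigned
                                 else rep(NA_real_, length(vocab)),
                    area_mm2 = areas, density_per_mm2 = dens,
                    stringsAsFactors = FALSE)
  n_un <- sum(reg == "unassigned", na.rm = TRUE)
  if (n_un > 0)
    out <- rbind(out, data.frame(region = "unassigned", count = n_un,
                                 proportion = NA_real_, area_mm2 = NA_real_,
                                 density_per_mm2 = NA_real_))
  out
}

#' Per-region density fold change between two conditions
#'
#' Ratio of per-region densities `b / a` (e.g., day 3 over day 0 of an
#' in-vivo activation series); `NA` where the baseline density is 0.
#'
#' @param stats_a,stats_b Outputs of [region_stats()] over the same
#'   region vocabulary.
#' @return data.frame with `region` and `fold_change`.
#' @export
fold_change <- function(stats_a, stats_b) {
  a <- stats_a[stats_a$region != "unassigned", ]
  b <- stats_b[stats_b$region != "unassigned", ]
  if (!identical(a$region, b$region))
    stop_validation("region vocabularies of the two conditions differ")
  fc <- ifelse(a$density_per_mm2 > 0,
               b$density_per_mm2 / a$density_per_mm2, NA_real_)
  data.frame(region = a$region, fold_change = fc, stringsAsFactors = FALSE)
}

# Medulla-side CMJ boundary pixels: medulla pixels with a 4-neighbour
# labelled cortex.
cmj_boundary_mask <- function(regions) {
  vocab <- regions$vocab
  med <- regions$labels == match("medulla", vocab)
  ctx <- regions$labels == match("cortex", vocab)
  if (!any(med) || !any(ctx))
    stop_validation("thymus region map must contain both cortex and medulla")
  nr <- nrow(med)
  nc <- ncol(med)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  med & (shift(ctx, 1, 0) | shift(ctx, -1, 0) |
         shift(ctx, 0, 1) | shift(ctx, 0, -1))
}

#' Count medullary cells within a distance band of the CMJ
#'
#' The corticomedullary junction (CMJ) is taken as the set of medulla
#' pixels bordering the cortex.  Every medullary cell gets its Euclidean
#' distance (um) to the nearest CMJ pixel (written into the returned
#' table as `distance_to_cmj_um`); the band zone is the medullary area
#' within `band_width` of the CMJ.  Cortical cells are excluded -- the
#' band is medullary by definition.
#'
#' @param cells A [cell_table()] with a `region` column (thymus labels).
#' @param regions A thymus [region_map()] containing cortex and medulla.
#' @param meta The [image_meta()].
#' @param band_width Band width in um (default 100).
#' @return List of class `band_count`: `band_width_um`, counts and
#'   densities (cells/mm2) inside/outside the band, zone areas, and
#'   `cells` (the table with distances filled in).
#' @export
cmj_band_count <- function(cells, regions, meta, band_width = 100) {
  boundary <- cmj_boundary_mask(regions)
  px <- meta$pixel_size_xy
  # distance of every pixel to the nearest CMJ pixel
  dist_px <- mat2(EBImage::distmap(1 - boundary))
  med <- regions$labels == match("medulla", regions$vocab)
  med_idx <- which(if ("costain_positive" %in% names(cells))
                     cells$costain_positive & cells$region == "medulla"
                   else cells$region == "medulla")
  cells$distance_to_cmj_um <- NA_real_
  if (length(med_idx)) {
    r <- um_to_px(cells$y_um[med_idx], px, nrow(med))
    c <- um_to_px(cells$x_um[med_idx], px, ncol(med))
    cells$distance_to_cmj_um[med_idx] <- dist_px[cbind(r, c)] * px
  }
  inside <- cells$distance_to_cmj_um[med_idx] <= band_width
  band_zone <- med & dist_px * px <= band_width
  px_area_mm2 <- px^2 / 1e6
  a_in <- sum(band_zone) * px_area_mm2
  a_out <- sum(med & !band_zone) * px_area_mm2
  n_in <- sum(inside)
  n_out <- sum(!inside)
  structure(list(
    band_width_um = band_width,
    n_inside = n_in, n_outside = n_out,
    area_inside_mm2 = a_in, area_outside_mm2 = a_out,
    density_inside_per_mm2 = if (a_in > 0) n_in / a_in else NA_real_,
    density_outside_per_mm2 = if (a_out > 0) n_out / a_out else NA_real_,
    cells = cell_table(cells)), class = "band_count")
}

#' Detect medullary voids in the keratin-5 stain
#'
#' Voids are continuous areas within the thymic medulla lacking K5
#' keratin stain and larger than `min_area` (default 5000 um2):
#' 8-connected components of medulla pixels with K5 at or below the
#' threshold.  Components touching the medulla border are retained --
#' they are still within the medullary ROI.
#'
#' @param image A [multichannel_image()] containing the K5 channel, or a
#'   plain K5 intensity matrix.
#' @param medulla_mask Logical matrix marking the medullary ROI.
#' @param meta The [image_meta()] (pixel area); may be omitted when
#'   `image` is a [multichannel_image()].
#' @param k5_channel K5 channel name (when `image` is multi-channel).
#' @param k5_threshold "Lacking stain" cutoff; default is a
#'   control-calibrated or Otsu threshold of the K5 intensities within
#'   the medulla.
#' @param min_area Minimum void area in um2, exclusive (default 5000).
#' @return List of class `void_report`: `void_areas_um2` (decreasing),
#'   `n_voids`, `mean_void_area_um2`, `min_area_um2`, `k5_threshold`.
#' @export
detect_voids <- function(image, medulla_mask, meta = NULL,
                         k5_channel = "K5", k5_threshold = NULL,
                         min_area = 5000) {
  if (inherits(image, "multichannel_image")) {
    k5 <- get_channel(image, k5_channel)
    meta <- meta %||% image$meta
  } else k5 <- image
  if (is.null(meta)) stop_validation("meta is required with a bare K5 matrix")
  if (!any(medulla_mask)) stop_validation("medulla mask is empty")
  thr <- k5_threshold %||% otsu_threshold(k5[medulla_mask])
  cand <- medulla_mask & (k5 <= thr)
  labels <- label_components(cand)
  px_area <- meta$pixel_size_xy^2
  areas <- if (max(labels) > 0)
    tabulate(labels[labels > 0], nbins = max(labels)) * px_area
  else numeric(0)
  voids <- sort(areas[areas > min_area], decreasing = TRUE)
  structure(list(void_areas_um2 = voids,
                 n_voids = length(voids),
                 mean_void_area_um2 = if (length(voids)) mean(voids) else NA_real_,
                 min_area_um2 = min_area,
                 k5_threshold = thr), class = "void_report")
}

#' Aggregate void reports per mouse (mean of image means)
#'
#' @param reports List of [detect_voids()] reports, one per image.
#' @param mouse Vector of mouse identifiers, one per report.
#' @return data.frame with per-mouse mean void count and mean void area.
#' @export
summarize_voids <- function(reports, mouse = rep("mouse1", length(reports))) {
  per_image <- data.frame(
    mouse = as.character(mouse),
    n_voids = vapply(reports, function(r) r$n_voids, 0L),
    mean_area = vapply(reports, function(r)
      if (is.na(r$mean_void_area_um2)) NA_real_ else r$mean_void_area_um2, 0))
  agg_n <- tapply(per_image$n_voids, per_image$mouse, mean)
  agg_a <- tapply(per_image$mean_area, per_image$mouse,
                  function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  data.frame(mouse = names(agg_n),
             mean_n_voids = as.numeric(agg_n),
             mean_void_area_um2 = as.numeric(agg_a[names(agg_n)]),
             stringsAsFactors = FALSE)
}
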
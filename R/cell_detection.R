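# Tetramer-positive object detection and specific-cell calling.
#
# A "cell" is a connected component of above-threshold tetramer pixels in
# a plausible size window; it is called a specific (NKT/MAIT) cell when
# its mean CD3/TCR intensity also exceeds the control-calibrated
# threshold, and split into CD4+/CD4- subsets by the CD4 channel.

#' 8-connected component labelling of a binary mask
#'
#' Labels connected sets of `TRUE` pixels using 8-connectivity (edge and
#' corner neighbours).  Labels are positive integers numbered in order of
#' each component's first pixel in column-major scan order; background is
#' 0.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of the same shape.
#' @export
label_components <- function(mask) {
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(out)
  vid <- integer(nr * nc)
  vid[idx] <- seq_along(idx)
  row_of <- (idx - 1L) %% nr + 1L
  col_of <- (idx - 1L) %/% nr + 1L
  # neighbour offsets in column-major order: S, E, SE, NE
  edges <- list()
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    ok <- row_of + o[1] >= 1L & row_of + o[1] <= nr & col_of + o[2] <= nc
    from <- idx[ok]
    to <- from + o[1] + o[2] * nr
    keep <- vid[to] > 0L
    if (any(keep))
      edges[[length(edges) + 1L]] <- rbind(vid[from[keep]], vid[to[keep]])
  }
  if (length(edges)) {
    g <- igraph::make_graph(edges = as.vector(do.call(cbind, edges)),
                            n = length(idx), directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  }
  memb <- igraph::components(g)$membership
  out[idx] <- match(memb, unique(memb))
  out
}

# Per-label summary of a labelled grid: areas (px), centroids (px), and
# mean intensity of each image channel over the label footprint.
label_features <- function(labels, image) {
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nlab <- max(labels)
  n_px <- tabulate(lab, nbins = nlab)
  nr <- nrow(labels)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  cen_r <- rowsum(rows, lab)[, 1] / n_px
  cen_c <- rowsum(cols, lab)[, 1] / n_px
  px <- image$meta$pixel_size_xy
  df <- data.frame(id = seq_len(nlab),
                   x_um = px_centre_um(cen_c, px),
                   y_um = px_centre_um(cen_r, px),
                   area_um2 = n_px * px^2)
  for (nm in names(image$channels)) {
    v <- image$channels[[nm]][idx]
    df[[paste0("mean_", nm)]] <- rowsum(v, lab)[, 1] / n_px
  }
  df
}

#' Detect tetramer-bright objects
#'
#' Connected components (8-connected) of tetramer-channel pixels above
#' the control-calibrated threshold, filtered to a plausible cell size
#' window.  Each retained object carries its centroid, area and mean
#' intensity in every channel over its footprint.
#'
#' @param image Single-plane [multichannel_image()] (apply
#'   [max_project()] to z-stacks first).
#' @param tet_channel Tetramer channel name.
#' @param thresholds A [threshold_set()] containing the tetramer channel.
#' @param min_area,max_area Object size window in um2 (defaults 10 and
#'   200, bracketing lymphocyte cross-sections).
#' @return A [cell_table()]; empty when nothing is detected.
#' @export
detect_tetramer_objects <- function(image, tet_channel, thresholds,
                                    min_area = 10, max_area = 200) {
  if (!(min_area > 0 && min_area < max_area))
    stop_validation("need 0 < min_area < max_area")
  if (image$meta$n_planes != 1L)
    stop_validation("detection operates on single-plane images; max_project first")
  thr <- threshold_for(thresholds, tet_channel)
  mask <- get_channel(image, tet_channel) > thr
  labels <- label_components(mask)
  if (max(labels) == 0L) {
    df <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                     area_um2 = numeric())
    for (nm in names(image$channels)) df[[paste0("mean_", nm)]] <- numeric()
    return(cell_table(df))
  }
  df <- label_features(labels, image)
  df <- df[df$area_um2 >= min_area & df$area_um2 <= max_area, , drop = FALSE]
  df$id <- seq_len(nrow(df))
  rownames(df) <- NULL
  cell_table(df, image$meta)
}

#' Call specific cells by T-cell co-staining
#'
#' Flags each tetramer object as a specific cell when its mean CD3/TCR
#' intensity over the object footprint exceeds the co-stain threshold.
#' Non-specific tetramer-bright objects are retained, flagged negative --
#' the contrast with negative controls depends on reporting both.
#'
#' @param objects A [cell_table()] from [detect_tetramer_objects()].
#' @param costain_channel CD3 or TCR-beta channel name.
#' @param thresholds A [threshold_set()] containing the co-stain channel.
#' @return The table with a logical `costain_positive` column.
#' @export
call_specific_cells <- function(objects, costain_channel, thresholds) {
  col <- paste0("mean_", costain_channel)
  if (!col %in% names(objects))
    stop_validation("objects carry no mean intensity for channel '",
                    costain_channel, "'")
  thr <- threshold_for(thresholds, costain_channel)
  objects$costain_positive <- objects[[col]] > thr
  cell_table(objects)
}

#' Split specific cells into CD4+ and CD4- subsets
#'
#' For costain-positive cells, `subset` is `"CD4pos"` when the mean CD4
#' intensity over the footprint exceeds the CD4 threshold, `"CD4neg"`
#' otherwise; costain-negative objects get `NA`.
#'
#' @param cells Output of [call_specific_cells()].
#' @param cd4_channel CD4 channel name.
#' @param thresholds A [threshold_set()] containing the CD4 channel.
#' @return The table with a `subset` column.
#' @export
classify_cd4_subset <- function(cells, cd4_channel, thresholds) {
  col <- paste0("mean_", cd4_channel)
  if (!col %in% names(cells))
    stop_validation("cells carry no mean intensity for channel '",
                    cd4_channel, "'")
  if (!"costain_positive" %in% names(cells))
    stop_validation("run call_specific_cells before classify_cd4_subset")
  thr <- threshold_for(thresholds, cd4_channel)
  cells$subset <- ifelse(cells$costain_positive,
                         ifelse(cells[[col]] > thr, "CD4pos", "CD4neg"),
                         NA_character_)
  cell_table(cells)
}

#' Specific-cell count normalised to a reference field area
#'
#' Scales the number of specific cells to the conventional 0.63 mm2
#' reporting field, making counts comparable across acquisition settings.
#'
#' @param cells A [cell_table()]; when a `costain_positive` column is
#'   present only positive cells are counted.
#' @param meta The [image_meta()] of the source field.
#' @param reference_area Reference area in mm2 (default 0.63).
#' @return Count per `reference_area`.
#' @export
count_per_field <- function(cells, meta, reference_area = 0.63) {
  fa <- field_area(meta)
  if (fa <= 0) stop_validation("field area must be positive")
  n <- if ("costain_positive" %in% names(cells))
    sum(cells$costain_positive, na.rm = TRUE) else nrow(cells)
  n * reference_area / fa
}

#' Match detected cells to ground-truth positions
#'
#' Greedy nearest-neighbour matching within `max_dist`: each truth
#' position may be claimed by the detections in order of increasing
#' distance; recall is the matched fraction of truth positions and
#' precision the matched fraction of detections.  Objects formed by two
#' touching cells can match both, so merging does not penalise recall.
#'
#' @param detected A [cell_table()] (optionally filtered to specific
#'   cells by the caller).
#' @param truth_xy Two-column matrix/data.frame of true centroids (um).
#' @param max_dist Match radius in um (default 10).
#' @return List with `recall`, `precision`, `n_detected`, `n_truth`.
#' @export
match_to_truth <- function(detected, truth_xy, max_dist = 10) {
  n_d <- nrow(detected)
  n_t <- nrow(truth_xy)
  if (n_t == 0L)
    return(list(recall = NA_real_, precision = if (n_d) 0 else NA_real_,
                n_detected = n_d, n_truth = 0L))
  if (n_d == 0L)
    return(list(recall = 0, precision = NA_real_, n_detected = 0L,
                n_truth = n_t))
  dx <- outer(detected$x_um, truth_xy[[1]], "-")
  dy <- outer(detected$y_um, truth_xy[[2]], "-")
  d <- sqrt(dx^2 + dy^2)
  truth_hit <- apply(d, 2, min) <= max_dist
  det_hit <- apply(d, 1, min) <= max_dist
  list(recall = mean(truth_hit), precision = mean(det_hit),
       n_detected = n_d, n_truth = n_t)
}
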
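# Voxelwise association between two stains: the specificity read-outs used
# to validate tetramer staining against negative controls (Pearson
# correlation, co-stained area, voxel plots).

coloc_pair <- function(image, chA, chB, mask) {
  a <- as.numeric(get_channel(image, chA))
  b <- as.numeric(get_channel(image, chB))
  if (is.null(mask)) keep <- rep(TRUE, length(a))
  else {
    if (length(mask) != length(a))
      stop_validation("mask shape does not match image")
    keep <- as.logical(mask)
  }
  if (!any(keep)) stop_validation("analysed set (mask) is empty")
  list(a = a[keep], b = b[keep])
}

#' Pearson colocalization coefficient of two channels
#'
#' Sample Pearson correlation of paired voxel intensities over the
#' analysed set.  By default the analysed set is the whole mask (or whole
#' image); with `restrict = TRUE` it is further limited to voxels above
#' the calibrated threshold in at least one of the two channels, which
#' mirrors threshold-based commercial colocalization modules.  Returns
#' `NA` when either channel is constant on the analysed set.
#'
#' @param image A [multichannel_image()] (single plane).
#' @param chA,chB Channel names.
#' @param mask Optional logical matrix restricting the analysed voxels.
#' @param thresholds A [threshold_set()]; required when `restrict = TRUE`.
#' @param restrict If `TRUE`, analyse only voxels above threshold in at
#'   least one channel.
#' @return Pearson r in \[-1, 1\] (or `NA`), with attribute `n_voxels`.
#' @export
pearson_coloc <- function(image, chA, chB, mask = NULL, thresholds = NULL,
                          restrict = FALSE) {
  p <- coloc_pair(image, chA, chB, mask)
  if (restrict) {
    if (is.null(thresholds))
      stop_validation("restrict = TRUE requires thresholds for both channels")
    tA <- threshold_for(thresholds, chA)
    tB <- threshold_for(thresholds, chB)
    keep <- p$a > tA | p$b > tB
    if (!any(keep)) stop_validation("analysed set is empty after restriction")
    p$a <- p$a[keep]
    p$b <- p$b[keep]
  }
  r <- if (stats::sd(p$a) == 0 || stats::sd(p$b) == 0) NA_real_
       else stats::cor(p$a, p$b)
  structure(r, n_voxels = length(p$a))
}

#' Area co-stained by two channels
#'
#' Counts analysed voxels above threshold in both channels and converts
#' to physical area.
#'
#' @inheritParams pearson_coloc
#' @param thresholds A [threshold_set()] holding both channels.
#' @return List with `area_um2`, `fraction` (of analysed voxels) and
#'   `n_voxels` (co-stained count).
#' @export
costain_area <- function(image, chA, chB, thresholds, mask = NULL) {
  p <- coloc_pair(image, chA, chB, mask)
  tA <- threshold_for(thresholds, chA)
  tB <- threshold_for(thresholds, chB)
  n_co <- sum(p$a > tA & p$b > tB)
  px_area <- image$meta$pixel_size_xy^2
  list(area_um2 = n_co * px_area,
       fraction = n_co / length(p$a),
       n_voxels = n_co,
       n_analysed = length(p$a))
}

#' Two-channel voxel intensity histogram ("voxel plot")
#'
#' 2-D histogram of paired voxel intensities with equal-width bins
#' spanning each channel's observed range on the analysed set.  The
#' histogram total equals the analysed voxel count.
#'
#' @inheritParams pearson_coloc
#' @param n_bins Number of bins per axis (>= 2).
#' @return Integer `n_bins x n_bins` count matrix with attributes
#'   `breaks_a`, `breaks_b`.
#' @export
voxel_scatter <- function(image, chA, chB, n_bins = 64L, mask = NULL) {
  if (n_bins < 2) stop_validation("n_bins must be >= 2")
  p <- coloc_pair(image, chA, chB, mask)
  bin_index <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(list(idx = rep(1L, length(v)),
                                    breaks = rng[1] + 0:n_bins))
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- findInterval(v, breaks, rightmost.closed = TRUE)
    list(idx = pmin(idx, n_bins), breaks = breaks)
  }
  ia <- bin_index(p$a)
  ib <- bin_index(p$b)
  h <- matrix(0L, n_bins, n_bins)
  tab <- table(factor(ia$idx, levels = seq_len(n_bins)),
               factor(ib$idx, levels = seq_len(n_bins)))
  h[] <- as.integer(tab)
  structure(h, breaks_a = ia$breaks, breaks_b = ib$breaks)
}

#' Display a voxel histogram
#' @param hist Output of [voxel_scatter()].
#' @param ... Passed to [graphics::image()].
#' @export
plot_voxel_hist <- function(hist, ...) {
  graphics::image(attr(hist, "breaks_a"), attr(hist, "breaks_b"),
                  log1p(unclass(hist)), xlab = "channel A", ylab = "channel B",
                  ...)
  invisible(hist)
}
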
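#' Spectral mixing / spillover matrix
#'
#' Non-negative matrix mapping pure fluorophore intensities to detected
#' channel intensities, `detected = M %*% pure`.  Rows are detector
#' channels, columns fluorophores.  Full column rank is required so the
#' linear system can be inverted by [unmix_channels()].
#'
#' @param entries Numeric matrix (detectors x fluorophores), entries >= 0.
#' @param detectors,fluorophores Channel name vectors; default to the
#'   dimnames of `entries`.
#' @return Object of class `mixing_matrix` (a named matrix).
#' @export
mixing_matrix <- function(entries,
                          detectors = rownames(entries),
                          fluorophores = colnames(entries)) {
  entries <- as.matrix(entries)
  if (is.null(detectors)) detectors <- paste0("det", seq_len(nrow(entries)))
  if (is.null(fluorophores)) fluorophores <- paste0("fluo", seq_len(ncol(entries)))
  if (anyNA(entries) || min(entries) < 0)
    stop_validation("mixing matrix entries must be non-negative")
  if (qr(entries)$rank < ncol(entries))
    stop_validation("mixing matrix is rank deficient: columns {",
                    paste(fluorophores, collapse = ", "),
                    "} are linearly dependent")
  dimnames(entries) <- list(detectors, fluorophores)
  class(entries) <- c("mixing_matrix", class(entries))
  entries
}

#' Read/write a mixing matrix as CSV with named header row/column
#' @param path CSV path.
#' @param m A [mixing_matrix()].
#' @return The matrix (reader) or `path` invisibly (writer).
#' @export
read_mixing_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  mixing_matrix(as.matrix(df))
}

#' @rdname read_mixing_matrix
#' @export
write_mixing_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)), path, row.names = TRUE)
  invisible(path)
}

# Flatten channels to a (channels x pixels) matrix and back.
channels_to_mat <- function(image) {
  do.call(rbind, lapply(image$channels, function(ch) as.numeric(ch)))
}

mat_to_channels <- function(mat, template, new_names) {
  d <- dim(template$channels[[1]])
  channels <- lapply(seq_len(nrow(mat)), function(i) array(mat[i, ], dim = d))
  names(channels) <- new_names
  m <- template$meta
  meta <- image_meta(m$pixel_size_xy, new_names, m$width, m$height,
                     m$n_planes, m$pixel_size_z)
  multichannel_image(channels, meta)
}

#' Forward spectral mixing of pure fluorophore channels
#'
#' Applies `detected = mixing %*% pure` per pixel; the forward model whose
#' inverse is [unmix_channels()].  Channel names become the detector
#' names.
#'
#' @param image A [multichannel_image()] of pure fluorophore channels.
#' @param mixing A [mixing_matrix()] with one column per image channel.
#' @return Mixed [multichannel_image()] with detector channel names.
#' @export
mix_channels <- function(image, mixing) {
  if (ncol(mixing) != length(image$channels))
    stop_validation("mixing matrix has ", ncol(mixing),
                    " fluorophore columns but image has ",
                    length(image$channels), " channels")
  out <- unclass(mixing) %*% channels_to_mat(image)
  mat_to_channels(out, image, rownames(mixing))
}

#' Linear spectral unmixing
#'
#' Recovers per-pixel fluorophore intensities from detected channels by
#' least squares (`mixing %*% f = detected`), clamping negative solutions
#' to zero.  Channel names become the fluorophore names.
#'
#' @param image Detected [multichannel_image()]; channel count must equal
#'   the detector (row) count of `mixing`.
#' @param mixing A [mixing_matrix()] (full column rank, enforced by its
#'   constructor).
#' @return Unmixed [multichannel_image()].
#' @export
unmix_channels <- function(image, mixing) {
  if (nrow(mixing) != length(image$channels))
    stop_validation("mixing matrix has ", nrow(mixing),
                    " detector rows but image has ",
                    length(image$channels), " channels")
  qrm <- qr(unclass(mixing))
  f <- qr.coef(qrm, channels_to_mat(image))
  f[f < 0] <- 0
  mat_to_channels(f, image, colnames(mixing))
}

#' Conventional spillover compensation
#'
#' Applies `corrected = solve(spillover) %*% observed` per pixel, clamping
#' at zero.  The spillover matrix must be square with unit diagonal.
#'
#' @param image Observed [multichannel_image()].
#' @param spillover Square [mixing_matrix()] with unit diagonal.
#' @return Compensated [multichannel_image()] (channel names unchanged).
#' @export
compensate <- function(image, spillover) {
  s <- unclass(spillover)
  if (nrow(s) != ncol(s))
    stop_validation("spillover matrix must be square")
  if (any(abs(diag(s) - 1) > 1e-8))
    stop_validation("spillover matrix must have unit diagonal")
  if (nrow(s) != length(image$channels))
    stop_validation("spillover dimension does not match channel count")
  inv <- try(solve(s), silent = TRUE)
  if (inherits(inv, "try-error"))
    stop_validation("spillover matrix is singular")
  out <- inv %*% channels_to_mat(image)
  out[out < 0] <- 0
  mat_to_channels(out, image, names(image$channels))
}

# ---- Negative-control threshold calibration --------------------------------

#' Per-channel intensity thresholds with provenance
#'
#' @param channel,threshold,control_id,q Vectors of equal length: channel
#'   name, threshold intensity (>= 0), identifier of the negative-control
#'   image used, and the quantile applied (0 < q <= 1).
#' @return A data.frame of class `threshold_set`.
#' @export
threshold_set <- function(channel = character(), threshold = numeric(),
                          control_id = NA_character_, q = NA_real_) {
  df <- data.frame(channel = as.character(channel),
                   threshold = as.numeric(threshold),
                   control_id = as.character(control_id),
                   q = as.numeric(q),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$threshold < 0))
    stop_validation("thresholds must be >= 0")
  if (nrow(df) && any(!is.na(df$q) & (df$q <= 0 | df$q > 1)))
    stop_validation("quantile q must be in (0, 1]")
  class(df) <- c("threshold_set", class(df))
  df
}

#' Look up the threshold for a channel
#' @param thresholds A [threshold_set()].
#' @param channel Channel name.
#' @return The threshold intensity (error if absent).
#' @export
threshold_for <- function(thresholds, channel) {
  i <- match(channel, thresholds$channel)
  if (is.na(i))
    stop_validation("no threshold calibrated for channel '", channel, "'")
  thresholds$threshold[i]
}

#' Calibrate a channel threshold from a negative-control image
#'
#' The threshold is the `q`-quantile (linear interpolation between order
#' statistics, quantile type 7) of all intensities of that channel in the
#' control image.  Sections that cannot contain true signal (control
#' ligand tetramer, knockout tissue) define what "negative" looks like;
#' positives in test sections must exceed this.
#'
#' @param control A [multichannel_image()] of the negative control.
#' @param channel Channel name to calibrate.
#' @param q Quantile in (0, 1]; default 0.999.
#' @param control_id Identifier recorded as provenance.
#' @return A one-row [threshold_set()].
#' @export
calibrate_threshold <- function(control, channel, q = 0.999,
                                control_id = "control") {
  if (!is_scalar_number(q) || q <= 0 || q > 1)
    stop_validation("q must be a number in (0, 1]")
  v <- as.numeric(get_channel(control, channel))
  thr <- unname(stats::quantile(v, probs = q, type = 7))
  threshold_set(channel, thr, control_id, q)
}

#' Calibrate several channels at once
#' @inheritParams calibrate_threshold
#' @param channels Character vector of channel names.
#' @return A [threshold_set()] with one row per channel.
#' @export
calibrate_thresholds <- function(control, channels, q = 0.999,
                                 control_id = "control") {
  do.call(rbind, lapply(channels, function(ch)
    calibrate_threshold(control, ch, q, control_id)))
}

#' Write/read a threshold set as a JSON report with provenance
#' @param thresholds A [threshold_set()].
#' @param path JSON path.
#' @return `path` invisibly (writer) or a [threshold_set()] (reader).
#' @export
write_thresholds <- function(thresholds, path) {
  jsonlite::write_json(as.data.frame(thresholds), path, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  threshold_set(df$channel, df$threshold, df$control_id %||% NA, df$q %||% NA)
}
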
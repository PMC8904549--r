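#' Image metadata in physical units
#'
#' Records the pixel grid and physical calibration of a multi-channel
#' section image.  All physical quantities are in micrometres; the derived
#' `field_area()` is in mm2 and is the normalisation constant for
#' per-field cell counts.
#'
#' @param pixel_size_xy Lateral pixel size, um per pixel (> 0).
#' @param channel_names Character vector of unique, non-empty channel names.
#' @param width,height Image size in pixels (columns, rows).
#' @param n_planes Number of z planes (default 1).
#' @param pixel_size_z Axial plane spacing in um (optional, `NA` for 2-D).
#' @return An object of class `image_meta`.
#' @export
image_meta <- function(pixel_size_xy, channel_names, width, height,
                       n_planes = 1L, pixel_size_z = NA_real_) {
  if (!is_scalar_number(pixel_size_xy) || pixel_size_xy <= 0)
    stop_validation("pixel_size_xy must be a positive number")
  channel_names <- as.character(channel_names)
  if (length(channel_names) == 0L || anyDuplicated(channel_names) ||
      any(!nzchar(channel_names)))
    stop_validation("channel_names must be unique and non-empty")
  if (width < 1 || height < 1 || n_planes < 1)
    stop_validation("width, height and n_planes must be >= 1")
  structure(list(
    pixel_size_xy = as.numeric(pixel_size_xy),
    pixel_size_z = as.numeric(pixel_size_z),
    channel_names = channel_names,
    width = as.integer(width),
    height = as.integer(height),
    n_planes = as.integer(n_planes)
  ), class = "image_meta")
}

#' Field area of an image in mm2
#'
#' @param meta An [image_meta()].
#' @return Area `width * height * pixel_size_xy^2` converted from um2 to mm2.
#' @export
field_area <- function(meta) {
  meta$width * meta$height * meta$pixel_size_xy^2 / 1e6
}

#' Multi-channel intensity image
#'
#' A named list of per-channel intensity grids plus an [image_meta()].
#' Each channel is a `height x width` matrix (single plane) or a
#' `height x width x n_planes` array.  Intensities are non-negative
#' numerics regardless of on-disk integer depth, because unmixing and
#' compensation produce non-integer values.
#'
#' @param channels Named list of matrices/arrays, names matching
#'   `meta$channel_names`.
#' @param meta An [image_meta()].
#' @return Object of class `multichannel_image`.
#' @export
multichannel_image <- function(channels, meta) {
  if (!inherits(meta, "image_meta")) stop_validation("meta must be an image_meta")
  if (!identical(names(channels), meta$channel_names))
    stop_validation("channel names of data and metadata disagree")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    d <- dim(ch)
    if (is.null(d) || d[1] != meta$height || d[2] != meta$width)
      stop_validation("channel '", nm, "' does not match meta dimensions")
    np <- if (length(d) == 3L) d[3] else 1L
    if (np != meta$n_planes)
      stop_validation("channel '", nm, "' plane count disagrees with meta")
    if (anyNA(ch) || min(ch) < 0)
      stop_validation("channel '", nm, "' has negative or missing intensities")
  }
  structure(list(meta = meta, channels = channels),
            class = "multichannel_image")
}

#' Extract one channel of a multi-channel image
#'
#' @param image A [multichannel_image()].
#' @param name Channel name.
#' @return The channel's intensity matrix (or array for z-stacks).
#' @export
get_channel <- function(image, name) {
  if (!name %in% names(image$channels))
    stop_validation("channel '", name, "' not present; have: ",
                    paste(names(image$channels), collapse = ", "))
  image$channels[[name]]
}

#' @export
print.multichannel_image <- function(x, ...) {
  m <- x$meta
  cat(sprintf("multichannel_image: %d x %d px, %d plane(s), %.4g um/px (%.4g mm2)\n",
              m$width, m$height, m$n_planes, m$pixel_size_xy, field_area(m)))
  cat("channels:", paste(m$channel_names, collapse = ", "), "\n")
  invisible(x)
}

# ---- Region maps -----------------------------------------------------------

#' Tissue-compartment label vocabulary
#'
#' @param tissue One of `"spleen"`, `"thymus"`, `"lymph_node"`.
#' @return Ordered character vector of region labels for that tissue:
#'   spleen RP/BCZ/TCZ, thymus cortex/medulla, lymph node F/P/M.
#' @export
region_vocabulary <- function(tissue) {
  switch(match.arg(tissue, c("spleen", "thymus", "lymph_node")),
    spleen = c("RP", "BCZ", "TCZ"),
    thymus = c("cortex", "medulla"),
    lymph_node = c("F", "P", "M"))
}

#' Per-pixel tissue-compartment labels
#'
#' Integer label grid over the tissue-specific vocabulary; 0 marks
#' background (outside the section).
#'
#' @param tissue Tissue type, see [region_vocabulary()].
#' @param labels Integer matrix, values in `0:length(vocab)`.
#' @return Object of class `region_map` with fields `tissue`, `labels`,
#'   `vocab`.
#' @export
region_map <- function(tissue, labels) {
  vocab <- region_vocabulary(tissue)
  labels <- matrix(as.integer(labels), nrow = nrow(labels))
  if (anyNA(labels) || min(labels) < 0 || max(labels) > length(vocab))
    stop_validation("labels out of range for tissue '", tissue, "'")
  structure(list(tissue = tissue, labels = labels, vocab = vocab),
            class = "region_map")
}

#' Region name at each pixel (or for a vector of label codes)
#' @param regions A [region_map()].
#' @param codes Integer codes; defaults to the whole grid.
#' @return Character vector; background (0) maps to `NA`.
#' @export
region_names <- function(regions, codes = regions$labels) {
  out <- rep(NA_character_, length(codes))
  i <- codes > 0
  out[i] <- regions$vocab[codes[i]]
  out
}

# ---- TIFF I/O --------------------------------------------------------------

sidecar_path <- function(path) paste0(path, ".json")

#' Write a multi-channel image as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered channel-major (all planes of channel 1, then channel
#' 2, ...).  Samples are stored as 16-bit integers with a per-file
#' `intensity_unit` scale in the sidecar; integer-valued data in
#' \[0, 65535\] round-trips bit-exact.  The sidecar also records pixel
#' sizes and channel names, which plain TIFF tags cannot carry here.
#'
#' @param image A [multichannel_image()].
#' @param path Output TIFF path; `<path>.json` is written alongside.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  m <- image$meta
  vmax <- max(vapply(image$channels, max, 0))
  integral <- all(vapply(image$channels,
                         function(ch) all(ch == round(ch)), TRUE))
  unit <- if (integral && vmax <= 65535) 1 else max(vmax, 1e-12) / 65535
  pages <- list()
  for (ch in image$channels) {
    if (length(dim(ch)) == 3L) {
      for (p in seq_len(dim(ch)[3])) pages[[length(pages) + 1L]] <- ch[, , p] / (unit * 65535)
    } else pages[[length(pages) + 1L]] <- ch / (unit * 65535)
  }
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                            compression = "none", reduce = FALSE),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write TIFF to '", path, "'", call. = FALSE)
  meta_json <- list(pixel_size_xy = m$pixel_size_xy,
                    pixel_size_z = m$pixel_size_z,
                    channel_names = m$channel_names,
                    width = m$width, height = m$height,
                    n_planes = m$n_planes, intensity_unit = unit)
  jsonlite::write_json(meta_json, sidecar_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a multi-channel TIFF image
#'
#' Metadata comes from the JSON sidecar written by [write_image()] when
#' present; otherwise every page is treated as one single-plane channel
#' (`ch1`, `ch2`, ...) and the pixel size must be supplied via
#' `meta_override`.  Fields given in `meta_override` win over file
#' metadata.
#'
#' @param path TIFF path.
#' @param meta_override Optional named list of [image_meta()] fields.
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, meta_override = NULL) {
  if (!file.exists(path)) stop("cannot read image: no file at '", path, "'",
                               call. = FALSE)
  pages <- try(tiff::readTIFF(path, all = TRUE, as.is = TRUE), silent = TRUE)
  if (inherits(pages, "try-error"))
    stop("cannot read image: unreadable TIFF '", path, "'", call. = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  side <- sidecar_path(path)
  info <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
          else list()
  unit <- info$intensity_unit %||% 1
  n_planes <- info$n_planes %||% 1L
  ch_names <- info$channel_names %||% paste0("ch", seq_len(length(pages) / n_planes))
  if (!is.null(meta_override$channel_names)) {
    if (length(meta_override$channel_names) != length(ch_names))
      stop_validation("meta_override channel count disagrees with file")
    ch_names <- meta_override$channel_names
  }
  px <- meta_override$pixel_size_xy %||% info$pixel_size_xy
  if (is.null(px) || is.na(px))
    stop_validation("no pixel size in file metadata; supply meta_override")
  pz <- meta_override$pixel_size_z %||% info$pixel_size_z %||% NA_real_
  if (length(pages) != length(ch_names) * n_planes)
    stop_validation("page count does not match channels x planes")
  channels <- vector("list", length(ch_names))
  names(channels) <- ch_names
  k <- 1L
  for (i in seq_along(ch_names)) {
    if (n_planes == 1L) {
      channels[[i]] <- matrix(as.numeric(pages[[k]]) * unit,
                              nrow = nrow(pages[[k]]))
      k <- k + 1L
    } else {
      arr <- array(0, c(dim(pages[[k]]), n_planes))
      for (p in seq_len(n_planes)) {
        arr[, , p] <- as.numeric(pages[[k]]) * unit
        k <- k + 1L
      }
      channels[[i]] <- arr
    }
  }
  meta <- image_meta(px, ch_names, ncol(channels[[1]]),
                     nrow(channels[[1]]), n_planes, if (is.null(pz)) NA_real_ else pz)
  multichannel_image(channels, meta)
}

#' Maximum-intensity projection of a z-stack
#'
#' Flattens each channel to a single plane by taking, at every (row,
#' column), the maximum over z planes.
#'
#' @param image A [multichannel_image()].
#' @return A single-plane [multichannel_image()].
#' @export
max_project <- function(image) {
  m <- image$meta
  if (m$n_planes == 1L) return(image)
  channels <- lapply(image$channels, function(ch) {
    d <- dim(ch)
    out <- matrix(ch[, , 1], d[1], d[2])
    for (p in seq_len(d[3])[-1])
      out <- pmax(out, matrix(ch[, , p], d[1], d[2]))
    out
  })
  meta <- image_meta(m$pixel_size_xy, m$channel_names, m$width, m$height,
                     1L, m$pixel_size_z)
  multichannel_image(channels, meta)
}

#' Write/read a region map as label TIFF + JSON sidecar
#'
#' The sidecar names the tissue and the integer label -> region mapping.
#'
#' @param regions A [region_map()].
#' @param path Output TIFF path.
#' @return `path` invisibly (writer); a [region_map()] (reader).
#' @export
write_region_map <- function(regions, path) {
  tiff::writeTIFF(regions$labels / 65535, path, bits.per.sample = 16L,
                  compression = "none", reduce = FALSE)
  mapping <- as.list(regions$vocab)
  names(mapping) <- as.character(seq_along(regions$vocab))
  jsonlite::write_json(list(tissue = regions$tissue, labels = mapping),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_region_map
#' @export
read_region_map <- function(path) {
  labels <- tiff::readTIFF(path, as.is = TRUE)
  info <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  rm <- region_map(info$tissue, labels)
  expected <- unname(unlist(info$labels))
  if (!identical(expected, rm$vocab))
    stop_validation("label mapping in sidecar does not match tissue vocabulary")
  rm
}

# ---- Cell tables -----------------------------------------------------------

cell_table_core <- c("id", "x_um", "y_um", "area_um2")
cell_table_optional <- c("costain_positive", "subset", "region",
                         "distance_to_cmj_um", "population")

#' Validate a per-cell record table
#'
#' The central tabular product of the pipeline: one row per detected
#' cell/object with centroid (um), area (um2), per-channel mean
#' intensities (`mean_<channel>` columns) and optional analysis columns
#' (`costain_positive`, `subset`, `region`, `distance_to_cmj_um`,
#' `population`).
#'
#' @param df A data.frame with at least `id`, `x_um`, `y_um`, `area_um2`.
#' @param meta Optional [image_meta()]; if given, centroids are checked to
#'   lie within the physical image bounds.
#' @return `df` with class `cell_table` prepended.
#' @export
cell_table <- function(df, meta = NULL) {
  missing_cols <- setdiff(cell_table_core, names(df))
  if (length(missing_cols))
    stop_validation("cell table lacks columns: ",
                    paste(missing_cols, collapse = ", "))
  if (nrow(df) && any(df$area_um2 <= 0))
    stop_validation("cell areas must be positive")
  if (!is.null(meta) && nrow(df)) {
    if (any(df$x_um < 0 | df$x_um > meta$width * meta$pixel_size_xy |
            df$y_um < 0 | df$y_um > meta$height * meta$pixel_size_xy))
      stop_validation("cell centroids fall outside the image bounds")
  }
  if ("subset" %in% names(df) && "costain_positive" %in% names(df) && nrow(df)) {
    bad <- !is.na(df$subset) & !is.na(df$costain_positive) & !df$costain_positive
    if (any(bad))
      stop_validation("subset may be set only for costain-positive cells")
  }
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Export a cell table to CSV
#'
#' Plain CSV, one row per cell, positions/areas in um and um2.  Numeric
#' columns are written at full double precision so the matching reader
#' restores them losslessly.  Optional columns that are absent are simply
#' omitted; [read_cell_table()] restores them as `NA`.
#'
#' @param cells A [cell_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(cells, path) {
  df <- as.data.frame(cells)
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- formatC(df[[nm]], digits = 17, format = "g")
      v[is.na(df[[nm]])] <- NA_character_
      df[[nm]] <- v
    }
  }
  ok <- try(utils::write.csv(df, path, row.names = FALSE, na = ""),
            silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("cannot write cell table to '", path, "'", call. = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fill <- list(costain_positive = NA, subset = NA_character_,
               region = NA_character_, distance_to_cmj_um = NA_real_,
               population = NA_character_)
  for (nm in names(fill)) {
    if (!nm %in% names(df)) df[[nm]] <- rep(fill[[nm]], nrow(df))
  }
  for (nm in c("x_um", "y_um", "area_um2", "distance_to_cmj_um")) {
    if (nm %in% names(df)) df[[nm]] <- as.numeric(df[[nm]])
  }
  if ("costain_positive" %in% names(df))
    df$costain_positive <- as.logical(df$costain_positive)
  for (nm in c("subset", "region", "population")) {
    if (nm %in% names(df)) {
      df[[nm]] <- as.character(df[[nm]])
      df[[nm]][!nzchar(df[[nm]]) | is.na(df[[nm]])] <- NA_character_
    }
  }
  cell_table(df)
}
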
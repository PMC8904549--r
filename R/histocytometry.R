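# Histo-cytometry: DAPI-based single-cell segmentation, per-cell feature
# export, hierarchical gating into named populations, and back-mapping of
# populations onto tissue coordinates.

#' Segment nuclei from the DAPI channel
#'
#' Thresholds DAPI, splits touching nuclei by a distance-transform
#' watershed, and removes fragments below `min_nucleus_area`.  The
#' watershed neighbourhood radius is derived from `seed_min_distance`,
#' the minimum separation at which two intensity peaks count as distinct
#' nuclei.
#'
#' @param image Single-plane [multichannel_image()].
#' @param dapi_channel DAPI channel name.
#' @param dapi_threshold Foreground cutoff; default Otsu on the DAPI
#'   channel.
#' @param min_nucleus_area Minimum nucleus area in um2 (default 8).
#' @param seed_min_distance Minimum peak separation in um (default 4).
#' @return Integer label matrix (background 0, labels numbered in
#'   column-major order of first pixel).
#' @export
segment_nuclei <- function(image, dapi_channel = "DAPI",
                           dapi_threshold = NULL, min_nucleus_area = 8,
                           seed_min_distance = 4) {
  dapi <- get_channel(image, dapi_channel)
  px <- image$meta$pixel_size_xy
  thr <- dapi_threshold %||% otsu_threshold(dapi)
  fg <- dapi > thr
  if (!any(fg)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  d <- mat2(EBImage::distmap(fg * 1))
  ext <- max(1L, as.integer(round(seed_min_distance / px / 2)))
  labels <- mat2(EBImage::watershed(d, tolerance = 1, ext = ext))
  labels <- matrix(as.integer(labels), nrow(labels))
  # drop sub-minimum fragments, renumber deterministically
  if (max(labels) > 0L) {
    areas <- tabulate(labels[labels > 0L], nbins = max(labels)) * px^2
    keep <- which(areas >= min_nucleus_area)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels[labels > 0L] <- remap[labels[labels > 0L]]
    idx <- which(labels > 0L)
    if (length(idx)) {
      first <- tapply(idx, labels[idx], min)
      ord <- order(first)
      remap2 <- integer(length(ord))
      remap2[as.integer(names(first))[ord]] <- seq_along(ord)
      labels[idx] <- remap2[labels[idx]]
    }
  }
  labels
}

#' Extract per-cell features from a segmentation
#'
#' One row per label: mean intensity of every channel over the label
#' footprint, area (um2) and centroid (um).  Volume and z position are
#' not applicable after maximum projection and are reported as `NA`.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param image The [multichannel_image()] the labels were derived from.
#' @return A [cell_table()] with an extra `volume_um3` column of `NA`.
#' @export
extract_features <- function(labels, image) {
  if (!identical(dim(labels), dim(image$channels[[1]])[1:2]))
    stop_validation("labels and image dimensions disagree")
  if (max(labels) == 0L) {
    df <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                     area_um2 = numeric())
    for (nm in names(image$channels)) df[[paste0("mean_", nm)]] <- numeric()
    df$volume_um3 <- numeric()
    return(cell_table(df))
  }
  df <- label_features(labels, image)
  df$volume_um3 <- NA_real_
  cell_table(df, image$meta)
}

# ---- Gate trees ------------------------------------------------------------

#' Hierarchical gate tree
#'
#' A list of nodes defining 2-D gates in feature space.  Each node has
#' `name`, `parent` (`"root"` for top-level gates), `x` and `y` feature
#' names, and either a rectangle (`xmin/xmax/ymin/ymax`) or a closed
#' polygon (`vertices`: two-column matrix).  Nodes without children are
#' leaf populations.  Features are cell-table column names; the prefix
#' `asinh_` requests an asinh transform (`asinh(value / cofactor)`) of
#' the remaining column name.
#'
#' Boundary convention: closed -- a cell exactly on a gate edge is
#' inside.
#'
#' @param nodes List of node lists as described above.
#' @return Object of class `gate_tree`.
#' @export
gate_tree <- function(nodes) {
  names(nodes) <- vapply(nodes, function(n) n$name, "")
  if (anyDuplicated(names(nodes)))
    stop_validation("gate names must be unique")
  for (n in nodes) {
    p <- n$parent %||% "root"
    if (!identical(p, "root") && !p %in% names(nodes))
      stop_validation("gate '", n$name, "' has unknown parent '", p, "'")
    if (is.null(n$x) || is.null(n$y))
      stop_validation("gate '", n$name, "' lacks x/y features")
    has_rect <- all(c("xmin", "xmax", "ymin", "ymax") %in% names(n))
    has_poly <- !is.null(n$vertices)
    if (!has_rect && !has_poly)
      stop_validation("gate '", n$name, "' has neither rectangle nor polygon")
    if (has_poly && nrow(as.matrix(n$vertices)) < 3)
      stop_validation("gate '", n$name, "' polygon needs >= 3 vertices")
  }
  # acyclicity: walking parents must terminate at root
  for (nm in names(nodes)) {
    seen <- character()
    p <- nm
    while (!identical(p, "root")) {
      if (p %in% seen) stop_validation("gate tree contains a cycle at '", p, "'")
      seen <- c(seen, p)
      p <- nodes[[p]]$parent %||% "root"
    }
  }
  structure(nodes, class = "gate_tree")
}

#' Read/write a gate tree as JSON
#' @param path JSON path.
#' @param tree A [gate_tree()].
#' @return A [gate_tree()] (reader) or `path` invisibly (writer).
#' @export
read_gate_tree <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- lapply(raw, function(n) {
    if (!is.null(n$vertices))
      n$vertices <- do.call(rbind, lapply(n$vertices, unlist))
    n
  })
  gate_tree(nodes)
}

#' @rdname read_gate_tree
#' @export
write_gate_tree <- function(tree, path) {
  out <- lapply(unclass(tree), function(n) {
    if (!is.null(n$vertices)) {
      v <- as.matrix(n$vertices)
      n$vertices <- lapply(seq_len(nrow(v)), function(i) as.numeric(v[i, ]))
    }
    n
  })
  jsonlite::write_json(unname(out), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Point-in-polygon with closed boundaries: even-odd ray casting plus an
# explicit on-edge test so that boundary points are always inside.
in_polygon <- function(x, y, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    # on-segment test
    cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
    within <- x >= pmin(xi, xj) & x <= pmax(xi, xj) &
              y >= pmin(yi, yj) & y <= pmax(yi, yj)
    on_edge <- on_edge | (abs(cross) < 1e-12 * (1 + abs(xj - xi) + abs(yj - yi)) & within)
    crosses <- ((yi > y) != (yj > y)) &
               (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | on_edge
}

resolve_feature <- function(cells, feature, cofactor) {
  if (startsWith(feature, "asinh_")) {
    base <- sub("^asinh_", "", feature)
    if (!base %in% names(cells))
      stop_validation("unknown gate feature '", feature, "'")
    return(asinh(cells[[base]] / cofactor))
  }
  if (!feature %in% names(cells))
    stop_validation("unknown gate feature '", feature, "'")
  cells[[feature]]
}

gate_member <- function(cells, node, cofactor) {
  x <- resolve_feature(cells, node$x, cofactor)
  y <- resolve_feature(cells, node$y, cofactor)
  if (!is.null(node$vertices)) {
    v <- as.matrix(node$vertices)
    in_polygon(x, y, v[, 1], v[, 2])
  } else {
    x >= node$xmin & x <= node$xmax & y >= node$ymin & y <= node$ymax
  }
}

#' Gate cells into named populations
#'
#' Each cell is assigned the deepest leaf gate whose whole
#' ancestor-boundary chain it satisfies; cells failing all of the root's
#' children become `"misc"`.  When overlapping sibling leaves both match,
#' the first in document order wins (deterministic).  Per-gate counts and
#' percentages of parent and of total are attached as the
#' `gate_stats` attribute.
#'
#' @param cells A [cell_table()] from [extract_features()].
#' @param tree A [gate_tree()].
#' @param cofactor Cofactor for `asinh_` derived features (default 150).
#' @return The table with a `population` column; attribute `gate_stats`
#'   is a data.frame of per-gate counts/percentages.
#' @export
apply_gates <- function(cells, tree, cofactor = 150) {
  n <- nrow(cells)
  member <- list(root = rep(TRUE, n))
  # topological order: parents before children (constructor guarantees
  # acyclicity; iterate until all nodes placed)
  remaining <- names(tree)
  ordered <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      p <- tree[[nm]]$parent %||% "root"
      identical(p, "root") || p %in% ordered
    }, TRUE)]
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  for (nm in ordered) {
    node <- tree[[nm]]
    p <- node$parent %||% "root"
    member[[nm]] <- member[[p]] & gate_member(cells, node, cofactor)
  }
  children <- function(nm) names(tree)[vapply(tree, function(x)
    identical(x$parent %||% "root", nm), TRUE)]
  leaves <- names(tree)[vapply(names(tree),
                               function(nm) length(children(nm)) == 0L, TRUE)]
  pop <- rep("misc", n)
  for (nm in rev(leaves)) pop[member[[nm]]] <- nm
  # first-in-document-order leaf wins: assign in reverse so earlier
  # leaves overwrite later ones
  cells$population <- pop
  stats_df <- do.call(rbind, lapply(names(tree), function(nm) {
    p <- tree[[nm]]$parent %||% "root"
    n_in <- sum(member[[nm]])
    n_p <- sum(member[[p]])
    data.frame(gate = nm, parent = p, n = n_in,
               pct_of_parent = if (n_p > 0) 100 * n_in / n_p else NA_real_,
               pct_of_total = if (n > 0) 100 * n_in / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  structure(cell_table(cells), gate_stats = stats_df)
}

#' Map gated populations back onto tissue coordinates
#'
#' Produces an integer image whose pixel value encodes the population of
#' the segmented cell occupying it (background 0), plus the legend
#' mapping.
#'
#' @param cells A gated [cell_table()] (with `population`).
#' @param labels The segmentation label matrix the cells came from.
#' @return List with `image` (integer matrix) and `legend` (named
#'   integer vector population -> code).
#' @export
map_back <- function(cells, labels) {
  if (!"population" %in% names(cells))
    stop_validation("cells carry no population assignments")
  pops <- unique(cells$population)
  pops <- c(setdiff(pops, "misc"), intersect("misc", pops))
  codes <- seq_along(pops)
  names(codes) <- pops
  lut <- integer(max(labels, 1L))
  lut[cells$id] <- codes[cells$population]
  out <- matrix(0L, nrow(labels), ncol(labels))
  fg <- labels > 0L
  out[fg] <- lut[labels[fg]]
  list(image = out, legend = codes)
}
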
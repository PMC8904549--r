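# Independent reference implementations used to check package results.
# These deliberately use different algorithms from the package code.

# 8-connected component labelling by breadth-first flood fill.
oracle_flood_fill <- function(mask) {
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  visited <- matrix(FALSE, nr, nc)
  lab <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (start in which(mask)) {
    if (visited[start]) next
    lab <- lab + 1L
    frontier <- start
    visited[start] <- TRUE
    out[start] <- lab
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer()
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs$dr[k]
        cc <- c + offs$dc[k]
        ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] & !visited[idx]]
        if (length(idx)) {
          visited[idx] <- TRUE
          out[idx] <- lab
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  out
}

# Textbook sample Pearson correlation by explicit scalar loop.
oracle_pearson <- function(a, b) {
  n <- length(a)
  ma <- 0; mb <- 0
  for (i in seq_len(n)) { ma <- ma + a[i]; mb <- mb + b[i] }
  ma <- ma / n; mb <- mb / n
  sab <- 0; saa <- 0; sbb <- 0
  for (i in seq_len(n)) {
    sab <- sab + (a[i] - ma) * (b[i] - mb)
    saa <- saa + (a[i] - ma)^2
    sbb <- sbb + (b[i] - mb)^2
  }
  sab / sqrt(saa * sbb)
}

# Brute-force nearest-boundary-pixel distance (um) for one point.
oracle_nearest_boundary <- function(x, y, boundary_xy) {
  min(sqrt((boundary_xy[, 1] - x)^2 + (boundary_xy[, 2] - y)^2))
}

# Winding-number point-in-polygon (closed boundary): independent of the
# package's even-odd ray casting.
oracle_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  wn <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # on-edge check
    cr <- (vx[j] - vx[i]) * (py - vy[i]) - (vy[j] - vy[i]) * (px - vx[i])
    if (abs(cr) < 1e-12 &&
        px >= min(vx[i], vx[j]) && px <= max(vx[i], vx[j]) &&
        py >= min(vy[i], vy[j]) && py <= max(vy[i], vy[j])) return(TRUE)
    if (vy[i] <= py) {
      if (vy[j] > py && cr > 0) wn <- wn + 1
    } else {
      if (vy[j] <= py && cr < 0) wn <- wn - 1
    }
  }
  wn != 0
}

# Recursive per-cell gate evaluation, independent of apply_gates.
oracle_gate_one <- function(cell, tree, cofactor = 150) {
  feat <- function(f) {
    if (startsWith(f, "asinh_")) asinh(cell[[sub("^asinh_", "", f)]] / cofactor)
    else cell[[f]]
  }
  passes <- function(nm) {
    node <- tree[[nm]]
    x <- feat(node$x)
    y <- feat(node$y)
    ok <- if (!is.null(node$vertices)) {
      v <- as.matrix(node$vertices)
      oracle_in_polygon(x, y, v[, 1], v[, 2])
    } else {
      x >= node$xmin && x <= node$xmax && y >= node$ymin && y <= node$ymax
    }
    p <- node$parent
    if (is.null(p) || identical(p, "root")) ok else ok && passes(p)
  }
  kids <- function(nm) names(tree)[vapply(tree, function(x)
    identical(x$parent, nm), TRUE)]
  leaves <- names(tree)[vapply(names(tree),
                               function(nm) length(kids(nm)) == 0L, TRUE)]
  for (nm in leaves) if (passes(nm)) return(nm)
  "misc"
}

# Random binary blob mask from thresholded smoothed noise (base R only).
random_blob_mask <- function(n, smooth_px = 6, frac = 0.35) {
  z <- matrix(stats::rnorm(n * n), n)
  k <- stats::dnorm(seq(-3, 3, length.out = 2 * smooth_px + 1))
  k <- k / sum(k)
  for (i in seq_len(n)) z[i, ] <- stats::filter(z[i, ], k, circular = TRUE)
  for (j in seq_len(n)) z[, j] <- stats::filter(z[, j], k, circular = TRUE)
  z > stats::quantile(z, 1 - frac)
}
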
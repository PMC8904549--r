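# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) stop(..., call. = FALSE)

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage sub-seed so that, e.g., the placement of one
# population does not perturb the RNG stream of another (paired wild-type /
# control sections must share everything except the omitted population).
sub_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587L) + 1L
}

# Pixel-centre physical coordinates: pixel (row r, col c), 1-based, has
# centre x = (c - 0.5) * pixel_size, y = (r - 0.5) * pixel_size.
px_centre_um <- function(i, pixel_size) (i - 0.5) * pixel_size

um_to_px <- function(u, pixel_size, n) {
  i <- floor(u / pixel_size) + 1
  pmax(1L, pmin(as.integer(n), as.integer(i)))
}

# Coerce an EBImage return value back to a plain matrix/array.
as_grid <- function(x) {
  d <- dim(x)
  array(as.numeric(x), dim = d)
}

mat2 <- function(x) {
  m <- as_grid(x)
  dim(m) <- dim(x)[1:2]
  m
}

# Odd-sized disc brush with radius `r_px` (>= 1) for morphology.
disc_brush <- function(r_px) {
  size <- 2L * max(1L, as.integer(round(r_px))) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Separable Gaussian smoothing as banded-matrix products, with the
# truncated kernel renormalised at the image edges (replicate-style
# boundary).  Band matrices are memoised per (size, sigma).
.blur_cache <- new.env(parent = emptyenv())

blur_band_matrix <- function(n, sigma) {
  key <- paste(n, signif(sigma, 12))
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  B <- Matrix::bandSparse(n, n, k = -r:r,
                          diagonals = lapply(k, rep, n))
  B <- Matrix::Diagonal(x = 1 / Matrix::rowSums(B)) %*% B
  .blur_cache[[key]] <- B
  B
}

gaussian_smooth <- function(x, sigma_px) {
  if (sigma_px <= 0) return(x)
  Br <- blur_band_matrix(nrow(x), sigma_px)
  Bc <- blur_band_matrix(ncol(x), sigma_px)
  as.matrix(Br %*% x %*% Matrix::t(Bc))
}

# Otsu threshold of a numeric vector/matrix on its own range.
otsu_threshold <- function(v) {
  v <- as.numeric(v)
  rng <- range(v)
  if (diff(rng) <= 0) return(rng[1])
  m <- matrix(v, ncol = 1L)
  EBImage::otsu(m, range = rng, levels = 256L)
}
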
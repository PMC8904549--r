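# Synthetic multi-channel tissue sections with exact ground truth.
#
# The generator draws a parametric region geometry (disc follicles with a
# T-cell-zone core and B-cell-zone ring inside red pulp; thymic medullary
# lobes inside cortex; lymph-node follicles around a paracortex core),
# places cells as Poisson counts per compartment, renders each cell as a
# Gaussian-blurred disc in its positive channels, and applies
# Poisson + Gaussian noise last.  Ground truth records everything
# pre-noise, so every downstream stage can be scored against it.

#' Simulation configuration
#'
#' Low-level constructor; most users want the tissue-specific builders
#' [spleen_sim_config()], [thymus_sim_config()],
#' [lymph_node_sim_config()] or [histocytometry_sim_config()].
#'
#' @param tissue `"spleen"`, `"thymus"` or `"lymph_node"`.
#' @param seed RNG seed; identical config + seed gives bit-identical
#'   output.
#' @param width,height Image size in pixels.
#' @param pixel_size_xy um per pixel.  The defaults (1024 x 1024 at
#'   0.775 um/px) give a 0.63 mm2 field, the conventional per-field
#'   normalisation area.
#' @param geometry Named list of tissue geometry parameters (um); see the
#'   builders for the per-tissue fields.
#' @param populations Named list; each entry has `channels` (named
#'   per-channel mean amplitudes above background), `rates` (named
#'   per-region expected counts per field), `specific` (logical: a
#'   tetramer+CD3+ double-positive population, removed in negative
#'   controls), and optional `radius_um` (default 3.5, a lymphocyte) and
#'   `nucleus_radius_um` (default 2.5; used for the DAPI footprint).
#' @param region_stains Named list: channel -> list(regions, amplitude);
#'   diffuse lineage stains rendered as uniform fills of whole
#'   compartments.
#' @param background Per-channel background level (scalar or named).
#' @param psf_sigma Gaussian PSF sigma in um.
#' @param noise List `poisson_scale` (shot-noise scale; intensities are
#'   drawn as `rpois(signal * scale) / scale`) and `gaussian_sd`.
#' @param nonspecific List `rate` (expected count per field of
#'   tetramer-bright CD3-negative objects) and `channels` (their
#'   amplitude profile).
#' @param void_spec Numeric vector of void areas (um2) to carve from the
#'   K5 stain inside the thymic medulla.
#' @param cmj_band For thymus: list `frac` (fraction of medullary cells
#'   placed within the CMJ band) and `width_um` (band width).
#' @param activation_fold Optional named per-region multipliers applied
#'   to all population rates (condition series).
#' @param min_separation_um Hard-core minimum distance between cell
#'   centres (um; default 7, two lymphocyte radii -- cells are solid and
#'   do not interpenetrate).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(tissue, seed = 1L, width = 1024L, height = 1024L,
                       pixel_size_xy = 0.775, geometry = list(),
                       populations = list(), region_stains = list(),
                       background = 100, psf_sigma = 1,
                       noise = list(poisson_scale = 1, gaussian_sd = 10),
                       nonspecific = list(rate = 0, channels = numeric()),
                       void_spec = numeric(), cmj_band = NULL,
                       activation_fold = NULL, min_separation_um = 7) {
  tissue <- match.arg(tissue, c("spleen", "thymus", "lymph_node"))
  cfg <- structure(list(
    tissue = tissue, seed = as.integer(seed),
    width = as.integer(width), height = as.integer(height),
    pixel_size_xy = pixel_size_xy, geometry = geometry,
    populations = populations, region_stains = region_stains,
    background = background, psf_sigma = psf_sigma, noise = noise,
    nonspecific = nonspecific, void_spec = void_spec,
    cmj_band = cmj_band, activation_fold = activation_fold,
    min_separation_um = min_separation_um
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$pixel_size_xy <= 0) stop_validation("pixel size must be positive")
  if (cfg$psf_sigma < 0) stop_validation("psf_sigma must be >= 0")
  if (cfg$noise$poisson_scale < 0 || cfg$noise$gaussian_sd < 0)
    stop_validation("noise parameters must be >= 0")
  if (length(cfg$void_spec) && any(cfg$void_spec <= 0))
    stop_validation("void areas must be positive")
  if ((cfg$nonspecific$rate %||% 0) < 0)
    stop_validation("nonspecific rate must be >= 0")
  if ((cfg$min_separation_um %||% 0) < 0)
    stop_validation("min_separation_um must be >= 0")
  vocab <- region_vocabulary(cfg$tissue)
  for (nm in names(cfg$populations)) {
    p <- cfg$populations[[nm]]
    if (any(p$channels < 0)) stop_validation("amplitudes must be >= 0 (", nm, ")")
    if (any(p$rates < 0)) stop_validation("rates must be >= 0 (", nm, ")")
    if (!all(names(p$rates) %in% vocab))
      stop_validation("population '", nm, "' has rates for unknown regions")
  }
  invisible(cfg)
}

sim_channel_names <- function(cfg) {
  chs <- unique(c("DAPI",
                  names(cfg$region_stains),
                  unlist(lapply(cfg$populations, function(p) names(p$channels))),
                  names(cfg$nonspecific$channels %||% numeric())))
  chs[nzchar(chs)]
}

bg_level <- function(cfg, ch) {
  if (length(cfg$background) == 1L && is.null(names(cfg$background)))
    return(as.numeric(cfg$background))
  as.numeric(cfg$background[[ch]] %||% 0)
}

# ---- geometry --------------------------------------------------------------

# Place `n` non-overlapping disc centres of radius r (um) fully inside the
# field (optionally inside a candidate pixel set).
place_discs <- function(n, r_um, w_um, h_um, max_tries = 100L,
                        max_restarts = 200L) {
  if (2 * r_um > w_um || 2 * r_um > h_um)
    stop_validation("region geometry cannot fit: disc radius ", r_um,
                    " um exceeds the field")
  # sequential rejection sampling can paint itself into a corner when the
  # discs are large relative to the field, so restart the whole set
  for (restart in seq_len(max_restarts)) {
    centres <- matrix(numeric(), 0, 2)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (t in seq_len(max_tries)) {
        x <- stats::runif(1, r_um, w_um - r_um)
        y <- stats::runif(1, r_um, h_um - r_um)
        if (!nrow(centres) ||
            all(sqrt((centres[, 1] - x)^2 + (centres[, 2] - y)^2) >
                  2 * r_um)) {
          centres <- rbind(centres, c(x, y))
          placed <- TRUE
          break
        }
      }
      if (!placed) break
    }
    if (nrow(centres) == n) return(centres)
  }
  stop_validation("region geometry cannot fit: ", n, " discs of radius ",
                  r_um, " um do not fit the field")
}

disc_px_idx <- function(h, w, row_c, col_c, r_px) {
  r0 <- max(1L, floor(row_c - r_px))
  r1 <- min(h, ceiling(row_c + r_px))
  c0 <- max(1L, floor(col_c - r_px))
  c1 <- min(w, ceiling(col_c + r_px))
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1
  cols <- c0:c1
  dr2 <- outer((rows - row_c)^2, (cols - col_c)^2, "+")
  sel <- which(dr2 <= r_px^2)
  (rep(cols, each = length(rows))[sel] - 1L) * h + rep(rows, length(cols))[sel]
}

make_geometry <- function(cfg) {
  h <- cfg$height
  w <- cfg$width
  px <- cfg$pixel_size_xy
  vocab <- region_vocabulary(cfg$tissue)
  code <- function(nm) match(nm, vocab)
  labels <- matrix(0L, h, w)
  g <- cfg$geometry
  if (cfg$tissue == "spleen") {
    labels[] <- code("RP")
    cen <- place_discs(g$n_follicles, g$follicle_radius, w * px, h * px)
    for (i in seq_len(nrow(cen))) {
      rc <- cen[i, 2] / px + 0.5
      cc <- cen[i, 1] / px + 0.5
      labels[disc_px_idx(h, w, rc, cc, g$follicle_radius / px)] <- code("BCZ")
      labels[disc_px_idx(h, w, rc, cc, g$tcz_radius / px)] <- code("TCZ")
    }
  } else if (cfg$tissue == "thymus") {
    labels[] <- code("cortex")
    cen <- place_discs(g$n_lobes, g$lobe_radius, w * px, h * px)
    for (i in seq_len(nrow(cen))) {
      labels[disc_px_idx(h, w, cen[i, 2] / px + 0.5, cen[i, 1] / px + 0.5,
                         g$lobe_radius / px)] <- code("medulla")
    }
  } else {
    labels[] <- code("M")
    ctr_r <- h / 2 + 0.5
    ctr_c <- w / 2 + 0.5
    labels[disc_px_idx(h, w, ctr_r, ctr_c, g$paracortex_radius / px)] <- code("P")
    # follicles in a ring outside the paracortex
    ring_r <- g$paracortex_radius + g$follicle_radius + 20
    n_f <- g$n_follicles
    ang <- 2 * pi * (seq_len(n_f) - 1) / n_f + stats::runif(1, 0, 2 * pi)
    for (a in ang) {
      fx <- w * px / 2 + ring_r * cos(a)
      fy <- h * px / 2 + ring_r * sin(a)
      idx <- disc_px_idx(h, w, fy / px + 0.5, fx / px + 0.5,
                         g$follicle_radius / px)
      if (!length(idx))
        stop_validation("region geometry cannot fit: follicle outside field")
      labels[idx] <- code("F")
    }
  }
  out <- list(labels = labels)
  if (cfg$tissue == "thymus") {
    rm_tmp <- region_map("thymus", labels)
    boundary <- cmj_boundary_mask(rm_tmp)
    out$cmj_dist_px <- mat2(EBImage::distmap((1 - boundary) * 1))
    out$cmj_boundary <- boundary
  }
  out
}

# ---- placement -------------------------------------------------------------

# Sample `n` cell centres uniformly over the candidate pixels with a
# hard-core constraint: cells are solid bodies, so no two centres (across
# all populations of the section) come closer than `min_sep` um.  If the
# constraint cannot be met within `max_tries` draws the most isolated
# candidate seen is accepted, so crowded regions degrade gracefully
# instead of failing.  `acc` is an environment with a growing `xy`
# matrix shared across all placements of one section.
sample_positions <- function(n, candidate_px, acc, min_sep, px, h,
                             max_tries = 100L) {
  out <- matrix(numeric(), 0, 2)
  for (i in seq_len(n)) {
    best <- NULL
    best_d2 <- -Inf
    for (t in seq_len(max_tries)) {
      idx <- candidate_px[sample.int(length(candidate_px), 1L)]
      r <- (idx - 1L) %% h + 1L
      cl <- (idx - 1L) %/% h + 1L
      x <- (cl - 1 + stats::runif(1)) * px
      y <- (r - 1 + stats::runif(1)) * px
      d2 <- if (nrow(acc$xy)) min((acc$xy[, 1] - x)^2 + (acc$xy[, 2] - y)^2)
            else Inf
      if (d2 > best_d2) {
        best <- c(x, y)
        best_d2 <- d2
      }
      if (d2 >= min_sep^2) break
    }
    acc$xy <- rbind(acc$xy, best)
    out <- rbind(out, best)
  }
  out
}

place_population <- function(cfg, geom, name, seed, acc) {
  pop <- cfg$populations[[name]]
  px <- cfg$pixel_size_xy
  h <- cfg$height
  min_sep <- cfg$min_separation_um %||% 7
  vocab <- region_vocabulary(cfg$tissue)
  rows <- list()
  for (region in names(pop$rates)) {
    fold <- if (!is.null(cfg$activation_fold))
      cfg$activation_fold[[region]] %||% 1 else 1
    lambda <- pop$rates[[region]] * fold
    res <- with_seed(sub_seed(seed, paste0("pop:", name, ":", region)), {
      n <- stats::rpois(1, lambda)
      if (n == 0) NULL else {
        region_px <- which(geom$labels == match(region, vocab))
        if (!length(region_px))
          stop_validation("no pixels available for region ", region)
        if (cfg$tissue == "thymus" && region == "medulla" &&
            !is.null(cfg$cmj_band)) {
          band <- region_px[geom$cmj_dist_px[region_px] * px <=
                              cfg$cmj_band$width_um]
          inner <- setdiff(region_px, band)
          n_band <- stats::rbinom(1, n, cfg$cmj_band$frac)
          if (!length(inner)) n_band <- n
          if (!length(band)) n_band <- 0L
          xy <- rbind(
            if (n_band > 0) sample_positions(n_band, band, acc, min_sep,
                                             px, h),
            if (n - n_band > 0) sample_positions(n - n_band, inner, acc,
                                                 min_sep, px, h))
        } else {
          xy <- sample_positions(n, region_px, acc, min_sep, px, h)
        }
        data.frame(x_um = xy[, 1], y_um = xy[, 2],
                   population = name, region = region,
                   specific = isTRUE(pop$specific),
                   radius_um = pop$radius_um %||% 3.5,
                   nucleus_radius_um = pop$nucleus_radius_um %||% 2.5,
                   stringsAsFactors = FALSE)
      }
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}

place_nonspecific <- function(cfg, geom, seed, acc) {
  rate <- cfg$nonspecific$rate %||% 0
  if (rate <= 0) return(NULL)
  px <- cfg$pixel_size_xy
  h <- cfg$height
  with_seed(sub_seed(seed, "nonspecific"), {
    n <- stats::rpois(1, rate)
    if (n == 0) return(NULL)
    tissue_px <- which(geom$labels > 0L)
    xy <- sample_positions(n, tissue_px, acc,
                           cfg$min_separation_um %||% 7, px, h)
    idx <- (um_to_px(xy[, 1], px, cfg$width) - 1L) * h +
      um_to_px(xy[, 2], px, h)
    vocab <- region_vocabulary(cfg$tissue)
    data.frame(x_um = xy[, 1], y_um = xy[, 2],
               population = "nonspecific",
               region = vocab[geom$labels[idx]],
               specific = FALSE,
               radius_um = 3.5, nucleus_radius_um = 2.5,
               stringsAsFactors = FALSE)
  })
}

# ---- rendering -------------------------------------------------------------

object_amplitude <- function(cfg, population, channel) {
  if (population == "nonspecific")
    return(as.numeric((cfg$nonspecific$channels %||% numeric())[channel] %||% 0))
  as.numeric(cfg$populations[[population]]$channels[channel] %||% 0)
}

render_channel <- function(cfg, geom, cells, channel) {
  h <- cfg$height
  w <- cfg$width
  px <- cfg$pixel_size_xy
  vocab <- region_vocabulary(cfg$tissue)
  canvas <- matrix(bg_level(cfg, channel), h, w)
  st <- cfg$region_stains[[channel]]
  if (!is.null(st)) {
    sel <- geom$labels %in% match(st$regions, vocab)
    canvas[sel] <- canvas[sel] + st$amplitude
  }
  if (!is.null(cells) && nrow(cells)) {
    amps <- vapply(cells$population, object_amplitude, 0,
                   cfg = cfg, channel = channel)
    use <- which(amps > 0)
    for (i in use) {
      r_um <- if (channel == "DAPI") cells$nucleus_radius_um[i] else
        cells$radius_um[i]
      idx <- disc_px_idx(h, w, cells$y_um[i] / px + 0.5,
                         cells$x_um[i] / px + 0.5, r_um / px)
      canvas[idx] <- canvas[idx] + amps[i]
    }
  }
  if (cfg$psf_sigma > 0)
    canvas <- gaussian_smooth(canvas, cfg$psf_sigma / px)
  canvas
}

carve_voids <- function(cfg, geom, canvas, seed) {
  if (!length(cfg$void_spec)) return(list(canvas = canvas, areas = numeric(),
                                          centres = matrix(numeric(), 0, 2)))
  px <- cfg$pixel_size_xy
  h <- cfg$height
  med_dist <- mat2(EBImage::distmap((geom$labels ==
    match("medulla", region_vocabulary("thymus"))) * 1))
  bg <- bg_level(cfg, "K5")
  with_seed(sub_seed(seed, "voids"), {
    areas <- numeric()
    centres <- matrix(numeric(), 0, 2)
    radii <- numeric()
    for (a in cfg$void_spec) {
      r_px <- sqrt(a / pi) / px
      cand <- which(med_dist >= r_px + 2)
      ok <- FALSE
      for (t in seq_len(500L)) {
        ctr <- cand[sample.int(length(cand), 1L)]
        rc <- (ctr - 1L) %% h + 1L
        cc <- (ctr - 1L) %/% h + 1L
        if (!nrow(centres) ||
            all(sqrt((centres[, 1] - rc)^2 + (centres[, 2] - cc)^2) >
                radii + r_px + 3)) {
          idx <- disc_px_idx(h, cfg$width, rc, cc, r_px)
          canvas[idx] <- bg
          areas <- c(areas, length(idx) * px^2)
          centres <- rbind(centres, c(rc, cc))
          radii <- c(radii, r_px)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop_validation("void of area ", a, " um2 cannot fit in medulla")
    }
    list(canvas = canvas, areas = areas, centres = centres)
  })
}

apply_noise <- function(cfg, canvas, channel, seed) {
  s <- cfg$noise$poisson_scale
  g <- cfg$noise$gaussian_sd
  with_seed(sub_seed(seed, paste0("noise:", channel)), {
    v <- as.numeric(canvas)
    if (s > 0) v <- stats::rpois(length(v), v * s) / s
    if (g > 0) v <- v + stats::rnorm(length(v), 0, g)
    v[v < 0] <- 0
    matrix(v, nrow(canvas), ncol(canvas))
  })
}

# ---- main entry points -----------------------------------------------------

#' Generate a synthetic tissue section with ground truth
#'
#' Deterministic given `config$seed`: the region map is drawn first, cells
#' are placed as Poisson counts per compartment, rendered as
#' Gaussian-blurred discs in their positive channels (DAPI for all
#' cells), and Poisson + Gaussian noise is applied last.  Each generative
#' stage uses its own seed stream derived from the base seed, so paired
#' sections that differ in one population share everything else.
#'
#' @param config A [sim_config()].
#' @return List with `image` (a [multichannel_image()]), `regions` (the
#'   true [region_map()]) and `truth` (a `ground_truth` list: `cells`
#'   data.frame with positions/populations/regions, `region_map`,
#'   `cmj_xy` boundary pixel coordinates in um (thymus),
#'   `void_areas_um2` as carved, and the `config`).
#' @export
generate_section <- function(config) {
  cfg <- validate_sim_config(config)
  seed <- cfg$seed
  geom <- with_seed(sub_seed(seed, "geometry"), make_geometry(cfg))
  # placement order is fixed so that a matched negative control (specific
  # populations zeroed) reproduces every other object exactly: shared
  # objects first, double-positive populations last
  acc <- new.env(parent = emptyenv())
  acc$xy <- matrix(numeric(), 0, 2)
  is_spec <- vapply(cfg$populations, function(p) isTRUE(p$specific), TRUE)
  ord <- c(sort(names(cfg$populations)[!is_spec]),
           sort(names(cfg$populations)[is_spec]))
  parts <- list(place_nonspecific(cfg, geom, seed, acc))
  for (nm in ord)
    parts[[length(parts) + 1L]] <- place_population(cfg, geom, nm, seed, acc)
  cells <- do.call(rbind, Filter(Negate(is.null), parts))
  if (is.null(cells))
    cells <- data.frame(x_um = numeric(), y_um = numeric(),
                        population = character(), region = character(),
                        specific = logical(), radius_um = numeric(),
                        nucleus_radius_um = numeric())
  cells$area_um2 <- pi * cells$radius_um^2
  ch_names <- sim_channel_names(cfg)
  channels <- vector("list", length(ch_names))
  names(channels) <- ch_names
  void_areas <- numeric()
  for (ch in ch_names) {
    canvas <- render_channel(cfg, geom, cells, ch)
    if (ch == "K5" && cfg$tissue == "thymus" && length(cfg$void_spec)) {
      cv <- carve_voids(cfg, geom, canvas, seed)
      canvas <- cv$canvas
      void_areas <- cv$areas
    }
    channels[[ch]] <- apply_noise(cfg, canvas, ch, seed)
  }
  meta <- image_meta(cfg$pixel_size_xy, ch_names, cfg$width, cfg$height)
  image <- multichannel_image(channels, meta)
  regions <- region_map(cfg$tissue, geom$labels)
  cmj_xy <- NULL
  if (cfg$tissue == "thymus") {
    b <- which(geom$cmj_boundary)
    cmj_xy <- cbind(x_um = px_centre_um((b - 1L) %/% cfg$height + 1L,
                                        cfg$pixel_size_xy),
                    y_um = px_centre_um((b - 1L) %% cfg$height + 1L,
                                        cfg$pixel_size_xy))
  }
  truth <- structure(list(cells = cells, region_map = regions,
                          cmj_xy = cmj_xy, void_areas_um2 = void_areas,
                          config = cfg), class = "ground_truth")
  list(image = image, regions = regions, truth = truth)
}

#' Generate a matched negative-control section
#'
#' Identical generative process to [generate_section()] except that every
#' `specific` (tetramer+CD3+ double-positive) population is forced to
#' zero planted cells; non-specific tetramer-bright CD3-negative objects
#' are retained at their configured rate, emulating control-ligand
#' tetramer staining and knockout tissue.
#'
#' @param config A [sim_config()].
#' @return As [generate_section()].
#' @export
generate_negative_control <- function(config) {
  for (nm in names(config$populations)) {
    if (isTRUE(config$populations[[nm]]$specific))
      config$populations[[nm]]$rates[] <- 0
  }
  generate_section(config)
}

# ---- tissue-specific builders ---------------------------------------------

#' Spleen section configuration
#'
#' Defaults emulate a wild-type BALB/c spleen field: about 100
#' tetramer+CD3+ NKT cells per 0.63 mm2 field split 70/15/15 across
#' TCZ/BCZ/RP, with ~75% of TCZ NKT cells CD4+ and equal CD4+/CD4-
#' proportions elsewhere, plus a handful of non-specific tetramer-bright
#' CD3- objects.  Diffuse B220 marks the BCZ and diffuse CD3 the TCZ.
#'
#' @param seed RNG seed.
#' @param n_cells Expected specific cells per field.
#' @param region_split Named fractions over TCZ/BCZ/RP (sums to 1).
#' @param cd4_frac Named per-region CD4+ fraction among specific cells.
#' @param nonspecific_rate Expected non-specific objects per field.
#' @param geometry Tissue geometry parameters in um (follicle/lobe count
#'   and radii); must fit the field.
#' @param tet_channel Tetramer channel name.
#' @param amplitude Marker amplitude above background (background 100,
#'   so the default 500 gives signal-to-background 5).
#' @param activation_fold Optional named per-region rate multipliers.
#' @param ... Passed on to [sim_config()].
#' @return A [sim_config()].
#' @export
spleen_sim_config <- function(seed = 1L, n_cells = 100,
                              geometry = list(n_follicles = 3,
                                              follicle_radius = 160,
                                              tcz_radius = 120),
                              region_split = c(TCZ = 0.70, BCZ = 0.15, RP = 0.15),
                              cd4_frac = c(TCZ = 0.75, BCZ = 0.5, RP = 0.5),
                              nonspecific_rate = 5,
                              tet_channel = "CD1dTet",
                              amplitude = 500,
                              activation_fold = NULL, ...) {
  regions <- names(region_split)
  pos <- n_cells * region_split * cd4_frac[regions]
  neg <- n_cells * region_split * (1 - cd4_frac[regions])
  pops <- list(
    NKT_CD4pos = list(
      channels = stats::setNames(c(amplitude, amplitude, amplitude, 400),
                                 c(tet_channel, "CD3", "CD4", "DAPI")),
      rates = pos, specific = TRUE),
    NKT_CD4neg = list(
      channels = stats::setNames(c(amplitude, amplitude, 400),
                                 c(tet_channel, "CD3", "DAPI")),
      rates = neg, specific = TRUE))
  sim_config(
    tissue = "spleen", seed = seed, geometry = geometry,
    populations = pops,
    region_stains = list(
      B220 = list(regions = "BCZ", amplitude = 150),
      CD3 = list(regions = "TCZ", amplitude = 150),
      DAPI = list(regions = c("RP", "BCZ", "TCZ"), amplitude = 200)),
    nonspecific = list(rate = nonspecific_rate,
                       channels = stats::setNames(c(amplitude, 400),
                                                  c(tet_channel, "DAPI"))),
    activation_fold = activation_fold, ...)
}

#' Thymus section configuration
#'
#' Defaults emulate a wild-type thymus field: NKT cells overwhelmingly
#' medullary with 90% of medullary cells placed within 100 um of the
#' corticomedullary junction; diffuse CD205 marks the cortex and K5 the
#' medulla.  `void_spec` carves K5-free voids into the medulla.
#'
#' @inheritParams spleen_sim_config
#' @param n_medulla,n_cortex Expected specific cells per compartment.
#' @param cmj_frac Fraction of medullary cells placed within the band.
#' @param band_width_um CMJ band width (um).
#' @param void_spec Numeric void areas (um2) to carve.
#' @return A [sim_config()].
#' @export
thymus_sim_config <- function(seed = 1L, n_medulla = 60, n_cortex = 5,
                              geometry = list(n_lobes = 2, lobe_radius = 180),
                              cd4_frac = c(medulla = 0.6, cortex = 0.75),
                              cmj_frac = 0.9, band_width_um = 100,
                              void_spec = numeric(),
                              nonspecific_rate = 3,
                              tet_channel = "CD1dTet",
                              amplitude = 500, ...) {
  rates_of <- function(f) c(medulla = n_medulla * f[["medulla"]],
                            cortex = n_cortex * f[["cortex"]])
  pops <- list(
    NKT_CD4pos = list(
      channels = stats::setNames(c(amplitude, amplitude, amplitude, 400),
                                 c(tet_channel, "CD3", "CD4", "DAPI")),
      rates = rates_of(cd4_frac), specific = TRUE),
    NKT_CD4neg = list(
      channels = stats::setNames(c(amplitude, amplitude, 400),
                                 c(tet_channel, "CD3", "DAPI")),
      rates = rates_of(1 - cd4_frac), specific = TRUE))
  sim_config(
    tissue = "thymus", seed = seed, geometry = geometry,
    populations = pops,
    region_stains = list(
      CD205 = list(regions = "cortex", amplitude = 150),
      K5 = list(regions = "medulla", amplitude = 400),
      DAPI = list(regions = c("cortex", "medulla"), amplitude = 200)),
    nonspecific = list(rate = nonspecific_rate,
                       channels = stats::setNames(c(amplitude, 400),
                                                  c(tet_channel, "DAPI"))),
    void_spec = void_spec,
    cmj_band = list(frac = cmj_frac, width_um = band_width_um), ...)
}

#' Lymph-node section configuration
#'
#' Defaults emulate a brachial lymph node: few NKT cells per field,
#' mostly in the paracortex; B220 follicles ring a central CD3
#' paracortex, the remainder is medulla.
#'
#' @inheritParams spleen_sim_config
#' @return A [sim_config()].
#' @export
lymph_node_sim_config <- function(seed = 1L, n_cells = 20,
                                  geometry = list(paracortex_radius = 240,
                                                  follicle_radius = 90,
                                                  n_follicles = 4),
                                  region_split = c(P = 0.7, F = 0.15, M = 0.15),
                                  nonspecific_rate = 2,
                                  tet_channel = "CD1dTet",
                                  amplitude = 500, ...) {
  pops <- list(
    NKT = list(
      channels = stats::setNames(c(amplitude, amplitude, 400),
                                 c(tet_channel, "CD3", "DAPI")),
      rates = n_cells * region_split, specific = TRUE))
  sim_config(
    tissue = "lymph_node", seed = seed, geometry = geometry,
    populations = pops,
    region_stains = list(
      B220 = list(regions = "F", amplitude = 150),
      CD3 = list(regions = "P", amplitude = 150),
      DAPI = list(regions = c("F", "P", "M"), amplitude = 200)),
    nonspecific = list(rate = nonspecific_rate,
                       channels = stats::setNames(c(amplitude, 400),
                                                  c(tet_channel, "DAPI"))), ...)
}

#' Histo-cytometry section configuration
#'
#' A spleen section carrying nine populations with distinct marker
#' profiles (B cells, CD11b-/CD11b+ dendritic cells, macrophages,
#' CD4+/CD4- NKT cells, CD4+/CD4- conventional T cells, miscellaneous),
#' placed with region preferences (B cells in the BCZ, T/NKT cells in
#' the TCZ, APCs in the red pulp).  Lineage channels are rendered only
#' on the cells themselves, so compartments emerge from cell placement
#' as they do in stained tissue; diffuse DAPI is kept low for clean
#' nuclear segmentation.
#'
#' @inheritParams spleen_sim_config
#' @param rate_scale Multiplier on all population rates (problem-size
#'   knob).
#' @return A [sim_config()].
#' @export
histocytometry_sim_config <- function(seed = 1L, tet_channel = "CD1dTet",
                                      amplitude = 500, rate_scale = 1, ...) {
  amp <- function(...) {
    v <- c(...)
    stats::setNames(c(unname(v), 500), c(names(v), "DAPI"))
  }
  a <- amplitude
  pops <- list(
    B = list(channels = amp(B220 = a), rates = c(BCZ = 300, RP = 20)),
    T_CD4pos = list(channels = amp(CD3 = a, CD4 = a), rates = c(TCZ = 150)),
    T_CD4neg = list(channels = amp(CD3 = a), rates = c(TCZ = 80)),
    NKT_CD4pos = list(channels = stats::setNames(c(a, a, a, 500),
                                                 c(tet_channel, "CD3", "CD4", "DAPI")),
                      rates = c(TCZ = 30), specific = TRUE),
    NKT_CD4neg = list(channels = stats::setNames(c(a, a, 500),
                                                 c(tet_channel, "CD3", "DAPI")),
                      rates = c(TCZ = 8, BCZ = 4, RP = 4), specific = TRUE),
    DC_CD11bneg = list(channels = amp(CD11c = a), rates = c(RP = 50)),
    DC_CD11bpos = list(channels = amp(CD11c = a, CD11b = a), rates = c(RP = 50)),
    Mac = list(channels = amp(CD11b = a), rates = c(RP = 70)),
    misc = list(channels = amp(), rates = c(RP = 60, BCZ = 20, TCZ = 20)))
  for (nm in names(pops)) pops[[nm]]$rates <- pops[[nm]]$rates * rate_scale
  sim_config(
    tissue = "spleen", seed = seed,
    geometry = list(n_follicles = 3, follicle_radius = 160, tcz_radius = 120),
    populations = pops,
    region_stains = list(DAPI = list(regions = c("RP", "BCZ", "TCZ"),
                                     amplitude = 30)),
    nonspecific = list(rate = 0, channels = numeric()),
    min_separation_um = 5.5, ...)
}

#' Default gate tree for the histo-cytometry demonstration panel
#'
#' Hierarchical gates over raw per-cell channel means that reproduce the
#' nine-population taxonomy of [histocytometry_sim_config()]: B cells,
#' then T cells split into NKT (tetramer+) and conventional T with CD4
#' subsets, then CD11c/CD11b dendritic-cell and macrophage gates among
#' B220-CD3- cells; everything else is misc.  Gate boundaries sit at
#' `cut` (default 300), midway between background and positive-marker
#' footprint means under the default simulator amplitudes.
#'
#' @param tet_channel Tetramer channel name.
#' @param cut Gate boundary intensity.
#' @param hi Upper bound standing in for +infinity in rectangles.
#' @return A [gate_tree()].
#' @export
default_gate_tree <- function(tet_channel = "CD1dTet", cut = 300, hi = 1e9) {
  tet <- paste0("mean_", tet_channel)
  gate_tree(list(
    list(name = "B", parent = "root", x = "mean_B220", y = "mean_CD3",
         xmin = cut, xmax = hi, ymin = -hi, ymax = cut),
    list(name = "Tcells", parent = "root", x = "mean_B220", y = "mean_CD3",
         xmin = -hi, xmax = cut, ymin = cut, ymax = hi),
    list(name = "NKT", parent = "Tcells", x = tet, y = "mean_CD3",
         xmin = cut, xmax = hi, ymin = -hi, ymax = hi),
    list(name = "NKT_CD4pos", parent = "NKT", x = "mean_CD4", y = tet,
         xmin = cut, xmax = hi, ymin = -hi, ymax = hi),
    list(name = "NKT_CD4neg", parent = "NKT", x = "mean_CD4", y = tet,
         xmin = -hi, xmax = cut, ymin = -hi, ymax = hi),
    list(name = "Tconv", parent = "Tcells", x = tet, y = "mean_CD3",
         xmin = -hi, xmax = cut, ymin = -hi, ymax = hi),
    list(name = "T_CD4pos", parent = "Tconv", x = "mean_CD4", y = "mean_CD3",
         xmin = cut, xmax = hi, ymin = -hi, ymax = hi),
    list(name = "T_CD4neg", parent = "Tconv", x = "mean_CD4", y = "mean_CD3",
         xmin = -hi, xmax = cut, ymin = -hi, ymax = hi),
    list(name = "APC", parent = "root", x = "mean_B220", y = "mean_CD3",
         xmin = -hi, xmax = cut, ymin = -hi, ymax = cut),
    list(name = "DC", parent = "APC", x = "mean_CD11c", y = "mean_CD11b",
         xmin = cut, xmax = hi, ymin = -hi, ymax = hi),
    list(name = "DC_CD11bpos", parent = "DC", x = "mean_CD11c",
         y = "mean_CD11b", xmin = cut, xmax = hi, ymin = cut, ymax = hi),
    list(name = "DC_CD11bneg", parent = "DC", x = "mean_CD11c",
         y = "mean_CD11b", xmin = cut, xmax = hi, ymin = -hi, ymax = cut),
    list(name = "Mac", parent = "APC", x = "mean_CD11c", y = "mean_CD11b",
         vertices = rbind(c(-1e9, cut), c(cut, cut), c(cut, 1e9),
                          c(-1e9, 1e9)))))
}

#' Write simulator ground truth to CSV
#' @param truth A `ground_truth` object from [generate_section()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth$cells, path, row.names = FALSE)
  invisible(path)
}
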
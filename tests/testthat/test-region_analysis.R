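# Hand-built thymus region map: cortex in the left half, medulla in the
# right half, so the CMJ is a vertical line with trivially computable
# distances.
split_thymus <- function(n = 200, px = 1) {
  lab <- matrix(1L, n, n)          # cortex
  lab[, (n / 2 + 1):n] <- 2L       # medulla
  list(regions = region_map("thymus", lab),
       meta = image_meta(px, "K5", n, n))
}

test_that("region segmentation recovers the simulated compartments", {
  e <- spleen_eval(42)
  expect_gte(e$region_agreement, 0.9)
})

test_that("a marker with no signal produces no corresponding region", {
  set.seed(5)
  n <- 128
  cd3 <- matrix(100, n, n)
  cd3[, 1:64] <- 300  # left half T-cell zone
  b220 <- matrix(100, n, n)  # B220 blank -> no BCZ anywhere
  noise <- function(m) m + matrix(stats::rnorm(n * n, 0, 5), n)
  img <- make_image(list(B220 = pmax(noise(b220), 0),
                         CD3 = pmax(noise(cd3), 0)))
  ts <- threshold_set(c("B220", "CD3"), c(200, 200))
  rm <- segment_regions(img, "spleen", smoothing_scale = 4,
                        thresholds = ts, dapi_channel = NULL)
  expect_equal(sum(rm$labels == match("BCZ", rm$vocab)), 0L)
  expect_gt(sum(rm$labels == match("TCZ", rm$vocab)), 0.4 * n * n)

  # swapping the channel roles relabels the regions correspondingly
  rm2 <- segment_regions(img, "spleen", smoothing_scale = 4,
                         marker_channels = c(TCZ = "B220", BCZ = "CD3"),
                         thresholds = ts, dapi_channel = NULL)
  expect_equal(sum(rm2$labels == match("TCZ", rm2$vocab)), 0L)
  expect_gt(sum(rm2$labels == match("BCZ", rm2$vocab)), 0.4 * n * n)
})

test_that("cells are assigned the region under their centroid", {
  st <- split_thymus()
  cells <- cell_table(data.frame(id = 1:2, x_um = c(25, 175),
                                 y_um = c(50, 50), area_um2 = 38))
  out <- assign_cells(cells, st$regions, st$meta)
  expect_equal(out$region, c("cortex", "medulla"))
  empty <- cell_table(data.frame(id = integer(), x_um = numeric(),
                                 y_um = numeric(), area_um2 = numeric()))
  expect_equal(nrow(assign_cells(empty, st$regions, st$meta)), 0L)

  # background pixels give "unassigned"
  lab <- st$regions$labels
  lab[, 1:50] <- 0L
  rz <- region_map("thymus", lab)
  expect_equal(assign_cells(cells, rz, st$meta)$region[1], "unassigned")

  e <- spleen_eval(42)
  expect_gte(e$assign_acc_truthmap, 0.95)
})

test_that("region statistics partition counts, proportions and densities", {
  st <- split_thymus()
  cells <- cell_table(data.frame(id = 1:4, x_um = c(110, 120, 130, 140),
                                 y_um = 50, area_um2 = 38))
  cells <- assign_cells(cells, st$regions, st$meta)
  stats <- region_stats(cells, st$regions, st$meta)
  expect_equal(stats$proportion[stats$region == "medulla"], 1)
  expect_equal(stats$proportion[stats$region == "cortex"], 0)
  expect_equal(stats$density_per_mm2[stats$region == "cortex"], 0)
  expect_equal(sum(stats$proportion), 1)
  expect_equal(stats$density_per_mm2[stats$region == "medulla"],
               4 / (200 * 100 / 1e6))
})

test_that("fold changes ratio densities region by region", {
  st <- split_thymus()
  mk <- function(xs) {
    cells <- cell_table(data.frame(id = seq_along(xs), x_um = xs, y_um = 50,
                                   area_um2 = 38))
    region_stats(assign_cells(cells, st$regions, st$meta), st$regions,
                 st$meta)
  }
  a <- mk(c(110, 120))
  expect_equal(fold_change(a, a)$fold_change, c(NA, 1))
  b <- mk(c(110, 120, 130, 140, 150, 160))
  expect_equal(fold_change(a, b)$fold_change[2], 3)
  # empty-baseline region is NA, mismatched vocabularies error
  expect_true(is.na(fold_change(a, b)$fold_change[1]))
  spl <- data.frame(region = c("RP", "BCZ", "TCZ"), density_per_mm2 = 1)
  expect_error(fold_change(a, spl), "vocabular")
})

test_that("CMJ band distances follow hand geometry on a straight junction", {
  st <- split_thymus()
  cells <- cell_table(data.frame(
    id = 1:3,
    x_um = c(100.5, 150, 199),  # on-boundary, 50 um in, 99 um in
    y_um = c(50, 50, 50), area_um2 = 38))
  cells <- assign_cells(cells, st$regions, st$meta)
  bc <- cmj_band_count(cells, st$regions, st$meta, band_width = 100)
  expect_equal(bc$cells$distance_to_cmj_um, c(0, 50, 99))
  expect_equal(bc$n_inside, 3L)
  expect_equal(bc$n_outside, 0L)

  far <- cell_table(data.frame(id = 1, x_um = 199, y_um = 50, area_um2 = 38))
  far <- assign_cells(far, st$regions, st$meta)
  bc2 <- cmj_band_count(far, st$regions, st$meta, band_width = 50)
  expect_equal(bc2$n_inside, 0L)
  expect_equal(bc2$n_outside, 1L)

  # missing compartment errors
  all_med <- region_map("thymus", matrix(2L, 10, 10))
  expect_error(cmj_band_count(far, all_med, st$meta), "cortex")
})

test_that("CMJ distances match brute force on simulated thymus", {
  e <- thymus_eval(1)
  cc <- e$cells
  idx <- which(!is.na(cc$distance_to_cmj_um))
  expect_gt(length(idx), 10)
  for (i in idx) {
    ref <- oracle_nearest_boundary(cc$x_um[i], cc$y_um[i], e$boundary_xy)
    expect_lt(abs(cc$distance_to_cmj_um[i] - ref), e$pixel_size)
  }
  expect_equal(e$band$n_inside + e$band$n_outside, e$n_medulla)
})

test_that("medullary cells concentrate in the CMJ band as planted", {
  evs <- lapply(1:20, thymus_eval)
  higher <- vapply(evs, function(e)
    isTRUE(e$band$density_inside_per_mm2 > e$band$density_outside_per_mm2),
    TRUE)
  expect_gte(mean(higher), 0.95)
})

test_that("void detection applies the area cutoff and measures carves", {
  fx <- thymus_voids_fixture()
  vr <- detect_voids(fx$section$image, fx$medulla)
  expect_equal(vr$n_voids, 1L)
  truth <- max(fx$section$truth$void_areas_um2)  # the 8000 um2 carve
  expect_lt(abs(vr$void_areas_um2[1] - truth) / truth, 0.02)
  expect_equal(vr$min_area_um2, 5000)
  expect_equal(formals(detect_voids)$min_area, 5000)

  # uniformly stained medulla: no voids
  meta <- image_meta(2, "K5", 64, 64)
  k5 <- matrix(400, 64, 64)
  med <- matrix(TRUE, 64, 64)
  v0 <- detect_voids(k5, med, meta, k5_threshold = 200)
  expect_equal(v0$n_voids, 0L)
  expect_true(is.na(v0$mean_void_area_um2))
  expect_error(detect_voids(k5, matrix(FALSE, 64, 64), meta), "empty")
})

test_that("void detection equals the flood-fill oracle on random masks", {
  set.seed(20)
  meta <- image_meta(2.5, "K5", 96, 96)
  for (i in 1:25) {
    holes <- random_blob_mask(96, smooth_px = 5, frac = 0.3)
    k5 <- matrix(400, 96, 96)
    k5[holes] <- 50
    med <- matrix(TRUE, 96, 96)
    vr <- detect_voids(k5, med, meta, k5_threshold = 200, min_area = 500)
    ref <- oracle_flood_fill(holes)
    ref_areas <- tabulate(ref[ref > 0]) * 2.5^2
    ref_areas <- sort(ref_areas[ref_areas > 500], decreasing = TRUE)
    expect_equal(vr$n_voids, length(ref_areas))
    expect_equal(vr$void_areas_um2, ref_areas)
  }
})

test_that("per-mouse void aggregation is the mean of image means", {
  r1 <- structure(list(void_areas_um2 = c(8000, 6000), n_voids = 2L,
                       mean_void_area_um2 = 7000, min_area_um2 = 5000,
                       k5_threshold = 200), class = "void_report")
  r2 <- structure(list(void_areas_um2 = 9000, n_voids = 1L,
                       mean_void_area_um2 = 9000, min_area_um2 = 5000,
                       k5_threshold = 200), class = "void_report")
  agg <- summarize_voids(list(r1, r2), mouse = c("m1", "m1"))
  expect_equal(agg$mean_n_voids, 1.5)
  expect_equal(agg$mean_void_area_um2, 8000)
})
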
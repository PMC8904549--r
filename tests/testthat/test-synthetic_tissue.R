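# Small, fast configuration for generator-property tests.
tiny_spleen <- function(seed, n_cells = 10, noise = list(poisson_scale = 1,
                                                         gaussian_sd = 10),
                        nonspecific_rate = 1) {
  spleen_sim_config(seed = seed, width = 160, height = 160,
                    n_cells = n_cells, nonspecific_rate = nonspecific_rate,
                    geometry = list(n_follicles = 1, follicle_radius = 45,
                                    tcz_radius = 32), noise = noise)
}

test_that("zero rates give a background-only section with empty truth", {
  cfg <- tiny_spleen(1, n_cells = 0, nonspecific_rate = 0)
  out <- generate_section(cfg)
  expect_equal(nrow(out$truth$cells), 0L)
  tet <- out$image$channels$CD1dTet
  expect_lt(abs(mean(tet) - 100), 3)   # background 100 plus noise
  expect_lt(max(tet), 100 + 8 * sqrt(200))
})

test_that("identical config and seed reproduce sections bit-exactly", {
  cfg <- tiny_spleen(33)
  a <- generate_section(cfg)
  b <- generate_section(cfg)
  expect_identical(a$image$channels, b$image$channels)
  expect_identical(a$truth$cells, b$truth$cells)
  expect_identical(a$regions$labels, b$regions$labels)
  c <- generate_section(tiny_spleen(34))
  expect_false(identical(a$image$channels, c$image$channels))
})

test_that("planted double-positives sit above background pre-noise", {
  cfg <- tiny_spleen(5, n_cells = 12,
                     noise = list(poisson_scale = 0, gaussian_sd = 0))
  out <- generate_section(cfg)
  tr <- out$truth$cells[out$truth$cells$specific, ]
  px <- out$image$meta$pixel_size_xy
  for (i in seq_len(nrow(tr))) {
    rr <- pmax(1, pmin(160, round(tr$y_um[i] / px + 0.5)))
    cc <- pmax(1, pmin(160, round(tr$x_um[i] / px + 0.5)))
    win_r <- pmax(1, pmin(160, (rr - 2):(rr + 2)))
    win_c <- pmax(1, pmin(160, (cc - 2):(cc + 2)))
    for (ch in c("CD1dTet", "CD3")) {
      m <- mean(out$image$channels[[ch]][win_r, win_c])
      expect_gte(m, 100 + 0.5 * 500)
    }
  }
})

test_that("per-region planted counts are Poisson with the configured means", {
  counts <- matrix(0, 200, 3, dimnames = list(NULL, c("TCZ", "BCZ", "RP")))
  for (s in seq_len(200)) {
    cfg <- tiny_spleen(1000 + s, n_cells = 10, nonspecific_rate = 0)
    tr <- generate_section(cfg)$truth$cells
    for (r in colnames(counts)) counts[s, r] <- sum(tr$region == r)
  }
  lambda <- c(TCZ = 7, BCZ = 1.5, RP = 1.5)
  for (r in colnames(counts)) {
    se <- sqrt(lambda[[r]] / 200)
    expect_lt(abs(mean(counts[, r]) - lambda[[r]]), 3 * se)
  }
})

test_that("negative controls drop exactly the double-positive populations", {
  cfg <- tiny_spleen(17, n_cells = 15, nonspecific_rate = 3)
  wt <- generate_section(cfg)
  ctrl <- generate_negative_control(cfg)
  expect_equal(sum(ctrl$truth$cells$specific), 0L)
  # the non-specific objects are identical in both sections
  ns_wt <- wt$truth$cells[wt$truth$cells$population == "nonspecific", ]
  ns_ct <- ctrl$truth$cells[ctrl$truth$cells$population == "nonspecific", ]
  rownames(ns_wt) <- rownames(ns_ct) <- NULL
  expect_identical(ns_wt, ns_ct)
  # and the geometry is shared
  expect_identical(wt$regions$labels, ctrl$regions$labels)
  # control with zero nonspecific rate: tetramer channel is background only
  cfg0 <- tiny_spleen(17, n_cells = 15, nonspecific_rate = 0)
  c0 <- generate_negative_control(cfg0)
  expect_equal(nrow(c0$truth$cells[c0$truth$cells$population ==
                                     "nonspecific", ]), 0L)
  expect_lt(abs(mean(c0$image$channels$CD1dTet) - 100), 3)
})

test_that("carved voids appear as measured K5 holes inside the medulla", {
  cfg <- thymus_sim_config(seed = 3, void_spec = c(8000, 3000),
                           width = 512, height = 512,
                           geometry = list(n_lobes = 1, lobe_radius = 140),
                           noise = list(poisson_scale = 0, gaussian_sd = 0))
  out <- generate_section(cfg)
  expect_length(out$truth$void_areas_um2, 2L)
  expect_lt(abs(out$truth$void_areas_um2[1] - 8000) / 8000, 0.02)
  expect_lt(abs(out$truth$void_areas_um2[2] - 3000) / 3000, 0.02)
  # pixels in the carved area really lack K5
  med <- out$regions$labels == match("medulla", out$regions$vocab)
  hole_px <- sum(med & out$image$channels$K5 <= 150)
  px_area <- out$image$meta$pixel_size_xy^2
  expect_lt(abs(hole_px * px_area - sum(out$truth$void_areas_um2)) /
              sum(out$truth$void_areas_um2), 0.05)
})

test_that("infeasible geometry is rejected", {
  expect_error(generate_section(
    spleen_sim_config(seed = 1, width = 128, height = 128,
                      geometry = list(n_follicles = 4, follicle_radius = 60,
                                      tcz_radius = 40))),
    "cannot fit")
})

test_that("forward spectral mixing follows the matrix model", {
  img <- make_image(list(f1 = matrix(10, 2, 2), f2 = matrix(0, 2, 2)))
  m <- mixing_matrix(rbind(c(1, 0.3), c(0.2, 1)), c("d1", "d2"),
                     c("f1", "f2"))
  mixed <- mix_channels(img, m)
  expect_identical(names(mixed$channels), c("d1", "d2"))
  expect_equal(mixed$channels$d1, matrix(10, 2, 2))
  expect_equal(mixed$channels$d2, matrix(2, 2, 2))
  expect_error(mix_channels(img, mixing_matrix(diag(3))), "channels")
})
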
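random_mixing <- function(k, seed) {
  set.seed(seed)
  mixing_matrix(diag(k) + matrix(stats::runif(k * k, 0, 0.3), k),
                paste0("det", 1:k), paste0("fluo", 1:k))
}

random_image <- function(k, n = 16, seed = 1, names = paste0("fluo", 1:k)) {
  set.seed(seed)
  chs <- lapply(seq_len(k), function(i) matrix(stats::runif(n * n, 0, 100), n))
  names(chs) <- names
  make_image(chs)
}

test_that("identity mixing and unmixing leave images unchanged", {
  img <- random_image(3)
  id <- mixing_matrix(diag(3), paste0("fluo", 1:3), paste0("fluo", 1:3))
  expect_equal(mix_channels(img, id)$channels, img$channels)
  expect_equal(unmix_channels(img, id)$channels, img$channels)
})

test_that("mixing and unmixing reproduce the worked 2x2 example", {
  m <- mixing_matrix(rbind(c(1, 0.3), c(0.2, 1)), c("d1", "d2"),
                     c("f1", "f2"))
  pure <- make_image(list(f1 = matrix(10, 1, 1), f2 = matrix(0, 1, 1)))
  mixed <- mix_channels(pure, m)
  expect_equal(mixed$channels$d1[1, 1], 10)
  expect_equal(mixed$channels$d2[1, 1], 2)
  rec <- unmix_channels(mixed, m)
  expect_equal(rec$channels$f1[1, 1], 10, tolerance = 1e-10)
  expect_equal(rec$channels$f2[1, 1], 0, tolerance = 1e-10)
})

test_that("unmixing inverts mixing for random well-conditioned matrices", {
  for (s in 1:5) {
    m <- random_mixing(4, s)
    img <- random_image(4, seed = s + 100)
    rec <- unmix_channels(mix_channels(img, m), m)
    rel <- max(vapply(names(img$channels), function(nm)
      max(abs(rec$channels[[nm]] - img$channels[[nm]])) /
        max(img$channels[[nm]]), 0))
    expect_lt(rel, 1e-6)
  }
})

test_that("rank-deficient mixing matrices are rejected by name", {
  m <- cbind(c(1, 2), c(2, 4))
  expect_error(mixing_matrix(m, c("d1", "d2"), c("fA", "fB")),
               "rank deficient.*fA.*fB")
  expect_error(mixing_matrix(matrix(-1, 2, 2)), "non-negative")
})

test_that("compensation solves the spillover system and clamps at zero", {
  s <- mixing_matrix(rbind(c(1, 0), c(0.1, 1)), c("a", "b"), c("a", "b"))
  obs <- make_image(list(a = matrix(10, 2, 2), b = matrix(1, 2, 2)))
  comp <- compensate(obs, s)
  expect_equal(comp$channels$a, matrix(10, 2, 2))
  expect_equal(comp$channels$b, matrix(0, 2, 2))

  # identity leaves the image unchanged
  id <- mixing_matrix(diag(2), c("a", "b"), c("a", "b"))
  expect_equal(compensate(obs, id)$channels, obs$channels)

  # round trip through a random unit-diagonal spillover
  set.seed(9)
  sp <- diag(3) + matrix(stats::runif(9, 0, 0.2), 3)
  diag(sp) <- 1
  spm <- mixing_matrix(sp, paste0("c", 1:3), paste0("c", 1:3))
  img <- random_image(3, seed = 5, names = paste0("c", 1:3))
  spilled <- mix_channels(img, spm)
  rec <- compensate(spilled, spm)
  for (nm in names(img$channels))
    expect_equal(rec$channels[[nm]], img$channels[[nm]], tolerance = 1e-8)

  expect_error(compensate(obs, mixing_matrix(rbind(c(2, 0), c(0, 1)))),
               "unit diagonal")
})

test_that("threshold calibration matches the empirical quantile", {
  const <- make_image(list(Tet = matrix(7, 10, 10)))
  expect_equal(threshold_for(calibrate_threshold(const, "Tet", 0.5), "Tet"), 7)
  expect_equal(threshold_for(calibrate_threshold(const, "Tet", 1), "Tet"), 7)

  set.seed(3)
  v <- matrix(stats::rnorm(400 * 400, 100, 10), 400)
  ctl <- make_image(list(Tet = v - min(v)))  # keep intensities >= 0
  ts <- calibrate_threshold(ctl, "Tet", 0.999)
  thr <- threshold_for(ts, "Tet")
  # independent oracle: sort and linearly interpolate order statistics
  sv <- sort(as.numeric(ctl$channels$Tet))
  h <- (length(sv) - 1) * 0.999 + 1
  expected <- sv[floor(h)] + (h - floor(h)) * (sv[floor(h) + 1] - sv[floor(h)])
  expect_equal(thr, expected, tolerance = 1e-12)
  # shifted-Gaussian range check from the 0.999 normal quantile
  expect_gt(thr + min(v), 125)
  expect_lt(thr + min(v), 137)

  # q = 1 is the maximum
  expect_equal(threshold_for(calibrate_threshold(ctl, "Tet", 1), "Tet"),
               max(ctl$channels$Tet))
  expect_error(calibrate_threshold(ctl, "missing", 0.9), "not present")
  expect_error(calibrate_threshold(ctl, "Tet", 0), "q must")
})

test_that("a control thresholded at its own q leaves <= 1 - q positive", {
  set.seed(11)
  ctl <- make_image(list(Tet = matrix(stats::rpois(512 * 512, 100), 512)))
  thr <- threshold_for(calibrate_threshold(ctl, "Tet", 0.999), "Tet")
  frac_pos <- mean(ctl$channels$Tet > thr)
  tie_mass <- mean(ctl$channels$Tet == thr)
  expect_lte(frac_pos, 0.001 + tie_mass + 1e-12)
})

test_that("thresholds and mixing matrices round-trip through disk", {
  ts <- threshold_set(c("Tet", "CD3"), c(146.5, 299.25), "ctrl-01", 0.999)
  path <- withr::local_tempfile(fileext = ".json")
  write_thresholds(ts, path)
  back <- read_thresholds(path)
  expect_equal(back$threshold, ts$threshold)
  expect_equal(back$channel, ts$channel)
  expect_equal(back$q, ts$q)

  m <- random_mixing(3, 2)
  mp <- withr::local_tempfile(fileext = ".csv")
  write_mixing_matrix(m, mp)
  expect_equal(unclass(read_mixing_matrix(mp)), unclass(m),
               ignore_attr = TRUE, tolerance = 1e-12)
})
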
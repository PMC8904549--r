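# Deterministic nucleus scene: discs of radius r at given centres
# (pixel units), no noise.
nuclei_image <- function(centres, size = 128, r = 3.2, amp = 500, bg = 100,
                         pixel_size = 1) {
  dapi <- matrix(bg, size, size)
  for (i in seq_len(nrow(centres))) {
    for (rr in seq_len(size)) for (cc in seq_len(size)) {
      if ((rr - centres[i, 1])^2 + (cc - centres[i, 2])^2 <= r^2)
        dapi[rr, cc] <- bg + amp
    }
  }
  make_image(list(DAPI = dapi), pixel_size)
}

test_that("nucleus segmentation recovers isolated nuclei exactly", {
  set.seed(8)
  centres <- as.matrix(expand.grid(seq(10, 122, 14), seq(10, 122, 14)))
  centres <- centres + matrix(stats::runif(nrow(centres) * 2, -2, 2),
                              ncol = 2)
  centres <- centres[1:50, ]
  img <- nuclei_image(centres)
  labels <- segment_nuclei(img, dapi_threshold = 300)
  expect_equal(max(labels), 50L)
  feats <- extract_features(labels, img)
  for (i in seq_len(50)) {
    d <- sqrt((feats$x_um - (centres[i, 2] - 0.5))^2 +
              (feats$y_um - (centres[i, 1] - 0.5))^2)
    expect_lt(min(d), 1)
  }
  blank <- make_image(list(DAPI = matrix(100, 32, 32)))
  expect_equal(max(segment_nuclei(blank, dapi_threshold = 300)), 0L)
})

test_that("touching nuclei are split by the watershed in most placements", {
  set.seed(12)
  r <- 3.2
  d <- 1.7 * 2 * r / 2  # centres 1.7 r apart: ~30 % overlap of radius
  split_ok <- 0L
  for (i in 1:50) {
    ang <- stats::runif(1, 0, 2 * pi)
    ctr <- matrix(c(32 + c(-1, 1) * d * sin(ang) / 1,
                    32 + c(-1, 1) * d * cos(ang) / 1), ncol = 2)
    ctr <- ctr + stats::runif(4, -0.5, 0.5)
    img <- nuclei_image(ctr, size = 64, r = r)
    labels <- segment_nuclei(img, dapi_threshold = 300,
                             min_nucleus_area = 8, seed_min_distance = 4)
    if (max(labels) == 2L) split_ok <- split_ok + 1L
  }
  expect_gte(split_ok, 45L)
})

test_that("feature extraction matches brute-force accumulation", {
  set.seed(3)
  img <- make_image(list(DAPI = matrix(stats::runif(400, 0, 10), 20),
                         CD3 = matrix(stats::runif(400, 0, 10), 20)),
                    pixel_size = 2)
  labels <- matrix(0L, 20, 20)
  labels[2:4, 2:4] <- 1L
  labels[10:15, 8:12] <- 2L
  feats <- extract_features(labels, img)
  expect_equal(nrow(feats), 2L)
  expect_equal(feats$area_um2, c(9, 30) * 4)
  for (lab in 1:2) {
    tot <- 0; n <- 0
    for (r in 1:20) for (c in 1:20) {
      if (labels[r, c] == lab) { tot <- tot + img$channels$CD3[r, c]; n <- n + 1 }
    }
    expect_equal(feats$mean_CD3[lab], tot / n, tolerance = 1e-12)
  }
  # constant channel: mean equals the constant; row count = label count
  const <- make_image(list(X = matrix(5, 20, 20)), pixel_size = 2)
  f2 <- extract_features(labels, const)
  expect_equal(f2$mean_X, c(5, 5))
})

test_that("gate trees validate their structure", {
  expect_error(gate_tree(list(list(name = "a", parent = "zz", x = "u",
                                   y = "v", xmin = 0, xmax = 1, ymin = 0,
                                   ymax = 1))), "unknown parent")
  expect_error(gate_tree(list(list(name = "a", parent = "root", x = "u",
                                   y = "v"))), "neither")
  tree <- default_gate_tree()
  path <- withr::local_tempfile(fileext = ".json")
  write_gate_tree(tree, path)
  back <- read_gate_tree(path)
  expect_identical(names(back), names(tree))
  expect_equal(back$Mac$vertices, tree$Mac$vertices, ignore_attr = TRUE)
})

test_that("gating matches independent per-cell evaluation exactly", {
  set.seed(21)
  n <- 1000
  cells <- cell_table(data.frame(
    id = seq_len(n), x_um = stats::runif(n, 0, 100),
    y_um = stats::runif(n, 0, 100), area_um2 = 20,
    mean_B220 = stats::runif(n, 0, 600),
    mean_CD3 = stats::runif(n, 0, 600),
    mean_CD4 = stats::runif(n, 0, 600),
    mean_CD11b = stats::runif(n, 0, 600),
    mean_CD11c = stats::runif(n, 0, 600),
    mean_CD1dTet = stats::runif(n, 0, 600)))
  tree <- default_gate_tree()
  gated <- apply_gates(cells, tree)
  ref <- vapply(seq_len(n), function(i)
    oracle_gate_one(as.list(cells[i, ]), tree), "")
  expect_identical(gated$population, ref)
  # partition: every cell in exactly one population
  expect_false(anyNA(gated$population))
  gs <- attr(gated, "gate_stats")
  expect_true(all(c("gate", "pct_of_parent", "pct_of_total") %in% names(gs)))
})

test_that("gate boundaries are closed (edge cells are inside)", {
  tree <- gate_tree(list(list(name = "g", parent = "root", x = "mean_A",
                              y = "mean_B", xmin = 10, xmax = 20,
                              ymin = 10, ymax = 20)))
  cells <- cell_table(data.frame(id = 1:2, x_um = 0, y_um = 0,
                                 area_um2 = 1, mean_A = c(10, 20),
                                 mean_B = c(20, 10)))
  expect_equal(apply_gates(cells, tree)$population, c("g", "g"))

  # an all-space rectangle captures 100 %
  all_tree <- gate_tree(list(list(name = "all", parent = "root",
                                  x = "mean_A", y = "mean_B",
                                  xmin = -1e12, xmax = 1e12,
                                  ymin = -1e12, ymax = 1e12)))
  gs <- attr(apply_gates(cells, all_tree), "gate_stats")
  expect_equal(gs$pct_of_total[gs$gate == "all"], 100)
})

test_that("asinh-derived features feed gates", {
  cells <- cell_table(data.frame(id = 1, x_um = 0, y_um = 0, area_um2 = 1,
                                 mean_A = 1500, mean_B = 0))
  tree <- gate_tree(list(list(name = "hi", parent = "root",
                              x = "asinh_mean_A", y = "mean_B",
                              xmin = asinh(10), xmax = 1e9,
                              ymin = -1, ymax = 1)))
  expect_equal(apply_gates(cells, tree)$population, "hi")
  bad <- gate_tree(list(list(name = "hi", parent = "root", x = "mean_zz",
                             y = "mean_B", xmin = 0, xmax = 1, ymin = 0,
                             ymax = 1)))
  expect_error(apply_gates(cells, bad), "unknown gate feature")
})

test_that("populations map back onto the segmentation mask", {
  fx <- histo_fixture()
  mb <- map_back(fx$gated, fx$labels)
  # conservation: pixels per population equal summed member areas
  px_area <- fx$section$image$meta$pixel_size_xy^2
  for (pop in names(mb$legend)) {
    n_px <- sum(mb$image == mb$legend[[pop]])
    members <- fx$gated$area_um2[fx$gated$population == pop]
    expect_equal(n_px * px_area, sum(members), tolerance = 1e-9)
  }
  # background is preserved
  expect_equal(sum(mb$image > 0), sum(fx$labels > 0))
  # single-population degenerate case: mask equals foreground
  one <- fx$gated
  one$population <- "only"
  mb1 <- map_back(one, fx$labels)
  expect_equal(mb1$image > 0, fx$labels > 0)
})

test_that("simulated nine-population section is gated accurately", {
  fx <- histo_fixture()
  acc <- histo_accuracy(fx$gated, fx$section$truth$cells)
  expect_gte(acc, 0.9)
  # partition property on real output
  expect_false(anyNA(fx$gated$population))
  expect_true(all(fx$gated$population %in%
                    c(names(default_gate_tree()), "misc")))
})
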
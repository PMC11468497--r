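test_that("index attains exact bounds on pure fixtures and is a ratio", {
  cal <- default_calibration()
  allm <- synthetic_micrograph(120, 120, m = 0.5, noise_sd = 4, seed = 3)
  cnt <- classify_pixels(allm$img, roi(60, 60, side = 100), cal)
  expect_identical(mixing_index(cnt)$value, 1)
  half <- synthetic_micrograph(120, 120,
                               m = function(y) as.numeric(y > 0.5),
                               noise_sd = 4, seed = 4)
  cnth <- classify_pixels(half$img, roi(60, 60, side = 100), cal)
  expect_identical(mixing_index(cnth)$value, 0)
  # plain arithmetic on counts
  fake <- structure(list(n_mixed = 300L, n_unmixed = 100L,
                         n_unclassified = 0L, total = 400L),
                    class = "pixel_class_counts")
  expect_equal(mixing_index(fake)$value, 0.75)
  empty <- structure(list(n_mixed = 0L, n_unmixed = 0L,
                          n_unclassified = 10L, total = 10L),
                     class = "pixel_class_counts")
  expect_error(mixing_index(empty), "classified")
})

test_that("vectorized classification equals the brute-force pixel loop", {
  cal <- default_calibration()
  set.seed(42)
  for (k in 1:50) {
    mfun <- function(y) pmin(1, pmax(0, y + stats::runif(1, -0.4, 0.4)))
    tru <- synthetic_micrograph(24, 24, m = mfun, noise_sd = 4, seed = k)
    r <- roi(12, 12, side = 20, pixel_size = 1)
    got <- classify_pixels(tru$img, r, cal)
    want <- brute_force_counts(tru$img, r, cal)
    expect_identical(got$n_mixed, want$n_mixed)
    expect_identical(got$n_unmixed, want$n_unmixed)
    expect_identical(got$n_mixed + got$n_unmixed + got$n_unclassified,
                     got$total)
  }
})

test_that("pixel counts are invariant under in-ROI permutation", {
  cal <- default_calibration()
  tru <- synthetic_micrograph(60, 60, m = function(y) y, noise_sd = 4,
                              seed = 9)
  r <- roi(30, 30, side = 40)
  before <- classify_pixels(tru$img, r, cal)
  img2 <- tru$img
  set.seed(1)
  idx <- sample(length(r$rows) * length(r$cols))
  for (ch in 1:3) {
    block <- img2[r$rows, r$cols, ch]
    img2[r$rows, r$cols, ch] <- matrix(block[idx], nrow(block))
  }
  after <- classify_pixels(img2, r, cal)
  expect_identical(before$n_mixed, after$n_mixed)
  expect_identical(before$n_unmixed, after$n_unmixed)
})

test_that("mixed-box precedence resolves overlapping calibrations", {
  cal <- suppressWarnings(rgb_calibration(
    mixed = c(0, 255, 0, 255, 0, 255),       # everything
    blue = c(0, 100, 0, 100, 150, 255),
    yellow = c(200, 255, 180, 255, 0, 100)))
  tru <- synthetic_micrograph(30, 30, m = 0, noise_sd = 0, seed = 1)
  cnt <- classify_pixels(tru$img, roi(15, 15, side = 20), cal)
  expect_identical(cnt$n_unmixed, 0L)
  expect_identical(cnt$n_mixed, cnt$total)
})

test_that("calibration from references is percentile-robust and symmetric", {
  tb <- synthetic_micrograph(80, 80, m = 0, noise_sd = 4, seed = 11)
  ty <- synthetic_micrograph(80, 80, m = 1, noise_sd = 4, seed = 12)
  tm <- synthetic_micrograph(80, 80, m = 0.5, noise_sd = 4, seed = 13)
  cal <- calibrate_rgb_ranges(tb$img, ty$img, tm$img)
  # 1% salt-and-pepper outliers do not move the p = 1 bounds beyond margin
  spoil <- function(img, seed) {
    set.seed(seed)
    n <- round(0.01 * prod(dim(img)[1:2]))
    i <- sample(dim(img)[1], n, TRUE); j <- sample(dim(img)[2], n, TRUE)
    for (k in seq_len(n)) img[i[k], j[k], ] <- c(255, 255, 255) * (k %% 2)
    img
  }
  cal2 <- calibrate_rgb_ranges(spoil(tb$img, 1), spoil(ty$img, 2),
                               spoil(tm$img, 3))
  for (nm in names(cal))
    expect_true(all(abs(cal2[[nm]] - cal[[nm]]) <= 5 + 1e-9))
  # swapping the blue and yellow references swaps the classes
  cal_sw <- calibrate_rgb_ranges(ty$img, tb$img, tm$img)
  expect_equal(cal_sw$blue, cal$yellow)
  expect_equal(cal_sw$yellow, cal$blue)
  # constant-color references give degenerate boxes of anchor +/- margin
  solid <- synthetic_micrograph(20, 20, m = 0, noise_sd = 0, seed = 1)
  calc <- calibrate_rgb_ranges(solid$img, ty$img, tm$img, margin = 5)
  anchor <- fixture_colors()$blue
  expect_equal(calc$blue, as.vector(rbind(anchor - 5, anchor + 5)))
})

test_that("ROI placement insets from walls and stays disjoint", {
  # 400 um channel at 1 um/px: 380 um ROI leaves a 10 px inset per side
  mask <- matrix(FALSE, 500, 1400)
  mask[51:450, ] <- TRUE
  rois <- roi_grid(mask, station_col = 700, n = 3, side = 380,
                   pixel_size = 1)
  expect_length(rois, 3)
  for (r in rois) {
    expect_gte(min(r$rows), 51 + 10)
    expect_lte(max(r$rows), 450 - 10)
  }
  # pairwise disjoint along the axis
  cols <- lapply(rois, `[[`, "cols")
  expect_length(Reduce(intersect, cols), 0)
  expect_identical(length(roi_grid(mask, 700, n = 1)), 1L)
  narrow <- matrix(TRUE, 100, 400)
  expect_error(roi_grid(narrow, 200), "smaller side")
  expect_error(roi(50, 50, side = 380, pixel_size = 100), "10 px")
})

test_that("MI versus distance reproduces fixture ground truth", {
  cal <- default_calibration()
  stations <- c(0, 10, 15, 20, 25, 40)
  ells <- c(0, 30, 45, 60, 80, 120)
  imgs <- lapply(seq_along(stations), function(k)
    synthetic_micrograph(1200, 400, m = erf_mixing_profile(ells[k]),
                         noise_sd = 4, seed = 20 + k)$img)
  tab <- mi_vs_distance(imgs, stations, cal, pixel_size = 1)
  expect_identical(nrow(tab), 6L)
  # fully unmixed at the junction
  expect_identical(tab$mi_mean[1], 0)
  # mixed fraction increases monotonically downstream by construction
  expect_true(all(diff(tab$mi_mean) >= 0))
  expect_true(all(tab$unclassified == 0))
  # unmixed-everywhere series gives all-zero means
  imgs0 <- lapply(1:3, function(k)
    synthetic_micrograph(1200, 400,
                         m = function(y) as.numeric(y > 0.5),
                         noise_sd = 4, seed = 30 + k)$img)
  tab0 <- mi_vs_distance(imgs0, c(0, 10, 15), cal, pixel_size = 1)
  expect_true(all(tab0$mi_mean == 0))
  expect_error(mi_vs_distance(imgs0, c(0, 10, 15), cal,
                              pixel_size = NULL), "pixel size")
  expect_error(classify_pixels(array(0, c(10, 10, 1)),
                               roi(5, 5, side = 10), cal), "RGB")
})
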
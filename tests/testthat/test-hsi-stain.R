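test_that("rgb_to_hsi matches the arccos closed forms", {
  blue <- rgb_to_hsi(c(0, 0, 255))
  expect_equal(blue$h, 240)
  expect_equal(blue$s, 1)
  expect_equal(blue$i, 85)
  red <- rgb_to_hsi(c(255, 0, 0))
  expect_equal(red$h, 0)
  expect_equal(red$s, 1)
  expect_equal(red$i, 85)
  grey <- rgb_to_hsi(c(100, 100, 100))
  expect_true(is.na(grey$h))
  expect_equal(grey$s, 0)
  expect_equal(grey$i, 100)
  black <- rgb_to_hsi(c(0, 0, 0))
  expect_equal(black$s, 0)
})

test_that("hsi round-trip through hsi_to_rgb is exact inside the gamut", {
  set.seed(8)
  h <- runif(50, 0, 359.9); s <- runif(50, 0.05, 0.6); i <- runif(50, 30, 140)
  rgb <- lfbmil:::hsi_to_rgb(h, s, i)
  ok <- apply(rgb, 1, function(v) all(v >= 0 & v <= 255))
  for (k in which(ok)) {
    back <- rgb_to_hsi(rgb[k, ])
    expect_equal(back$h, h[k], tolerance = 1e-6)
    expect_equal(back$s, s[k], tolerance = 1e-6)
    expect_equal(back$i, i[k], tolerance = 1e-6)
  }
})

test_that("hue and saturation are invariant under global intensity scaling", {
  set.seed(9)
  img <- array(runif(48 * 48 * 3, 20, 240), dim = c(48, 48, 3))
  base <- rgb_to_hsi(img)
  for (c_scale in c(0.35, 0.8, 1)) {
    sc <- rgb_to_hsi(img * c_scale)
    expect_equal(sc$h, base$h, tolerance = 1e-9)
    expect_equal(sc$s, base$s, tolerance = 1e-9)
    expect_equal(sc$i, base$i * c_scale, tolerance = 1e-9)
  }
})

test_that("count_positive applies hue band, saturation gate and intensity gates", {
  blue_tile <- solid_tile(c(0, 0, 255), 256, 256)
  expect_equal(count_positive(blue_tile, dark_blue_range()), 65536)
  grey_tile <- solid_tile(c(128, 128, 128), 64, 64)
  expect_equal(count_positive(grey_tile, dark_blue_range()), 0)
  half <- solid_tile(c(0, 0, 255), 64, 64)
  half[, 33:64, ] <- rep(c(255, 0, 0), each = 64 * 32)
  expect_equal(count_positive(half, dark_blue_range()), 64 * 32)
  # bright blue is light, not dark: intensity (140+140+230)/3 = 170
  bright <- solid_tile(c(140, 140, 230), 32, 32)
  expect_equal(count_positive(bright, dark_blue_range()), 0)
  expect_equal(count_positive(bright, light_blue_range()), 32 * 32)
})

test_that("tile_counts computes the dark/light ratio with guards", {
  tl <- solid_tile(c(0, 0, 255), 32, 32)
  tl[1:16, , ] <- rep(c(140, 140, 230), each = 16 * 32)
  tc <- tile_counts(tl)
  expect_equal(tc$dark_count, 512)
  expect_equal(tc$light_count, 512)
  expect_equal(tc$ratio, 1)
  expect_false(tc$zero_positive)
  # zero light -> ratio undefined, counts retained
  dark_only <- tile_counts(solid_tile(c(0, 0, 255), 16, 16))
  expect_equal(dark_only$dark_count, 256)
  expect_true(is.na(dark_only$ratio))
  # zero dark -> flagged
  expect_true(tile_counts(solid_tile(c(250, 250, 250), 16, 16))$zero_positive)
  # overlapping bands rejected
  expect_error(
    tile_counts(tl, dark = hue_range("a", intensity_max = 150),
                light = hue_range("b", intensity_min = 120, intensity_max = 190)),
    "overlap")
})

test_that("summarize_slide drops zero-dark tiles and takes medians", {
  counts <- data.frame(dark_count = c(10, 0, 30), light_count = c(5, 7, 10))
  s <- summarize_slide(counts, "D1")
  expect_equal(s$median_dark, 20)
  expect_equal(s$median_ratio, 2.5)
  expect_equal(s$n_tiles_used, 2L)
  expect_equal(s$n_tiles_dropped, 1L)
  single <- summarize_slide(data.frame(dark_count = 7, light_count = 2), "D2")
  expect_equal(single$median_dark, 7)
  expect_equal(single$median_ratio, 3.5)
  all_zero <- summarize_slide(data.frame(dark_count = c(0, 0), light_count = c(1, 2)), "D3")
  expect_true(all_zero$missing)
  expect_equal(all_zero$n_tiles_dropped, 2L)
  either <- summarize_slide(data.frame(dark_count = c(5, 6), light_count = c(0, 2)),
                            "D4", zero_rule = "either")
  expect_equal(either$n_tiles_used, 1L)
})

test_that("compare_groups runs Welch t-tests on both stain metrics", {
  summ <- data.frame(median_dark = c(1, 2, 3, 4, 5, 6),
                     median_ratio = c(1, 2, 3, 4, 5, 6))
  g <- rep(c("a", "b"), each = 3)
  res <- compare_groups(summ, g)
  expect_equal(res$t[1], -3.674, tolerance = 1e-3)
  same <- compare_groups(data.frame(median_dark = rep(2, 6), median_ratio = rep(2, 6)), g)
  expect_equal(same$t, c(0, 0))
  expect_equal(same$p.value, c(1, 1))
  expect_error(compare_groups(summ[1:3, ], factor(c("a", "a", "b"), levels = c("a", "b"))),
               "at least 2 slides")
})

test_that("stain_kde2d yields normalised densities with sane modes", {
  set.seed(10)
  x <- rnorm(200, 5, 1); y <- rnorm(200, -2, 0.5)
  kd <- stain_kde2d(x, y, n = 80)
  z <- kd$all$z
  dx <- diff(kd$grid$x[1:2]); dy <- diff(kd$grid$y[1:2])
  expect_equal(sum(z) * dx * dy, 1, tolerance = 0.01)
  # tight cluster: mode within one grid cell of the mean
  xc <- rnorm(50, 0, 0.02); yc <- rnorm(50, 1, 0.02)
  kdc <- stain_kde2d(xc, yc, n = 64)
  idx <- which(kdc$all$z == max(kdc$all$z), arr.ind = TRUE)
  # mode within a few grid cells / Monte Carlo error of the cluster mean
  tol <- function(v, g) 3 * sd(v) / sqrt(length(v)) + 2 * diff(range(g)) / 63
  expect_lt(abs(kdc$grid$x[idx[1]] - mean(xc)), tol(xc, kdc$grid$x))
  expect_lt(abs(kdc$grid$y[idx[2]] - mean(yc)), tol(yc, kdc$grid$y))
  # mirrored data gives mirrored density
  kdm <- stain_kde2d(-x, y, n = 80)
  expect_equal(kdm$all$z, kd$all$z[80:1, ], tolerance = 1e-9)
  expect_error(stain_kde2d(rep(1, 10), y[1:10]), "degenerate")
  expect_gt(length(kd$all$contours), 0)
})

test_that("KDE surfaces export as gridded CSV and GeoJSON contours", {
  set.seed(11)
  kd <- stain_kde2d(rnorm(60), rnorm(60), group = rep(c("a", "b"), 30), n = 32)
  d <- tempfile()
  write_kde2d(kd, d)
  expect_true(file.exists(file.path(d, "a_density.csv")))
  expect_true(file.exists(file.path(d, "b_contours.geojson")))
  grid_df <- read.csv(file.path(d, "a_density.csv"))
  expect_equal(nrow(grid_df), 32 * 32)
  expect_equal(matrix(grid_df$density, 32, 32), kd$a$z, tolerance = 1e-12)
  gj <- jsonlite::read_json(file.path(d, "a_contours.geojson"))
  expect_equal(gj$type, "FeatureCollection")
  expect_gt(length(gj$features), 0)
  expect_equal(gj$features[[1]]$geometry$type, "LineString")
  unlink(d, recursive = TRUE)
})
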
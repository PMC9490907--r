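#' Hue-range parameters for positive pixel counting
#'
#' A pixel is positive for a band when its circular hue distance to
#' `hue_center` is at most `hue_width / 2`, its saturation is at least
#' `saturation_min`, and its intensity lies in `[intensity_min,
#' intensity_max)`. Achromatic pixels (undefined hue) are never positive.
#' The shipped dark/light defaults share the blue hue band and are split by
#' intensity; they are generator-consistent artifact defaults, exposed so
#' users can supply bands annotated on their own stains.
#'
#' @param name Band label.
#' @param hue_center Hue centre in degrees `[0, 360)`.
#' @param hue_width Full width of the hue band in degrees.
#' @param saturation_min Minimum saturation.
#' @param intensity_min,intensity_max Half-open intensity interval (0-255).
#' @return A `hue_range` object.
#' @export
hue_range <- function(name, hue_center = 240, hue_width = 80,
                      saturation_min = 0.15, intensity_min = 0,
                      intensity_max = 120) {
  stopifnot(intensity_min < intensity_max, hue_width > 0,
            saturation_min >= 0, saturation_min <= 1)
  structure(list(name = name, hue_center = hue_center %% 360,
                 hue_width = hue_width, saturation_min = saturation_min,
                 intensity_min = intensity_min, intensity_max = intensity_max),
            class = "hue_range")
}

#' @rdname hue_range
#' @export
dark_blue_range <- function() hue_range("dark_blue", intensity_min = 0, intensity_max = 120)

#' @rdname hue_range
#' @export
light_blue_range <- function() hue_range("light_blue", intensity_min = 120, intensity_max = 190)

# positive-pixel mask on precomputed HSI channels
positive_mask_hsi <- function(h, s, i, params) {
  d <- abs(((h - params$hue_center + 180) %% 360) - 180)
  !is.na(h) & d <= params$hue_width / 2 & s >= params$saturation_min &
    i >= params$intensity_min & i < params$intensity_max
}

#' Count positive pixels in a tile for one hue band
#'
#' @param tile `H x W x 3` RGB array (0-255).
#' @param params A [hue_range()].
#' @return Number of positive pixels.
#' @examples
#' blue <- array(rep(c(0, 0, 255), each = 16), dim = c(4, 4, 3))
#' count_positive(blue, dark_blue_range())  # 16
#' @export
count_positive <- function(tile, params) {
  hsi <- rgb_to_hsi(tile)
  sum(positive_mask_hsi(hsi$h, hsi$s, hsi$i, params))
}

#' Dark/light positive pixel counts and their ratio for one tile
#'
#' The two bands must be disjoint in hue-by-intensity space. The ratio
#' (dark / light) is undefined (`NA`) when the light count is zero; a tile
#' with zero dark pixels is flagged as zero-positive.
#'
#' @param tile RGB tile array, or `NULL` if `hsi` is supplied.
#' @param dark,light [hue_range()] parameter sets.
#' @param hsi Optional precomputed HSI list (for pipeline reuse).
#' @return A one-row data frame: `dark_count`, `light_count`, `ratio`,
#'   `zero_positive`.
#' @export
tile_counts <- function(tile, dark = dark_blue_range(), light = light_blue_range(),
                        hsi = NULL) {
  hue_gap <- abs(((dark$hue_center - light$hue_center + 180) %% 360) - 180)
  hue_overlap <- hue_gap < (dark$hue_width + light$hue_width) / 2
  int_overlap <- dark$intensity_min < light$intensity_max &&
    light$intensity_min < dark$intensity_max
  if (hue_overlap && int_overlap)
    stop("dark and light bands overlap in hue x intensity space", call. = FALSE)
  if (is.null(hsi)) hsi <- rgb_to_hsi(tile)
  dk <- sum(positive_mask_hsi(hsi$h, hsi$s, hsi$i, dark))
  lt <- sum(positive_mask_hsi(hsi$h, hsi$s, hsi$i, light))
  data.frame(dark_count = dk, light_count = lt,
             ratio = if (lt > 0) dk / lt else NA_real_,
             zero_positive = dk == 0)
}

#' Summarise positive-pixel counts over a slide's top-attention tiles
#'
#' Tiles with zero dark-positive pixels are treated as outliers and removed;
#' the slide summary is the median dark count over retained tiles and the
#' median ratio over retained tiles with a defined ratio. With
#' `zero_rule = "either"` tiles with zero pixels in either band are removed
#' instead.
#'
#' @param counts Data frame of per-tile counts (from [tile_counts()] rows) for
#'   the tiles of one slide.
#' @param donor_id Identifier carried into the summary.
#' @param zero_rule Outlier rule: `"dark"` (default) or `"either"`.
#' @return One-row data frame: `donor_id`, `median_dark`, `median_ratio`,
#'   `n_tiles_used`, `n_tiles_dropped`, `missing` (TRUE when every tile was
#'   dropped).
#' @examples
#' counts <- data.frame(dark_count = c(10, 0, 30), light_count = c(5, 7, 10))
#' summarize_slide(counts, "D0001")  # median dark 20, median ratio 2.5
#' @export
summarize_slide <- function(counts, donor_id = "slide",
                            zero_rule = c("dark", "either")) {
  zero_rule <- match.arg(zero_rule)
  drop <- if (zero_rule == "dark") counts$dark_count == 0
          else counts$dark_count == 0 | counts$light_count == 0
  kept <- counts[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(data.frame(donor_id = donor_id, median_dark = NA_real_,
                      median_ratio = NA_real_, n_tiles_used = 0L,
                      n_tiles_dropped = sum(drop), missing = TRUE))
  }
  ratio <- kept$dark_count / kept$light_count
  ratio[kept$light_count == 0] <- NA_real_
  data.frame(donor_id = donor_id,
             median_dark = stats::median(kept$dark_count),
             median_ratio = stats::median(ratio, na.rm = TRUE),
             n_tiles_used = nrow(kept), n_tiles_dropped = sum(drop),
             missing = FALSE)
}

#' Compare slide-level stain summaries between groups
#'
#' Welch two-sample t-tests on the slide-level median dark count and median
#' dark/light ratio between two groups (e.g. predicted-CI vs predicted-NCI,
#' or labeled-CI vs labeled-NCI).
#'
#' @param summaries Data frame of [summarize_slide()] rows.
#' @param group Two-level grouping vector aligned with `summaries` rows.
#' @return Data frame with one row per metric: `metric`, `t`, `p.value`,
#'   `mean_1`, `mean_2` (group order = factor level order), `n_1`, `n_2`.
#' @export
compare_groups <- function(summaries, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("`group` must have exactly two levels", call. = FALSE)
  out <- lapply(c("median_dark", "median_ratio"), function(metric) {
    x <- summaries[[metric]][g == levels(g)[1]]
    y <- summaries[[metric]][g == levels(g)[2]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L)
      stop("each group needs at least 2 slides", call. = FALSE)
    if (stats::sd(c(x, y)) == 0) {
      data.frame(metric = metric, t = 0, p.value = 1, mean_1 = mean(x),
                 mean_2 = mean(y), n_1 = length(x), n_2 = length(y))
    } else {
      tt <- stats::t.test(x, y)
      data.frame(metric = metric, t = unname(tt$statistic), p.value = tt$p.value,
                 mean_1 = mean(x), mean_2 = mean(y),
                 n_1 = length(x), n_2 = length(y))
    }
  })
  do.call(rbind, out)
}

#' Two-dimensional kernel density estimate of slide stain summaries
#'
#' Gaussian product-kernel density on a shared grid, one surface per group,
#' with per-axis bandwidths from the normal reference rule, plus contour
#' polylines. Thin wrapper around `MASS::kde2d`.
#'
#' @param x,y Coordinates (e.g. median dark count and median ratio per slide).
#' @param group Optional grouping; one surface per level.
#' @param n Grid resolution per axis.
#' @param nlevels Number of contour levels.
#' @return List with `grid` (shared x/y grid vectors) and per-group entries
#'   each holding `z` (density matrix) and `contours`
#'   (`grDevices::contourLines` output).
#' @export
stain_kde2d <- function(x, y, group = NULL, n = 64, nlevels = 6) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 points", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (zero-variance) axis", call. = FALSE)
  pad <- function(v) {
    r <- range(v); span <- diff(r)
    c(r[1] - 0.5 * span - 1e-9, r[2] + 0.5 * span + 1e-9)
  }
  lims <- c(pad(x), pad(y))
  groups <- if (is.null(group)) factor(rep("all", length(x))) else factor(group[ok])
  surfaces <- lapply(levels(groups), function(gl) {
    xi <- x[groups == gl]; yi <- y[groups == gl]
    if (length(xi) < 5L) stop("need at least 5 points per group", call. = FALSE)
    kd <- MASS::kde2d(xi, yi, n = n, lims = lims)
    list(z = kd$z,
         contours = grDevices::contourLines(kd$x, kd$y, kd$z, nlevels = nlevels))
  })
  names(surfaces) <- levels(groups)
  kd0 <- MASS::kde2d(x, y, n = n, lims = lims)
  c(list(grid = list(x = kd0$x, y = kd0$y)), surfaces)
}

#' Write a KDE surface as gridded CSV and its contours as GeoJSON
#'
#' @param kd Result of [stain_kde2d()].
#' @param dir Output directory; one `<group>_density.csv` (columns `x`, `y`,
#'   `density`) and one `<group>_contours.geojson` per group.
#' @return `dir`, invisibly.
#' @export
write_kde2d <- function(kd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- setdiff(names(kd), "grid")
  for (gl in groups) {
    z <- kd[[gl]]$z
    grid_df <- data.frame(x = rep(kd$grid$x, times = length(kd$grid$y)),
                          y = rep(kd$grid$y, each = length(kd$grid$x)),
                          density = as.vector(z))
    utils::write.csv(grid_df, file.path(dir, paste0(gl, "_density.csv")),
                     row.names = FALSE)
    feats <- lapply(kd[[gl]]$contours, function(cl) {
      list(type = "Feature",
           properties = list(level = cl$level),
           geometry = list(type = "LineString",
                           coordinates = mapply(c, cl$x, cl$y,
                                                SIMPLIFY = FALSE)))
    })
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         file.path(dir, paste0(gl, "_contours.geojson")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
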
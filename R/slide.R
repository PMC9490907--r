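#' Generate a synthetic LFB-like slide image for one donor
#'
#' Renders a square RGB raster emulating a Luxol-fast-blue / hematoxylin-eosin
#' stained brain section: an elliptical tissue blob with a pink grey-matter
#' rim (plus dark violet nuclei) around a pale white-matter core filled with
#' short blue fibre strokes. Fibre stroke intensity is drawn uniformly on
#' [60, 210]; strokes darker than intensity 120 are the "dark blue" myelin
#' signal. For donors whose `true_state` is `"CI"`, dark strokes inside the
#' affected white-matter patch (a `patchiness` fraction of WM) are thinned
#' with probability `effect_size`, so the planted dark-blue pixel density is
#' `base_density * (1 - effect_size)` there. Finally the whole image is
#' multiplied by a per-slide gain `~ Normal(1, stain_gain_sd)` and clipped to
#' [0, 255], emulating systemic staining variation across slides.
#'
#' @param donor One row of the cohort from [generate_cohort()].
#' @param config The [sim_config()] used to generate the cohort.
#' @return An object of class `synthetic_slide`: a list with `image`
#'   (`px x px x 3` array, 0-255), `region_mask` (`px x px` integer matrix,
#'   0 = background, 1 = grey matter, 2 = white matter), `true_tile_density`
#'   (matrix of ground-truth dark-blue pixel fractions per 256 px tile,
#'   computed before the gain is applied), and `donor_id`.
#' @examples
#' cfg <- sim_config(n_donors = 2, slide_px = 512)
#' cohort <- generate_cohort(cfg)
#' sl <- generate_slide(cohort[1, ], cfg)
#' dim(sl$image)
#' @export
generate_slide <- function(donor, config) {
  stopifnot(inherits(config, "sim_config"), nrow(donor) == 1L)
  px <- config$slide_px
  if (px < 512) stop("slide too small to contain both tissue compartments", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(slide_seed(donor$donor_id, config$seed))

  mask <- make_region_mask(px, config$wm_fraction, config$n_pieces)
  gm <- mask == 1L
  wm <- mask == 2L
  if (!any(wm) || !any(gm))
    stop("slide too small to contain both tissue compartments", call. = FALSE)

  # base colours with light texture noise
  r <- matrix(248, px, px); g <- matrix(248, px, px); b <- matrix(248, px, px)
  ngm <- sum(gm); nwm <- sum(wm)
  r[gm] <- 232 + stats::rnorm(ngm, 0, 3)
  g[gm] <- 172 + stats::rnorm(ngm, 0, 3)
  b[gm] <- 182 + stats::rnorm(ngm, 0, 3)
  r[wm] <- 205 + stats::rnorm(nwm, 0, 2)
  g[wm] <- 205 + stats::rnorm(nwm, 0, 2)
  b[wm] <- 228 + stats::rnorm(nwm, 0, 2)

  affected <- affected_patch(wm, config$patchiness, px)

  # fibre strokes: intensity record for ground truth
  fib <- draw_fibres(wm, affected,
                     is_ci = identical(donor$true_state, "CI"),
                     config = config, px = px)
  if (length(fib$idx)) {
    r[fib$idx] <- fib$rgb[, 1]
    g[fib$idx] <- fib$rgb[, 2]
    b[fib$idx] <- fib$rgb[, 3]
  }
  fibre_i <- matrix(NA_real_, px, px)
  fibre_i[fib$idx] <- fib$intensity

  # hematoxylin-like nuclei, denser in grey matter; they overwrite fibres
  nuc <- draw_nuclei(gm, wm, px)
  if (length(nuc$idx)) {
    r[nuc$idx] <- nuc$rgb[, 1]
    g[nuc$idx] <- nuc$rgb[, 2]
    b[nuc$idx] <- nuc$rgb[, 3]
    fibre_i[nuc$idx] <- NA_real_
  }

  dark <- !is.na(fibre_i) & fibre_i < 120
  tdens <- tile_block_mean(dark, 256L)

  gain <- stats::rnorm(1, 1, config$stain_gain_sd)
  clamp <- function(m) pmin(pmax(m * gain, 0), 255)
  image <- array(c(clamp(r), clamp(g), clamp(b)), dim = c(px, px, 3))

  structure(list(image = image, region_mask = mask,
                 true_tile_density = tdens, donor_id = donor$donor_id,
                 gain = gain),
            class = "synthetic_slide")
}

# deterministic per-slide seed below 2^31
slide_seed <- function(donor_id, seed) {
  idx <- suppressWarnings(as.integer(gsub("\\D", "", donor_id)))
  if (is.na(idx)) idx <- sum(utf8ToInt(donor_id))
  as.integer((abs(seed) %% 65536L) * 31627L + idx * 7919L + 17L)
}

# elliptical tissue blob(s) with a concentric white-matter core whose area is
# wm_fraction of the tissue
make_region_mask <- function(px, wm_fraction, n_pieces) {
  xs <- matrix(rep(seq_len(px), each = px), px, px)   # column index (x)
  ys <- matrix(rep(seq_len(px), times = px), px, px)  # row index (y)
  mask <- matrix(0L, px, px)
  theta <- stats::runif(1, 0, pi)
  centres <- if (n_pieces == 1L) {
    list(c(0.5, 0.5, 0.42, 0.34))
  } else {
    list(c(0.28, 0.5, 0.20, 0.30), c(0.74, 0.5, 0.20, 0.30))
  }
  for (cc in centres) {
    cx <- cc[1] * px; cy <- cc[2] * px; a <- cc[3] * px; b <- cc[4] * px
    xr <- (xs - cx) * cos(theta) + (ys - cy) * sin(theta)
    yr <- -(xs - cx) * sin(theta) + (ys - cy) * cos(theta)
    d2 <- (xr / a)^2 + (yr / b)^2
    sc <- wm_fraction  # inner ellipse area scales linearly with axis^2 factor
    mask[d2 <= 1 & mask == 0L] <- 1L
    mask[d2 <= sc] <- 2L
  }
  mask
}

# scattered discs covering ~patchiness of the white matter
affected_patch <- function(wm, patchiness, px) {
  if (patchiness >= 1) return(wm)
  affected <- matrix(FALSE, px, px)
  if (patchiness <= 0) return(affected)
  target <- patchiness * sum(wm)
  wm_idx <- which(wm)
  xs <- ((wm_idx - 1L) %/% px) + 1L
  ys <- ((wm_idx - 1L) %% px) + 1L
  rad <- px / 12
  xg <- matrix(rep(seq_len(px), each = px), px, px)
  yg <- matrix(rep(seq_len(px), times = px), px, px)
  for (iter in seq_len(200)) {
    if (sum(affected) >= target) break
    k <- sample.int(length(wm_idx), 1L)
    disc <- (xg - xs[k])^2 + (yg - ys[k])^2 <= rad^2
    affected <- affected | (disc & wm)
  }
  affected
}

# short randomly oriented blue strokes; returns linear pixel indices, the
# stroke intensity per pixel, and RGB colours
draw_fibres <- function(wm, affected, is_ci, config, px) {
  frac_dark <- (120 - 60) / (210 - 60)  # share of strokes that are dark
  n_px_target <- sum(wm) * config$base_density / frac_dark
  mean_pts <- 10 / 0.6
  n_strokes <- max(1L, round(n_px_target / mean_pts))
  wm_idx <- which(wm)
  ctr <- wm_idx[sample.int(length(wm_idx), n_strokes, replace = TRUE)]
  cx <- ((ctr - 1L) %/% px) + 1L
  cy <- ((ctr - 1L) %% px) + 1L
  len <- stats::runif(n_strokes, 6, 14)
  phi <- stats::runif(n_strokes, 0, pi)
  ii <- stats::runif(n_strokes, 60, 210)
  # thin dark strokes inside the affected patch for truly impaired donors
  keep <- rep(TRUE, n_strokes)
  if (is_ci && config$effect_size > 0) {
    dark_stroke <- ii < 120
    in_patch <- affected[ctr]
    keep <- !(dark_stroke & in_patch & stats::runif(n_strokes) < config$effect_size)
  }
  hue <- 240 - 35 * pmax(0, ii - 150) / 60 + stats::runif(n_strokes, -4, 4)
  # per-stroke saturation inside the RGB gamut at this hue/intensity
  m1 <- apply(hsi_to_rgb(hue, 1, ii), 1L, max)
  smax <- pmin(0.95 * (255 - ii) / pmax(m1 - ii, 1e-9), 0.5)
  sat <- stats::runif(n_strokes, 0.18, pmax(smax, 0.181))
  rgb_stroke <- hsi_to_rgb(hue, sat, ii)

  sel <- which(keep)
  if (!length(sel)) return(list(idx = integer(0)))
  npts <- pmax(2L, as.integer(ceiling(len[sel] / 0.6)) + 1L)
  sid <- rep(sel, npts)
  tt <- (sequence(npts) - 1L) * 0.6 - rep(len[sel], npts) / 2
  xpt <- as.integer(round(cx[sid] + tt * cos(phi[sid])))
  ypt <- as.integer(round(cy[sid] + tt * sin(phi[sid])))
  ok <- xpt >= 1L & xpt <= px & ypt >= 1L & ypt <= px
  xpt <- xpt[ok]; ypt <- ypt[ok]; sid <- sid[ok]
  lin <- (xpt - 1L) * px + ypt
  ok2 <- wm[lin]
  lin <- lin[ok2]; sid <- sid[ok2]
  # later strokes overwrite earlier ones
  last <- !duplicated(lin, fromLast = TRUE)
  lin <- lin[last]; sid <- sid[last]
  list(idx = lin, intensity = ii[sid],
       rgb = rgb_stroke[sid, , drop = FALSE])
}

draw_nuclei <- function(gm, wm, px) {
  gm_idx <- which(gm); wm_idx <- which(wm)
  n_gm <- stats::rpois(1, 0.004 * length(gm_idx))
  n_wm <- stats::rpois(1, 0.0012 * length(wm_idx))
  ctr <- c(if (n_gm > 0) gm_idx[sample.int(length(gm_idx), n_gm, replace = TRUE)],
           if (n_wm > 0) wm_idx[sample.int(length(wm_idx), n_wm, replace = TRUE)])
  if (!length(ctr)) return(list(idx = integer(0)))
  cx <- ((ctr - 1L) %/% px) + 1L
  cy <- ((ctr - 1L) %% px) + 1L
  # 3x3 blocks minus corners: a small round-ish nucleus
  offs <- cbind(dx = c(0, 1, -1, 0, 0, 1, 1, -1, -1),
                dy = c(0, 0, 0, 1, -1, 1, -1, 1, -1))
  use <- c(rep(TRUE, 5), rep(TRUE, 4))
  nid <- rep(seq_along(ctr), each = sum(use))
  xpt <- cx[nid] + rep(offs[use, "dx"], times = length(ctr))
  ypt <- cy[nid] + rep(offs[use, "dy"], times = length(ctr))
  ok <- xpt >= 1L & xpt <= px & ypt >= 1L & ypt <= px
  lin <- (xpt[ok] - 1L) * px + ypt[ok]
  lin <- unique(lin)
  n <- length(lin)
  list(idx = lin,
       rgb = cbind(110 + stats::rnorm(n, 0, 3),
                   60 + stats::rnorm(n, 0, 3),
                   125 + stats::rnorm(n, 0, 3)))
}

# mean of a logical matrix over a grid of size x size blocks anchored at the
# origin; partial edge blocks are dropped (matching the tiling convention)
tile_block_mean <- function(m, size) {
  nr <- nrow(m) %/% size
  nc <- ncol(m) %/% size
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1L) * size + 1L):(i * size)
    sub <- m[rows, seq_len(nc * size), drop = FALSE]
    cs <- colSums(sub)
    out[i, ] <- tapply(cs, rep(seq_len(nc), each = size), sum) / (size * size)
  }
  out
}

#' Write a slide image or region mask as PNG
#'
#' Images are written as 8-bit RGB; region masks as single-channel PNG with
#' grey levels equal to the region codes (0 = background, 1 = grey matter,
#' 2 = white matter).
#'
#' @param slide A `synthetic_slide` (or an `H x W x 3` array, 0-255).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slide_png <- function(slide, path) {
  img <- if (inherits(slide, "synthetic_slide")) slide$image else slide
  png::writePNG(round(img) / 255, path)
  invisible(path)
}

#' @rdname write_slide_png
#' @export
write_mask_png <- function(slide, path) {
  m <- if (inherits(slide, "synthetic_slide")) slide$region_mask else slide
  png::writePNG(m / 255, path)
  invisible(path)
}

#' Read a slide PNG back into a 0-255 RGB array
#' @param path PNG path.
#' @return For images, an `H x W x 3` array of 0-255 values; for masks, an
#'   integer matrix of region codes.
#' @export
read_slide_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1:3, drop = FALSE]
  img * 255
}

#' @rdname read_slide_png
#' @export
read_mask_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write ground-truth tile densities to CSV
#'
#' One row per (donor, tile); tiles are indexed 0-based, row-major, on the
#' 256 px grid anchored at the image origin.
#'
#' @param slides A list of `synthetic_slide` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_true_density_csv <- function(slides, path) {
  rows <- lapply(slides, function(sl) {
    d <- sl$true_tile_density
    data.frame(donor_id = sl$donor_id,
               tile_row = rep(seq_len(nrow(d)) - 1L, times = ncol(d)),
               tile_col = rep(seq_len(ncol(d)) - 1L, each = nrow(d)),
               true_density = as.vector(d))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
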
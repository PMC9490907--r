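#' z-transform attention scores within a slide
#'
#' Centers and scales with the sample standard deviation (denominator K-1).
#' Degenerate inputs (a single tile, or constant scores) map to all zeros.
#'
#' @param scores Numeric attention scores for one slide.
#' @return z-scores with mean 0 and sample sd 1 (or all zeros).
#' @examples
#' z_transform(c(1, 2, 3))  # -1 0 1
#' @export
z_transform <- function(scores) {
  if (length(scores) < 2L) return(rep(0, length(scores)))
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) return(rep(0, length(scores)))
  (scores - mean(scores)) / s
}

#' Re-scope attention z-scores across a cohort
#'
#' By default attention z-scores are computed within each slide (matching
#' heatmaps normalised to the rest of the same slide). This helper recomputes
#' them over the pooled attention of all slides instead.
#'
#' @param maps List of [attention_map()]s.
#' @return The list with each map's `z` column replaced by cohort-scope
#'   z-scores.
#' @export
cohort_z_transform <- function(maps) {
  all_a <- unlist(lapply(maps, `[[`, "attention"))
  mu <- mean(all_a)
  s <- stats::sd(all_a)
  lapply(maps, function(mp) {
    mp$z <- if (is.finite(s) && s > 0) (mp$attention - mu) / s
            else rep(0, nrow(mp))
    mp
  })
}

#' Build an attention map for one slide
#'
#' Runs attention pooling and attaches raw and z-transformed attention to the
#' tile coordinates.
#'
#' @param bag A `feature_bag`.
#' @param model A `mil_model`.
#' @return An `attention_map`: data frame with the tile coordinates plus
#'   `attention` and `z`, and attribute `donor_id`.
#' @export
attention_map <- function(bag, model) {
  ap <- attention_pool(bag, model)
  out <- bag$coords
  out$attention <- ap$attention
  out$z <- z_transform(ap$attention)
  attr(out, "donor_id") <- bag$donor_id
  attr(out, "tile_size") <- attr(bag$coords, "tile_size")
  class(out) <- c("attention_map", "data.frame")
  out
}

#' Select the top-k attention tiles of a slide
#'
#' Tiles are ranked by descending raw attention; ties are broken by ascending
#' row-major tile index so the selection is a deterministic function of the
#' map. Because ranking is invariant to monotone transforms, raw and
#' z-transformed attention give the same selection.
#'
#' @param map An [attention_map()] (any data frame with `row`, `col`,
#'   `attention`).
#' @param k Number of tiles to select; if fewer tiles exist all are returned
#'   with a warning.
#' @return The selected rows, ordered by rank, with a `rank` column added.
#' @export
top_k_tiles <- function(map, k = 100) {
  stopifnot(k >= 1)
  if (nrow(map) < k) {
    warning("slide has only ", nrow(map), " tiles; returning all of them")
    k <- nrow(map)
  }
  idx <- order(-map$attention, map$row, map$col)[seq_len(k)]
  out <- map[idx, , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Summarise attention by tissue region across slides
#'
#' Assigns each tile to the region (grey or white matter) containing its
#' centre pixel, takes the per-slide median of the z-transformed attention in
#' each region, and compares white versus grey matter across slides with a
#' paired t-test. Slides lacking tiles in either region are excluded from the
#' paired test and counted.
#'
#' @param maps List of [attention_map()]s.
#' @param masks List of region masks (`0` background, `1` GM, `2` WM) aligned
#'   with the maps, in the same order.
#' @return List with `per_slide` (data frame: donor_id, gm_median, wm_median),
#'   `t` and `p.value` of the paired t-test (WM minus GM), and `n_excluded`.
#' @export
region_attention <- function(maps, masks) {
  stopifnot(length(maps) == length(masks))
  rows <- mapply(function(mp, msk) {
    ts <- attr(mp, "tile_size"); if (is.null(ts)) ts <- 256L
    cx <- mp$x0 + ts %/% 2L
    cy <- mp$y0 + ts %/% 2L
    reg <- msk[cbind(cy + 1L, cx + 1L)]
    data.frame(donor_id = attr(mp, "donor_id") %||% NA_character_,
               gm_median = stats::median(mp$z[reg == 1L]),
               wm_median = stats::median(mp$z[reg == 2L]))
  }, maps, masks, SIMPLIFY = FALSE)
  per_slide <- do.call(rbind, rows)
  ok <- stats::complete.cases(per_slide[, c("gm_median", "wm_median")])
  n_excluded <- sum(!ok)
  if (!any(ok)) stop("no slide contains tiles in both regions", call. = FALSE)
  d <- per_slide$wm_median[ok] - per_slide$gm_median[ok]
  if (length(d) >= 2L && stats::sd(d) > 1e-10 * max(1, abs(mean(d)))) {
    tt <- stats::t.test(per_slide$wm_median[ok], per_slide$gm_median[ok],
                        paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    t_stat <- 0; p <- 1
  }
  list(per_slide = per_slide, t = t_stat, p.value = p, n_excluded = n_excluded)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render an attention heatmap overlay
#'
#' Min-max normalises the per-slide attention (a constant map renders at the
#' middle of the scale) and alpha-blends a blue-to-red colour ramp over the
#' slide at each tile's footprint.
#'
#' @param map An [attention_map()].
#' @param image The slide RGB array (0-255).
#' @param alpha Overlay opacity in `[0, 1]`.
#' @return An array of the same dimensions as `image`, with attribute
#'   `colorbar` (data frame mapping normalised score to RGB) for legends.
#' @export
render_heatmap <- function(map, image, alpha = 0.5) {
  ts <- attr(map, "tile_size"); if (is.null(ts)) ts <- 256L
  h <- dim(image)[1]; w <- dim(image)[2]
  if (any(map$y0 + ts > h) || any(map$x0 + ts > w))
    stop("tile coordinates fall outside the image", call. = FALSE)
  rng <- range(map$attention)
  norm <- if (rng[2] > rng[1]) (map$attention - rng[1]) / (rng[2] - rng[1])
          else rep(0.5, nrow(map))
  ramp <- grDevices::colorRamp(c("blue", "white", "red"))
  cols <- ramp(norm)  # n x 3, 0-255
  out <- image
  for (k in seq_len(nrow(map))) {
    ys <- (map$y0[k] + 1L):(map$y0[k] + ts)
    xs <- (map$x0[k] + 1L):(map$x0[k] + ts)
    for (ch in 1:3) {
      out[ys, xs, ch] <- (1 - alpha) * out[ys, xs, ch] + alpha * cols[k, ch]
    }
  }
  attr(out, "colorbar") <- data.frame(value = seq(0, 1, length.out = 11),
                                      ramp(seq(0, 1, length.out = 11)))
  out
}
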
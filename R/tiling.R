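#' Segment tissue from background
#'
#' Foreground detection by saturation thresholding in HSI space after 3x3
#' median smoothing, the standard automated approach for slide scans: tissue
#' pixels are chromatic (stained), background pixels are near-achromatic
#' white. All disconnected tissue pieces are retained.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param saturation_min Saturation threshold above which a pixel is tissue.
#' @param smooth Apply the 3x3 median filter before thresholding.
#' @return A logical `H x W` matrix (`TRUE` = tissue). If no pixel passes the
#'   threshold the returned mask carries `attr(, "empty") = TRUE` so callers
#'   can skip the slide with a log entry.
#' @export
segment_tissue <- function(image, saturation_min = 0.02, smooth = TRUE) {
  if (!is.array(image) || length(dim(image)) != 3L || any(dim(image)[1:2] == 0L))
    stop("`image` must be a non-empty H x W x 3 array", call. = FALSE)
  s <- rgb_to_hsi(image)$s
  if (smooth && nrow(s) >= 3L && ncol(s) >= 3L) s <- median_filter3(s)
  mask <- s > saturation_min
  if (!any(mask)) attr(mask, "empty") <- TRUE
  mask
}

# 3x3 median filter via a pmin/pmax selection network on shifted copies
# (edges replicated); O(19) vectorised comparisons per image
median_filter3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- m[c(1, seq_len(nr), nr), c(1, seq_len(nc), nc)]
  p <- vector("list", 9L)
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    p[[k]] <- pad[dy + seq_len(nr), dx + seq_len(nc)]
  }
  sw <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]])
    p[[j]] <<- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo
  }
  # median-of-9 sorting network (indices 1-based)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 2); sw(4, 5); sw(7, 8)
  sw(2, 3); sw(5, 6); sw(8, 9); sw(1, 4); sw(6, 9); sw(5, 8)
  sw(4, 7); sw(2, 5); sw(3, 6); sw(5, 8); sw(5, 3); sw(7, 5); sw(5, 3)
  p[[5]]
}

#' Tile an image into a non-overlapping grid
#'
#' The grid is anchored at the image origin with no offset search; partial
#' tiles at the right/bottom edges are dropped. A tile is kept when the
#' fraction of its pixels inside the tissue mask is at least `min_tissue`.
#'
#' @param image `H x W x 3` RGB array.
#' @param mask Logical tissue mask aligned with `image` (from
#'   [segment_tissue()]).
#' @param tile_size Tile side in pixels.
#' @param min_tissue Minimum tissue fraction for a tile to be kept.
#' @return A data frame of kept tiles in row-major order with 0-based `row`,
#'   `col`, pixel offsets `x0`, `y0` (half-open intervals
#'   `[x0, x0 + tile_size)`), and `tissue_fraction`. The tile size is attached
#'   as `attr(, "tile_size")`.
#' @examples
#' img <- array(120, dim = c(512, 512, 3))
#' nrow(tile(img, matrix(TRUE, 512, 512)))  # 4 tiles
#' @export
tile <- function(image, mask, tile_size = 256, min_tissue = 0.5) {
  h <- dim(image)[1]; w <- dim(image)[2]
  stopifnot(nrow(mask) == h, ncol(mask) == w)
  if (tile_size > h || tile_size > w)
    stop("tile_size larger than the image", call. = FALSE)
  nr <- h %/% tile_size; nc <- w %/% tile_size
  frac <- tile_block_mean(mask, as.integer(tile_size))
  grid <- data.frame(
    row = rep(seq_len(nr) - 1L, each = nc),
    col = rep(seq_len(nc) - 1L, times = nr)
  )
  grid$x0 <- grid$col * tile_size
  grid$y0 <- grid$row * tile_size
  grid$tissue_fraction <- frac[cbind(grid$row + 1L, grid$col + 1L)]
  keep <- grid$tissue_fraction >= min_tissue
  out <- grid[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tile_size") <- as.integer(tile_size)
  out
}

#' Hand-crafted deterministic tile feature extractor
#'
#' Maps a 256x256 RGB tile to a fixed-length feature vector: a 12-bin HSI hue
#' histogram gated at saturation >= 0.15 (bin mass as a fraction of all tile
#' pixels), per-channel mean and standard deviation, an 8-bin intensity
#' histogram, and the mean and standard deviation of the intensity gradient
#' magnitude, zero-padded to `dim`. CPU-cheap and fully deterministic; any
#' object with fields `id`, `dim` and `fn(tile) -> numeric(dim)` (for example
#' a learned CNN embedding) can be plugged in instead.
#'
#' @param dim Output dimension (zero-padded); must be >= 28.
#' @param saturation_min Saturation gate for the hue histogram.
#' @return A `feature_extractor` object.
#' @export
default_extractor <- function(dim = 1024, saturation_min = 0.15) {
  if (dim < 28) stop("`dim` must be at least 28", call. = FALSE)
  fn <- function(tile) {
    npx <- prod(dim(tile)[1:2])
    hsi <- rgb_to_hsi(tile)
    gate <- !is.na(hsi$h) & hsi$s >= saturation_min
    hue_hist <- tabulate(findInterval(hsi$h[gate], seq(0, 360, by = 30),
                                      rightmost.closed = FALSE), nbins = 12) / npx
    ch_stats <- as.vector(vapply(1:3, function(k) {
      v <- tile[, , k]
      c(mean(v), stats::sd(v))
    }, numeric(2)))
    int_hist <- tabulate(findInterval(hsi$i, seq(0, 256, by = 32)),
                         nbins = 8) / npx
    gx <- hsi$i[, -1, drop = FALSE] - hsi$i[, -ncol(hsi$i), drop = FALSE]
    gy <- hsi$i[-1, , drop = FALSE] - hsi$i[-nrow(hsi$i), , drop = FALSE]
    gm <- sqrt(gx[-nrow(gx), , drop = FALSE]^2 + gy[, -ncol(gy), drop = FALSE]^2)
    feat <- c(hue_hist, ch_stats, int_hist, mean(gm), stats::sd(gm))
    c(feat, numeric(dim - length(feat)))
  }
  structure(list(id = "hsi-moments-v1", dim = as.integer(dim), fn = fn),
            class = "feature_extractor")
}

#' Extract per-tile features into a feature bag
#'
#' Applies the extractor to every kept tile of the grid, producing the
#' `K x D` instance matrix consumed by the attention-MIL model.
#'
#' @param image `H x W x 3` RGB array (0-255).
#' @param grid Tile grid from [tile()].
#' @param extractor A `feature_extractor` (default [default_extractor()]).
#' @param donor_id Identifier stored in the bag.
#' @return A `feature_bag`: list with `features` (`K x D`), `coords` (the grid
#'   data frame), `donor_id` and `extractor_id`.
#' @export
extract_features <- function(image, grid, extractor = default_extractor(),
                             donor_id = "slide") {
  stopifnot(inherits(extractor, "feature_extractor"))
  ts <- attr(grid, "tile_size")
  if (is.null(ts)) ts <- 256L
  if (nrow(grid) < 1L) stop("grid has no kept tiles", call. = FALSE)
  feats <- matrix(0, nrow(grid), extractor$dim)
  for (k in seq_len(nrow(grid))) {
    tl <- image[(grid$y0[k] + 1L):(grid$y0[k] + ts),
                (grid$x0[k] + 1L):(grid$x0[k] + ts), , drop = FALSE]
    v <- extractor$fn(tl)
    if (length(v) != extractor$dim)
      stop("extractor returned ", length(v), " values; declared dim is ",
           extractor$dim, call. = FALSE)
    feats[k, ] <- v
  }
  if (any(!is.finite(feats))) stop("non-finite feature values", call. = FALSE)
  structure(list(features = feats, coords = grid, donor_id = donor_id,
                 extractor_id = extractor$id),
            class = "feature_bag")
}

#' Persist / load feature bags as plain text
#'
#' Each bag is written as `<donor_id>_features.csv` (K x D matrix) and
#' `<donor_id>_coords.csv`, with a JSON index recording donor ids and the
#' extractor id.
#'
#' @param bags List of `feature_bag` objects.
#' @param dir Directory.
#' @return `write_feature_bags()` returns `dir` invisibly; `read_feature_bags()`
#'   returns the list of bags.
#' @export
write_feature_bags <- function(bags, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in bags) {
    utils::write.csv(as.data.frame(b$features),
                     file.path(dir, paste0(b$donor_id, "_features.csv")),
                     row.names = FALSE)
    utils::write.csv(b$coords,
                     file.path(dir, paste0(b$donor_id, "_coords.csv")),
                     row.names = FALSE)
  }
  idx <- list(donor_ids = vapply(bags, `[[`, "", "donor_id"),
              extractor_id = bags[[1]]$extractor_id)
  jsonlite::write_json(idx, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_feature_bags
#' @export
read_feature_bags <- function(dir) {
  idx <- jsonlite::read_json(file.path(dir, "index.json"), simplifyVector = TRUE)
  lapply(idx$donor_ids, function(id) {
    feats <- as.matrix(utils::read.csv(file.path(dir, paste0(id, "_features.csv"))))
    dimnames(feats) <- NULL
    coords <- utils::read.csv(file.path(dir, paste0(id, "_coords.csv")))
    structure(list(features = feats, coords = coords, donor_id = id,
                   extractor_id = idx$extractor_id),
              class = "feature_bag")
  })
}
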
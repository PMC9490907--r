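#' Convert RGB to HSI (hue, saturation, intensity) colour space
#'
#' Uses the classic arccos formulation on 8-bit RGB. Intensity is the channel
#' mean `(R+G+B)/3`, saturation is `1 - 3*min(R,G,B)/(R+G+B)` (0 for pure
#' black), and hue is the arccos angle, reflected (`360 - theta`) when
#' `B > G`. Hue is undefined (`NA`) for achromatic pixels (`S = 0`).
#'
#' @param x Either a numeric vector of length 3 (one RGB pixel, 0-255) or an
#'   `H x W x 3` array of 0-255 values.
#' @return A list with components `h` (degrees in `[0, 360)`, `NA` where
#'   undefined), `s` in `[0, 1]` and `i` in `[0, 255]`, each shaped like the
#'   input channels.
#' @examples
#' rgb_to_hsi(c(0, 0, 255))   # pure blue: H = 240, S = 1, I = 85
#' rgb_to_hsi(c(100, 100, 100))  # grey: S = 0, H undefined
#' @export
rgb_to_hsi <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L) {
    r <- x[, , 1]; g <- x[, , 2]; b <- x[, , 3]
  } else if (is.numeric(x) && length(x) == 3L) {
    x <- unname(x)
    r <- x[1]; g <- x[2]; b <- x[3]
  } else {
    stop("`x` must be an RGB triplet or an H x W x 3 array", call. = FALSE)
  }
  tot <- r + g + b
  i <- tot / 3
  s <- ifelse(tot > 0, 1 - 3 * pmin(r, g, b) / tot, 0)
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  ratio <- ifelse(den > 0, pmin(pmax(num / den, -1), 1), NA_real_)
  theta <- acos(ratio) * 180 / pi
  h <- ifelse(b > g, 360 - theta, theta)
  h[s == 0 | is.na(ratio)] <- NA_real_
  h[!is.na(h) & h >= 360] <- 0
  list(h = h, s = s, i = i)
}

#' Convert HSI coordinates to RGB
#'
#' Inverse of the arccos HSI transform, used by the slide generator to place
#' stain colours at exact hue/saturation/intensity coordinates. Values are
#' returned on the 0-255 scale, unclipped (the caller is responsible for
#' staying inside the gamut).
#'
#' @param h Hue in degrees `[0, 360)`.
#' @param s Saturation in `[0, 1]`.
#' @param i Intensity in `[0, 255]`.
#' @return A matrix with columns `r`, `g`, `b`.
#' @keywords internal
hsi_to_rgb <- function(h, s, i) {
  n <- max(length(h), length(s), length(i))
  h <- rep_len(h %% 360, n); s <- rep_len(s, n); i <- rep_len(i, n)
  r <- g <- b <- numeric(n)
  sector <- findInterval(h, c(0, 120, 240))  # 1, 2, 3
  hp <- h - c(0, 120, 240)[sector]
  rad <- pi / 180
  mid <- i * (1 + s * cos(hp * rad) / cos((60 - hp) * rad))
  lo <- i * (1 - s)
  hi <- 3 * i - mid - lo
  s1 <- sector == 1L; s2 <- sector == 2L; s3 <- sector == 3L
  r[s1] <- mid[s1]; g[s1] <- hi[s1]; b[s1] <- lo[s1]
  r[s2] <- lo[s2]; g[s2] <- mid[s2]; b[s2] <- hi[s2]
  r[s3] <- hi[s3]; g[s3] <- lo[s3]; b[s3] <- mid[s3]
  cbind(r = r, g = g, b = b)
}
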
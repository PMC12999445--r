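#' Stochastic training augmentation
#'
#' Applies, in order: horizontal flip, vertical flip, rotation within
#' +/- 20 degrees (nearest-neighbour, background fill), then brightness,
#' contrast and hue scaling each within +/- 10%. The lesion mask is
#' transformed with the same geometry as the pixels and the label is never
#' changed. Each component can be pinned to a fixed value for testing; `NULL`
#' draws it from the seeded RNG.
#'
#' @param image a `lesion_image`.
#' @param seed integer seed.
#' @param flip_h,flip_v logical, or `NULL` to draw with probability 0.5.
#' @param rotation rotation angle in degrees, or `NULL` to draw from the
#'   range `c(-rotation_range, rotation_range)`.
#' @param brightness,contrast,hue signed fractional adjustment (e.g. `0.1`
#'   for +10%), or `NULL` to draw from `+/- jitter_range`.
#' @param rotation_range,jitter_range draw ranges (degrees / fraction).
#' @return The augmented `lesion_image` (pixels clipped to \[0,1\]).
#' @export
augment <- function(image, seed = 1L, flip_h = NULL, flip_v = NULL,
                    rotation = NULL, brightness = NULL, contrast = NULL,
                    hue = NULL, rotation_range = 20, jitter_range = 0.1) {
  stopifnot(inherits(image, "lesion_image"))
  draws <- with_seed(derive_seed(seed, 211L), list(
    flip_h = flip_h %||% (stats::runif(1) < 0.5),
    flip_v = flip_v %||% (stats::runif(1) < 0.5),
    rotation = rotation %||% stats::runif(1, -rotation_range, rotation_range),
    brightness = brightness %||% stats::runif(1, -jitter_range, jitter_range),
    contrast = contrast %||% stats::runif(1, -jitter_range, jitter_range),
    hue = hue %||% stats::runif(1, -jitter_range, jitter_range)
  ))
  px <- image$pixels
  mask <- image$lesion_mask
  if (draws$flip_h) {
    px <- px[, rev(seq_len(ncol(mask))), , drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask)))]
  }
  if (draws$flip_v) {
    px <- px[rev(seq_len(nrow(mask))), , , drop = FALSE]
    mask <- mask[rev(seq_len(nrow(mask))), ]
  }
  if (abs(draws$rotation) > 1e-12) {
    rot <- rotate_nn(px, mask, draws$rotation)
    px <- rot$pixels
    mask <- rot$mask
  }
  if (abs(draws$brightness) > 0) px <- px * (1 + draws$brightness)
  if (abs(draws$contrast) > 0) {
    m <- mean(px)
    px <- m + (px - m) * (1 + draws$contrast)
  }
  if (abs(draws$hue) > 0) px <- shift_hue(px, draws$hue)
  out <- image
  out$pixels <- clamp01(px)
  out$lesion_mask <- mask
  out
}

# nearest-neighbour rotation about the image centre; source pixels falling
# outside the canvas are filled with the median border colour
rotate_nn <- function(px, mask, degrees) {
  n <- nrow(mask)
  ang <- degrees * pi / 180
  ctr <- (n + 1) / 2
  cols <- matrix(rep(seq_len(n), each = n), n) - ctr
  rows <- matrix(rep(seq_len(n), times = n), n) - ctr
  # inverse map: source coordinates for each destination pixel
  sc <- round(cos(ang) * cols - sin(ang) * rows + ctr)
  sr <- round(sin(ang) * cols + cos(ang) * rows + ctr)
  ok <- sr >= 1 & sr <= n & sc >= 1 & sc <= n
  src <- cbind(as.vector(pmin(pmax(sr, 1), n)),
               as.vector(pmin(pmax(sc, 1), n)))
  border <- rbind(px[1, , ], px[n, , ], px[, 1, ], px[, n, ])
  fill <- apply(border, 2, stats::median)
  out <- array(0, dim(px))
  for (ch in 1:3) {
    plane <- px[, , ch][src]
    plane[!ok] <- fill[ch]
    out[, , ch] <- matrix(plane, n)
  }
  m <- mask[src]
  m[!ok] <- FALSE
  list(pixels = out, mask = matrix(m, n))
}

# multiplicative hue scaling in HSV space (hue wraps on [0,1))
shift_hue <- function(px, frac) {
  px <- clamp01(px)  # brightness/contrast may have left the unit range
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  hsv[1, ] <- (hsv[1, ] * (1 + frac)) %% 1
  out <- grDevices::hsv(hsv[1, ], hsv[2, ], hsv[3, ])
  cr <- grDevices::col2rgb(out) / 255
  array(c(cr[1, ], cr[2, ], cr[3, ]), d)
}
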
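#' Synthetic dermoscopy-like lesion images
#'
#' The generator renders a pigmented blob on a skin-toned background on a
#' 224x224 canvas. The lesion boundary is an ellipse-like radial profile with
#' a first-harmonic asymmetry term and higher Fourier harmonics for border
#' irregularity; the interior is split into angular sectors carrying distinct
#' pigment colors. Malignant-class draws use strictly higher asymmetry,
#' border-irregularity and color-heterogeneity ranges than benign draws, so
#' the ABCD-style cue axes (asymmetry, border, color) separate the classes by
#' construction and the diagnosis task is learnable.
#'
#' @name synthetic_lesions
NULL

IMG_SIZE <- 224L

# Interpolation endpoint ranges for generator attributes. Classes map to a
# severity in [0,1]: class 1 (benign) -> 0, class K (malignant) -> 1.
#' Generator configuration
#'
#' @param K number of classes (>= 2). Class 1 is the most benign, class K the
#'   most malignant; intermediate classes interpolate the attribute ranges.
#' @param image_size canvas size in pixels (square).
#' @return A list of generator ranges used by [generate_lesion()].
#' @export
lesion_params <- function(K = 2L, image_size = IMG_SIZE) {
  stopifnot(K >= 2)
  list(
    K = as.integer(K),
    image_size = as.integer(image_size),
    radius = list(benign = c(26, 34), malignant = c(30, 40)),
    asymmetry = list(benign = c(0.0, 0.06), malignant = c(0.25, 0.45)),
    border = list(benign = c(0.01, 0.04), malignant = c(0.10, 0.20)),
    n_colors = list(benign = c(1L, 2L), malignant = c(3L, 5L)),
    darkness = list(benign = c(0.75, 0.95), malignant = c(0.45, 0.70)),
    center_jitter = 8,
    skin = c(0.87, 0.72, 0.63),
    skin_noise_sd = 0.012,
    lesion_noise_sd = 0.02
  )
}

lesion_palette <- function() {
  rbind(
    c(0.62, 0.44, 0.30),  # light brown
    c(0.50, 0.33, 0.20),  # brown
    c(0.38, 0.22, 0.12),  # dark brown
    c(0.24, 0.14, 0.09),  # black-brown
    c(0.55, 0.25, 0.22),  # red
    c(0.36, 0.38, 0.45)   # blue-gray
  )
}

lerp_range <- function(ranges, s) {
  (1 - s) * ranges$benign + s * ranges$malignant
}

#' Generate one synthetic lesion image
#'
#' Deterministic for fixed `(class_id, seed, params)`: the same inputs always
#' yield bit-identical pixel arrays.
#'
#' @param class_id integer class in `1..params$K`; higher ids draw higher
#'   asymmetry/irregularity/heterogeneity.
#' @param seed integer seed.
#' @param params generator configuration from [lesion_params()].
#' @return A `lesion_image`: list with `pixels` (HxWx3 in \[0,1\]), `label`,
#'   logical `lesion_mask`, `seed`, ground-truth `features` (asymmetry,
#'   border irregularity, color count, darkness) and the full generator
#'   parameter record `gen` needed to re-render the lesion (e.g. for
#'   pseudo-sequences).
#' @export
#' @examples
#' img <- generate_lesion(1, seed = 1)
#' dim(img$pixels)
#' img$features$asymmetry
generate_lesion <- function(class_id, seed = 1L, params = lesion_params()) {
  if (length(class_id) != 1 || is.na(class_id) ||
      class_id != as.integer(class_id) ||
      class_id < 1 || class_id > params$K) {
    stop_domain("class_id must be an integer in 1..", params$K)
  }
  class_id <- as.integer(class_id)
  sev <- (class_id - 1) / (params$K - 1)
  gen <- with_seed(derive_seed(seed, class_id), {
    rr <- lerp_range(params$radius, sev)
    ar <- lerp_range(params$asymmetry, sev)
    br <- lerp_range(params$border, sev)
    nr <- round(lerp_range(params$n_colors, sev))
    dr <- lerp_range(params$darkness, sev)
    n_colors <- if (nr[1] >= nr[2]) nr[1] else sample(nr[1]:nr[2], 1L)
    pool <- if (sev < 0.5) 1:3 else seq_len(nrow(lesion_palette()))
    harmonics <- 2:6
    amp_total <- stats::runif(1, br[1], br[2])
    w <- stats::runif(length(harmonics))
    list(
      image_size = params$image_size,
      center = params$image_size / 2 + stats::runif(2, -1, 1) * params$center_jitter,
      r0 = stats::runif(1, rr[1], rr[2]),
      asymmetry = stats::runif(1, ar[1], ar[2]),
      theta0 = stats::runif(1, 0, 2 * pi),
      harmonics = harmonics,
      amps = amp_total * w / sum(w),
      amp_total = amp_total,
      phases = stats::runif(length(harmonics), 0, 2 * pi),
      n_colors = n_colors,
      color_ids = sample(pool, n_colors),
      sector_offset = stats::runif(1, 0, 2 * pi),
      darkness = stats::runif(1, dr[1], dr[2]),
      aspect = stats::runif(1, 0.75, 1),
      skin = params$skin,
      skin_noise_sd = params$skin_noise_sd,
      lesion_noise_sd = params$lesion_noise_sd,
      noise_seed = sample.int(900000L, 1L)
    )
  })
  rend <- render_lesion(gen)
  new_lesion_image(rend$pixels, label = class_id, mask = rend$mask,
                   seed = as.integer(seed), gen = gen,
                   features = list(
                     asymmetry = gen$asymmetry,
                     border_irregularity = gen$amp_total,
                     n_colors = gen$n_colors,
                     darkness = gen$darkness
                   ))
}

new_lesion_image <- function(pixels, label, mask, seed = NA_integer_,
                             gen = NULL, features = NULL) {
  structure(
    list(pixels = pixels, label = as.integer(label), lesion_mask = mask,
         seed = seed, gen = gen, features = features),
    class = "lesion_image"
  )
}

#' @export
print.lesion_image <- function(x, ...) {
  cat(sprintf("<lesion_image> %dx%d, label %d, lesion area %d px\n",
              nrow(x$pixels), ncol(x$pixels), x$label, sum(x$lesion_mask)))
  invisible(x)
}

# Scale-independent polar fields for a generator record: the distance matrix
# and the unit radial boundary profile R1(theta). mask(scale) = r <= scale*R1.
polar_fields <- function(gen) {
  n <- gen$image_size
  xs <- matrix(rep(seq_len(n), each = n), n)   # column coordinate
  ys <- matrix(rep(seq_len(n), times = n), n)  # row coordinate
  dx <- xs - gen$center[1]
  dy <- (ys - gen$center[2]) / gen$aspect
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx)
  # one-sided angular lobe: a first-harmonic term alone is (to first order)
  # just a translation of the blob, which recentring would cancel; a local
  # protrusion produces genuine mirror asymmetry about the centroid axes
  dtheta <- ((theta - gen$theta0 + pi) %% (2 * pi)) - pi
  prof <- 1 + 1.6 * gen$asymmetry * exp(-(dtheta / 0.7)^2)
  for (i in seq_along(gen$harmonics)) {
    prof <- prof + gen$amps[i] * cos(gen$harmonics[i] * theta + gen$phases[i])
  }
  list(r = r, theta = theta, R1 = gen$r0 * prof)
}

mask_at_scale <- function(polar, scale) {
  polar$r <= scale * polar$R1
}

render_lesion <- function(gen, scale = 1, polar = NULL) {
  n <- gen$image_size
  if (is.null(polar)) polar <- polar_fields(gen)
  mask <- mask_at_scale(polar, scale)
  # noise fields are a function of noise_seed only, so every frame of a
  # pseudo-sequence shares the same background and texture
  noise <- with_seed(gen$noise_seed, {
    list(bg = matrix(stats::rnorm(n * n, sd = gen$skin_noise_sd), n),
         tex = matrix(stats::rnorm(n * n, sd = gen$lesion_noise_sd), n))
  })
  pal <- lesion_palette()
  sector <- (floor((polar$theta - gen$sector_offset) %% (2 * pi) /
                     (2 * pi / gen$n_colors)) %% gen$n_colors) + 1L
  col_id <- gen$color_ids[sector]
  # soft edge over ~1.5 px inside the boundary
  alpha <- clamp01((scale * polar$R1 - polar$r) / 1.5)
  radial <- 0.88 + 0.12 * clamp01(polar$r / pmax(scale * polar$R1, 1e-9))
  pixels <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    bg <- gen$skin[ch] + noise$bg
    lesion <- pal[cbind(col_id, ch)] * gen$darkness * radial + noise$tex
    pixels[, , ch] <- clamp01(bg * (1 - alpha) + lesion * alpha)
  }
  list(pixels = pixels, mask = mask)
}

# -- measured shape statistics ----------------------------------------------

#' Measured asymmetry of a lesion mask
#'
#' Reflects the mask about the vertical and horizontal axes through its
#' centroid and reports the larger normalized non-overlap
#' `|mask XOR mirror| / (2 |mask|)`, a standard ABCD-style asymmetry score.
#'
#' @param mask logical matrix.
#' @return Scalar in \[0,1\].
#' @export
asymmetry_score <- function(mask) {
  a <- sum(mask)
  if (a == 0) stop_domain("empty lesion mask")
  idx <- which(mask, arr.ind = TRUE)
  cr <- mean(idx[, 1])
  cc <- mean(idx[, 2])
  score_axis <- function(center, coord) {
    mirrored <- round(2 * center - idx[, coord])
    other <- idx
    other[, coord] <- mirrored
    keep <- other[, coord] >= 1 & other[, coord] <= dim(mask)[coord]
    inside <- rep(FALSE, nrow(idx))
    inside[keep] <- mask[other[keep, , drop = FALSE]]
    # XOR area = pixels whose mirror falls outside the mask, counted twice
    sum(!inside) / a
  }
  max(score_axis(cc, 2), score_axis(cr, 1))
}

#' Mask eccentricity from second moments
#' @param mask logical matrix.
#' @return Scalar in \[0,1\); 0 for a circle.
#' @export
mask_eccentricity <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 2) return(0)
  cv <- stats::cov(idx)
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# boundary pixel count (4-connectivity) and compactness-based irregularity
border_irregularity_score <- function(mask) {
  n <- nrow(mask)
  pad <- matrix(FALSE, n + 2, n + 2)
  pad[2:(n + 1), 2:(n + 1)] <- mask
  inner <- pad[2:(n + 1), 2:(n + 1)]
  nb <- pad[1:n, 2:(n + 1)] & pad[3:(n + 2), 2:(n + 1)] &
    pad[2:(n + 1), 1:n] & pad[2:(n + 1), 3:(n + 2)]
  per <- sum(inner & !nb)
  area <- sum(mask)
  max(0, per^2 / (4 * pi * area) / 1.05 - 1)
}

#' Mean lesion-interior intensity
#'
#' Mean of the RGB values over the lesion mask; the quantity the
#' pseudo-sequence darkening rates act on.
#'
#' @param pixels HxWx3 array.
#' @param mask logical HxW matrix.
#' @return Scalar in \[0,1\].
#' @export
lesion_interior_mean <- function(pixels, mask) {
  if (sum(mask) == 0) stop_domain("empty lesion mask")
  mean(pixels[array(mask, dim(pixels))])
}
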
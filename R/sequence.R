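#' Build a 3-step pseudo-sequence from a single lesion
#'
#' Emulates slow lesion evolution from a single-timepoint image: three frames
#' `(t-2, t-1, t)` in which the lesion area grows by a per-step factor drawn
#' once from 5--15% and the lesion-interior mean intensity darkens by a
#' per-step factor drawn once from 3--10%. Growth is applied to the mask
#' pixel area; the realised radial scale is found by bisection so the
#' *measured* inter-frame area ratio always lies in \[1.05, 1.15\] despite
#' pixel discretisation, and darkening is realised exactly by rescaling the
#' lesion-interior pixels to the target mean.
#'
#' @param base a `lesion_image` produced by [generate_lesion()] (the frame at
#'   `t-2`); it must carry its generator record and a nonempty mask.
#' @param seed integer seed for the per-sequence rate draws.
#' @param growth optional fixed per-step area-growth fraction (e.g. `0.1` for
#'   +10%); `0` disables growth; `NULL` (default) draws from \[0.05, 0.15\].
#' @param darkening optional fixed per-step darkening fraction; `0` disables;
#'   `NULL` draws from \[0.03, 0.10\].
#' @return A `lesion_sequence`: list with `frames` (3 `lesion_image`s),
#'   `area_growth_per_step` and `darkening_per_step`.
#' @export
#' @examples
#' seq3 <- make_pseudo_sequence(generate_lesion(2, seed = 7), seed = 7)
#' sapply(seq3$frames, function(f) sum(f$lesion_mask))
make_pseudo_sequence <- function(base, seed = 1L, growth = NULL,
                                 darkening = NULL) {
  if (!inherits(base, "lesion_image") || is.null(base$gen)) {
    stop_domain("base must be a generated lesion_image with generator record")
  }
  if (sum(base$lesion_mask) == 0) stop_domain("base lesion mask is empty")
  rates <- with_seed(derive_seed(seed, 101L), {
    list(g = growth %||% stats::runif(1, 0.05, 0.15),
         d = darkening %||% stats::runif(1, 0.03, 0.10))
  })
  if (rates$g < 0 || rates$d < 0 || rates$d >= 1) {
    stop_domain("growth/darkening rates must be nonnegative (darkening < 1)")
  }
  polar <- polar_fields(base$gen)
  frames <- vector("list", 3L)
  frames[[1]] <- base
  prev_scale <- 1
  prev_area <- sum(base$lesion_mask)
  prev_mean <- lesion_interior_mean(base$pixels, base$lesion_mask)
  for (k in 2:3) {
    if (rates$g > 0) {
      # keep the measured ratio strictly inside the admissible band
      target_ratio <- min(max(1 + rates$g, 1.0505), 1.1495)
      scale <- find_area_scale(polar, prev_scale, prev_area, target_ratio)
    } else {
      scale <- prev_scale
    }
    rend <- render_lesion(base$gen, scale = scale, polar = polar)
    if (rates$d > 0 || rates$g > 0) {
      target_mean <- prev_mean * (1 - rates$d)
      cur_mean <- lesion_interior_mean(rend$pixels, rend$mask)
      sel <- array(rend$mask, dim(rend$pixels))
      rend$pixels[sel] <- rend$pixels[sel] * (target_mean / cur_mean)
      rend$pixels <- clamp01(rend$pixels)
    }
    frames[[k]] <- new_lesion_image(rend$pixels, label = base$label,
                                    mask = rend$mask, seed = base$seed,
                                    gen = base$gen, features = base$features)
    prev_scale <- scale
    prev_area <- sum(rend$mask)
    prev_mean <- lesion_interior_mean(rend$pixels, rend$mask)
  }
  structure(list(frames = frames,
                 area_growth_per_step = rates$g,
                 darkening_per_step = rates$d),
            class = "lesion_sequence")
}

# Bisect the radial scale so the mask pixel count is as close as possible to
# prev_area * target_ratio; pixel areas of ~2,500+ px make the residual
# ratio error < 0.2%, well inside the admissible band.
find_area_scale <- function(polar, prev_scale, prev_area, target_ratio) {
  target <- prev_area * target_ratio
  lo <- prev_scale
  hi <- prev_scale * 1.3
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (sum(mask_at_scale(polar, mid)) < target) lo <- mid else hi <- mid
  }
  # pick whichever endpoint's area is closer to the target
  a_lo <- sum(mask_at_scale(polar, lo))
  a_hi <- sum(mask_at_scale(polar, hi))
  if (abs(a_lo - target) < abs(a_hi - target)) lo else hi
}

#' @export
print.lesion_sequence <- function(x, ...) {
  cat(sprintf("<lesion_sequence> 3 frames, label %d, growth %.3f/step, darkening %.3f/step\n",
              x$frames[[1]]$label, x$area_growth_per_step, x$darkening_per_step))
  invisible(x)
}
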
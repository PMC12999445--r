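#' Descriptor vocabulary
#'
#' Fixed vocabulary for the rule-based lesion descriptor that stands in for
#' a prompt-based visual-language model. Tokens are referenced by index into
#' this vector.
#'
#' @return Character vector of tokens.
#' @export
lesion_vocabulary <- function() {
  c("lesion", "regular", "asymmetric", "shape", "irregular", "border",
    "multiple", "colors", "dark", "pigmentation", "<sep>")
}

#' Descriptor rule thresholds
#'
#' A cue token is emitted when the corresponding ground-truth (or measured)
#' feature exceeds its threshold. Thresholds sit between the benign and
#' malignant generator ranges.
#'
#' @return Named list of thresholds.
#' @export
describe_thresholds <- function() {
  list(asymmetry = 0.15, border = 0.07, n_colors = 3L, darkness = 0.72)
}

#' Rule-based textual description of a lesion
#'
#' Deterministic stand-in for the visual-language model: emits clinically
#' styled cue phrases ("asymmetric shape", "irregular border", "multiple
#' colors", "dark pigmentation") for each feature above its threshold, or
#' the fixed template "regular lesion" when no cue fires. Uses the
#' generator's ground-truth feature record when present; for images without
#' one (e.g. loaded from disk) features are measured from the pixels with
#' [estimate_features()].
#'
#' @param image a `lesion_image`.
#' @param thresholds rule thresholds, see [describe_thresholds()].
#' @return A `text_descriptor`: list with integer `tokens`, `vocab_size` and
#'   the `source_features` record the rules were applied to.
#' @export
#' @examples
#' describe(generate_lesion(2, seed = 1))$tokens
describe <- function(image, thresholds = describe_thresholds()) {
  stopifnot(inherits(image, "lesion_image"))
  feats <- image$features
  if (is.null(feats)) feats <- estimate_features(image)
  needed <- c("asymmetry", "border_irregularity", "n_colors", "darkness")
  if (!all(needed %in% names(feats))) {
    stop_domain("image carries no usable feature record")
  }
  vocab <- lesion_vocabulary()
  words <- character(0)
  if (feats$asymmetry > thresholds$asymmetry) {
    words <- c(words, "asymmetric", "shape")
  }
  if (feats$border_irregularity > thresholds$border) {
    words <- c(words, "irregular", "border")
  }
  if (feats$n_colors >= thresholds$n_colors) {
    words <- c(words, "multiple", "colors")
  }
  if (feats$darkness < thresholds$darkness) {
    words <- c(words, "dark", "pigmentation")
  }
  words <- if (length(words) == 0) c("regular", "lesion") else c("lesion", words)
  structure(
    list(tokens = match(words, vocab), vocab_size = length(vocab),
         source_features = feats),
    class = "text_descriptor"
  )
}

#' Descriptor for a sequence: one per frame, separator-joined
#'
#' Encodes lesion evolution as the concatenation of the three per-frame
#' descriptors with a `<sep>` token between frames.
#'
#' @param x a `lesion_sequence` or single `lesion_image`.
#' @param thresholds rule thresholds.
#' @return A `text_descriptor`.
#' @export
describe_input <- function(x, thresholds = describe_thresholds()) {
  if (inherits(x, "lesion_image")) return(describe(x, thresholds))
  stopifnot(inherits(x, "lesion_sequence"))
  vocab <- lesion_vocabulary()
  sep <- match("<sep>", vocab)
  parts <- lapply(x$frames, function(f) describe(f, thresholds)$tokens)
  tokens <- parts[[1]]
  for (k in 2:length(parts)) tokens <- c(tokens, sep, parts[[k]])
  structure(
    list(tokens = tokens, vocab_size = length(vocab),
         source_features = x$frames[[length(x$frames)]]$features),
    class = "text_descriptor"
  )
}

#' Measure descriptor features from pixels
#'
#' For images without a generator ground-truth record: estimates the lesion
#' mask by luminance thresholding against the background, then measures
#' asymmetry ([asymmetry_score()]), border irregularity (compactness),
#' colour heterogeneity (occupied quantised-colour bins covering >= 8% of
#' the interior) and mean darkness.
#'
#' @param image a `lesion_image`.
#' @return Named list matching the generator feature record.
#' @export
estimate_features <- function(image) {
  lum <- luminance(image$pixels)
  bg <- stats::median(lum)
  mask <- lum < (bg - 0.15)
  if (sum(mask) < 25) mask <- lum < stats::quantile(lum, 0.05)
  q <- 4  # quantisation bins per channel
  idx <- array(mask, dim(image$pixels))
  r <- pmin(floor(image$pixels[, , 1][mask] * q), q - 1)
  g <- pmin(floor(image$pixels[, , 2][mask] * q), q - 1)
  b <- pmin(floor(image$pixels[, , 3][mask] * q), q - 1)
  tab <- table(r + q * g + q * q * b)
  n_colors <- sum(tab / sum(tab) >= 0.08)
  list(
    asymmetry = asymmetry_score(mask),
    border_irregularity = border_irregularity_score(mask),
    n_colors = as.integer(n_colors),
    darkness = mean(lum[mask]) / max(bg, 1e-6)
  )
}
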
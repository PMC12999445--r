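# Dataset exchange format: PNG images plus a CSV manifest with fixed columns
# (path, label, sequence_id, timestep, seed). The manifest is the single
# interface between simulate, train and evaluate.

manifest_columns <- c("path", "label", "sequence_id", "timestep", "seed")

#' Write a lesion image as PNG
#' @param image a `lesion_image`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_lesion_png <- function(image, path) {
  png::writePNG(image$pixels, target = path)
  invisible(path)
}

#' Read a lesion image from file
#'
#' Reads a PNG/JPEG-decoded array, resizes it to 224x224 with
#' nearest-neighbour sampling if needed and returns a `lesion_image` without
#' generator metadata (descriptor features are then measured from pixels).
#'
#' @param path image file path.
#' @param label integer class label.
#' @return A `lesion_image`.
#' @export
read_lesion_png <- function(path, label) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] > 3) px <- px[, , 1:3, drop = FALSE]
  if (dim(px)[1] != IMG_SIZE || dim(px)[2] != IMG_SIZE) {
    ri <- round(seq(1, dim(px)[1], length.out = IMG_SIZE))
    ci <- round(seq(1, dim(px)[2], length.out = IMG_SIZE))
    px <- px[ri, ci, , drop = FALSE]
  }
  new_lesion_image(px, label = label, mask = matrix(FALSE, IMG_SIZE, IMG_SIZE))
}

#' Write a dataset manifest
#' @param df data frame with columns path, label, sequence_id, timestep, seed.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(df, path) {
  stopifnot(all(manifest_columns %in% names(df)))
  utils::write.csv(df[, manifest_columns], path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#' @param path manifest CSV path.
#' @return Data frame with the fixed manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop_domain("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing)) {
    stop_domain("manifest is missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

# Load a manifest into a list of lesion_image / lesion_sequence objects.
# Rows sharing a sequence_id are ordered by timestep and grouped.
load_manifest_data <- function(path) {
  df <- read_manifest(path)
  base <- dirname(path)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  singles <- df[is.na(df$sequence_id) | df$sequence_id == "", , drop = FALSE]
  out <- lapply(seq_len(nrow(singles)), function(i) {
    read_lesion_png(resolve(singles$path[i]), singles$label[i])
  })
  seq_df <- df[!(is.na(df$sequence_id) | df$sequence_id == ""), , drop = FALSE]
  if (nrow(seq_df)) {
    for (sid in unique(seq_df$sequence_id)) {
      rows <- seq_df[seq_df$sequence_id == sid, , drop = FALSE]
      rows <- rows[order(rows$timestep), , drop = FALSE]
      frames <- lapply(seq_len(nrow(rows)), function(i) {
        read_lesion_png(resolve(rows$path[i]), rows$label[i])
      })
      out <- c(out, list(structure(
        list(frames = frames, area_growth_per_step = NA_real_,
             darkening_per_step = NA_real_),
        class = "lesion_sequence"
      )))
    }
  }
  out
}

# ImageNet channel normalisation, applied at model input (never stored).
imagenet_normalize <- function(patch) {
  mean <- c(0.485, 0.456, 0.406)
  sd <- c(0.229, 0.224, 0.225)
  for (ch in 1:3) patch[, , ch] <- (patch[, , ch] - mean[ch]) / sd[ch]
  patch
}
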
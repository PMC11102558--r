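#' Construct a single-channel 8-bit image
#'
#' The working currency of the pipeline: a rectangular raster of integer
#' intensities in \[0, 255\] together with the image's identity and its
#' experimental group. Every filter in the package consumes and returns
#' this type, appending the applied operator to the `provenance` field.
#'
#' @param pixels Integer matrix with values in \[0, 255\] (rows = image rows).
#' @param image_id Character scalar identifying the image.
#' @param group_label Character scalar naming the experimental condition
#'   (may be `NA` when the image is not part of a grouped design).
#' @param provenance Character vector of operator descriptions already
#'   applied (normally left at its default).
#' @return An object of class `image_channel`.
#' @examples
#' img <- image_channel(matrix(0L, 32, 32), "blank")
#' img
#' @export
image_channel <- function(pixels, image_id = "image", group_label = NA_character_,
                          provenance = character()) {
  if (!is.matrix(pixels) || length(pixels) == 0) {
    stop_field("pixels", "must be a non-empty matrix")
  }
  if (anyNA(pixels)) stop_field("pixels", "must not contain NA")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop_field("pixels", "values must lie in [0, 255]")
  }
  if (any(pixels != round(pixels))) {
    stop_field("pixels", "values must be integers (8-bit intensities)")
  }
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, image_id = as.character(image_id),
         group_label = as.character(group_label), provenance = provenance),
    class = "image_channel"
  )
}

#' @export
print.image_channel <- function(x, ...) {
  cat(sprintf("<image_channel> %s (group: %s), %d x %d px, range [%d, %d]\n",
              x$image_id, x$group_label, nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}

as_image_channel <- function(x) {
  if (inherits(x, "image_channel")) return(x)
  if (is.matrix(x)) return(image_channel(clip8(x)))
  stop("expected an image_channel or a numeric matrix", call. = FALSE)
}

# Append an operator record and rebuild the object with new pixels.
with_pixels <- function(img, pixels, op) {
  image_channel(pixels, img$image_id, img$group_label,
                provenance = c(img$provenance, op))
}

#' Read an 8-bit grayscale TIFF as an image channel
#'
#' Multi-channel TIFFs require `channel` to pick the stained junction
#' channel. Inputs that are not 8-bit are rejected unless
#' `auto_rescale = TRUE`, in which case intensities are min-max rescaled
#' to \[0, 255\] with a warning (the fixed 21-255 scoring threshold is
#' scale-dependent, so silent rescaling would be unsafe).
#'
#' @param path Path to a TIFF file.
#' @param image_id Identifier; defaults to the file name without extension.
#' @param group_label Experimental group label.
#' @param channel 1-based channel index for multi-channel inputs.
#' @param auto_rescale Rescale non-8-bit data to \[0, 255\]? Default `FALSE`.
#' @return An [image_channel()].
#' @export
read_image_channel <- function(path, image_id = NULL, group_label = NA_character_,
                               channel = 1L, auto_rescale = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  if (is.null(image_id)) {
    image_id <- sub("\\.[^.]*$", "", basename(path))
  }
  arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits <- attr(arr, "bits.per.sample")
  if (length(dim(arr)) == 3) {
    if (channel < 1 || channel > dim(arr)[3]) {
      stop(sprintf("channel %d not present (image has %d channels)",
                   channel, dim(arr)[3]), call. = FALSE)
    }
    arr <- arr[, , channel]
  }
  m <- matrix(as.numeric(arr), nrow = nrow(arr), ncol = ncol(arr))
  if (!is.null(bits) && bits != 8 || max(m) > 255 || min(m) < 0) {
    if (!auto_rescale) {
      stop(sprintf("not an 8-bit image: %s (use auto_rescale = TRUE to min-max rescale)",
                   path), call. = FALSE)
    }
    rng <- range(m)
    m <- if (diff(rng) == 0) m * 0 else (m - rng[1]) / diff(rng) * 255
    warning(sprintf("rescaled %s from [%g, %g] to [0, 255]", path, rng[1], rng[2]))
  }
  image_channel(clip8(m), image_id = image_id, group_label = group_label)
}

#' Write an image channel as an 8-bit grayscale TIFF
#'
#' @param img An [image_channel()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_channel <- function(img, path) {
  img <- as_image_channel(img)
  tiff::writeTIFF(img$pixels / 255, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}
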
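# The headline statistic: the percentage of each cell outline lying on
# zero pixels of a fixed-threshold binary junction mask. The mask comes
# from the lightly processed track (background subtraction + fixed 21-255
# threshold), never from the blurred/sharpened geometry intermediate.

#' Fixed-threshold binary junction mask
#'
#' Applies rolling-ball background subtraction (radius 20) to the raw
#' stained-junction channel and binarizes with the fixed inclusive range
#' `threshold_low`-`threshold_high` on the 8-bit scale: in-range pixels
#' become 255, everything else 0.
#'
#' @param raw The raw (unblurred) [image_channel()], or a
#'   background-subtracted channel if `subtract = FALSE`.
#' @param radius Rolling-ball radius, pixels; default 20.
#' @param threshold_low,threshold_high Inclusive 8-bit thresholds;
#'   defaults 21 and 255.
#' @param subtract Apply background subtraction first? Default `TRUE`;
#'   set to `FALSE` when passing an already background-subtracted channel.
#' @return A `binary_junction_mask`: list with `pixels` (integer matrix of
#'   0/255), `source_image_id`, `threshold_low`, `threshold_high`.
#' @export
junction_binary_mask <- function(raw, radius = 20, threshold_low = 21L,
                                 threshold_high = 255L, subtract = TRUE) {
  raw <- as_image_channel(raw)
  if (threshold_low < 0 || threshold_low > threshold_high || threshold_high > 255) {
    stop_field("threshold_low", "need 0 <= threshold_low <= threshold_high <= 255")
  }
  sub <- if (subtract) subtract_background(raw, radius) else raw
  px <- sub$pixels
  mask <- clip8(ifelse(px >= threshold_low & px <= threshold_high, 255L, 0L))
  structure(
    list(pixels = mask, source_image_id = raw$image_id,
         threshold_low = as.integer(threshold_low),
         threshold_high = as.integer(threshold_high)),
    class = "binary_junction_mask"
  )
}

#' @export
print.binary_junction_mask <- function(x, ...) {
  cat(sprintf("<binary_junction_mask> %s, %d x %d px, threshold %d-%d, %.1f%% foreground\n",
              x$source_image_id, nrow(x$pixels), ncol(x$pixels),
              x$threshold_low, x$threshold_high, 100 * mean(x$pixels > 0)))
  invisible(x)
}

#' Plot-profile of a mask along a cell outline
#'
#' Reads the binary mask value at each outline pixel, in path order, each
#' pixel exactly once.
#'
#' @param mask A `binary_junction_mask` from [junction_binary_mask()].
#' @param outline A [cell_outline()] whose path lies within the mask bounds.
#' @return Integer vector of 0/255 values, one per outline pixel.
#' @export
profile_outline <- function(mask, outline) {
  stopifnot(inherits(mask, "binary_junction_mask"),
            inherits(outline, "cell_outline"))
  p <- outline$path
  bad <- p[, 1] < 1 | p[, 1] > nrow(mask$pixels) |
         p[, 2] < 1 | p[, 2] > ncol(mask$pixels)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("outline pixel (%d, %d) is outside the %d x %d mask",
                 p[i, 1], p[i, 2], nrow(mask$pixels), ncol(mask$pixels)),
         call. = FALSE)
  }
  as.integer(mask$pixels[p])
}

#' Discontinuity ratio of a profile
#'
#' `100 * (number of zero entries) / (profile length)`, in percent. This
#' is the per-cell junction discontinuity statistic: the share of the
#' cell's outline with no above-threshold junction signal.
#'
#' @param profile Non-empty vector of profile values (0 = no signal).
#' @return Percentage in \[0, 100\].
#' @export
discontinuity_ratio <- function(profile) {
  if (length(profile) == 0) stop("empty profile", call. = FALSE)
  100 * sum(profile == 0) / length(profile)
}

#' Score selected outlines of one image
#'
#' Composes [junction_binary_mask()], [profile_outline()] and
#' [discontinuity_ratio()] into one record per outline.
#'
#' @param raw The raw [image_channel()] the outlines were extracted from.
#' @param selected_outlines List of [cell_outline()] objects.
#' @param mask Optional precomputed `binary_junction_mask` (to reuse the
#'   shared background-subtraction step); computed from `raw` when `NULL`.
#' @param radius,threshold_low Parameters forwarded to
#'   [junction_binary_mask()] when `mask` is `NULL`.
#' @return A `data.frame` with columns `image_id`, `group_label`,
#'   `cell_id`, `outline_pixels`, `zero_pixels`, `ratio_percent`.
#' @export
score_image <- function(raw, selected_outlines, mask = NULL, radius = 20,
                        threshold_low = 21L) {
  raw <- as_image_channel(raw)
  if (is.null(mask)) {
    mask <- junction_binary_mask(raw, radius = radius,
                                 threshold_low = threshold_low)
  }
  if (length(selected_outlines) == 0) {
    return(data.frame(image_id = character(), group_label = character(),
                      cell_id = integer(), outline_pixels = integer(),
                      zero_pixels = integer(), ratio_percent = numeric(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(selected_outlines, function(o) {
    prof <- profile_outline(mask, o)
    z <- sum(prof == 0L)
    data.frame(image_id = raw$image_id, group_label = raw$group_label,
               cell_id = o$cell_id, outline_pixels = length(prof),
               zero_pixels = z, ratio_percent = 100 * z / length(prof),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
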
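# Extraction of closed single-cell outlines from a skeletonized junction
# network: interior faces of the skeleton are traced as closed 8-connected
# pixel loops, and a seeded uniform subsample of complete (non-border)
# outlines is taken for scoring.

#' Construct a single-cell outline
#'
#' A closed, ordered pixel path delineating one cell: consecutive path
#' pixels (including last-to-first) are 8-adjacent, no pixel repeats, and
#' the path has at least 20 pixels. Outlines that touch the image border
#' are flagged and are never selected for scoring (an outline interrupted
#' by the frame is not a complete cell outline).
#'
#' @param cell_id Integer identifier within the image.
#' @param path n x 2 integer matrix of (row, col) pixel coordinates
#'   (1-based); closure is implicit (first pixel is not repeated at the end).
#' @param image_id Identifier of the source image.
#' @param touches_border Does the enclosed region touch the image border?
#' @return An object of class `cell_outline`.
#' @export
cell_outline <- function(cell_id, path, image_id = "image",
                         touches_border = FALSE) {
  if (!is.matrix(path) || ncol(path) != 2) {
    stop_field("path", "must be an n x 2 matrix of pixel coordinates")
  }
  n <- nrow(path)
  if (n < 20) stop_field("path", "must have at least 20 pixels")
  storage.mode(path) <- "integer"
  k <- path[, 1] * 100000 + path[, 2]
  if (anyDuplicated(k)) stop_field("path", "must not repeat a pixel")
  nxt <- rbind(path[-1, , drop = FALSE], path[1, , drop = FALSE])
  cheb <- pmax(abs(nxt[, 1] - path[, 1]), abs(nxt[, 2] - path[, 2]))
  if (any(cheb != 1)) {
    stop_field("path", "consecutive pixels must be 8-adjacent around a closed loop")
  }
  structure(
    list(cell_id = as.integer(cell_id), path = path,
         image_id = as.character(image_id),
         touches_border = isTRUE(touches_border)),
    class = "cell_outline"
  )
}

#' @export
print.cell_outline <- function(x, ...) {
  cat(sprintf("<cell_outline> cell %d of %s: %d px%s\n", x$cell_id, x$image_id,
              nrow(x$path), if (x$touches_border) " (touches border)" else ""))
  invisible(x)
}

# Remove tracing artifacts from a raw contour: consecutive duplicates,
# one-pixel out-and-back spikes, and repeated pixels (the shorter arc
# between two visits of the same pixel is cut). All phases treat the path
# as cyclic.
clean_loop <- function(path) {
  for (round in 1:10) {
    changed <- FALSE
    repeat {
      n <- nrow(path)
      if (n < 3) return(path)
      k <- path[, 1] * 100000 + path[, 2]
      dup_next <- k == k[c(2:n, 1)]
      if (any(dup_next)) {
        path <- path[-((which(dup_next) %% n) + 1L), , drop = FALSE]
        changed <- TRUE
        next
      }
      spike <- k[c(n, 1:(n - 1))] == k[c(2:n, 1)]
      if (any(spike)) {
        path <- path[-which(spike)[1], , drop = FALSE]
        changed <- TRUE
        next
      }
      break
    }
    n <- nrow(path)
    k <- path[, 1] * 100000 + path[, 2]
    d <- which(duplicated(k))
    if (length(d) == 0) {
      if (!changed) break
      next
    }
    j <- d[1]
    i <- which(k == k[j])[1]
    if ((j - i) <= n - (j - i)) {
      path <- path[-(i:(j - 1L)), , drop = FALSE]
    } else {
      path <- path[i:(j - 1L), , drop = FALSE]
    }
  }
  path
}

#' Extract closed cell outlines from a junction skeleton
#'
#' Connected background regions of the skeleton (4-connected faces) are
#' identified; each face's boundary -- the face plus its adjacent skeleton
#' pixels -- is traced as a closed 8-connected loop. Faces touching the
#' image border are returned flagged with `touches_border = TRUE`, except
#' that a border region covering more than half of the frame is treated as
#' exterior background rather than a cell (so an open, non-enclosing curve
#' yields an empty collection). Loops shorter than `min_path` pixels are
#' discarded as noise.
#'
#' @param skeleton A `junction_skeleton` from [skeletonize()].
#' @param image_id Identifier recorded on each outline.
#' @param min_path Minimum loop length in pixels; default 20.
#' @return List of [cell_outline()] objects (possibly empty).
#' @export
extract_cell_outlines <- function(skeleton, image_id = "image", min_path = 20L) {
  stopifnot(inherits(skeleton, "junction_skeleton"))
  sk <- skeleton$skeleton_mask
  H <- nrow(sk); W <- ncol(sk)
  labs <- EBImage::bwlabel(!sk)
  labs <- matrix(as.integer(labs), H, W)
  nfaces <- max(labs)
  if (nfaces == 0) return(list())
  border_ids <- unique(c(labs[1, ], labs[H, ], labs[, 1], labs[, W]))
  border_ids <- border_ids[border_ids > 0]
  face_area <- tabulate(labs[labs > 0], nbins = nfaces)
  outlines <- list()
  cid <- 0L
  for (f in seq_len(nfaces)) {
    touches <- f %in% border_ids
    if (touches && face_area[f] > 0.5 * H * W) next
    face <- labs == f
    ring <- cpp_dilate3(face, 1L) & sk
    M <- face | ring
    oc <- EBImage::ocontour(matrix(as.integer(M), H, W))
    if (length(oc) == 0) next
    path <- oc[[1]] + 1L
    path <- clean_loop(path)
    if (nrow(path) < min_path) next
    # an outline running along the frame margin is not a complete cell
    # outline even when its face is sealed off from the frame itself
    # (converging walls can fuse just inside the frame and enclose a
    # border cell); 5 px covers the fusion zone of dilated walls
    near_frame <- any(path[, 1] <= 6L | path[, 1] >= H - 5L |
                      path[, 2] <= 6L | path[, 2] >= W - 5L)
    cid <- cid + 1L
    outlines[[cid]] <- cell_outline(cid, path, image_id = image_id,
                                    touches_border = touches || near_frame)
  }
  outlines
}

#' Randomly select outlines for scoring
#'
#' Uniform sample without replacement of `k` complete (non-border)
#' outlines, deterministic given `rng_seed`. When fewer than `k` are
#' eligible, all of them are returned with a warning.
#'
#' @param outlines List of [cell_outline()] objects.
#' @param k Number of outlines to select; default 25 (per-image sample size).
#' @param rng_seed Integer seed controlling the draw.
#' @return List of selected [cell_outline()] objects.
#' @export
select_outlines <- function(outlines, k = 25L, rng_seed = 1L) {
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop_field("k", "must be a single integer >= 1")
  }
  eligible <- which(!vapply(outlines, function(o) o$touches_border, logical(1)))
  if (length(eligible) < k) {
    warning(sprintf("only %d eligible outlines available (%d requested); returning all",
                    length(eligible), k))
    return(outlines[eligible])
  }
  idx <- withr::with_seed(as.integer(rng_seed),
                          eligible[sample.int(length(eligible), k)])
  outlines[idx]
}

#' Trace cell outlines from a raw junction channel
#'
#' Runs the full geometry track in its fixed order: rolling-ball
#' background subtraction, double Gaussian blur, sharpen, Huang
#' auto-threshold, binarization, double binary dilation, endpoint
#' bridging, skeletonization, and face tracing. The background-subtracted
#' intermediate is returned so the scoring track (which shares only that
#' step) can reuse it.
#'
#' @param img An [image_channel()] holding the raw stained-junction channel.
#' @param rolling_radius Rolling-ball radius, pixels; default 20.
#' @param blur_sigma Gaussian sigma, pixels; default 2.0.
#' @param blur_passes Number of blur passes; default 2.
#' @param dilate_iterations Binary dilation repeats; default 2.
#' @param bridge_max Endpoint bridging distance, pixels; default 10.
#' @param prune_len Skeleton spur pruning length, pixels; default 5.
#' @param min_path Minimum outline length, pixels; default 20.
#' @return List with `outlines`, `skeleton`, `threshold` (the Huang
#'   threshold used), `background_subtracted` (reusable intermediate) and
#'   `provenance`.
#' @export
trace_cell_outlines <- function(img, rolling_radius = 20, blur_sigma = 2.0,
                                blur_passes = 2L, dilate_iterations = 2L,
                                bridge_max = 10, prune_len = 5L,
                                min_path = 20L) {
  img <- as_image_channel(img)
  bg <- subtract_background(img, rolling_radius)
  bl <- gaussian_blur(bg, blur_sigma, blur_passes)
  sh <- sharpen(bl)
  thr <- huang_threshold(sh)
  bin <- binarize(sh, thr)
  dil <- dilate_binary(bin, dilate_iterations)
  br <- close_gaps(dil, bridge_max)
  prov <- c(sh$provenance,
            sprintf("binarize(threshold=%d [huang])", thr),
            sprintf("dilate_binary(iterations=%d)", as.integer(dilate_iterations)),
            sprintf("close_gaps(max_bridge=%g)", bridge_max))
  sk <- skeletonize(br, prune_len, provenance = prov)
  outlines <- extract_cell_outlines(sk, image_id = img$image_id,
                                    min_path = min_path)
  list(outlines = outlines, skeleton = sk, threshold = thr,
       background_subtracted = bg, provenance = sk$provenance)
}
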
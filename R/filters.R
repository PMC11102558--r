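# The junction-map operator chain. Each operator mirrors one step of the
# image-processing recipe used to trace cell outlines from a stained
# junction channel; all of them work on 8-bit intensities and record
# themselves in the image's provenance.

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with
#' a non-flat ball structuring element of the given radius (the classic
#' rolling-ball construction: the envelope of a ball rolled under the
#' intensity surface) and subtracts it. The result is clipped at 0 and is
#' pixelwise no larger than the input; a constant image maps to zero.
#'
#' @param img An [image_channel()] (or plain 8-bit matrix).
#' @param radius Ball radius in pixels; default 20.
#' @return Background-subtracted [image_channel()].
#' @export
subtract_background <- function(img, radius = 20) {
  img <- as_image_channel(img)
  if (!is.numeric(radius) || length(radius) != 1 || radius < 1) {
    stop_field("radius", "must be a single value >= 1")
  }
  bg <- cpp_ball_background(img$pixels + 0.0, as.integer(radius))
  out <- clip8(img$pixels - pmax(bg, 0))
  with_pixels(img, out, sprintf("subtract_background(radius=%g)", radius))
}

#' Gaussian blur
#'
#' Separable Gaussian filtering with reflective boundaries, applied
#' `passes` times with quantization to 8 bits after each pass. Two passes
#' at sigma are equivalent to a single pass at sigma * sqrt(2) to within
#' one intensity unit.
#'
#' @param img An [image_channel()].
#' @param sigma Gaussian standard deviation in pixels; default 2.0.
#' @param passes Number of repeated applications; default 2.
#' @return Blurred [image_channel()].
#' @export
gaussian_blur <- function(img, sigma = 2.0, passes = 2L) {
  img <- as_image_channel(img)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    stop_field("sigma", "must be a single value > 0")
  }
  if (!is.numeric(passes) || length(passes) != 1 || passes < 1) {
    stop_field("passes", "must be a single integer >= 1")
  }
  px <- img$pixels + 0.0
  for (i in seq_len(passes)) px <- clip8(cpp_gauss_blur(px, sigma)) + 0.0
  with_pixels(img, px, sprintf("gaussian_blur(sigma=%g, passes=%d)", sigma, passes))
}

#' Sharpen
#'
#' 3x3 unsharp convolution with the kernel
#' `[[-1,-1,-1],[-1,12,-1],[-1,-1,-1]] / 4` (replicated edges), clipped to
#' \[0, 255\]. Constants are left unchanged since the kernel sums to one.
#'
#' @param img An [image_channel()].
#' @return Sharpened [image_channel()].
#' @export
sharpen <- function(img) {
  img <- as_image_channel(img)
  out <- clip8(cpp_sharpen(img$pixels + 0.0))
  with_pixels(img, out, "sharpen()")
}

#' Huang fuzzy auto-threshold
#'
#' Selects the threshold minimizing Huang's measure of fuzziness: for each
#' candidate threshold the two class means define a membership function
#' `u(g) = 1 / (1 + |g - mu_class| / C)` (with `C` the intensity range of
#' the histogram), and the fuzziness is the Shannon entropy of membership
#' summed over the 256-bin histogram. Ties break toward the smaller
#' threshold. Foreground is then `intensity > threshold` (see
#' [binarize()]).
#'
#' @param img An [image_channel()].
#' @return Integer threshold in \[0, 255\].
#' @export
huang_threshold <- function(img) {
  img <- as_image_channel(img)
  h <- tabulate(as.vector(img$pixels) + 1L, nbins = 256L)
  nz <- which(h > 0)
  if (length(nz) < 2) {
    stop("no threshold exists: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  first <- nz[1] - 1L
  last <- nz[length(nz)] - 1L
  g <- 0:255
  C <- last - first
  W <- cumsum(h * g)
  S <- cumsum(h)
  total_w <- W[256]
  total_s <- S[256]
  best_t <- NA_integer_
  best_e <- Inf
  for (t in first:(last - 1L)) {
    s0 <- S[t + 1L]; s1 <- total_s - s0
    mu0 <- W[t + 1L] / s0
    mu1 <- (total_w - W[t + 1L]) / s1
    u <- ifelse(g <= t, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    hf <- -u * log(u) - (1 - u) * log(pmax(1 - u, .Machine$double.xmin))
    hf[u >= 1] <- 0
    e <- sum(h * hf)
    if (e < best_e) {  # strict: exact ties keep the smaller threshold
      best_e <- e
      best_t <- t
    }
  }
  as.integer(best_t)
}

#' Binarize at a fixed threshold
#'
#' Foreground iff `intensity > threshold` (strict; the convention is fixed
#' so results are bit-reproducible).
#'
#' @param img An [image_channel()].
#' @param threshold Integer in \[0, 255\].
#' @return Logical matrix.
#' @export
binarize <- function(img, threshold) {
  img <- as_image_channel(img)
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 255) {
    stop_field("threshold", "must be a single value in [0, 255]")
  }
  img$pixels > threshold
}

#' Binary dilation
#'
#' Dilation with the full 3x3 (8-connected) structuring element, applied
#' `iterations` times; `iterations = 0` is the identity.
#'
#' @param mask Logical matrix.
#' @param iterations Non-negative integer; default 2.
#' @return Logical matrix containing the input.
#' @export
dilate_binary <- function(mask, iterations = 2L) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.numeric(iterations) || length(iterations) != 1 || iterations < 0) {
    stop_field("iterations", "must be a single integer >= 0")
  }
  if (iterations == 0) return(mask)
  out <- cpp_dilate3(mask, as.integer(iterations))
  dimnames(out) <- NULL
  out
}

#' Bridge open ends of a junction mask
#'
#' Automated stand-in for interactive line-tool corrections: at each open
#' end of the mask's centerline (a skeleton endpoint), the mask pixels
#' around the end are separated from mask pixels that are not connected to
#' it by a short path through the mask (so forks and stubs on intact walls
#' are left alone, while true breaks -- whose far side is only reachable
#' the long way around -- are detected), and the closest such pixel pair
#' is joined by a straight rasterized segment when the physical gap width
#' is at most `max_bridge` pixels. The bridge step is iterated to a fixed
#' point, since closing one break can bring the remaining ends within
#' reach. Closed loops have no endpoints and pass through unchanged;
#' `max_bridge = 0` is the identity.
#'
#' @param mask Logical matrix.
#' @param max_bridge Maximum Euclidean bridging distance, pixels;
#'   default 10.
#' @return Logical matrix containing the input.
#' @export
close_gaps <- function(mask, max_bridge = 10) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!is.numeric(max_bridge) || length(max_bridge) != 1 || max_bridge < 0) {
    stop_field("max_bridge", "must be a single value >= 0")
  }
  if (max_bridge == 0 || !any(mask)) return(mask)
  out <- mask
  steps <- ceiling(4 * max_bridge)
  for (round in 1:6) {
    thin <- cpp_thin(out)
    ep <- skeleton_endpoints(thin)
    if (nrow(ep) == 0) break
    drawn <- 0L
    for (i in seq_len(nrow(ep))) {
      br <- nearest_nonlocal_pixel(out, ep[i, ], max_bridge, steps)
      if (is.null(br)) next
      seg <- bresenham(br$from[1], br$from[2], br$to[1], br$to[2])
      out[seg] <- TRUE
      drawn <- drawn + 1L
    }
    if (drawn == 0L) break
  }
  out
}

# Shortest bridge across the break at an open end: the endpoint's own wall
# (its geodesic neighborhood through the mask, up to `steps` pixels) is
# separated from any other mask pixels in the window; the closest pair
# between the near side (within `max_bridge` of the endpoint) and the far
# side defines the bridge, accepted when the physical gap width is at most
# `max_bridge`. Returns list(from=, to=) or NULL. Computed on a local
# window by geodesic reconstruction (iterated dilation-and-mask).
nearest_nonlocal_pixel <- function(mask, from, max_bridge, steps) {
  H <- nrow(mask); W <- ncol(mask)
  r0 <- max(1L, from[1] - steps); r1 <- min(H, from[1] + steps)
  c0 <- max(1L, from[2] - steps); c1 <- min(W, from[2] + steps)
  crop <- mask[r0:r1, c0:c1, drop = FALSE]
  er <- from[1] - r0 + 1L; ec <- from[2] - c0 + 1L
  ball <- matrix(FALSE, nrow(crop), ncol(crop))
  ball[er, ec] <- TRUE
  for (s in seq_len(steps)) {
    grown <- cpp_dilate3(ball, 1L) & crop
    if (identical(grown, ball)) break
    ball <- grown
  }
  other <- which(crop & !ball, arr.ind = TRUE, useNames = FALSE)
  if (nrow(other) == 0) return(NULL)
  own <- which(ball, arr.ind = TRUE, useNames = FALSE)
  own <- own[(own[, 1] - er)^2 + (own[, 2] - ec)^2 <= max_bridge^2, ,
             drop = FALSE]
  best <- NULL
  best_d <- max_bridge
  for (i in seq_len(nrow(own))) {
    dd <- sqrt((other[, 1] - own[i, 1])^2 + (other[, 2] - own[i, 2])^2)
    j <- which.min(dd)
    if (dd[j] <= best_d) {
      best_d <- dd[j]
      best <- list(from = own[i, ], to = other[j, ])
    }
  }
  if (is.null(best)) return(NULL)
  list(from = c(best$from[1] + r0 - 1L, best$from[2] + c0 - 1L),
       to = c(best$to[1] + r0 - 1L, best$to[2] + c0 - 1L))
}

# Endpoints (degree <= 1) of a thin mask, as an n x 2 (row, col) matrix.
skeleton_endpoints <- function(thin) {
  deg <- neighbor_count(thin)
  which(thin & deg == 1, arr.ind = TRUE, useNames = FALSE)
}

# 8-neighbor count of TRUE pixels at every position.
neighbor_count <- function(m) {
  H <- nrow(m); W <- ncol(m)
  p <- matrix(0L, H + 2, W + 2)
  p[2:(H + 1), 2:(W + 1)] <- m
  acc <- matrix(0L, H, W)
  for (a in 0:2) for (b in 0:2) {
    if (a == 1 && b == 1) next
    acc <- acc + p[(1:H) + a, (1:W) + b]
  }
  acc
}

# Breadth-first search along TRUE pixels from `from`, capped at max_steps
# levels; returns the logical matrix of reached pixels (the geodesic ball).
geodesic_ball <- function(mask, from, max_steps) {
  H <- nrow(mask); W <- ncol(mask)
  visited <- matrix(FALSE, H, W)
  frontier <- matrix(as.integer(from), ncol = 2)
  visited[from[1], from[2]] <- TRUE
  for (step in seq_len(max_steps)) {
    if (nrow(frontier) == 0) break
    nxt <- NULL
    for (i in seq_len(nrow(frontier))) {
      r0 <- frontier[i, 1]; c0 <- frontier[i, 2]
      for (a in -1:1) for (b in -1:1) {
        if (a == 0 && b == 0) next
        r <- r0 + a; c <- c0 + b
        if (r < 1 || r > H || c < 1 || c > W) next
        if (!mask[r, c] || visited[r, c]) next
        visited[r, c] <- TRUE
        nxt <- rbind(nxt, c(r, c))
      }
    }
    frontier <- if (is.null(nxt)) matrix(integer(0), ncol = 2) else nxt
  }
  visited
}

#' Skeletonize a junction mask
#'
#' Topology-preserving thinning to 1-pixel-wide curves (sequential
#' simple-point deletion in four directional sub-passes, which provably
#' preserves foreground 8-connectivity and background 4-connectivity),
#' followed by removal of spur branches shorter than `prune_len` pixels
#' and of stray components smaller than `prune_len` (thinning artifacts).
#' Tiny enclosed holes (below `fill_holes` pixels) are filled beforehand:
#' they are sub-threshold specks inside thick junction bands, and because
#' thinning preserves topology exactly they would otherwise survive as
#' spurious micro-faces. The operation is idempotent on its own output.
#'
#' @param mask Logical matrix.
#' @param prune_len Minimum retained branch/component length in pixels;
#'   default 5.
#' @param fill_holes Enclosed background components smaller than this many
#'   pixels are filled before thinning; default 64 (far below any
#'   plausible cell face).
#' @param provenance Optional character vector of upstream operator
#'   records to carry into the skeleton object.
#' @return A `junction_skeleton`: list with `skeleton_mask` (logical
#'   matrix) and `provenance`.
#' @export
skeletonize <- function(mask, prune_len = 5L, fill_holes = 64L,
                        provenance = character()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (fill_holes > 0 && any(mask) && !all(mask)) {
    labs <- EBImage::bwlabel(!mask)
    labs <- matrix(as.integer(labs), nrow(mask), ncol(mask))
    if (max(labs) > 0) {
      area <- tabulate(labs[labs > 0], nbins = max(labs))
      border <- unique(c(labs[1, ], labs[nrow(labs), ],
                         labs[, 1], labs[, ncol(labs)]))
      small <- which(area < fill_holes)
      small <- setdiff(small, border)
      if (length(small)) mask[labs %in% small] <- TRUE
    }
  }
  sk <- cpp_prune(cpp_thin(mask), as.integer(prune_len))
  dimnames(sk) <- NULL
  structure(
    list(skeleton_mask = sk,
         provenance = c(provenance,
                        sprintf("skeletonize(prune_len=%d, fill_holes=%d)",
                                as.integer(prune_len), as.integer(fill_holes)))),
    class = "junction_skeleton"
  )
}

#' @export
print.junction_skeleton <- function(x, ...) {
  cat(sprintf("<junction_skeleton> %d x %d px, %d skeleton pixels\n",
              nrow(x$skeleton_mask), ncol(x$skeleton_mask), sum(x$skeleton_mask)))
  if (length(x$provenance)) {
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  }
  invisible(x)
}
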
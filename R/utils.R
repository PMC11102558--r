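# Internal helpers shared across modules.

# Clip to [0,255] and quantize to integer (8-bit semantics after each operator).
clip8 <- function(x) {
  m <- pmin(pmax(round(x), 0), 255)
  storage.mode(m) <- "integer"
  m
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

# djb2-style 31-bit hash of a string; fingerprint for configs in output files.
config_hash <- function(x) {
  if (!is.character(x)) {
    x <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10)
  }
  bytes <- utf8ToInt(paste(x, collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Run-length encoding of a logical matrix for compact JSON truth files.
# Runs alternate FALSE/TRUE in column-major order, starting with FALSE
# (a leading zero-length run is used when the first pixel is TRUE).
rle_encode_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  r <- rle(as.vector(mask))
  lens <- r$lengths
  if (length(lens) > 0 && r$values[1]) lens <- c(0L, lens)
  list(dim = dim(mask), runs = as.integer(lens))
}

rle_decode_mask <- function(enc) {
  runs <- as.integer(enc$runs)
  vals <- rep(c(FALSE, TRUE), length.out = length(runs))
  keep <- runs > 0
  v <- inverse.rle(structure(list(lengths = runs[keep], values = vals[keep]),
                             class = "rle"))
  matrix(v, nrow = enc$dim[1], ncol = enc$dim[2])
}

# Integer run-length encoding for label maps.
rle_encode_int <- function(m) {
  stopifnot(is.matrix(m))
  r <- rle(as.vector(m))
  list(dim = dim(m), lengths = as.integer(r$lengths), values = as.integer(r$values))
}

rle_decode_int <- function(enc) {
  v <- inverse.rle(structure(list(lengths = as.integer(enc$lengths),
                                  values = as.integer(enc$values)),
                   class = "rle"))
  matrix(v, nrow = enc$dim[1], ncol = enc$dim[2])
}

# Bresenham raster of the segment between two pixels (inclusive).
bresenham <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  pts <- matrix(0L, nrow = dr + dc + 1L, ncol = 2L)
  n <- 0L
  repeat {
    n <- n + 1L
    pts[n, ] <- c(r0, c0)
    if (r0 == r1 && c0 == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
    if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
  }
  pts[seq_len(n), , drop = FALSE]
}

# Symmetric Hausdorff distance (pixels) between two point sets given as
# n x 2 matrices of (row, col) coordinates.
hausdorff_px <- function(a, b) {
  stopifnot(nrow(a) > 0, nrow(b) > 0)
  directed <- function(p, q) {
    m <- 0
    for (i in seq_len(nrow(p))) {
      d <- sqrt(min((q[, 1] - p[i, 1])^2 + (q[, 2] - p[i, 2])^2))
      if (d > m) m <- d
    }
    m
  }
  max(directed(a, b), directed(b, a))
}

# Border touch test for a set of (row, col) pixels.
touches_image_border <- function(px, dims) {
  any(px[, 1] == 1L | px[, 1] == dims[1] | px[, 2] == 1L | px[, 2] == dims[2])
}
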
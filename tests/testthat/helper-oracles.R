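# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, unoptimized transcription of the definition it
# checks, kept separate from the package's implementation path.

# Grayscale opening with a non-flat ball structuring element, computed by
# direct min/max over shifted copies (restricted at the image edge).
naive_ball_opening <- function(img, radius) {
  H <- nrow(img); W <- ncol(img)
  offs <- expand.grid(a = -radius:radius, b = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 <= radius^2, ]
  offs$se <- sqrt(radius^2 - offs$a^2 - offs$b^2)
  ero <- matrix(Inf, H, W)
  for (k in seq_len(nrow(offs))) {
    sh <- matrix(Inf, H, W)
    a <- offs$a[k]; b <- offs$b[k]
    rs <- max(1, 1 - a):min(H, H - a)
    cs <- max(1, 1 - b):min(W, W - b)
    sh[rs, cs] <- img[rs + a, cs + b] - offs$se[k]
    ero <- pmin(ero, sh)
  }
  dil <- matrix(-Inf, H, W)
  for (k in seq_len(nrow(offs))) {
    sh <- matrix(-Inf, H, W)
    a <- offs$a[k]; b <- offs$b[k]
    rs <- max(1, 1 - a):min(H, H - a)
    cs <- max(1, 1 - b):min(W, W - b)
    sh[rs, cs] <- ero[rs + a, cs + b] + offs$se[k]
    dil <- pmax(dil, sh)
  }
  dil
}

# Direct 3x3 convolution with replicated edges.
naive_conv3 <- function(img, kernel) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (a in -1:1) for (b in -1:1) {
      r <- min(max(i + a, 1), H)
      c <- min(max(j + b, 1), W)
      acc <- acc + kernel[a + 2, b + 2] * img[r, c]
    }
    out[i, j] <- acc
  }
  out
}

# Huang's fuzziness for every candidate threshold of a 256-bin histogram;
# returns the exhaustive-scan argmin (first minimum = smallest threshold).
huang_brute_force <- function(h) {
  g <- 0:255
  nz <- which(h > 0) - 1L
  first <- min(nz); last <- max(nz)
  C <- last - first
  ent <- sapply(first:(last - 1L), function(t) {
    lo <- g <= t
    mu0 <- sum(h[lo] * g[lo]) / sum(h[lo])
    mu1 <- sum(h[!lo] * g[!lo]) / sum(h[!lo])
    mu <- ifelse(lo, mu0, mu1)
    u <- 1 / (1 + abs(g - mu) / C)
    hf <- ifelse(u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    sum(h * hf)
  })
  (first:(last - 1L))[which.min(ent)]
}

# Kruskal-Wallis H by direct rank arithmetic with mid-ranks and the
# standard tie correction.
kw_H_by_hand <- function(groups) {
  x <- unlist(groups)
  gsz <- lengths(groups)
  N <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), gsz)
  Rbar <- tapply(r, idx, mean)
  H <- 12 / (N * (N + 1)) * sum(gsz * (Rbar - (N + 1) / 2)^2)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Count 8-connected components of a logical matrix (flood fill).
count_components8 <- function(m) {
  lab <- matrix(0L, nrow(m), ncol(m))
  nxt <- 0L
  H <- nrow(m); W <- ncol(m)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!m[i, j] || lab[i, j] > 0) next
    nxt <- nxt + 1L
    stack <- list(c(i, j)); lab[i, j] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (a in -1:1) for (b in -1:1) {
        r <- p[1] + a; c <- p[2] + b
        if (r < 1 || r > H || c < 1 || c > W) next
        if (m[r, c] && lab[r, c] == 0) {
          lab[r, c] <- nxt
          stack[[length(stack) + 1]] <- c(r, c)
        }
      }
    }
  }
  nxt
}

# Closed rectangular pixel loop (clockwise), for crafting outlines.
rect_loop_path <- function(r0, c0, height, width) {
  top <- cbind(r0, c0:(c0 + width - 1))
  right <- cbind((r0 + 1):(r0 + height - 1), c0 + width - 1)
  bottom <- cbind(r0 + height - 1, (c0 + width - 2):c0)
  left <- cbind((r0 + height - 2):(r0 + 1), c0)
  unname(rbind(top, right, bottom, left))
}

# Truth boundary pixels (region pixels adjacent to any other label) for
# each of the given cells.
truth_boundaries <- function(label_map, cells) {
  lapply(cells, function(cl) {
    m <- label_map == cl
    ring <- m & ajdisc:::cpp_dilate3(!m, 1L)
    which(ring, arr.ind = TRUE, useNames = FALSE)
  })
}

# Small, fast monolayer configuration for module-level tests.
quick_config <- function(...) {
  args <- list(image_size = c(256L, 256L), n_cells = 16L, rng_seed = 402L)
  args[names(list(...))] <- list(...)
  do.call(simulation_config, args)
}
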
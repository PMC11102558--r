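# Synthetic confluent-monolayer image generator. Emulates a single-channel
# fluorescence micrograph of an endothelial monolayer: a Voronoi
# tessellation of the field into convex cells, a bright ridge with
# Gaussian cross-section along shared cell borders, contiguous gaps of
# known total fraction (the ground truth for discontinuity), a smooth
# uneven-illumination background, and additive noise -- all reproducible
# from a single seed.

#' Simulation configuration
#'
#' Parameters of one synthetic monolayer image. Defaults describe a
#' confluent field of about 60 cells at 512 x 512 px with a bright,
#' narrow junction ridge, moderate shading and noise; with them the
#' junction peak plus illumination cannot saturate the 8-bit range by
#' construction.
#'
#' @param image_size `(height, width)` in pixels, each >= 128.
#' @param n_cells Number of cells tiling the field, >= 4.
#' @param gap_fraction Fraction of total junction length removed as gaps,
#'   in \[0, 1).
#' @param junction_width_sigma Gaussian cross-section sigma of the
#'   junction ridge, pixels.
#' @param junction_peak_intensity Ridge peak, 0-255.
#' @param noise_sigma Additive Gaussian noise standard deviation,
#'   intensity units.
#' @param illumination_amplitude Amplitude of the smooth low-frequency
#'   background, intensity units;
#'   `junction_peak_intensity + illumination_amplitude` must be <= 255.
#' @param gap_length_pixels Typical contiguous gap run length, pixels.
#' @param elongation Anisotropy of the tessellation metric (> 1 elongates
#'   cells horizontally, mimicking inflammation-induced cell elongation);
#'   default 1 (off).
#' @param lloyd_iterations Lloyd (centroidal Voronoi) relaxation steps
#'   applied to the seed points; default 2. Confluent monolayers have
#'   compact, roughly isotropic cells without needle-thin corners, which
#'   is what relaxation produces.
#' @param rng_seed Integer seed; identical configs reproduce images
#'   bit-exactly.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(image_size = c(512L, 512L), n_cells = 60L,
                              gap_fraction = 0, junction_width_sigma = 1.5,
                              junction_peak_intensity = 180L, noise_sigma = 8,
                              illumination_amplitude = 40,
                              gap_length_pixels = 12L, elongation = 1,
                              lloyd_iterations = 2L, rng_seed = 1L) {
  if (length(image_size) != 2 || any(image_size < 128)) {
    stop_field("image_size", "must be (height, width) with each >= 128")
  }
  if (length(n_cells) != 1 || n_cells < 4) {
    stop_field("n_cells", "must be a single integer >= 4")
  }
  if (length(gap_fraction) != 1 || gap_fraction < 0 || gap_fraction >= 1) {
    stop_field("gap_fraction", "must lie in [0, 1)")
  }
  if (junction_width_sigma <= 0) {
    stop_field("junction_width_sigma", "must be > 0")
  }
  if (junction_peak_intensity < 1 || junction_peak_intensity > 255) {
    stop_field("junction_peak_intensity", "must lie in [1, 255]")
  }
  if (noise_sigma < 0) stop_field("noise_sigma", "must be >= 0")
  if (illumination_amplitude < 0) {
    stop_field("illumination_amplitude", "must be >= 0")
  }
  if (junction_peak_intensity + illumination_amplitude > 255) {
    stop_field("illumination_amplitude",
               "junction_peak_intensity + illumination_amplitude must be <= 255")
  }
  if (gap_length_pixels < 1) stop_field("gap_length_pixels", "must be >= 1")
  if (elongation <= 0) stop_field("elongation", "must be > 0")
  if (lloyd_iterations < 0) stop_field("lloyd_iterations", "must be >= 0")
  structure(
    list(image_size = as.integer(image_size), n_cells = as.integer(n_cells),
         gap_fraction = gap_fraction,
         junction_width_sigma = junction_width_sigma,
         junction_peak_intensity = as.integer(junction_peak_intensity),
         noise_sigma = noise_sigma,
         illumination_amplitude = illumination_amplitude,
         gap_length_pixels = as.integer(gap_length_pixels),
         elongation = elongation,
         lloyd_iterations = as.integer(lloyd_iterations),
         rng_seed = as.integer(rng_seed)),
    class = "simulation_config"
  )
}

# Uniform seed points with a minimum-separation rejection rule, so cells
# look confluent and convex rather than clustered.
sample_seed_points <- function(H, W, n, elongation) {
  min_sep <- 0.55 * sqrt(H * W / n)
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 4000L * n) {
    tries <- tries + 1L
    cand <- c(runif(1, 1, H), runif(1, 1, W))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 +
                 ((pts[, 2] - cand[2]) / elongation)^2)) >= min_sep) {
      pts <- rbind(pts, cand)
    }
  }
  if (nrow(pts) < n) {  # dense request: fill remaining without the rule
    extra <- n - nrow(pts)
    pts <- rbind(pts, cbind(runif(extra, 1, H), runif(extra, 1, W)))
  }
  dimnames(pts) <- NULL
  pts
}

# Delete contiguous runs along ordered edge polylines until the requested
# fraction of junction pixels is gapped. `edge_of` groups junction pixels
# by the unordered pair of adjacent cells; pixels within an edge are
# ordered by projection on the edge direction so runs are geometric gaps,
# not scattered pixels.
place_gaps <- function(junction_idx, edge_order, gap_fraction, gap_length,
                       cell_of_pixel) {
  L <- length(junction_idx)
  target <- round(gap_fraction * L)
  gapped <- logical(L)
  if (target == 0) return(gapped)
  edges <- unique(edge_order$edge)
  edge_lengths <- tabulate(match(edge_order$edge, edges))
  guard <- 0L
  while (sum(gapped) < target && guard < 50L * L) {
    guard <- guard + 1L
    e <- sample.int(length(edges), 1, prob = edge_lengths)
    members <- which(edge_order$edge == edges[e])
    ne <- length(members)
    run <- max(3L, rpois(1, gap_length))
    start <- sample.int(ne, 1)
    sel <- members[start:min(ne, start + run - 1L)]
    gapped[sel] <- TRUE
  }
  # safeguard: no cell's border may be entirely gap (a fully erased cell
  # is not a plausible monolayer phenotype below gap_fraction 1)
  for (cell in unique(c(cell_of_pixel$a, cell_of_pixel$b))) {
    mine <- which(cell_of_pixel$a == cell | cell_of_pixel$b == cell)
    if (length(mine) > 0 && all(gapped[mine])) {
      keep <- mine[seq_len(min(length(mine), max(gap_length, 5L)))]
      gapped[keep] <- FALSE
    }
  }
  gapped
}

# A tessellation is border-clean when every cell either keeps out of the
# 8-pixel frame zone entirely or touches the frame itself with at least 12
# pixels of solid contact. Interior cells are then at least 8 px clear of
# the frame, so border-ness of a traced outline can be decided from frame
# proximity without ambiguity.
tessellation_border_clean <- function(label_map, n_cells) {
  H <- nrow(label_map); W <- ncol(label_map)
  on_frame <- tabulate(c(label_map[1, ], label_map[H, ],
                         label_map[, 1], label_map[, W]), nbins = n_cells)
  zone <- c(label_map[1:8, ], label_map[(H - 7):H, ],
            label_map[, 1:8], label_map[, (W - 7):W])
  in_zone <- tabulate(zone, nbins = n_cells)
  all(in_zone == 0 | on_frame >= 12)
}

# Smooth low-frequency illumination field in [0, 1]: a random corner ramp
# plus a broad radial blob.
illumination_field <- function(H, W) {
  corners <- runif(4)
  r <- (seq_len(H) - 1) / (H - 1)
  cc <- (seq_len(W) - 1) / (W - 1)
  ramp <- outer(1 - r, 1 - cc) * corners[1] + outer(1 - r, cc) * corners[2] +
    outer(r, 1 - cc) * corners[3] + outer(r, cc) * corners[4]
  cr <- runif(1, 0.2, 0.8) * H
  ccen <- runif(1, 0.2, 0.8) * W
  sig <- 0.5 * max(H, W)
  blob <- exp(-(outer((seq_len(H) - cr)^2, (seq_len(W) - ccen)^2, "+")) /
                (2 * sig^2))
  f <- 0.5 * ramp + 0.5 * blob
  rng <- range(f)
  if (diff(rng) == 0) f * 0 else (f - rng[1]) / diff(rng)
}

#' Generate one synthetic monolayer image with ground truth
#'
#' Builds the image as: Voronoi tessellation of seed points (with a
#' minimum-separation rejection rule) -> shared borders rasterized as the
#' junction mask -> contiguous runs deleted until the requested gap
#' fraction is realized -> ridge rendered as a Gaussian profile of the
#' distance to the remaining junction -> smooth illumination added ->
#' Gaussian noise added -> clipped to \[0, 255\] and quantized. Identical
#' configurations (including the seed) reproduce the image bit-exactly.
#'
#' @param config A [simulation_config()].
#' @param image_id,group_label Identity recorded on the image channel.
#' @return List with `image` (an [image_channel()]) and `truth` (a
#'   `monolayer_truth`: `seed_points`, `cell_label_map`, `junction_mask`,
#'   `gap_mask`, `per_cell_gap_fraction`, `border_cells`,
#'   `realized_gap_fraction`, `rng_seed`).
#' @export
generate_monolayer <- function(config, image_id = "synthetic",
                               group_label = NA_character_) {
  stopifnot(inherits(config, "simulation_config"))
  H <- config$image_size[1]
  W <- config$image_size[2]
  withr::with_seed(config$rng_seed, {
    # resample tessellations in which some cell only grazes the frame:
    # a cell must either stay clear of the border zone or sit solidly on
    # the frame, otherwise "touches the border" is ambiguous at the pixel
    # level (for the truth and the tracing alike)
    for (attempt in 1:25) {
      pts <- sample_seed_points(H, W, config$n_cells, config$elongation)
      for (it in seq_len(config$lloyd_iterations)) {
        nn <- cpp_nearest_two(pts[, 1], pts[, 2], H, W, config$elongation)
        for (k in seq_len(config$n_cells)) {
          reg <- which(nn$label1 == k, arr.ind = TRUE)
          if (nrow(reg) > 0) pts[k, ] <- colMeans(reg)
        }
      }
      nn <- cpp_nearest_two(pts[, 1], pts[, 2], H, W, config$elongation)
      if (tessellation_border_clean(nn$label1, config$n_cells)) break
    }
    label_map <- nn$label1
    junction_mask <- (nn$dist2 - nn$dist1) < 1.0
    jidx <- which(junction_mask)
    a <- pmin(nn$label1[jidx], nn$label2[jidx])
    b <- pmax(nn$label1[jidx], nn$label2[jidx])
    edge <- paste(a, b, sep = "-")
    # order pixels within each edge by projection on the edge tangent
    rc <- arrayInd(jidx, c(H, W))
    ord <- order(edge, {
      ta <- pts[a, , drop = FALSE]
      tb <- pts[b, , drop = FALSE]
      # tangent of the perpendicular bisector between the two seeds
      tx <- -(tb[, 2] - ta[, 2])
      ty <- tb[, 1] - ta[, 1]
      (rc[, 1] * tx + rc[, 2] * ty) / sqrt(tx^2 + ty^2)
    })
    jidx <- jidx[ord]
    edge <- edge[ord]
    a <- a[ord]
    b <- b[ord]
    gapped <- place_gaps(jidx, data.frame(edge = edge),
                         config$gap_fraction, config$gap_length_pixels,
                         data.frame(a = a, b = b))
    gap_mask <- matrix(FALSE, H, W)
    gap_mask[jidx[gapped]] <- TRUE
    kept <- matrix(FALSE, H, W)
    kept[jidx[!gapped]] <- TRUE
    # ridge: Gaussian profile of distance to the nearest kept junction pixel
    ridge <- matrix(0, H, W)
    if (any(kept)) {
      d <- EBImage::distmap(matrix(as.numeric(!kept), H, W), metric = "euclidean")
      d <- matrix(as.numeric(d), H, W)
      ridge <- config$junction_peak_intensity *
        exp(-d^2 / (2 * config$junction_width_sigma^2))
    }
    illum <- if (config$illumination_amplitude > 0) {
      config$illumination_amplitude * illumination_field(H, W)
    } else 0
    noise <- if (config$noise_sigma > 0) {
      matrix(rnorm(H * W, 0, config$noise_sigma), H, W)
    } else 0
    px <- clip8(ridge + illum + noise)
    # per-cell truth
    per_cell <- vapply(seq_len(config$n_cells), function(cell) {
      mine <- a == cell | b == cell
      if (!any(mine)) return(NA_real_)
      mean(gapped[mine])
    }, numeric(1))
    border_cells <- sort(unique(c(label_map[1, ], label_map[H, ],
                                  label_map[, 1], label_map[, W])))
    truth <- structure(
      list(seed_points = pts, cell_label_map = label_map,
           junction_mask = junction_mask, gap_mask = gap_mask,
           per_cell_gap_fraction = per_cell, border_cells = border_cells,
           realized_gap_fraction = if (length(jidx)) mean(gapped) else 0,
           rng_seed = config$rng_seed),
      class = "monolayer_truth"
    )
    list(image = image_channel(px, image_id = image_id,
                               group_label = group_label),
         truth = truth)
  })
}

#' @export
print.monolayer_truth <- function(x, ...) {
  cat(sprintf("<monolayer_truth> %d x %d px, %d cells (%d at border), gap fraction %.3f\n",
              nrow(x$cell_label_map), ncol(x$cell_label_map),
              nrow(x$seed_points), length(x$border_cells),
              x$realized_gap_fraction))
  invisible(x)
}

#' Generate a panel of images across conditions
#'
#' One independent image per (group, replicate), with per-replicate seeds
#' derived deterministically from the base configuration's seed.
#'
#' @param base_config A [simulation_config()]; its `gap_fraction` is
#'   overridden per group.
#' @param group_gap_fractions Named numeric vector or list mapping group
#'   label to true gap fraction.
#' @param images_per_group Number of replicate images per group, >= 1.
#' @return A list of entries, each with `group`, `image`, `truth`, `seed`;
#'   the derived seeds are also attached as attribute `seeds`.
#' @export
generate_condition_panel <- function(base_config, group_gap_fractions,
                                     images_per_group = 4L) {
  stopifnot(inherits(base_config, "simulation_config"))
  group_gap_fractions <- unlist(group_gap_fractions)
  if (length(group_gap_fractions) == 0) {
    stop("group mapping must not be empty", call. = FALSE)
  }
  if (is.null(names(group_gap_fractions)) ||
      any(names(group_gap_fractions) == "")) {
    stop("group gap fractions must be named by group label", call. = FALSE)
  }
  if (images_per_group < 1) {
    stop_field("images_per_group", "must be >= 1")
  }
  n_total <- length(group_gap_fractions) * images_per_group
  seeds <- withr::with_seed(base_config$rng_seed,
                            sample.int(.Machine$integer.max - 1L, n_total))
  entries <- vector("list", n_total)
  i <- 0L
  for (g in names(group_gap_fractions)) {
    for (rep in seq_len(images_per_group)) {
      i <- i + 1L
      args <- unclass(base_config)
      args$gap_fraction <- unname(group_gap_fractions[[g]])
      args$rng_seed <- seeds[i]
      cfg <- do.call(simulation_config, args)
      id <- sprintf("%s_%02d", g, rep)
      out <- generate_monolayer(cfg, image_id = id, group_label = g)
      entries[[i]] <- list(group = g, image = out$image, truth = out$truth,
                           seed = seeds[i])
    }
  }
  attr(entries, "seeds") <- seeds
  entries
}

#' Write a generated panel to disk
#'
#' Writes one 8-bit TIFF and one truth JSON (masks run-length encoded)
#' per image, plus a panel-level CSV manifest with columns `group`,
#' `image_path`, `truth_path`, `seed`, ready for [run_pipeline()].
#'
#' @param panel Output of [generate_condition_panel()].
#' @param output_dir Directory to create/fill.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_panel <- function(panel, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(panel, function(e) {
    img_path <- file.path(output_dir, paste0(e$image$image_id, ".tif"))
    truth_path <- file.path(output_dir, paste0(e$image$image_id, "_truth.json"))
    write_image_channel(e$image, img_path)
    write_truth_json(e$truth, truth_path)
    data.frame(group = e$group, image_path = img_path,
               truth_path = truth_path, seed = e$seed,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(output_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Write ground truth as JSON
#'
#' @param truth A `monolayer_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "monolayer_truth"))
  obj <- list(
    seed_points = truth$seed_points,
    cell_label_map = rle_encode_int(truth$cell_label_map),
    junction_mask = rle_encode_mask(truth$junction_mask),
    gap_mask = rle_encode_mask(truth$gap_mask),
    per_cell_gap_fraction = truth$per_cell_gap_fraction,
    border_cells = truth$border_cells,
    realized_gap_fraction = truth$realized_gap_fraction,
    rng_seed = truth$rng_seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read ground truth written by [write_truth_json()]
#'
#' @param path JSON path.
#' @return A `monolayer_truth`.
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(seed_points = matrix(unlist(obj$seed_points), ncol = 2,
                              byrow = !is.matrix(obj$seed_points)),
         cell_label_map = rle_decode_int(obj$cell_label_map),
         junction_mask = rle_decode_mask(obj$junction_mask),
         gap_mask = rle_decode_mask(obj$gap_mask),
         per_cell_gap_fraction = as.numeric(obj$per_cell_gap_fraction),
         border_cells = as.integer(obj$border_cells),
         realized_gap_fraction = as.numeric(obj$realized_gap_fraction),
         rng_seed = as.integer(obj$rng_seed)),
    class = "monolayer_truth"
  )
}
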
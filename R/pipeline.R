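# Batch orchestration: manifest-driven runs of the full two-track
# pipeline, simulation of ready-to-run panels, and closing the loop
# between generator truth and pipeline output.

#' Pipeline configuration
#'
#' All image-processing parameters in one validated object. The defaults
#' are the published recipe: rolling-ball radius 20, Gaussian sigma 2.0
#' applied twice, binary dilation twice, fixed 21-255 scoring threshold,
#' 25 cells sampled per image.
#'
#' @param manifest_path CSV manifest with columns `group`, `image_path`
#'   (optionally `truth_path`).
#' @param output_dir Directory for all artifacts (created if needed).
#' @param rolling_radius Rolling-ball radius, pixels; default 20.
#' @param blur_sigma Gaussian sigma, pixels; default 2.0.
#' @param blur_passes Blur repetitions; default 2.
#' @param dilate_iterations Binary dilation repetitions; default 2.
#' @param bridge_max Endpoint bridging distance, pixels; default 10.
#' @param threshold_low Lower scoring threshold (inclusive, 8-bit);
#'   default 21.
#' @param cells_per_image Outlines sampled per image; default 25.
#' @param rng_seed Base seed for all per-image sampling; default 1.
#' @param channel_index 1-based channel for multi-channel TIFFs; default 1.
#' @param auto_rescale Min-max rescale non-8-bit inputs (logged) instead
#'   of rejecting them; default `FALSE`.
#' @param write_overlays Write QC overlay PNGs per image; default `FALSE`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path, output_dir,
                            rolling_radius = 20, blur_sigma = 2.0,
                            blur_passes = 2L, dilate_iterations = 2L,
                            bridge_max = 10, threshold_low = 21L,
                            cells_per_image = 25L, rng_seed = 1L,
                            channel_index = 1L, auto_rescale = FALSE,
                            write_overlays = FALSE) {
  if (rolling_radius < 1) stop_field("rolling_radius", "must be >= 1")
  if (blur_sigma <= 0) stop_field("blur_sigma", "must be > 0")
  if (blur_passes < 1) stop_field("blur_passes", "must be >= 1")
  if (dilate_iterations < 0) stop_field("dilate_iterations", "must be >= 0")
  if (bridge_max < 0) stop_field("bridge_max", "must be >= 0")
  if (threshold_low < 0 || threshold_low > 255) {
    stop_field("threshold_low", "must lie in [0, 255]")
  }
  if (cells_per_image < 1) stop_field("cells_per_image", "must be >= 1")
  structure(
    list(manifest_path = manifest_path, output_dir = output_dir,
         rolling_radius = rolling_radius, blur_sigma = blur_sigma,
         blur_passes = as.integer(blur_passes),
         dilate_iterations = as.integer(dilate_iterations),
         bridge_max = bridge_max, threshold_low = as.integer(threshold_low),
         cells_per_image = as.integer(cells_per_image),
         rng_seed = as.integer(rng_seed),
         channel_index = as.integer(channel_index),
         auto_rescale = isTRUE(auto_rescale),
         write_overlays = isTRUE(write_overlays)),
    class = "pipeline_config"
  )
}

read_manifest <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("manifest not found: %s", path), call. = FALSE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("group", "image_path") %in% names(m))) {
    stop("manifest must have columns `group` and `image_path`", call. = FALSE)
  }
  if (nrow(m) == 0) stop("manifest is empty", call. = FALSE)
  missing <- m$image_path[!file.exists(m$image_path)]
  if (length(missing)) {
    stop(sprintf("manifest references missing image file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  m
}

#' Run the discontinuity pipeline over a manifest of images
#'
#' For every image: the geometry track traces and samples cell outlines,
#' the scoring track builds the fixed-threshold junction mask (the two
#' tracks share only the raw channel and the background-subtraction
#' step), and per-cell discontinuity records are written to a pooled tidy
#' CSV. When at least two groups are present a Kruskal-Wallis comparison
#' with box summaries is written as JSON (and a box-plot PNG). Per-image
#' provenance JSONs and a run log with per-stage counts and timings are
#' always written. Reruns with an identical configuration reproduce the
#' CSV byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `records`, `comparison` (or `NULL`),
#'   `per_image` summary, and output file paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- read_manifest(config$manifest_path)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- config_hash(unclass(config))
  log_lines <- c(sprintf("run started: config hash %s", chash),
                 sprintf("parameters: %s",
                         jsonlite::toJSON(unclass(config), auto_unbox = TRUE)))
  image_seeds <- withr::with_seed(config$rng_seed,
                                  sample.int(.Machine$integer.max - 1L,
                                             nrow(manifest)))
  all_records <- list()
  for (i in seq_len(nrow(manifest))) {
    t0 <- proc.time()[["elapsed"]]
    img <- read_image_channel(manifest$image_path[i],
                              group_label = manifest$group[i],
                              channel = config$channel_index,
                              auto_rescale = config$auto_rescale)
    tr <- trace_cell_outlines(img,
                              rolling_radius = config$rolling_radius,
                              blur_sigma = config$blur_sigma,
                              blur_passes = config$blur_passes,
                              dilate_iterations = config$dilate_iterations,
                              bridge_max = config$bridge_max)
    n_found <- length(tr$outlines)
    n_eligible <- sum(!vapply(tr$outlines, function(o) o$touches_border,
                              logical(1)))
    sel_warn <- NA_character_
    selected <- withCallingHandlers(
      select_outlines(tr$outlines, k = config$cells_per_image,
                      rng_seed = image_seeds[i]),
      warning = function(w) {
        sel_warn <<- conditionMessage(w)
        invokeRestart("muffleWarning")
      }
    )
    mask <- junction_binary_mask(tr$background_subtracted, subtract = FALSE,
                                 threshold_low = config$threshold_low)
    mask$source_image_id <- img$image_id
    rec <- score_image(img, selected, mask = mask)
    all_records[[i]] <- rec
    prov <- list(image_id = img$image_id, group = manifest$group[i],
                 config_hash = chash,
                 operators = tr$provenance,
                 scoring = sprintf("junction_binary_mask(threshold=%d-255) on background-subtracted raw",
                                   config$threshold_low),
                 huang_threshold = tr$threshold,
                 selection_seed = image_seeds[i],
                 outlines_found = n_found, outlines_eligible = n_eligible,
                 outlines_selected = length(selected),
                 warning = sel_warn)
    jsonlite::write_json(prov,
                         file.path(config$output_dir,
                                   paste0(img$image_id, "_provenance.json")),
                         auto_unbox = TRUE, digits = NA, na = "null")
    if (config$write_overlays) {
      write_overlay(img, tr$outlines, selected,
                    file.path(config$output_dir,
                              paste0(img$image_id, "_overlay.png")))
    }
    dt <- proc.time()[["elapsed"]] - t0
    log_lines <- c(log_lines,
                   sprintf("%s: %d outlines (%d eligible, %d selected), huang=%d, %.1fs%s",
                           img$image_id, n_found, n_eligible, length(selected),
                           tr$threshold, dt,
                           if (is.na(sel_warn)) "" else paste0(" [", sel_warn, "]")))
  }
  records <- do.call(rbind, all_records)
  csv_path <- file.path(config$output_dir, "discontinuity_records.csv")
  utils::write.csv(records, csv_path, row.names = FALSE)
  per_image <- summarize_by_image(records)
  per_image_path <- file.path(config$output_dir, "per_image_summary.csv")
  utils::write.csv(per_image, per_image_path, row.names = FALSE)
  comparison <- NULL
  report_path <- NULL
  groups <- split(records$ratio_percent, records$group_label)
  if (length(groups) >= 2) {
    comparison <- kruskal_wallis(groups)
    report_path <- file.path(config$output_dir, "group_comparison.json")
    jsonlite::write_json(
      list(config_hash = chash,
           test = "Kruskal-Wallis rank sum test",
           H_statistic = comparison$H_statistic, df = comparison$df,
           p_value = comparison$p_value,
           note = "unit of analysis is the cell; cells within an image are not independent",
           group_summaries = comparison$group_summaries),
      report_path, auto_unbox = TRUE, digits = NA)
    boxplot_path <- file.path(config$output_dir, "group_boxplot.png")
    try(plot_group_boxplot(comparison, boxplot_path), silent = TRUE)
  }
  log_lines <- c(log_lines, sprintf("wrote %d records to %s", nrow(records),
                                    csv_path))
  writeLines(log_lines, file.path(config$output_dir, "run_log.txt"))
  invisible(list(records = records, comparison = comparison,
                 per_image = per_image,
                 files = list(records_csv = csv_path,
                              per_image_csv = per_image_path,
                              report_json = report_path)))
}

# QC overlay: raw image with all traced outlines (gray) and the selected
# subset (white).
write_overlay <- function(img, outlines, selected, path) {
  H <- nrow(img$pixels); W <- ncol(img$pixels)
  rgb <- array(rep(img$pixels / 255, 3), dim = c(H, W, 3))
  paint <- function(rgb, outline, col) {
    p <- outline$path
    for (ch in 1:3) rgb[cbind(p, ch)] <- col[ch]
    rgb
  }
  for (o in outlines) rgb <- paint(rgb, o, c(0.55, 0.55, 0.55))
  for (o in selected) rgb <- paint(rgb, o, c(1, 1, 0.2))
  grDevices::png(path, width = W, height = H)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::rasterImage(rgb, 0, 0, 1, 1)
  invisible(path)
}

#' Simulate a panel from a YAML configuration file
#'
#' Reads a flat YAML file describing the simulation (any
#' [simulation_config()] field, plus `groups`, a mapping from group label
#' to gap fraction, and `images_per_group`), generates the panel, and
#' writes images, truths and a manifest ready for [run_pipeline()].
#'
#' @param sim_config_path YAML file path.
#' @param output_dir Output directory.
#' @return Path of the written manifest CSV, invisibly.
#' @export
simulate_command <- function(sim_config_path, output_dir) {
  if (!file.exists(sim_config_path)) {
    stop(sprintf("simulation config not found: %s", sim_config_path),
         call. = FALSE)
  }
  y <- yaml::read_yaml(sim_config_path)
  if (is.null(y$groups) || length(y$groups) == 0) {
    stop_field("groups", "must map at least one group label to a gap fraction")
  }
  images_per_group <- if (is.null(y$images_per_group)) 4L else
    as.integer(y$images_per_group)
  sim_fields <- intersect(names(y), names(formals(simulation_config)))
  base <- do.call(simulation_config, y[sim_fields])
  panel <- generate_condition_panel(base, y$groups, images_per_group)
  write_panel(panel, output_dir)
}

#' Validate pipeline output against generator ground truth
#'
#' Joins per-image measured discontinuity (mean over cells) with the
#' realized true gap fraction from the truth JSONs, reports the Spearman
#' correlation between truth and measurement and whether group-mean
#' measurement is strictly increasing in truth.
#'
#' @param results_csv The pipeline's `discontinuity_records.csv`.
#' @param truth_dir Directory containing `<image_id>_truth.json` files
#'   for the same panel.
#' @return A list with `per_image` (data frame: `image_id`, `group_label`,
#'   `true_gap_fraction`, `mean_ratio_percent`), `spearman_rho` (`NA` when
#'   fewer than 2 images), and `monotone` (verdict over condition means).
#' @export
validate_recovery <- function(results_csv, truth_dir) {
  records <- utils::read.csv(results_csv, stringsAsFactors = FALSE)
  per_image <- summarize_by_image(records)
  truth_files <- list.files(truth_dir, pattern = "_truth\\.json$",
                            full.names = TRUE)
  truth_ids <- sub("_truth\\.json$", "", basename(truth_files))
  orphans_res <- setdiff(per_image$image_id, truth_ids)
  orphans_truth <- setdiff(truth_ids, per_image$image_id)
  if (length(orphans_res) || length(orphans_truth)) {
    stop(sprintf("image IDs do not match between results and truth; orphans: %s",
                 paste(c(orphans_res, orphans_truth), collapse = ", ")),
         call. = FALSE)
  }
  truth_gap <- vapply(truth_files, function(f) {
    read_truth_json(f)$realized_gap_fraction
  }, numeric(1))
  names(truth_gap) <- truth_ids
  per_image$true_gap_fraction <- unname(truth_gap[per_image$image_id])
  rho <- if (nrow(per_image) >= 2 &&
             stats::sd(per_image$true_gap_fraction) > 0 &&
             stats::sd(per_image$mean_ratio_percent) > 0) {
    stats::cor(per_image$true_gap_fraction, per_image$mean_ratio_percent,
               method = "spearman")
  } else NA_real_
  grp_truth <- tapply(per_image$true_gap_fraction, per_image$group_label, mean)
  cond_means <- tapply(per_image$mean_ratio_percent, per_image$group_label, mean)
  cond_means <- cond_means[order(grp_truth)]
  monotone <- length(cond_means) >= 2 && all(diff(cond_means) > 0)
  list(per_image = per_image[, c("image_id", "group_label",
                                 "true_gap_fraction", "mean_ratio_percent")],
       condition_means = cond_means,
       spearman_rho = rho, monotone = monotone)
}
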
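# Group-level statistics for discontinuity records and TEER utilities.

#' Kruskal-Wallis comparison of per-group discontinuity ratios
#'
#' Rank-based H with tie correction and a p value from the chi-squared
#' approximation on (groups - 1) degrees of freedom, plus per-group box
#' summaries (n, median, quartiles, min, max) computed with
#' linear-interpolation quantiles. The unit of analysis is the cell:
#' records from all images of a group are pooled. Cells within an image
#' are not independent, so per-image aggregation (see
#' [summarize_by_image()]) is the conservative companion view.
#'
#' @param per_group_ratios Named list mapping group label to a numeric
#'   vector of per-cell discontinuity ratios (at least 2 groups, each
#'   non-empty).
#' @return A `group_comparison`: list with `group_labels`,
#'   `per_group_ratios`, `H_statistic`, `p_value`, `df`, and a
#'   `group_summaries` data frame.
#' @examples
#' kruskal_wallis(list(ctrl = c(1, 2, 3), tnf = c(10, 11, 12)))
#' @export
kruskal_wallis <- function(per_group_ratios) {
  if (!is.list(per_group_ratios) || length(per_group_ratios) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  if (is.null(names(per_group_ratios)) || any(names(per_group_ratios) == "")) {
    stop("groups must be named", call. = FALSE)
  }
  sizes <- lengths(per_group_ratios)
  if (any(sizes < 1)) stop("every group needs at least 1 value", call. = FALSE)
  kt <- stats::kruskal.test(per_group_ratios)
  H <- unname(kt$statistic)
  p <- kt$p.value
  if (is.nan(H)) {  # all pooled values identical: no evidence of difference
    H <- 0
    p <- 1
  }
  summaries <- do.call(rbind, lapply(names(per_group_ratios), function(g) {
    v <- per_group_ratios[[g]]
    q <- unname(stats::quantile(v, c(0.25, 0.5, 0.75), type = 7))
    data.frame(group = g, n = length(v), min = min(v), q1 = q[1],
               median = q[2], q3 = q[3], max = max(v),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(group_labels = names(per_group_ratios),
         per_group_ratios = per_group_ratios,
         H_statistic = H, p_value = p,
         df = length(per_group_ratios) - 1L,
         group_summaries = summaries),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> Kruskal-Wallis H = %.4f, df = %d, p = %.4g\n",
              x$H_statistic, x$df, x$p_value))
  print(x$group_summaries, row.names = FALSE)
  invisible(x)
}

#' Per-image aggregation of discontinuity records
#'
#' Mean per-cell ratio within each image. Exported alongside the pooled
#' per-cell analysis because cells within one image share acquisition
#' conditions and are not independent observations.
#'
#' @param records Data frame of discontinuity records (from
#'   [score_image()] or the pipeline CSV).
#' @return Data frame with columns `group_label`, `image_id`, `n_cells`,
#'   `mean_ratio_percent`.
#' @export
summarize_by_image <- function(records) {
  stopifnot(all(c("image_id", "group_label", "ratio_percent") %in% names(records)))
  agg <- stats::aggregate(ratio_percent ~ group_label + image_id, data = records,
                          FUN = mean)
  n <- stats::aggregate(ratio_percent ~ group_label + image_id, data = records,
                        FUN = length)
  out <- data.frame(group_label = agg$group_label, image_id = agg$image_id,
                    n_cells = n$ratio_percent,
                    mean_ratio_percent = agg$ratio_percent,
                    stringsAsFactors = FALSE)
  out[order(out$group_label, out$image_id), , drop = FALSE]
}

#' Compute TEER from raw and blank resistances
#'
#' `(resistance of experimental wells - resistance of blank wells) *
#' area_factor`, with the 0.32 cm^2 membrane area of the cell-culture
#' insert as the default factor. Vectorized over readings.
#'
#' @param raw_resistance Resistances of experimental wells, ohm.
#' @param blank_resistance Resistances of blank wells, ohm (recycled).
#' @param area_factor Membrane area in cm^2; default 0.32.
#' @return TEER in ohm * cm^2.
#' @examples
#' compute_teer(100, 10)  # 28.8
#' @export
compute_teer <- function(raw_resistance, blank_resistance, area_factor = 0.32) {
  if (any(blank_resistance < 0)) {
    stop_field("blank_resistance", "must be >= 0")
  }
  if (any(raw_resistance < blank_resistance)) {
    stop("raw resistance below blank resistance: check well/blank labeling",
         call. = FALSE)
  }
  (raw_resistance - blank_resistance) * area_factor
}

#' Construct a TEER time series
#'
#' Blank-corrects and area-normalizes a series of resistance readings.
#'
#' @param timepoints Time in hours.
#' @param raw_resistance,blank_resistance Readings in ohm (same length as
#'   `timepoints`).
#' @param area_factor Membrane area in cm^2; default 0.32.
#' @return A `teer_series`: list with `timepoints`, `raw_resistance`,
#'   `blank_resistance`, `area_factor`, `teer`, and (after
#'   [relative_teer()]) `relative_teer` and `baseline_time`.
#' @export
teer_series <- function(timepoints, raw_resistance, blank_resistance,
                        area_factor = 0.32) {
  n <- length(timepoints)
  if (length(raw_resistance) != n || length(blank_resistance) != n) {
    stop_field("raw_resistance", "lengths must match timepoints")
  }
  structure(
    list(timepoints = as.numeric(timepoints),
         raw_resistance = as.numeric(raw_resistance),
         blank_resistance = as.numeric(blank_resistance),
         area_factor = area_factor,
         teer = compute_teer(raw_resistance, blank_resistance, area_factor),
         relative_teer = NULL, baseline_time = NULL),
    class = "teer_series"
  )
}

#' @export
print.teer_series <- function(x, ...) {
  df <- data.frame(time_h = x$timepoints, teer_ohm_cm2 = x$teer)
  if (!is.null(x$relative_teer)) df$relative_teer <- x$relative_teer
  print(df, row.names = FALSE)
  invisible(x)
}

#' Normalize a TEER series to its pre-stimulation baseline
#'
#' Divides every TEER value by the TEER at `baseline_time`, so the
#' baseline entry equals 1. Invariant to any common rescaling of the
#' resistance readings.
#'
#' @param series A [teer_series()].
#' @param baseline_time Baseline timepoint (hours); must be present in the
#'   series with strictly positive TEER.
#' @return The series with `relative_teer` and `baseline_time` filled in.
#' @export
relative_teer <- function(series, baseline_time) {
  stopifnot(inherits(series, "teer_series"))
  i <- which(series$timepoints == baseline_time)
  if (length(i) != 1) {
    stop(sprintf("baseline_time %g not found among timepoints", baseline_time),
         call. = FALSE)
  }
  base <- series$teer[i]
  if (base <= 0) {
    stop("TEER at baseline must be > 0 for normalization", call. = FALSE)
  }
  series$relative_teer <- series$teer / base
  series$baseline_time <- baseline_time
  series
}

#' Read a TEER assay CSV
#'
#' Expects columns `time_h`, `resistance_ohm`, `blank_ohm`.
#'
#' @param path CSV path.
#' @param area_factor Membrane area in cm^2; default 0.32.
#' @return A [teer_series()].
#' @export
read_teer_csv <- function(path, area_factor = 0.32) {
  df <- utils::read.csv(path)
  need <- c("time_h", "resistance_ohm", "blank_ohm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("TEER CSV is missing columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  }
  teer_series(df$time_h, df$resistance_ohm, df$blank_ohm, area_factor)
}

#' Box plot of per-group discontinuity ratios
#'
#' Writes a PNG box plot (first, second, third quartiles; whiskers at
#' min/max, matching the reported summaries).
#'
#' @param comparison A `group_comparison` from [kruskal_wallis()].
#' @param file Output PNG path.
#' @return `file`, invisibly.
#' @export
plot_group_boxplot <- function(comparison, file) {
  stopifnot(inherits(comparison, "group_comparison"))
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::boxplot(comparison$per_group_ratios, range = 0,
                    ylab = "junction discontinuity (%)",
                    main = sprintf("Kruskal-Wallis H = %.2f, p = %.3g",
                                   comparison$H_statistic, comparison$p_value))
  invisible(file)
}
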
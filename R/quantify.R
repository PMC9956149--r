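#' Experiment-wide median size calibration
#'
#' Converts areas into object counts via the median size adjustment: cell and
#' aggregate component areas are pooled over every frame of an experiment
#' (all conditions, all time points) and their medians become the reference
#' object sizes. Counting a frame then divides its total thresholded areas by
#' these medians ([quantify_frame()]). The calibration is computed once per
#' experiment and shared across all of its frames. For even-length pools the
#' median is the midpoint of the two central values.
#'
#' @param results List of `fq_seg` segmentation results (one per frame), or a
#'   single `fq_seg`.
#'
#' @return An object of class `fq_calibration` with `median_cell_area`,
#'   `median_aggregate_area` (`NA` when no aggregate component exists
#'   anywhere in the experiment), and `n_frames_pooled`.
#' @export
calibrate_medians <- function(results) {
  if (inherits(results, "fq_seg")) results <- list(results)
  if (length(results) == 0L)
    stop("no segmentation results supplied", call. = FALSE)
  cell_areas <- unlist(lapply(results, `[[`, "cell_areas"))
  agg_areas <- unlist(lapply(results, `[[`, "aggregate_areas"))
  if (length(cell_areas) == 0L)
    stop("no cell components in any frame; cannot calibrate", call. = FALSE)
  structure(
    list(median_cell_area = stats::median(cell_areas),
         median_aggregate_area = if (length(agg_areas) > 0L)
           stats::median(agg_areas) else NA_real_,
         n_frames_pooled = length(results)),
    class = "fq_calibration")
}

#' @export
print.fq_calibration <- function(x, ...) {
  cat(sprintf(
    "<fq_calibration> median cell area %s px, median aggregate area %s px (%d frames)\n",
    format(x$median_cell_area),
    ifelse(is.na(x$median_aggregate_area), "NA", format(x$median_aggregate_area)),
    x$n_frames_pooled))
  invisible(x)
}

#' Median-adjusted counts and per-cell fluorescence for one frame
#'
#' Applies the median size adjustment: `cell_count` is the total cell area
#' divided by the experiment-wide median cell area, `aggregate_count` is the
#' total aggregate area divided by the median aggregate area, and
#' `aggregates_per_cell` is their ratio. Counts are retained as fractional
#' values (area-ratio counting is inherently fractional; downstream
#' statistics average them across replicates). `fluorescence_per_cell` is the
#' background-corrected total fluorescence over the cell mask divided by
#' `cell_count`. With no cells in the frame the per-cell quantities are
#' reported as missing (`NA`), not zero; with no aggregate anywhere in the
#' calibration the aggregate count is 0.
#'
#' @param seg An `fq_seg` from [segment_frame()].
#' @param calib An `fq_calibration` from [calibrate_medians()] computed on
#'   the frame's own experiment.
#'
#' @return A one-row `data.frame` with columns `time_h`, `condition`,
#'   `replicate`, `total_cell_area`, `total_aggregate_area`, `cell_count`,
#'   `aggregate_count`, `aggregates_per_cell`, `total_fluorescence`,
#'   `fluorescence_per_cell`, `threshold_used`, `k_sigma`.
#' @export
quantify_frame <- function(seg, calib) {
  stopifnot(inherits(seg, "fq_seg"), inherits(calib, "fq_calibration"))
  cell_count <- seg$total_cell_area / calib$median_cell_area
  aggregate_count <-
    if (seg$total_aggregate_area == 0) 0
    else if (is.na(calib$median_aggregate_area)) 0
    else seg$total_aggregate_area / calib$median_aggregate_area
  if (cell_count > 0) {
    apc <- aggregate_count / cell_count
    fpc <- seg$total_fluorescence / cell_count
  } else {
    apc <- NA_real_
    fpc <- NA_real_
    cell_count <- 0
  }
  data.frame(
    time_h = seg$time_h,
    condition = seg$condition,
    replicate = as.character(seg$replicate),
    total_cell_area = seg$total_cell_area,
    total_aggregate_area = seg$total_aggregate_area,
    cell_count = cell_count,
    aggregate_count = aggregate_count,
    aggregates_per_cell = apc,
    total_fluorescence = seg$total_fluorescence,
    fluorescence_per_cell = fpc,
    threshold_used = seg$threshold_used,
    k_sigma = seg$k_sigma,
    stringsAsFactors = FALSE)
}

#' Segment and quantify a whole experiment
#'
#' Segments every frame, pools the component areas into one experiment-wide
#' median calibration, and applies it to each frame.
#'
#' @param frames List of [frame()] objects belonging to one experiment.
#' @inheritParams segment_frame
#'
#' @return List with `quant` (a `data.frame`, one row per frame, see
#'   [quantify_frame()]), `calibration`, and `segmentations` (mask-free
#'   `fq_seg` objects).
#' @export
quantify_experiment <- function(frames, k_cell = 3, k_sigma = 18,
                                min_cell_area_px = 20L, min_agg_area_px = 2L,
                                stat_basis = c("cell", "pixel")) {
  stat_basis <- match.arg(stat_basis)
  segs <- lapply(frames, segment_frame, k_cell = k_cell, k_sigma = k_sigma,
                 min_cell_area_px = min_cell_area_px,
                 min_agg_area_px = min_agg_area_px, stat_basis = stat_basis,
                 keep_masks = FALSE)
  calib <- calibrate_medians(segs)
  quant <- do.call(rbind, lapply(segs, quantify_frame, calib = calib))
  rownames(quant) <- NULL
  list(quant = quant, calibration = calib, segmentations = segs)
}

#' Transfection efficiency from fluorescing-cell counts
#'
#' The fraction of transfected cells is estimated by counting visibly
#' fluorescing cells (the cell components found by [segment_cells()]) against
#' the known total number of cells in each field (for synthetic data, the
#' ground-truth sidecar; for real data, a brightfield count supplied by the
#' user).
#'
#' @param frames List of [frame()] objects (or a single frame).
#' @param total_cells Integer vector of total cells per frame. If missing,
#'   the function looks for a `ground_truth` attribute on each frame.
#' @inheritParams segment_cells
#' @param min_cell_area_px Minimum cell component area in pixels.
#'
#' @return List with `per_frame` (fraction per frame) and `mean`.
#' @export
transfection_efficiency <- function(frames, total_cells = NULL, k_cell = 3,
                                    min_cell_area_px = 20L) {
  if (inherits(frames, "fq_frame")) frames <- list(frames)
  if (is.null(total_cells)) {
    total_cells <- vapply(frames, function(f) {
      gt <- attr(f, "ground_truth")
      if (is.null(gt)) NA_integer_ else nrow(gt$cells)
    }, integer(1))
  }
  if (length(total_cells) != length(frames) || anyNA(total_cells))
    stop("total cell counts are required for every frame", call. = FALSE)
  fractions <- mapply(function(f, tot) {
    if (tot == 0L) return(NA_real_)
    bg <- estimate_background(f)
    cells <- segment_cells(f, bg$mean, bg$sd, k_cell = k_cell,
                           min_cell_area_px = min_cell_area_px)
    length(cells$areas) / tot
  }, frames, total_cells)
  list(per_frame = as.numeric(fractions), mean = mean(fractions, na.rm = TRUE))
}
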
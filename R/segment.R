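#' Label connected components of a binary mask (8-connectivity)
#'
#' Components are labelled with 8-connectivity (edge- and corner-adjacent
#' pixels belong to the same object). Labelling starts from the 4-connected
#' components returned by [EBImage::bwlabel()], then merges labels that touch
#' diagonally using a small union-find pass; labels are renumbered 1..K in
#' order of each component's first pixel (column-major).
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param min_area Minimum component area in pixels; smaller components are
#'   dropped from the mask (default 0 = keep all).
#'
#' @return A list with `labels` (integer matrix, 0 = background), `areas`
#'   (integer vector of component areas, index = label), and `mask` (logical
#'   matrix after the minimum-area filter).
#' @export
label_components <- function(mask, min_area = 0L) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  m <- if (is.logical(mask)) mask else mask != 0
  if (!any(m)) {
    return(list(labels = matrix(0L, nrow(m), ncol(m)),
                areas = integer(0), mask = m))
  }
  lab <- EBImage::bwlabel(m * 1)
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  nlab <- max(lab)

  # Merge 4-connected labels that touch only diagonally.
  if (nlab > 1L) {
    nr <- nrow(lab); nc <- ncol(lab)
    a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # offset (+1, +1)
    a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # offset (+1, -1)
    keep1 <- a1 > 0L & b1 > 0L & a1 != b1
    keep2 <- a2 > 0L & b2 > 0L & a2 != b2
    pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
    if (nrow(pairs) > 0L) {
      parent <- seq_len(nlab)
      find <- function(i) {
        while (parent[i] != i) {
          parent[i] <<- parent[parent[i]]
          i <- parent[i]
        }
        i
      }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(pairs[k, 1L]); rb <- find(pairs[k, 2L])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_len(nlab), find, integer(1))
      lab[] <- c(0L, root)[lab + 1L]
    }
  }

  # Renumber so labels are consecutive, ordered by first occurrence.
  fg <- which(lab > 0L)
  first <- !duplicated(lab[fg])
  order_map <- integer(max(lab))
  order_map[lab[fg][first]] <- seq_len(sum(first))
  lab[fg] <- order_map[lab[fg]]

  areas <- tabulate(lab[fg])
  if (min_area > 0L && any(areas < min_area)) {
    drop <- which(areas < min_area)
    lab[lab %in% drop] <- 0L
    keep <- which(areas >= min_area)
    remap <- integer(length(areas)); remap[keep] <- seq_along(keep)
    fg <- which(lab > 0L)
    lab[fg] <- remap[lab[fg]]
    areas <- areas[keep]
  }
  list(labels = lab, areas = as.integer(areas), mask = lab > 0L)
}

#' Estimate background intensity statistics of a frame
#'
#' Robust background statistics from the pixel population after excluding
#' the upper intensity tail: pixels at or below the `tail_quantile` quantile
#' (default the 75th percentile) define the background set, so bright
#' objects (cells, aggregates, saturated pixels) do not perturb the
#' estimate. Because the retained set is itself truncated, its raw mean and
#' SD are corrected back to the untruncated values under a Gaussian
#' background model (the standard truncated-normal moment correction); on a
#' frame with no objects the estimates are unbiased for the true background
#' mean and SD.
#'
#' @param frame An [frame()] object or numeric matrix.
#' @param tail_quantile Quantile below which pixels are treated as background.
#'
#' @return List with `mean`, `sd`, and `degenerate` (`TRUE` when the retained
#'   background pixels are all identical, i.e. `sd == 0`).
#' @export
estimate_background <- function(frame, tail_quantile = 0.75) {
  px <- as_pixels(frame)
  stopifnot_scalar_prob(tail_quantile, "tail_quantile")
  cut <- stats::quantile(px, tail_quantile, names = FALSE)
  bg <- px[px <= cut]
  m <- mean(bg)
  s <- if (length(bg) > 1L) stats::sd(bg) else 0
  # truncated-normal correction for keeping only X <= q_p:
  # E[X | X <= q] = mu - sigma * h, Var = sigma^2 * (1 - z h - h^2),
  # with z = qnorm(p) and h = dnorm(z) / p.
  z <- stats::qnorm(tail_quantile)
  h <- stats::dnorm(z) / tail_quantile
  sigma <- s / sqrt(1 - z * h - h^2)
  mu <- m + sigma * h
  list(mean = mu, sd = sigma, degenerate = isTRUE(s == 0))
}

#' Segment fluorescing cells by background thresholding
#'
#' The cell mask is the set of 8-connected components of pixels brighter than
#' `bg_mean + k_cell * bg_sd`, after removing components smaller than
#' `min_cell_area_px`. When the background is degenerate (`bg_sd == 0`) the
#' threshold falls back to `bg_mean * fallback_factor`.
#'
#' @param frame An [frame()] object or numeric matrix.
#' @param bg_mean,bg_sd Background statistics, e.g. from
#'   [estimate_background()].
#' @param k_cell Threshold stringency in background standard deviations
#'   (default 3).
#' @param min_cell_area_px Minimum cell component area in pixels (default 20).
#' @param fallback_factor Multiplier applied to `bg_mean` when `bg_sd == 0`
#'   (default 1.5).
#'
#' @return List with `mask` (logical), `labels` (integer matrix),
#'   `areas` (component areas in px), `threshold` (AU) and `degenerate`.
#' @export
segment_cells <- function(frame, bg_mean, bg_sd, k_cell = 3,
                          min_cell_area_px = 20L, fallback_factor = 1.5) {
  px <- as_pixels(frame)
  degenerate <- isTRUE(bg_sd == 0)
  thr <- if (degenerate) bg_mean * fallback_factor else bg_mean + k_cell * bg_sd
  if (degenerate)
    message("degenerate background (sd = 0); cell threshold fell back to ",
            format(thr), " AU")
  comp <- label_components(px > thr, min_area = min_cell_area_px)
  list(mask = comp$mask, labels = comp$labels, areas = comp$areas,
       threshold = thr, degenerate = degenerate)
}

# Per-component diffuse intensity: the median pixel intensity of each cell
# component. The median is robust both to the bright aggregate foci inside
# the cell and to the dim soft-edge pixels at the cell boundary.
component_medians <- function(px, labels) {
  fg <- labels > 0L
  if (!any(fg)) return(numeric(0))
  vals <- split(px[fg], labels[fg])
  vapply(vals, stats::median, numeric(1))[order(as.integer(names(vals)))]
}

#' Detect aggregate foci within the cell mask
#'
#' Aggregates are bright sub-cellular foci detected with a stringent
#' intensity threshold of `k_sigma` (default 18) standard deviations above
#' the average fluorescence per cell. With the default `stat_basis = "cell"`
#' the base statistics are the mean and SD, across cell components, of each
#' component's diffuse intensity (its median pixel value); this per-cell
#' basis is robust to the foci themselves. `stat_basis = "pixel"` instead
#' uses the mean and SD of all pixel intensities under the cell mask.
#' With fewer than two cell components the spread is taken from the scaled
#' median absolute deviation of the masked pixels.
#'
#' The aggregate mask is restricted to the cell mask by construction, and
#' components smaller than `min_agg_area_px` are discarded.
#'
#' @param frame An [frame()] object or numeric matrix.
#' @param cells Result of [segment_cells()] (or a logical cell mask).
#' @param k_sigma Threshold stringency in standard deviations (default 18).
#' @param min_agg_area_px Minimum aggregate component area (default 2).
#' @param stat_basis `"cell"` (default) or `"pixel"`; see Details.
#'
#' @return List with `mask`, `labels`, `areas`, `threshold` (AU), and the
#'   base statistics `stat_mean` and `stat_sd`.
#' @export
detect_aggregates <- function(frame, cells, k_sigma = 18,
                              min_agg_area_px = 2L,
                              stat_basis = c("cell", "pixel")) {
  px <- as_pixels(frame)
  stat_basis <- match.arg(stat_basis)
  if (is.matrix(cells)) cells <- label_components(cells)
  labels <- cells$labels
  mask <- labels > 0L
  if (!any(mask)) {
    warning("empty cell mask; no aggregates can be detected")
    return(list(mask = mask, labels = matrix(0L, nrow(px), ncol(px)),
                areas = integer(0), threshold = NA_real_,
                stat_mean = NA_real_, stat_sd = NA_real_))
  }
  if (stat_basis == "cell") {
    med <- component_medians(px, labels)
    stat_mean <- mean(med)
    stat_sd <- if (length(med) >= 2L) stats::sd(med)
               else stats::mad(px[mask])
  } else {
    stat_mean <- mean(px[mask])
    stat_sd <- stats::sd(px[mask])
    if (is.na(stat_sd)) stat_sd <- 0
  }
  thr <- stat_mean + k_sigma * stat_sd
  agg <- mask & (px > thr)
  comp <- label_components(agg, min_area = min_agg_area_px)
  list(mask = comp$mask, labels = comp$labels, areas = comp$areas,
       threshold = thr, stat_mean = stat_mean, stat_sd = stat_sd)
}

#' Segment a frame end to end
#'
#' Convenience wrapper running [estimate_background()], [segment_cells()],
#' and [detect_aggregates()], returning the full segmentation result used by
#' [calibrate_medians()] and [quantify_frame()].
#'
#' @inheritParams segment_cells
#' @inheritParams detect_aggregates
#' @param frame An [frame()] object.
#' @param keep_masks Keep the logical masks and label matrices in the result
#'   (set `FALSE` to save memory when only areas and totals are needed
#'   downstream).
#'
#' @return An object of class `fq_seg`: background statistics, cell and
#'   aggregate masks/labels (optional), component areas, pixel statistics
#'   over the cell mask, background-corrected total fluorescence, and the
#'   aggregate threshold used.
#' @export
segment_frame <- function(frame, k_cell = 3, k_sigma = 18,
                          min_cell_area_px = 20L, min_agg_area_px = 2L,
                          stat_basis = c("cell", "pixel"),
                          keep_masks = TRUE) {
  stat_basis <- match.arg(stat_basis)
  px <- as_pixels(frame)
  bg <- estimate_background(frame)
  cells <- segment_cells(frame, bg$mean, bg$sd, k_cell = k_cell,
                         min_cell_area_px = min_cell_area_px)
  aggs <- if (length(cells$areas) > 0L) {
    detect_aggregates(frame, cells, k_sigma = k_sigma,
                      min_agg_area_px = min_agg_area_px,
                      stat_basis = stat_basis)
  } else {
    list(mask = cells$mask & FALSE, labels = cells$labels * 0L,
         areas = integer(0), threshold = NA_real_,
         stat_mean = NA_real_, stat_sd = NA_real_)
  }
  cm <- cells$mask
  res <- list(
    background_mean = bg$mean,
    background_sd = bg$sd,
    cell_areas = cells$areas,
    aggregate_areas = aggs$areas,
    cell_pixel_mean = if (any(cm)) mean(px[cm]) else NA_real_,
    cell_pixel_sd = if (sum(cm) > 1L) stats::sd(px[cm]) else NA_real_,
    total_cell_area = sum(cells$areas),
    total_aggregate_area = sum(aggs$areas),
    total_fluorescence = if (any(cm)) sum(pmax(px[cm] - bg$mean, 0)) else 0,
    threshold_used = aggs$threshold,
    k_sigma = k_sigma,
    cell_threshold = cells$threshold,
    time_h = if (inherits(frame, "fq_frame")) frame$time_h else NA_real_,
    condition = if (inherits(frame, "fq_frame")) frame$condition else NA_character_,
    replicate = if (inherits(frame, "fq_frame")) frame$replicate else NA)
  if (keep_masks) {
    res$cell_mask <- cells$mask
    res$cell_labels <- cells$labels
    res$aggregate_mask <- aggs$mask
    res$aggregate_labels <- aggs$labels
  }
  structure(res, class = "fq_seg")
}

#' @export
print.fq_seg <- function(x, ...) {
  cat(sprintf(
    "<fq_seg> %d cells (%d px), %d aggregate foci (%d px), T_agg=%s AU\n",
    length(x$cell_areas), x$total_cell_area, length(x$aggregate_areas),
    x$total_aggregate_area,
    ifelse(is.na(x$threshold_used), "NA", format(signif(x$threshold_used, 4)))))
  invisible(x)
}
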
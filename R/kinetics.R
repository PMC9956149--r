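# Time-course analysis of per-frame quantities: condition fold changes,
# plateau levels, and rupture-driven saw-tooth drop detection. All
# operations consume the long-format `quant` table produced by
# [quantify_experiment()] (columns `time_h`, `condition`, `replicate`, plus
# metric columns), or plain numeric series.

# Replicate-mean series of `metric` for one condition.
condition_mean_series <- function(quant, condition, metric) {
  q <- quant[quant$condition == condition & !is.na(quant[[metric]]), ]
  if (nrow(q) == 0L)
    stop(sprintf("no data for condition '%s'", condition), call. = FALSE)
  agg <- stats::aggregate(q[[metric]], by = list(time_h = q$time_h), FUN = mean)
  names(agg)[2] <- "mean"
  agg[order(agg$time_h), ]
}

#' Fold change between two conditions at a time point
#'
#' Ratio of the replicate-mean metric, condition A over condition B, at
#' `time_h`. When no frame was acquired exactly at `time_h`, the
#' replicate-mean series is linearly interpolated between the adjacent time
#' points; querying an existing time point returns the stored value exactly.
#'
#' @param quant Quantification table (see [quantify_experiment()]).
#' @param condition_a,condition_b Condition labels (numerator, denominator).
#' @param time_h Time (hours post-transfection) at which to compare.
#' @param metric Metric column (default `"aggregates_per_cell"`).
#'
#' @return The fold change (numeric); `NA` with a warning when the
#'   denominator mean is 0.
#' @export
fold_change_at <- function(quant, condition_a, condition_b, time_h,
                           metric = "aggregates_per_cell") {
  sa <- condition_mean_series(quant, condition_a, metric)
  sb <- condition_mean_series(quant, condition_b, metric)
  interp <- function(s) {
    if (time_h < min(s$time_h) || time_h > max(s$time_h))
      stop("`time_h` lies outside the acquired time course", call. = FALSE)
    stats::approx(s$time_h, s$mean, xout = time_h, ties = "ordered")$y
  }
  a <- interp(sa); b <- interp(sb)
  if (is.na(b) || b == 0) {
    warning("denominator mean is 0 at t = ", time_h, " h; fold change undefined")
    return(NA_real_)
  }
  a / b
}

#' Plateau level of a time course
#'
#' Mean of the metric over the final `window_h` hours of the course, across
#' replicates; the spread is the SD of the per-replicate window means.
#'
#' @inheritParams fold_change_at
#' @param condition Condition label.
#' @param window_h Width of the terminal window in hours (default 5).
#'
#' @return List with `level`, `sd`, `n_replicates`, and `n_points`.
#' @export
plateau_level <- function(quant, condition, window_h = 5,
                          metric = "aggregates_per_cell") {
  q <- quant[quant$condition == condition & !is.na(quant[[metric]]), ]
  if (nrow(q) == 0L)
    stop(sprintf("no data for condition '%s'", condition), call. = FALSE)
  span <- max(q$time_h) - min(q$time_h)
  if (window_h <= 0 || (span > 0 && window_h >= span))
    stop("`window_h` must be positive and shorter than the time course",
         call. = FALSE)
  w <- q[q$time_h >= max(q$time_h) - window_h, ]
  if (nrow(w) == 0L) stop("empty plateau window", call. = FALSE)
  rep_means <- tapply(w[[metric]], w$replicate, mean)
  list(level = mean(w[[metric]]),
       sd = if (length(rep_means) > 1L) stats::sd(rep_means) else NA_real_,
       n_replicates = length(rep_means), n_points = nrow(w))
}

#' Detect rupture-driven sudden drops in a metric series
#'
#' Cell rupture releases fluorescent aggregates into the medium, producing
#' saw-tooth kinetics: sudden drops in the aggregates-per-cell (or total
#' fluorescence) series. An event is called at each consecutive pair of
#' points where the metric falls below `(1 - min_drop)` times its previous
#' value. Detection depends only on ratios, so it is invariant under uniform
#' scaling of the metric.
#'
#' @param times Numeric vector of time points (hours), strictly increasing.
#' @param values Metric values at those times.
#' @param min_drop Minimum fractional drop to call an event (default 0.25).
#' @param metric Label recorded in the output (default
#'   `"aggregates_per_cell"`).
#'
#' @return A `data.frame` of events: `time_h` (time of the dropped point),
#'   `drop_fraction` in (0, 1], and `metric`.
#' @export
detect_ruptures <- function(times, values, min_drop = 0.25,
                            metric = "aggregates_per_cell") {
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length", call. = FALSE)
  if (length(times) < 2L)
    stop("at least two time points are required", call. = FALSE)
  stopifnot_scalar_prob(min_drop, "min_drop")
  prev <- values[-length(values)]
  nxt <- values[-1L]
  ok <- !is.na(prev) & !is.na(nxt) & prev > 0
  hit <- ok & (nxt < (1 - min_drop) * prev)
  data.frame(time_h = times[-1L][hit],
             drop_fraction = 1 - nxt[hit] / prev[hit],
             metric = rep(metric, sum(hit)),
             stringsAsFactors = FALSE)
}

#' Detect rupture events in every replicate time course of a table
#'
#' Applies [detect_ruptures()] to each (condition, replicate) series of the
#' quantification table.
#'
#' @inheritParams fold_change_at
#' @inheritParams detect_ruptures
#'
#' @return A `data.frame` of events with `condition` and `replicate` columns
#'   prepended.
#' @export
detect_ruptures_all <- function(quant, metric = "aggregates_per_cell",
                                min_drop = 0.25) {
  groups <- unique(quant[, c("condition", "replicate")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    q <- quant[quant$condition == groups$condition[i] &
               quant$replicate == groups$replicate[i], ]
    q <- q[order(q$time_h), ]
    if (nrow(q) < 2L) return(NULL)
    ev <- detect_ruptures(q$time_h, q[[metric]], min_drop = min_drop,
                          metric = metric)
    if (nrow(ev) == 0L) return(NULL)
    cbind(condition = groups$condition[i], replicate = groups$replicate[i],
          ev, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(condition = character(0), replicate = character(0),
                      time_h = numeric(0), drop_fraction = numeric(0),
                      metric = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a metric by condition and time
#'
#' Mean, SD and replicate count of a metric at each (condition, time) cell,
#' the layout used for time-course plots with +/- 1 SD error bars.
#'
#' @inheritParams fold_change_at
#' @return A `data.frame` with `condition`, `time_h`, `mean`, `sd`, `n`.
#' @export
summarize_timecourse <- function(quant, metric = "aggregates_per_cell") {
  q <- quant[!is.na(quant[[metric]]), ]
  agg <- stats::aggregate(
    q[[metric]], by = list(condition = q$condition, time_h = q$time_h),
    FUN = function(v) c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out <- data.frame(condition = agg$condition, time_h = agg$time_h,
                    mean = agg$x[, "mean"], sd = agg$x[, "sd"],
                    n = agg$x[, "n"], stringsAsFactors = FALSE)
  out[order(out$condition, out$time_h), ]
}
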
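#' Synthetic image generator configuration
#'
#' Bundles the parameters of the synthetic fluorescence-field generator:
#' frame geometry, cell population, intensities, aggregate foci load, and
#' rupture dynamics. Identical configuration plus seed always yields
#' bit-identical output.
#'
#' @param frame_shape Integer vector `c(rows, cols)` in pixels.
#' @param n_cells Number of cells placed in the field.
#' @param transfected_fraction Probability that a cell is transfected (and
#'   hence fluorescent), in `[0, 1]`.
#' @param cell_radius_px Numeric `c(mean, sd)` of the cell radius in pixels;
#'   draws are truncated to `mean +/- 2.5 sd` and a floor of 3 px.
#' @param cell_mean_intensity Mean diffuse fluorescence of a transfected cell
#'   (arbitrary units, AU).
#' @param cell_intensity_sdlog Log-scale SD of the per-cell lognormal
#'   brightness multiplier (default 0.2); the multiplier has mean exactly 1.
#' @param background_level,background_noise_sd Mean and SD (AU) of the
#'   Gaussian camera background.
#' @param aggregates_per_cell_lambda Expected number of aggregate foci per
#'   transfected cell: a single number, or a function of time (hours) for
#'   time lapses.
#' @param aggregate_radius_px Radius of an aggregate focus in pixels.
#' @param aggregate_intensity_multiplier Focus intensity as a multiple of the
#'   parent cell's diffuse intensity; must exceed 1 and is chosen large
#'   enough (default 15) that foci clear the detection threshold.
#' @param rupture_rate Per-transfected-cell, per-frame probability of a
#'   rupture event in a time lapse (the cell and its foci disappear from all
#'   subsequent frames).
#' @param n_replicates Default number of biological replicates generated by
#'   preset-driven runs.
#' @param seed Default RNG seed.
#'
#' @return An object of class `fq_config`.
#' @export
generator_config <- function(frame_shape = c(512L, 512L),
                             n_cells = 100L,
                             transfected_fraction = 1,
                             cell_radius_px = c(9, 1.2),
                             cell_mean_intensity = 100,
                             cell_intensity_sdlog = 0.2,
                             background_level = 10,
                             background_noise_sd = 2,
                             aggregates_per_cell_lambda = 0,
                             aggregate_radius_px = 1.6,
                             aggregate_intensity_multiplier = 15,
                             rupture_rate = 0,
                             n_replicates = 4L,
                             seed = 1L) {
  stopifnot_scalar_prob(transfected_fraction, "transfected_fraction")
  stopifnot_scalar_prob(rupture_rate, "rupture_rate")
  if (length(frame_shape) != 2L || any(frame_shape < 8))
    stop("`frame_shape` must be c(rows, cols), each >= 8", call. = FALSE)
  if (n_cells < 0) stop("`n_cells` must be >= 0", call. = FALSE)
  if (length(cell_radius_px) == 1L) cell_radius_px <- c(cell_radius_px, 0)
  if (cell_mean_intensity < 0 || background_level < 0 ||
      background_noise_sd < 0)
    stop("intensities must be non-negative", call. = FALSE)
  if (aggregate_intensity_multiplier <= 1)
    stop("`aggregate_intensity_multiplier` must exceed 1", call. = FALSE)
  if (!is.function(aggregates_per_cell_lambda) &&
      aggregates_per_cell_lambda < 0)
    stop("`aggregates_per_cell_lambda` must be >= 0", call. = FALSE)
  structure(
    list(frame_shape = as.integer(frame_shape),
         n_cells = as.integer(n_cells),
         transfected_fraction = transfected_fraction,
         cell_radius_px = as.numeric(cell_radius_px),
         cell_mean_intensity = cell_mean_intensity,
         cell_intensity_sdlog = cell_intensity_sdlog,
         background_level = background_level,
         background_noise_sd = background_noise_sd,
         aggregates_per_cell_lambda = aggregates_per_cell_lambda,
         aggregate_radius_px = aggregate_radius_px,
         aggregate_intensity_multiplier = aggregate_intensity_multiplier,
         rupture_rate = rupture_rate,
         n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "fq_config")
}

# Merge per-condition overrides into a base config.
modify_config <- function(config, ...) {
  dots <- list(...)
  dots <- dots[!vapply(dots, is.null, logical(1))]
  for (nm in names(dots)) config[[nm]] <- dots[[nm]]
  do.call(generator_config, config)
}

#' @export
print.fq_config <- function(x, ...) {
  cat(sprintf(
    "<fq_config> %dx%d px, %d cells (%.0f%% transfected), I=%.3g AU, lambda=%s\n",
    x$frame_shape[1], x$frame_shape[2], x$n_cells,
    100 * x$transfected_fraction, x$cell_mean_intensity,
    if (is.function(x$aggregates_per_cell_lambda)) "f(t)"
    else format(x$aggregates_per_cell_lambda)))
  invisible(x)
}
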
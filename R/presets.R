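# Named preset registry. Each preset encodes one experimental scenario of
# the study conditions: the generator configuration, the per-condition
# effect sizes injected as ground truth, and the effect sizes a downstream
# analysis is expected to recover. Condition labels are
# "<tRNA allele>/<reporter>", with tRNA in {none, AGA, AAA} (no ectopic
# tRNA, wild-type serine tRNA, mistranslating G35A variant) and reporter in
# {mCherry, FUS, R521C}.

# Piecewise-linear trajectory helper (constant extrapolation at the ends).
traj <- function(t_pts, lambda_pts) {
  stats::approxfun(t_pts, lambda_pts, rule = 2)
}

build_presets <- function() {
  presets <- list()

  # --- mCherry-only reporter fields: per-cell fluorescence effects -------
  fig1_base <- generator_config(
    frame_shape = c(512L, 512L), n_cells = 150L, transfected_fraction = 1,
    cell_radius_px = c(10, 1), cell_mean_intensity = 1000,
    aggregates_per_cell_lambda = 0, n_replicates = 36L)
  presets$fig1 <- list(
    name = "fig1", kind = "image", config = fig1_base,
    conditions = data.frame(
      condition = c("none/mCherry", "AGA/mCherry", "AAA/mCherry"),
      intensity = 1000 * c(1.00, 1.33, 0.78),
      stringsAsFactors = FALSE),
    ground_truth = list(
      relative_intensity = c("none/mCherry" = 1.00, "AGA/mCherry" = 1.33,
                             "AAA/mCherry" = 0.78)))

  # --- FUS reporter fields: total protein production -------------------
  fig5_base <- generator_config(
    frame_shape = c(512L, 512L), n_cells = 120L, transfected_fraction = 1,
    cell_radius_px = c(9, 1.2), cell_mean_intensity = 400,
    aggregates_per_cell_lambda = 0.5, n_replicates = 6L)
  fig5_rel <- c("none/FUS" = 1.00, "AGA/FUS" = 2.3, "AAA/FUS" = 2.3 / 2.5,
                "none/R521C" = 1.00, "AGA/R521C" = 2.0,
                "AAA/R521C" = 2.0 / 2.1)
  presets$fig5 <- list(
    name = "fig5", kind = "image", config = fig5_base,
    conditions = data.frame(
      condition = names(fig5_rel),
      intensity = 400 * unname(fig5_rel),
      stringsAsFactors = FALSE),
    ground_truth = list(relative_intensity = fig5_rel))

  # --- transfection-efficiency fields -----------------------------------
  presets$transfection <- list(
    name = "transfection", kind = "image",
    config = generator_config(
      frame_shape = c(256L, 256L), n_cells = 50L,
      transfected_fraction = 0.60, cell_radius_px = c(8, 1),
      cell_mean_intensity = 100, aggregates_per_cell_lambda = 0,
      n_replicates = 1L),
    conditions = data.frame(condition = "AGA/mCherry", intensity = 100,
                            stringsAsFactors = FALSE),
    ground_truth = list(transfected_fraction = 0.60))

  # --- wild-type FUS aggregation kinetics -------------------------------
  # Baseline 0.5 foci per transfected cell for the no-tRNA condition; the
  # other trajectories encode the printed fold relationships.
  fus_times <- seq(25, 68.5, length.out = 20L)
  presets[["fig6-FUS"]] <- list(
    name = "fig6-FUS", kind = "timelapse",
    config = generator_config(
      frame_shape = c(640L, 640L), n_cells = 200L, transfected_fraction = 1,
      cell_radius_px = c(10, 1.2), cell_mean_intensity = 400,
      aggregate_radius_px = 1.6, aggregate_intensity_multiplier = 15,
      n_replicates = 4L),
    times = fus_times,
    conditions = data.frame(
      condition = c("none/FUS", "AGA/FUS", "AAA/FUS"),
      intensity = 400 * c(1.00, 2.3, 0.92),
      rupture_rate = c(0, 0, 0),
      stringsAsFactors = FALSE),
    trajectories = list(
      "none/FUS" = traj(c(25, 68.5), c(0.5, 0.5)),
      "AGA/FUS" = traj(c(25, 68.5), c(2.5, 2.0)),
      "AAA/FUS" = traj(c(25, 63.5, 68.5), c(0.5, 0.6, 1.0))),
    ground_truth = list(fold_first = 5.0, fold_last = 4.0,
                        fold_aaa_last = 2.0, baseline_lambda = 0.5))

  # --- FUS R521C aggregation kinetics with rupture events ---------------
  # Small fields (12 cells) on a 30-min grid: single-cell ruptures are then
  # visible as sudden drops in the population aggregates-per-cell series.
  r521c_times <- seq(25, 68.5, by = 0.5)
  presets[["fig6-R521C"]] <- list(
    name = "fig6-R521C", kind = "timelapse",
    config = generator_config(
      frame_shape = c(256L, 256L), n_cells = 20L, transfected_fraction = 1,
      cell_radius_px = c(9, 1), cell_mean_intensity = 400,
      aggregate_radius_px = 1.6, aggregate_intensity_multiplier = 15,
      n_replicates = 4L),
    times = r521c_times,
    conditions = data.frame(
      condition = c("none/R521C", "AGA/R521C", "AAA/R521C"),
      intensity = 400 * c(1.00, 2.0, 0.95),
      rupture_rate = c(0, 0.002, 0.008),
      stringsAsFactors = FALSE),
    trajectories = list(
      "none/R521C" = traj(c(25, 68.5), c(0.5, 0.5)),
      "AGA/R521C" = traj(c(25, 68.5), c(2.0, 2.0)),
      "AAA/R521C" = traj(c(25, 51, 68.5), c(0.5, 1.5, 1.5))),
    ground_truth = list(plateau_ratio = 3.0, fold_aga = 4.0,
                        baseline_lambda = 0.5))

  # --- dye-exclusion cytotoxicity ---------------------------------------
  # Base death ratios chosen once as realistic dye-exclusion levels; the
  # five printed relations hold exactly in the injected truth:
  # (AAA,R521C) = 1.40 x (none,FUS) = 1.33 x (none,R521C)
  #            = 1.28 x (AGA,R521C); (AAA,mCh) = 1.10 x (none,mCh);
  # (AGA,R521C) = 1.17 x (AGA,mCh).
  aga_mch <- 0.20
  aga_r521c <- 1.17 * aga_mch
  aaa_r521c <- 1.28 * aga_r521c
  tox <- data.frame(
    condition = c("none/mCherry", "AGA/mCherry", "AAA/mCherry",
                  "none/FUS", "AGA/FUS", "AAA/FUS",
                  "none/R521C", "AGA/R521C", "AAA/R521C"),
    ratio = c(0.19, aga_mch, 1.10 * 0.19,
              aaa_r521c / 1.40, 0.225, 1.05 * aaa_r521c / 1.40,
              aaa_r521c / 1.33, aga_r521c, aaa_r521c),
    post_mean = 1000,
    stringsAsFactors = FALSE)
  presets$fig4 <- list(
    name = "fig4", kind = "toxicity", toxicity = tox, n_replicates = 5L,
    control = "AGA/mCherry",
    ground_truth = list(ratios = stats::setNames(tox$ratio, tox$condition),
                        fold_vs_none_fus = 1.40))

  # --- SDD-AGE aggregated fractions -------------------------------------
  lanes <- data.frame(
    condition = c("AGA/FUS", "AAA/FUS", "AGA/R521C", "AAA/R521C"),
    fraction = c(0.40, 0.20, 0.48, 0.36),
    total = 1000,
    stringsAsFactors = FALSE)
  presets$fig7 <- list(
    name = "fig7", kind = "lanes", lanes = lanes,
    ground_truth = list(
      fractions = stats::setNames(lanes$fraction, lanes$condition),
      fus_ratio_aaa_aga = 0.5, r521c_ratio_aaa_aga = 0.75))

  # --- tRNA sequencing count means --------------------------------------
  # The mutant Ser-AAA-2-3 transcript is unique-mapped (26 mean counts in
  # mistranslating cells, sequencing-error background 0.5 in wild-type
  # cells). The six identical Ser-AGA-2 gene copies are multi-mapped and
  # pool to ~2000. Non-AGA serine families sum to 6641 so that
  # 26 / (26 + 6641 + 2000) = 0.3% of the total serine pool, and the
  # phenylalanine-decoder pool is 1831 so that 26 / (26 + 1831) = 1.4%.
  # Lys-TTT-1-1 is 1.8-fold up and the mitochondrial cysteine tRNA 1.5-fold
  # up in wild-type (AGA) cells; all other transcripts are null background.
  null_means <- c(3200, 2400, 1500, 900, 650, 420, 300, 180, 120, 80,
                  60, 45, 30, 1100, 750, 520, 260, 140, 95, 55)
  cm <- rbind(
    data.frame(transcript_id = "Ser-AAA-2-3", family = "Ser-AAA",
               mapping_class = "unique", AGA = 0.5, AAA = 26),
    data.frame(transcript_id = paste0("Ser-AGA-2-", 1:6), family = "Ser-AGA",
               mapping_class = "multi", AGA = 2000 / 6, AAA = 2000 / 6),
    data.frame(transcript_id = c("Ser-CGA-1-1", "Ser-GCT-2-1", "Ser-TGA-1-1"),
               family = c("Ser-CGA", "Ser-GCT", "Ser-TGA"),
               mapping_class = "unique",
               AGA = c(2600, 2800, 1241), AAA = c(2600, 2800, 1241)),
    data.frame(transcript_id = paste0("Phe-GAA-1-", 1:2), family = "Phe-GAA",
               mapping_class = "multi", AGA = 1831 / 2, AAA = 1831 / 2),
    data.frame(transcript_id = "Lys-TTT-1-1", family = "Lys-TTT",
               mapping_class = "unique", AGA = 180, AAA = 100),
    data.frame(transcript_id = "mT-Cys-GCA-1", family = "mT-Cys-GCA",
               mapping_class = "unique", AGA = 150, AAA = 100),
    data.frame(transcript_id = sprintf("Null-%02d-1-1", seq_along(null_means)),
               family = sprintf("Null-%02d", seq_along(null_means)),
               mapping_class = "unique",
               AGA = null_means, AAA = null_means))
  presets$fig2 <- list(
    name = "fig2", kind = "counts", count_means = cm, n_replicates = 3L,
    ids = list(aaa = "Ser-AAA-2-3",
               ser_pools = c("Ser-AGA-2", "Ser-CGA-1-1", "Ser-GCT-2-1",
                             "Ser-TGA-1-1"),
               aga_pool = "Ser-AGA-2",
               phe_pools = "Phe-GAA-1"),
    ground_truth = list(aaa_mean = 26, aga_pool_mean = 2000,
                        lys_fold = 1.8, phe_fraction = 26 / (26 + 1831),
                        ser_fraction = 26 / (26 + 6641 + 2000),
                        transfection_eff = 0.60))

  presets
}

.preset_registry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_presets()
    cache
  }
})

#' Available preset names
#' @return Character vector of preset names.
#' @export
preset_names <- function() names(.preset_registry())

#' Retrieve a named study-condition preset
#'
#' Presets bundle the generator configuration and injected ground-truth
#' effect sizes for each emulated experimental scenario: reporter-only
#' fluorescence fields (`"fig1"`), FUS production fields (`"fig5"`),
#' transfection-efficiency fields (`"transfection"`), aggregation
#' time lapses for wild-type FUS (`"fig6-FUS"`) and the ALS-causative R521C
#' variant with rupture events (`"fig6-R521C"`), dye-exclusion toxicity
#' plates (`"fig4"`), SDD-AGE lane profiles (`"fig7"`), and tRNA-seq count
#' tables (`"fig2"`).
#'
#' @param name Preset name; see [preset_names()].
#' @return A list describing the preset (fields depend on its kind; all
#'   presets carry `ground_truth`).
#' @export
get_preset <- function(name) {
  reg <- .preset_registry()
  if (!name %in% names(reg))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  reg[[name]]
}
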
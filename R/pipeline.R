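# End-to-end orchestration: simulate a preset scenario, run the matching
# analysis stages, and report every recovered effect size next to its
# injected ground truth. run_pipeline() is the programmatic entry point;
# inst/cli/fociquant.R wraps it (and the stage functions) for shell use.

reporter_of <- function(condition) sub("^[^/]*/", "", condition)
trna_of <- function(condition) sub("/.*$", "", condition)

# Well-scattered per-(condition, replicate) seeds derived from a base seed.
# Entry (ci, r) depends only on the full condition count and (ci, r), so
# generating a subset of conditions reproduces the same frames.
preset_seed_matrix <- function(seed, n_conditions, n_replicates) {
  with_seed(seed,
            matrix(sample.int(2147483646L, n_conditions * n_replicates),
                   nrow = n_conditions))
}

#' Simulate every frame of an image preset
#'
#' @param preset A preset of kind `"image"` (see [get_preset()]).
#' @param seed Base seed; each (condition, replicate) frame uses a child
#'   seed derived from it.
#' @param conditions Optional subset of condition labels to generate.
#' @param n_replicates Optional override of the preset replicate count.
#'
#' @return A list of [frame()] objects with ground-truth attributes.
#' @export
simulate_image_preset <- function(preset, seed = 1L, conditions = NULL,
                                  n_replicates = NULL) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(preset$kind == "image")
  cond_all <- preset$conditions
  keep <- if (is.null(conditions)) seq_len(nrow(cond_all))
          else which(cond_all$condition %in% conditions)
  if (is.null(n_replicates)) n_replicates <- preset$config$n_replicates
  smat <- preset_seed_matrix(seed, nrow(cond_all), n_replicates)
  frames <- list()
  for (ci in keep) {
    cfg <- modify_config(preset$config,
                         cell_mean_intensity = cond_all$intensity[ci])
    for (r in seq_len(n_replicates)) {
      frames[[length(frames) + 1L]] <- generate_frame(
        cfg, condition = cond_all$condition[ci], replicate = r,
        seed = smat[ci, r])
    }
  }
  frames
}

#' Simulate every time lapse of a timelapse preset
#'
#' @inheritParams simulate_image_preset
#' @param render Render pixels (`TRUE`) or ground truth only (`FALSE`).
#'
#' @return A list with one element per (condition, replicate): the
#'   [generate_timelapse()] result plus `condition` and `replicate`.
#' @export
simulate_timelapse_preset <- function(preset, seed = 1L, conditions = NULL,
                                      n_replicates = NULL, render = TRUE) {
  if (is.character(preset)) preset <- get_preset(preset)
  stopifnot(preset$kind == "timelapse")
  cond_all <- preset$conditions
  keep <- if (is.null(conditions)) seq_len(nrow(cond_all))
          else which(cond_all$condition %in% conditions)
  if (is.null(n_replicates)) n_replicates <- preset$config$n_replicates
  smat <- preset_seed_matrix(seed, nrow(cond_all), n_replicates)
  out <- list()
  for (ci in keep) {
    cname <- cond_all$condition[ci]
    cfg <- modify_config(preset$config,
                         cell_mean_intensity = cond_all$intensity[ci],
                         rupture_rate = cond_all$rupture_rate[ci])
    for (r in seq_len(n_replicates)) {
      tl <- generate_timelapse(cfg, preset$times,
                               trajectory = preset$trajectories[[cname]],
                               condition = cname, replicate = r,
                               seed = smat[ci, r], render = render)
      tl$condition <- cname
      tl$replicate <- r
      out[[length(out) + 1L]] <- tl
    }
  }
  out
}

#' Simulate and quantify the time lapses of a preset
#'
#' Generates the preset's time lapses one (condition, replicate) at a time,
#' segments each frame immediately (pixel data and masks are discarded as
#' soon as a lapse has been segmented, keeping memory flat), pools all
#' component areas into one experiment-wide median calibration, and
#' quantifies every frame.
#'
#' @inheritParams simulate_timelapse_preset
#' @inheritParams segment_frame
#'
#' @return List with `quant` (per-frame quantification table),
#'   `calibration`, and `truth_series` (the generator's per-frame ground
#'   truth with `condition` and `replicate` columns).
#' @export
quantify_timelapse_preset <- function(preset, seed, conditions = NULL,
                                      n_replicates = NULL,
                                      k_cell = 3, k_sigma = 18,
                                      min_cell_area_px = 20L,
                                      min_agg_area_px = 2L) {
  if (is.character(preset)) preset <- get_preset(preset)
  cond_all <- preset$conditions
  keep <- if (is.null(conditions)) seq_len(nrow(cond_all))
          else which(cond_all$condition %in% conditions)
  if (is.null(n_replicates)) n_replicates <- preset$config$n_replicates
  smat <- preset_seed_matrix(seed, nrow(cond_all), n_replicates)
  segs <- list()
  truth <- list()
  for (ci in keep) {
    cname <- cond_all$condition[ci]
    cfg <- modify_config(preset$config,
                         cell_mean_intensity = cond_all$intensity[ci],
                         rupture_rate = cond_all$rupture_rate[ci])
    for (r in seq_len(n_replicates)) {
      tl <- generate_timelapse(cfg, preset$times,
                               trajectory = preset$trajectories[[cname]],
                               condition = cname, replicate = r,
                               seed = smat[ci, r])
      for (fr in tl$frames) {
        segs[[length(segs) + 1L]] <-
          segment_frame(fr, k_cell = k_cell, k_sigma = k_sigma,
                        min_cell_area_px = min_cell_area_px,
                        min_agg_area_px = min_agg_area_px,
                        keep_masks = FALSE)
      }
      s <- tl$ground_truth$series
      s$condition <- cname
      s$replicate <- r
      truth[[length(truth) + 1L]] <- s
      rm(tl)
    }
  }
  calib <- calibrate_medians(segs)
  quant <- do.call(rbind, lapply(segs, quantify_frame, calib = calib))
  rownames(quant) <- NULL
  list(quant = quant, calibration = calib,
       truth_series = do.call(rbind, truth))
}

# Per-condition mean fluorescence per cell, with each condition expressed
# relative to the no-tRNA condition of the same reporter arm.
relative_fluorescence <- function(quant) {
  cond_means <- tapply(quant$fluorescence_per_cell, quant$condition, mean,
                       na.rm = TRUE)
  out <- data.frame(condition = names(cond_means),
                    mean_fluorescence_per_cell = as.numeric(cond_means),
                    stringsAsFactors = FALSE)
  ref <- paste0("none/", reporter_of(out$condition))
  out$relative_to_none <- ifelse(ref %in% out$condition,
                                 out$mean_fluorescence_per_cell /
                                   cond_means[ref], NA_real_)
  out
}

#' Run a full preset scenario end to end
#'
#' Simulates the named preset, runs the applicable analysis stages
#' (segmentation + median-adjusted counting, kinetics, cytotoxicity,
#' tRNA-seq, SDD-AGE densitometry, pairwise Welch tests), and returns a
#' summary pairing every recovered effect size with its injected ground
#' truth. With `out_dir` set, tables are written as CSV/TSV and the summary
#' as JSON.
#'
#' @param preset Preset name (see [preset_names()]) or preset object.
#' @param seed Base seed for all randomness.
#' @param out_dir Optional output directory.
#' @param k_cell,k_sigma,min_cell_area_px,min_agg_area_px Segmentation
#'   parameters (see [segment_frame()]).
#' @param min_drop Rupture-detection sensitivity (see [detect_ruptures()]).
#' @param plateau_window_h Plateau window in hours (see [plateau_level()]).
#'
#' @return A list with `preset`, `seed`, `summary` (recovered vs injected),
#'   and the stage tables relevant to the preset kind (`quant`, `events`,
#'   `toxicity`, `diff_abundance`, `fractions`, ...).
#' @export
run_pipeline <- function(preset, seed = 1L, out_dir = NULL,
                         k_cell = 3, k_sigma = 18,
                         min_cell_area_px = 20L, min_agg_area_px = 2L,
                         min_drop = 0.25, plateau_window_h = 5) {
  if (is.character(preset)) preset <- get_preset(preset)
  res <- switch(
    preset$kind,
    image = run_image_pipeline(preset, seed, k_cell, k_sigma,
                               min_cell_area_px, min_agg_area_px),
    timelapse = run_timelapse_pipeline(preset, seed, k_cell, k_sigma,
                                       min_cell_area_px, min_agg_area_px,
                                       min_drop, plateau_window_h),
    toxicity = run_toxicity_pipeline(preset, seed),
    counts = run_counts_pipeline(preset, seed),
    lanes = run_lanes_pipeline(preset, seed),
    stop("unknown preset kind: ", preset$kind))
  res$preset <- preset$name
  res$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$quant))
      utils::write.csv(res$quant, file.path(out_dir, "quant.csv"),
                       row.names = FALSE)
    if (!is.null(res$events))
      utils::write.csv(res$events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
    if (!is.null(res$toxicity))
      write_toxicity_csv(res$toxicity, file.path(out_dir, "toxicity.csv"))
    if (!is.null(res$diff_abundance))
      utils::write.table(res$diff_abundance,
                         file.path(out_dir, "diff_abundance.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(preset = res$preset, seed = res$seed,
                              summary = res$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  res
}

run_image_pipeline <- function(preset, seed, k_cell, k_sigma,
                               min_cell_area_px, min_agg_area_px) {
  frames <- simulate_image_preset(preset, seed)
  if (identical(preset$name, "transfection")) {
    eff <- transfection_efficiency(frames, k_cell = k_cell,
                                   min_cell_area_px = min_cell_area_px)
    return(list(summary = list(
      recovered_transfected_fraction = eff$mean,
      injected_transfected_fraction =
        preset$ground_truth$transfected_fraction)))
  }
  qe <- quantify_experiment(frames, k_cell = k_cell, k_sigma = k_sigma,
                            min_cell_area_px = min_cell_area_px,
                            min_agg_area_px = min_agg_area_px)
  rel <- relative_fluorescence(qe$quant)
  inj <- preset$ground_truth$relative_intensity
  rel$injected_relative <- unname(inj[rel$condition])
  list(quant = qe$quant,
       summary = list(relative_fluorescence = rel))
}

run_timelapse_pipeline <- function(preset, seed, k_cell, k_sigma,
                                   min_cell_area_px, min_agg_area_px,
                                   min_drop, plateau_window_h) {
  qt <- quantify_timelapse_preset(preset, seed, k_cell = k_cell,
                                  k_sigma = k_sigma,
                                  min_cell_area_px = min_cell_area_px,
                                  min_agg_area_px = min_agg_area_px)
  quant <- qt$quant
  events <- detect_ruptures_all(quant, min_drop = min_drop)
  conds <- preset$conditions$condition
  none <- conds[trna_of(conds) == "none"][1L]
  t_first <- min(preset$times); t_last <- max(preset$times)
  folds <- lapply(setdiff(conds, none), function(cc) {
    list(condition = cc,
         fold_first = fold_change_at(quant, cc, none, t_first),
         fold_last = fold_change_at(quant, cc, none, t_last),
         plateau_ratio =
           plateau_level(quant, cc, plateau_window_h)$level /
           plateau_level(quant, none, plateau_window_h)$level)
  })
  list(quant = quant, events = events,
       summary = list(folds_vs_none = folds,
                      injected = preset$ground_truth,
                      n_events = nrow(events)))
}

run_toxicity_pipeline <- function(preset, seed) {
  plate <- generate_toxicity_plate(preset, seed)
  plate <- toxicity_ratio(plate)
  norm <- normalize_to_control(plate, preset$control)
  inj <- preset$ground_truth$ratios
  norm$injected_normalized <- unname(inj[norm$condition] / inj[preset$control])
  # pairwise Welch tests against the control condition
  ctrl <- plate$ratio[plate$condition == preset$control]
  norm$p_vs_control <- vapply(norm$condition, function(cc) {
    if (cc == preset$control) return(NA_real_)
    welch_t_test(ctrl, plate$ratio[plate$condition == cc])$p_value
  }, numeric(1))
  norm$stars <- ""
  ok <- !is.na(norm$p_vs_control)
  norm$stars[ok] <- significance_stars(pmax(norm$p_vs_control[ok], 1e-300))
  list(toxicity = plate,
       summary = list(normalized = norm,
                      fold_aaa_r521c_vs_none_fus =
                        norm$normalized_mean[norm$condition == "AAA/R521C"] /
                        norm$normalized_mean[norm$condition == "none/FUS"],
                      injected_fold =
                        preset$ground_truth$fold_vs_none_fus))
}

run_counts_pipeline <- function(preset, seed) {
  table <- generate_count_table(preset, seed)
  pooled <- pool_counts(table)
  norm <- normalize_counts(pooled)
  da <- differential_abundance(norm, "AAA", "AGA")
  fr <- pool_fractions(pooled, preset$ids$aaa, preset$ids$ser_pools,
                       preset$ids$aga_pool, preset$ids$phe_pools,
                       preset$ground_truth$transfection_eff)
  samples <- count_samples(pooled)
  aaa_cols <- samples$sample[samples$condition == "AAA"]
  aga_cols <- samples$sample[samples$condition == "AGA"]
  aaa_row <- pooled$transcript_id == preset$ids$aaa
  aga_row <- pooled$transcript_id == preset$ids$aga_pool
  list(counts = pooled, diff_abundance = da,
       summary = list(
         aaa_mean = mean(as.numeric(pooled[aaa_row, aaa_cols])),
         aga_pool_mean = mean(as.numeric(pooled[aga_row, c(aaa_cols, aga_cols)])),
         lys_fold = da$fold_change[da$transcript_id == "Lys-TTT-1-1"],
         fractions = fr,
         injected = preset$ground_truth))
}

run_lanes_pipeline <- function(preset, seed) {
  lanes <- generate_lane_profiles(preset, seed)
  # Rolling-minimum window of half the lane so the baseline estimate can
  # reach true baseline beside the broad smear; monomer window at +/- 3 SD
  # since the bands are well separated (see the methods vignette).
  measure <- function(l) {
    l <- subtract_baseline(l, window_fraction = 0.5)
    fraction_aggregated(l, window = monomer_window(l, k_sd = 3))
  }
  fa <- lapply(lanes, measure)
  fracs <- vapply(fa, `[[`, numeric(1), "fraction")
  aggs <- vapply(fa, `[[`, numeric(1), "aggregated_area")
  list(fractions = fracs,
       summary = list(
         fractions = as.list(fracs),
         fus_ratio_aaa_aga = unname(fracs["AAA/FUS"] / fracs["AGA/FUS"]),
         r521c_signal_ratio_aaa_aga =
           unname(aggs["AAA/R521C"] / aggs["AGA/R521C"]),
         injected = preset$ground_truth))
}
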
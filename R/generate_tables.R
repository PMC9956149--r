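# Generators for the non-image assays: tRNA-seq count tables, dye-exclusion
# toxicity plates, and SDD-AGE lane densitometry profiles.

#' Generate a synthetic tRNA read-count table
#'
#' Read counts are drawn independently per sample as `Poisson(mean)`, with
#' per-transcript, per-condition means taken from the preset. Mapping class
#' (`unique` for transcripts with a distinguishing mutation, `multi` for
#' pools of identical gene copies) is copied through from the preset.
#'
#' @param preset A preset from [get_preset()] with a `count_means` table
#'   (columns `transcript_id`, `family`, `mapping_class`, plus one mean
#'   column per condition), or such a table directly.
#' @param seed RNG seed.
#' @param n_replicates Biological replicates per condition (default from the
#'   preset, 3).
#'
#' @return A `data.frame` with columns `transcript_id`, `family`,
#'   `mapping_class` and one count column per sample
#'   (`<condition>_<replicate>`); sample metadata is stored in the
#'   `samples` attribute.
#' @export
generate_count_table <- function(preset, seed = 1L, n_replicates = NULL) {
  cm <- if (is.data.frame(preset)) preset else preset$count_means
  if (is.null(n_replicates))
    n_replicates <- if (!is.data.frame(preset) &&
                        !is.null(preset$n_replicates)) preset$n_replicates
                    else 3L
  meta_cols <- c("transcript_id", "family", "mapping_class")
  conditions <- setdiff(names(cm), meta_cols)
  if (length(conditions) == 0L)
    stop("preset count table defines no condition mean columns", call. = FALSE)
  means <- as.matrix(cm[, conditions, drop = FALSE])
  if (any(means < 0)) stop("negative mean read count", call. = FALSE)
  with_seed(seed, {
    out <- cm[, meta_cols]
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           condition = conditions,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)[, 2:1]
    samples$sample <- paste(samples$condition, samples$replicate, sep = "_")
    for (i in seq_len(nrow(samples))) {
      out[[samples$sample[i]]] <-
        stats::rpois(nrow(cm), means[, samples$condition[i]])
    }
    attr(out, "samples") <- samples
    out
  })
}

#' Generate a synthetic dye-exclusion toxicity plate
#'
#' For each condition and replicate, the post-lysis (total cells)
#' fluorescence is drawn lognormally around the preset's `post_mean`, and
#' the pre-lysis (dead cells) fluorescence is the total times the injected
#' death ratio times multiplicative lognormal noise (both noise terms have
#' mean 1).
#'
#' @param preset A preset from [get_preset()] with a `toxicity` table
#'   (columns `condition`, `ratio`, `post_mean`), or such a table directly.
#' @param seed RNG seed.
#' @param n_replicates Replicates per condition (default from preset, 5).
#' @param noise_sdlog Log-scale SD of the multiplicative noise (default 0.08).
#'
#' @return A `data.frame` with columns `condition`, `replicate`,
#'   `pre_lysis`, `post_lysis`; the injected ratios are stored in the
#'   `ground_truth` attribute.
#' @export
generate_toxicity_plate <- function(preset, seed = 1L, n_replicates = NULL,
                                    noise_sdlog = 0.08) {
  tox <- if (is.data.frame(preset)) preset else preset$toxicity
  if (is.null(n_replicates))
    n_replicates <- if (!is.data.frame(preset) &&
                        !is.null(preset$n_replicates)) preset$n_replicates
                    else 5L
  if (any(tox$ratio < 0 | tox$ratio > 1))
    stop("injected death ratios must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    rec <- expand.grid(replicate = seq_len(n_replicates),
                       condition = tox$condition,
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)[, 2:1]
    idx <- match(rec$condition, tox$condition)
    m <- -noise_sdlog^2 / 2
    post <- tox$post_mean[idx] * stats::rlnorm(nrow(rec), m, noise_sdlog)
    pre <- post * tox$ratio[idx] * stats::rlnorm(nrow(rec), m, noise_sdlog)
    out <- data.frame(condition = rec$condition, replicate = rec$replicate,
                      pre_lysis = pre, post_lysis = post,
                      stringsAsFactors = FALSE)
    attr(out, "ground_truth") <- tox
    out
  })
}

# One densitometry lane: a Gaussian monomer peak plus a broad half-Gaussian
# smear toward high molecular weight, with component areas set by the
# aggregated fraction. Positions run low -> high molecular weight.
sim_lane <- function(fraction, total, n_points = 400L,
                     monomer_center = 18, monomer_sd = 2.5,
                     smear_center = 55, smear_sd = 8, smear_from = 38,
                     baseline_level = 2, baseline_noise_sd = 0.05) {
  stopifnot_scalar_prob(fraction, "fraction")
  pos <- seq(0, 100, length.out = n_points)
  monomer <- stats::dnorm(pos, monomer_center, monomer_sd)
  monomer <- monomer / trapz(pos, monomer)
  smear <- exp(-0.5 * ((pos - smear_center) / smear_sd)^2)
  smear[pos < smear_from] <- 0
  s_area <- trapz(pos, smear)
  smear <- if (s_area > 0) smear / s_area else smear
  signal <- (1 - fraction) * total * monomer + fraction * total * smear +
    baseline_level +
    stats::rnorm(n_points, 0, baseline_noise_sd)
  list(position = pos, signal = pmax(signal, 0))
}

#' Generate synthetic SDD-AGE lane profiles
#'
#' Each lane is a 1-D densitometry profile: a sharp Gaussian peak of
#' monomeric protein at low molecular weight plus a broad smear extending
#' toward high molecular weight, on a noisy baseline. The areas of the two
#' components are set by the preset's injected aggregated fraction for that
#' lane (jittered multiplicatively per lane with mean 1), and the total lane
#' amount is drawn lognormally around the preset total.
#'
#' @param preset A preset from [get_preset()] with a `lanes` table (columns
#'   `condition`, `fraction`, `total`), or such a table directly.
#' @param seed RNG seed.
#' @param fraction_jitter_sdlog,total_sdlog Log-scale SDs of the per-lane
#'   multiplicative noise on the aggregated fraction and lane total.
#'
#' @return A named list of lanes; each lane is a list with `position`
#'   (migration coordinate, low to high molecular weight), `signal`, and
#'   `condition`. Injected fractions are in the `ground_truth` attribute.
#' @export
generate_lane_profiles <- function(preset, seed = 1L,
                                   fraction_jitter_sdlog = 0.05,
                                   total_sdlog = 0.1) {
  lanes <- if (is.data.frame(preset)) preset else preset$lanes
  with_seed(seed, {
    out <- lapply(seq_len(nrow(lanes)), function(i) {
      f <- lanes$fraction[i] *
        stats::rlnorm(1, -fraction_jitter_sdlog^2 / 2, fraction_jitter_sdlog)
      f <- min(f, 0.95)
      tot <- lanes$total[i] * stats::rlnorm(1, -total_sdlog^2 / 2, total_sdlog)
      lane <- sim_lane(f, tot)
      lane$condition <- lanes$condition[i]
      lane
    })
    names(out) <- lanes$condition
    attr(out, "ground_truth") <- lanes
    out
  })
}
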
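# Dye-exclusion cytotoxicity: a membrane-impermeant dye stains only dead
# cells; lysing the membrane with detergent then stains all cells. The
# fraction of dead cells in a well is the ratio of the fluorescence read
# before lysis (dead cells) to the fluorescence read after lysis (total
# cells).

#' Dead-to-total fluorescence ratio per well
#'
#' Computes `pre_lysis / post_lysis` for each well of a toxicity plate. The
#' ratio lies in `[0, 1]` for well-formed data; wells with `pre > post` are
#' retained with their computed ratio (> 1) and a warning rather than being
#' silently clipped, and wells with `post_lysis == 0` yield `NA` with a
#' warning.
#'
#' @param plate A `data.frame` with columns `condition`, `replicate`,
#'   `pre_lysis`, `post_lysis` (e.g. from [generate_toxicity_plate()]).
#'
#' @return The plate with a `ratio` column appended.
#' @export
toxicity_ratio <- function(plate) {
  req <- c("pre_lysis", "post_lysis")
  if (!all(req %in% names(plate)))
    stop("plate must have `pre_lysis` and `post_lysis` columns", call. = FALSE)
  if (any(plate$pre_lysis < 0 | plate$post_lysis < 0, na.rm = TRUE))
    stop("fluorescence readings must be non-negative", call. = FALSE)
  bad_zero <- plate$post_lysis == 0
  if (any(bad_zero))
    warning(sum(bad_zero), " well(s) with post-lysis fluorescence 0; ",
            "ratio undefined (NA)")
  flagged <- plate$pre_lysis > plate$post_lysis & !bad_zero
  if (any(flagged))
    warning(sum(flagged), " well(s) with pre-lysis > post-lysis ",
            "fluorescence; ratios > 1 retained, not clipped")
  plate$ratio <- ifelse(bad_zero, NA_real_,
                        plate$pre_lysis / plate$post_lysis)
  plate
}

#' Normalize per-condition death ratios to a control condition
#'
#' Biological replicate ratios of every condition are divided by the *mean*
#' ratio of the control condition (replicates are not paired), so the
#' control condition normalizes to exactly 1. Normalization is invariant
#' under uniform rescaling of all fluorescence readings.
#'
#' @param plate A plate with a `ratio` column (see [toxicity_ratio()]); the
#'   ratio column is computed on the fly if absent.
#' @param control Control condition label (e.g. the wild-type tRNA +
#'   reporter-only condition).
#'
#' @return A `data.frame` with one row per condition: `condition`, `n`,
#'   `mean_ratio`, `normalized_mean`, `normalized_sd`.
#' @export
normalize_to_control <- function(plate, control) {
  if (!"ratio" %in% names(plate)) plate <- toxicity_ratio(plate)
  if (!control %in% plate$condition)
    stop(sprintf("control condition '%s' not present", control), call. = FALSE)
  ctrl_mean <- mean(plate$ratio[plate$condition == control], na.rm = TRUE)
  if (is.na(ctrl_mean) || ctrl_mean == 0)
    stop("control condition mean ratio is 0; cannot normalize", call. = FALSE)
  conditions <- unique(plate$condition)
  out <- do.call(rbind, lapply(conditions, function(cond) {
    r <- plate$ratio[plate$condition == cond]
    r <- r[!is.na(r)]
    data.frame(condition = cond, n = length(r), mean_ratio = mean(r),
               normalized_mean = mean(r / ctrl_mean),
               normalized_sd = if (length(r) > 1L) stats::sd(r / ctrl_mean)
                               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
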
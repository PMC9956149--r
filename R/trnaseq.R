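# tRNA-seq count-table analysis. Mature-tRNA sequencing cannot attribute
# reads to individual members of a set of identical gene copies, so such
# transcripts arrive as `multi`-mapped rows that are analysed as one pooled
# transcript; transcripts with a distinguishing mutation are `unique`.

count_meta_cols <- c("transcript_id", "family", "mapping_class")

# Sample metadata (condition, replicate) for a count table; reconstructed
# from "<condition>_<replicate>" column names when the attribute is absent.
count_samples <- function(table) {
  s <- attr(table, "samples")
  if (!is.null(s)) return(s)
  cols <- setdiff(names(table), count_meta_cols)
  m <- regmatches(cols, regexec("^(.*)_([0-9]+)$", cols))
  data.frame(condition = vapply(m, `[`, "", 2L),
             replicate = as.integer(vapply(m, `[`, "", 3L)),
             sample = cols, stringsAsFactors = FALSE)
}

count_matrix <- function(table) {
  as.matrix(table[, setdiff(names(table), count_meta_cols), drop = FALSE])
}

#' Pool identical-gene-copy counts
#'
#' Multi-mapped transcripts assigned to the same pool have their counts
#' summed within each sample; unique-mapping transcripts pass through
#' unpooled. By default the pool of a multi-mapped transcript is its
#' identifier with the trailing copy number removed (so the six identical
#' `Ser-AGA-2-x` gene copies pool to `Ser-AGA-2`); a named `family_map`
#' (transcript id -> pool id) overrides this. Multi-mapped transcripts
#' missing from a supplied map are retained as their own pool with a
#' warning.
#'
#' @param table A count table (see [generate_count_table()]).
#' @param family_map Optional named character vector mapping transcript ids
#'   to pool ids.
#'
#' @return A pooled count table; pooled rows keep the shared family and
#'   mapping class, with `transcript_id` set to the pool id.
#' @export
pool_counts <- function(table, family_map = NULL) {
  samples <- count_samples(table)
  pool_id <- table$transcript_id
  multi <- table$mapping_class == "multi"
  if (is.null(family_map)) {
    pool_id[multi] <- sub("-[0-9]+$", "", table$transcript_id[multi])
  } else {
    mapped <- table$transcript_id %in% names(family_map)
    missing <- multi & !mapped
    if (any(missing))
      warning("transcript(s) missing from family_map retained as their own ",
              "pool: ", paste(table$transcript_id[missing], collapse = ", "))
    pool_id[mapped] <- family_map[table$transcript_id[mapped]]
  }
  counts <- count_matrix(table)
  pooled <- rowsum(counts, group = pool_id, reorder = FALSE)
  first <- !duplicated(pool_id)
  out <- data.frame(transcript_id = pool_id[first],
                    family = table$family[first],
                    mapping_class = table$mapping_class[first],
                    stringsAsFactors = FALSE)
  out <- out[match(rownames(pooled), out$transcript_id), ]
  out <- cbind(out, as.data.frame(pooled))
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Normalize read counts by per-sample totals
#'
#' Each sample's counts are divided by that sample's total read count and
#' multiplied by the mean total across samples, so that column sums are
#' equalized while count magnitudes remain comparable to the raw table.
#'
#' @param table A count table.
#'
#' @return The table with normalized (fractional) counts.
#' @export
normalize_counts <- function(table) {
  counts <- count_matrix(table)
  totals <- colSums(counts)
  if (any(totals == 0))
    stop("sample(s) with zero total reads cannot be normalized", call. = FALSE)
  norm <- sweep(counts, 2L, totals, "/") * mean(totals)
  out <- cbind(table[, intersect(count_meta_cols, names(table)), drop = FALSE],
               as.data.frame(norm))
  attr(out, "samples") <- count_samples(table)
  out
}

#' Differential tRNA abundance between two conditions
#'
#' Per-transcript fold change of group means and a two-sided Welch t-test,
#' with indicator flags at 1.5-fold and 2-fold in either direction. Fold
#' changes use a floor-style pseudocount: each group mean is floored at
#' `pseudocount` before the ratio, which stabilizes transcripts with zero
#' counts (the mutant tRNA has < 1 read on average in wild-type cells)
#' while leaving well-measured transcripts untouched. Transcripts with all
#' zero counts in both groups are excluded with a message. No
#' multiple-testing correction is applied by default; set
#' `p_adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param table A count table (typically normalized, see
#'   [normalize_counts()]).
#' @param group_a,group_b Condition labels (fold change is b over a).
#' @param pseudocount Floor applied to group means (default 0.5).
#' @param p_adjust Multiple-testing adjustment method (default `"none"`).
#'
#' @return A `data.frame`: `transcript_id`, `mean_a`, `mean_b`,
#'   `fold_change` (b/a), `log2_fc`, `p_value`, `flag_1.5x`, `flag_2x`.
#' @export
differential_abundance <- function(table, group_a, group_b,
                                   pseudocount = 0.5, p_adjust = "none") {
  samples <- count_samples(table)
  ia <- samples$sample[samples$condition == group_a]
  ib <- samples$sample[samples$condition == group_b]
  if (length(ia) < 2L || length(ib) < 2L)
    stop("each group needs at least 2 replicates", call. = FALSE)
  A <- as.matrix(table[, ia, drop = FALSE])
  B <- as.matrix(table[, ib, drop = FALSE])
  allzero <- rowSums(A) == 0 & rowSums(B) == 0
  if (any(allzero)) {
    message(sum(allzero), " transcript(s) with all-zero counts in both ",
            "groups excluded")
    A <- A[!allzero, , drop = FALSE]
    B <- B[!allzero, , drop = FALSE]
  }
  ids <- table$transcript_id[!allzero]
  mean_a <- rowMeans(A)
  mean_b <- rowMeans(B)
  fc <- pmax(mean_b, pseudocount) / pmax(mean_a, pseudocount)
  p <- vapply(seq_along(ids), function(i)
    welch_t_test(A[i, ], B[i, ])$p_value, numeric(1))
  p <- stats::p.adjust(p, method = p_adjust)
  out <- data.frame(transcript_id = ids, mean_a = mean_a, mean_b = mean_b,
                    fold_change = fc, log2_fc = log2(fc), p_value = p,
                    stringsAsFactors = FALSE)
  out$`flag_1.5x` <- out$fold_change >= 1.5 | out$fold_change <= 1 / 1.5
  out$flag_2x <- out$fold_change >= 2 | out$fold_change <= 0.5
  rownames(out) <- NULL
  out
}

#' Fractions of the mutant tRNA within reference tRNA pools
#'
#' Expresses the mutant transcript's mean read count in one condition as a
#' fraction of (i) the total serine-tRNA pool, (ii) the wild-type
#' serine-AGA pool, and (iii) the phenylalanine-decoder pool, on raw mean
#' counts within that condition. The mutant is itself a serine tRNA and a
#' phenylalanine decoder, so it is added to those two denominators; the AGA
#' pool excludes it. Because only transfected cells carry the mutant, the
#' population-level fraction of Phe decoders is also divided by the
#' transfection efficiency; adjusted values above 1 are flagged, not
#' clamped.
#'
#' @param table A (typically pooled, raw) count table.
#' @param aaa_id Transcript/pool id of the mutant tRNA.
#' @param ser_pool_ids Ids of all serine pools (excluding the mutant).
#' @param aga_pool_id Id of the wild-type Ser-AGA pool.
#' @param phe_pool_ids Ids of the phenylalanine-decoder pools (excluding
#'   the mutant).
#' @param transfection_eff Transfection efficiency in (0, 1].
#' @param condition Condition whose samples are averaged (default `"AAA"`,
#'   the mutant-expressing cells).
#'
#' @return List with `fraction_of_ser_pool`, `fraction_of_aga_pool`,
#'   `fraction_of_phe_decoders`, `transfection_adjusted_fraction`, and
#'   `flag_above_one`.
#' @export
pool_fractions <- function(table, aaa_id, ser_pool_ids, aga_pool_id,
                           phe_pool_ids, transfection_eff,
                           condition = "AAA") {
  stopifnot_scalar_prob(transfection_eff, "transfection_eff")
  if (transfection_eff == 0)
    stop("`transfection_eff` must be positive", call. = FALSE)
  samples <- count_samples(table)
  cols <- samples$sample[samples$condition == condition]
  if (length(cols) == 0L)
    stop(sprintf("no samples for condition '%s'", condition), call. = FALSE)
  mean_of <- function(ids) {
    hit <- table$transcript_id %in% ids
    if (!any(hit))
      stop("pool id(s) not found: ", paste(ids, collapse = ", "),
           call. = FALSE)
    sum(rowMeans(table[hit, cols, drop = FALSE]))
  }
  aaa <- mean_of(aaa_id)
  ser <- mean_of(ser_pool_ids)
  aga <- mean_of(aga_pool_id)
  phe <- mean_of(phe_pool_ids)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  phe_frac <- frac(aaa, phe + aaa)
  adj <- phe_frac / transfection_eff
  list(fraction_of_ser_pool = frac(aaa, ser + aaa),
       fraction_of_aga_pool = frac(aaa, aga),
       fraction_of_phe_decoders = phe_frac,
       transfection_adjusted_fraction = adj,
       flag_above_one = isTRUE(adj > 1))
}
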
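# Count pooling, normalization, differential abundance, and pool
# fractions.

toy_table <- function(counts, mapping_class = "unique",
                      conditions = c("A", "A", "B", "B")) {
  n <- nrow(counts)
  out <- data.frame(transcript_id = rownames(counts),
                    family = rownames(counts),
                    mapping_class = rep(mapping_class, length.out = n),
                    stringsAsFactors = FALSE)
  reps <- ave(seq_along(conditions), conditions, FUN = seq_along)
  cols <- paste(conditions, reps, sep = "_")
  for (j in seq_along(cols)) out[[cols[j]]] <- counts[, j]
  attr(out, "samples") <- data.frame(condition = conditions,
                                     replicate = reps, sample = cols,
                                     stringsAsFactors = FALSE)
  out
}

test_that("pooling sums identical gene copies and passes unique rows through", {
  m <- matrix(c(3, 7, 5), nrow = 3, ncol = 4,
              dimnames = list(c("Ser-AGA-2-1", "Ser-AGA-2-2", "Lys-1-1"), NULL))
  tab <- toy_table(m, mapping_class = c("multi", "multi", "unique"))
  pooled <- pool_counts(tab)
  expect_equal(nrow(pooled), 2L)
  expect_equal(unname(unlist(pooled[pooled$transcript_id == "Ser-AGA-2",
                                    4:7])), rep(10, 4))
  expect_equal(unname(unlist(pooled[pooled$transcript_id == "Lys-1-1",
                                    4:7])), rep(5, 4))

  # identity map leaves the table unchanged
  same <- pool_counts(toy_table(m, mapping_class = "unique"))
  expect_equal(fociquant:::count_matrix(same), fociquant:::count_matrix(tab))

  # multi transcript missing from a supplied map is kept, with a warning
  expect_warning(kept <- pool_counts(tab, family_map = c("Ser-AGA-2-1" = "p")),
                 "missing from family_map")
  expect_true("Ser-AGA-2-2" %in% kept$transcript_id)
})

test_that("normalization equalizes sample totals and preserves proportions", {
  m <- matrix(c(10, 30, 20, 60, 10, 30, 10, 30), nrow = 2)
  rownames(m) <- c("a", "b")
  tab <- toy_table(m)
  norm <- normalize_counts(tab)
  cm <- fociquant:::count_matrix(norm)
  expect_true(all(abs(colSums(cm) - mean(colSums(m))) < 1e-12))
  # sample 2 had double the total: its normalized counts halve
  expect_equal(unname(cm[, 2] / m[, 2]), rep(0.5 * mean(colSums(m)) / 40, 2))
  # equal-total samples are unchanged up to the common rescale
  expect_equal(unname(cm[, 3]), unname(m[, 3] * mean(colSums(m)) / 40))

  m0 <- m; m0[, 1] <- 0
  expect_error(normalize_counts(toy_table(m0)), "zero total")
})

test_that("pooling and normalization commute", {
  set.seed(3)
  m <- matrix(rpois(20, 40), nrow = 5,
              dimnames = list(paste0("Ser-AGA-2-", 1:5), NULL))
  tab <- toy_table(m, mapping_class = c(rep("multi", 4), "unique"))
  a <- fociquant:::count_matrix(pool_counts(normalize_counts(tab)))
  b <- fociquant:::count_matrix(normalize_counts(pool_counts(tab)))
  expect_equal(a, b)
})

test_that("fold changes follow the floored-pseudocount arithmetic", {
  m <- matrix(c(10, 10, 10, 10, 18, 18, 18, 18), nrow = 2, byrow = TRUE,
              dimnames = list(c("flat", "up"), NULL))
  m["flat", ] <- c(9, 11, 17, 19)
  m["up", ] <- c(10, 10, 18, 18)
  tab <- toy_table(m)
  da <- differential_abundance(tab, "A", "B")
  up <- da[da$transcript_id == "up", ]
  expect_equal(up$fold_change, 1.8)
  expect_true(up$`flag_1.5x`)
  expect_false(up$flag_2x)

  # identical groups: fold change 1, no flags
  m2 <- matrix(rep(c(5, 7), 4), nrow = 1,
               dimnames = list("x", NULL))
  m2 <- rbind(x = c(5, 7, 5, 7))
  da2 <- differential_abundance(toy_table(m2), "A", "B")
  expect_equal(da2$fold_change, 1)
  expect_false(da2$`flag_1.5x`)
})

test_that("fold changes are reciprocal under group swap", {
  set.seed(5)
  m <- matrix(rpois(40, 30), nrow = 10,
              dimnames = list(paste0("t", 1:10), NULL))
  tab <- toy_table(m)
  ab <- differential_abundance(tab, "A", "B")
  ba <- differential_abundance(tab, "B", "A")
  expect_equal(ab$fold_change, 1 / ba$fold_change)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("all-zero transcripts are excluded with a message", {
  m <- rbind(zero = c(0, 0, 0, 0), ok = c(5, 6, 7, 8))
  expect_message(da <- differential_abundance(toy_table(m), "A", "B"),
                 "all-zero")
  expect_equal(da$transcript_id, "ok")
})

test_that("pool fractions match the worked arithmetic", {
  m <- rbind("Ser-AAA-2-3" = rep(26, 4),
             "Ser-AGA-2" = rep(2000, 4),
             "Ser-CGA-1-1" = rep(6641, 4),
             "Phe-GAA-1" = rep(1831, 4))
  tab <- toy_table(m, conditions = c("AAA", "AAA", "AGA", "AGA"))
  fr <- pool_fractions(tab, "Ser-AAA-2-3",
                       ser_pool_ids = c("Ser-AGA-2", "Ser-CGA-1-1"),
                       aga_pool_id = "Ser-AGA-2",
                       phe_pool_ids = "Phe-GAA-1",
                       transfection_eff = 0.6)
  expect_equal(fr$fraction_of_aga_pool, 26 / 2000)
  expect_equal(fr$fraction_of_phe_decoders, 26 / (26 + 1831))
  expect_equal(fr$transfection_adjusted_fraction, 26 / (26 + 1831) / 0.6)
  expect_equal(fr$fraction_of_ser_pool, 26 / (26 + 2000 + 6641))
  expect_false(fr$flag_above_one)

  m0 <- m; m0["Ser-AAA-2-3", ] <- 0
  fr0 <- pool_fractions(toy_table(m0, conditions = c("AAA", "AAA", "AGA", "AGA")),
                        "Ser-AAA-2-3", c("Ser-AGA-2", "Ser-CGA-1-1"),
                        "Ser-AGA-2", "Phe-GAA-1", 0.6)
  expect_equal(fr0$fraction_of_aga_pool, 0)
  expect_equal(fr0$fraction_of_phe_decoders, 0)
})

test_that("null transcripts are almost never flagged at 2-fold", {
  p <- get_preset("fig2")
  flagged <- 0L; total <- 0L
  for (s in 1:30) {
    tab <- normalize_counts(pool_counts(generate_count_table(p, seed = s)))
    da <- differential_abundance(tab, "AAA", "AGA")
    nulls <- grepl("^Null", da$transcript_id)
    flagged <- flagged + sum(da$flag_2x[nulls])
    total <- total + sum(nulls)
  }
  expect_lt(flagged / total, 0.05)
})
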
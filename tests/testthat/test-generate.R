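# Synthetic-data generator: determinism, ground-truth consistency, and
# distributional behaviour of the simulated fields, time lapses, count
# tables, toxicity plates, and lane profiles.

test_that("an empty field is pure background with empty ground truth", {
  cfg <- generator_config(frame_shape = c(64L, 64L), n_cells = 0L)
  fr <- generate_frame(cfg, seed = 1)
  gt <- attr(fr, "ground_truth")
  expect_equal(nrow(gt$cells), 0L)
  expect_equal(nrow(gt$foci), 0L)
  expect_lt(max(fr$pixels), cfg$background_level + 6 * cfg$background_noise_sd)
})

test_that("identical config and seed give bit-identical output", {
  cfg <- generator_config(frame_shape = c(128L, 128L), n_cells = 15L,
                          aggregates_per_cell_lambda = 1)
  f1 <- generate_frame(cfg, seed = 7)
  f2 <- generate_frame(cfg, seed = 7)
  expect_identical(f1$pixels, f2$pixels)
  expect_identical(attr(f1, "ground_truth"), attr(f2, "ground_truth"))
  f3 <- generate_frame(cfg, seed = 8)
  expect_false(identical(f1$pixels, f3$pixels))

  tl1 <- generate_timelapse(cfg, times = c(1, 2, 3), seed = 5)
  tl2 <- generate_timelapse(cfg, times = c(1, 2, 3), seed = 5)
  expect_identical(lapply(tl1$frames, `[[`, "pixels"),
                   lapply(tl2$frames, `[[`, "pixels"))
  expect_identical(tl1$ground_truth, tl2$ground_truth)

  p2 <- get_preset("fig2")
  expect_identical(generate_count_table(p2, seed = 3),
                   generate_count_table(p2, seed = 3))
  p4 <- get_preset("fig4")
  expect_identical(generate_toxicity_plate(p4, seed = 3),
                   generate_toxicity_plate(p4, seed = 3))
  p7 <- get_preset("fig7")
  expect_identical(generate_lane_profiles(p7, seed = 3),
                   generate_lane_profiles(p7, seed = 3))
})

test_that("rendering does not change a time lapse's ground truth", {
  cfg <- generator_config(frame_shape = c(96L, 96L), n_cells = 6L,
                          aggregates_per_cell_lambda = 1, rupture_rate = 0.1)
  a <- generate_timelapse(cfg, times = 1:6, seed = 2, render = TRUE)
  b <- generate_timelapse(cfg, times = 1:6, seed = 2, render = FALSE)
  expect_null(b$frames)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("transfected fraction follows the binomial ground truth", {
  cfg <- generator_config(frame_shape = c(256L, 256L), n_cells = 50L,
                          transfected_fraction = 0.6, cell_radius_px = c(8, 1))
  fr <- generate_frame(cfg, seed = 1)
  gt <- attr(fr, "ground_truth")
  # the transfected flag and a positive rendered intensity must agree
  expect_identical(gt$cells$transfected, gt$cells$intensity > 0)

  fractions <- vapply(1:100, function(s) {
    gt <- attr(generate_frame(cfg, seed = s), "ground_truth")
    mean(gt$cells$transfected)
  }, numeric(1))
  se <- sqrt(0.6 * 0.4 / 50) / sqrt(100)
  expect_lt(abs(mean(fractions) - 0.6), 3 * se)
})

test_that("placement fails loudly when cells cannot fit", {
  cfg <- generator_config(frame_shape = c(48L, 48L), n_cells = 60L,
                          cell_radius_px = c(8, 0))
  expect_error(generate_frame(cfg, seed = 1), "placement failure")
})

test_that("cells persist without rupture and foci follow the Poisson rate", {
  cfg <- generator_config(frame_shape = c(128L, 128L), n_cells = 10L,
                          aggregates_per_cell_lambda = 2, rupture_rate = 0)
  tl <- generate_timelapse(cfg, times = seq(1, 10), seed = 4, render = FALSE)
  expect_equal(nrow(tl$ground_truth$ruptures), 0L)
  expect_true(all(tl$ground_truth$series$n_alive == 10L))

  # constant lambda: mean true foci per cell across frames ~ Poisson(2)
  apc <- unlist(lapply(1:40, function(s) {
    generate_timelapse(cfg, times = 1:10, seed = s,
                       render = FALSE)$ground_truth$series$aggregates_per_cell
  }))
  # Var(apc per frame) = lambda / n_cells
  expect_lt(abs(mean(apc) - 2), 3 * sqrt(2 / (length(apc) * 10)))
})

test_that("logged ruptures replay exactly from the rupture stream", {
  cfg <- generator_config(frame_shape = c(128L, 128L), n_cells = 12L,
                          transfected_fraction = 1, rupture_rate = 0.2)
  times <- seq(1, 20)
  tl <- generate_timelapse(cfg, times = times, seed = 9, render = FALSE)
  # replay: stream seeds are the first 3 + nt draws of sample.int under
  # the base seed; stream 2 holds the rupture uniforms, cell index fastest
  stream <- withr::with_seed(9L, sample.int(2147483646L, 3L + length(times)))
  U <- withr::with_seed(stream[2L],
                        matrix(runif(12 * (length(times) - 1L)), nrow = 12))
  expected <- data.frame(cell = integer(0), frame = integer(0))
  for (i in 1:12) {
    hit <- which(U[i, ] < 0.2)
    if (length(hit) > 0L)
      expected <- rbind(expected,
                        data.frame(cell = i, frame = hit[1L] + 1L))
  }
  got <- tl$ground_truth$ruptures
  expect_equal(got$cell, expected$cell)
  expect_equal(got$frame, expected$frame)
  expect_equal(got$time_h, times[expected$frame])
})

test_that("time lapses validate their inputs", {
  cfg <- generator_config(frame_shape = c(64L, 64L), n_cells = 2L)
  expect_error(generate_timelapse(cfg, times = numeric(0)), "non-empty")
  expect_error(generate_timelapse(cfg, times = c(2, 1)), "increasing")
})

test_that("count tables are Poisson draws with conserved totals", {
  cm <- data.frame(transcript_id = c("a", "b"), family = c("A", "B"),
                   mapping_class = "unique", X = c(0, 100), Y = c(5, 50))
  tab <- generate_count_table(cm, seed = 1, n_replicates = 3)
  expect_true(all(tab[tab$transcript_id == "a", startsWith(names(tab), "X")] == 0))
  counts <- as.matrix(tab[, -(1:3)])
  expect_equal(colSums(counts), colSums(counts))  # structural sanity
  expect_identical(dim(counts), c(2L, 6L))
  # additivity: per-sample totals equal the sum over transcripts
  expect_equal(unname(colSums(counts)),
               unname(vapply(as.data.frame(counts), sum, numeric(1))))
  cm$X[1] <- -1
  expect_error(generate_count_table(cm, seed = 1), "negative")
})

test_that("toxicity plates honour injected death ratios at the extremes", {
  tox <- data.frame(condition = c("dead0", "dead1"), ratio = c(0, 1),
                    post_mean = 1000)
  plate <- generate_toxicity_plate(tox, seed = 2, n_replicates = 4,
                                   noise_sdlog = 0)
  expect_true(all(plate$pre_lysis[plate$condition == "dead0"] == 0))
  expect_equal(plate$pre_lysis[plate$condition == "dead1"],
               plate$post_lysis[plate$condition == "dead1"])
})

test_that("lane profiles split monomer and smear areas by the injected fraction", {
  # no baseline, no noise: component areas are exact by construction
  l0 <- fociquant:::sim_lane(0, 1000, baseline_level = 0,
                             baseline_noise_sd = 0)
  fa <- fraction_aggregated(l0, window = c(8, 28))
  expect_lt(fa$fraction, 0.01)
  l5 <- fociquant:::sim_lane(0.5, 1000, baseline_level = 0,
                             baseline_noise_sd = 0)
  fa5 <- fraction_aggregated(l5, window = c(8, 28))
  expect_equal(fa5$fraction, 0.5, tolerance = 0.01)
})
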
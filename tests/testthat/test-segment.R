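# Background estimation, cell segmentation, aggregate detection, and the
# connected-components primitive.

test_that("background statistics are robust to bright objects", {
  const <- frame(matrix(10, 32, 32))
  bg <- estimate_background(const)
  expect_equal(bg$mean, 10)
  expect_equal(bg$sd, 0)
  expect_true(bg$degenerate)

  set.seed(11)
  px <- matrix(rnorm(200 * 200, 10, 2), 200, 200)
  bg2 <- estimate_background(frame(pmax(px, 0)))
  expect_lt(abs(bg2$mean - 10), 0.1)

  # 1% saturated pixels leave the estimate (nearly) unchanged
  px_sat <- px
  px_sat[sample(length(px_sat), 400)] <- 255
  bg3 <- estimate_background(frame(pmax(px_sat, 0)))
  expect_lt(abs(bg3$mean - bg2$mean), 0.05)
})

test_that("cell segmentation finds rendered disks with expected areas", {
  cfg <- generator_config(frame_shape = c(128L, 128L), n_cells = 0L,
                          background_noise_sd = 1)
  fr <- generate_frame(cfg, seed = 1)
  bg <- estimate_background(fr)
  empty <- segment_cells(fr, bg$mean, bg$sd)
  expect_equal(length(empty$areas), 0L)
  expect_false(any(empty$mask))

  # one disk of radius 8 at 10 sigma above background; the geometric
  # oracle is the disk area at the threshold-crossing radius of the
  # soft-edge profile (threshold k_cell = 3 sigma on a 10 sigma disk)
  px <- fr$pixels
  d <- sqrt(outer((1:128 - 50)^2, (1:128 - 60)^2, "+"))
  px <- px + 10 * bg$sd * fociquant:::disk_profile(d, 8)
  one <- segment_cells(frame(px), bg$mean, bg$sd)
  expect_equal(length(one$areas), 1L)
  r_star <- 6 + (2 / pi) * acos(2 * 0.3 - 1)
  expect_lt(abs(one$areas[1] - pi * r_star^2) / (pi * r_star^2), 0.12)
  expect_lt(abs(one$areas[1] - pi * 64) / (pi * 64), 0.20)

  # a second disjoint disk makes two components; overlapping disks merge
  d2 <- sqrt(outer((1:128 - 90)^2, (1:128 - 30)^2, "+"))
  two <- segment_cells(frame(px + 10 * bg$sd * fociquant:::disk_profile(d2, 8)),
                       bg$mean, bg$sd)
  expect_equal(length(two$areas), 2L)
  d3 <- sqrt(outer((1:128 - 52)^2, (1:128 - 68)^2, "+"))
  merged <- segment_cells(frame(px + 10 * bg$sd * fociquant:::disk_profile(d3, 8)),
                          bg$mean, bg$sd)
  expect_equal(length(merged$areas), 1L)
})

test_that("degenerate background falls back to a multiplicative threshold", {
  px <- matrix(10, 64, 64)
  px[20:30, 20:30] <- 100
  expect_message(seg <- segment_cells(frame(px), 10, 0), "degenerate")
  expect_equal(seg$threshold, 15)
  expect_equal(length(seg$areas), 1L)
  expect_equal(seg$areas[1], 121L)
})

test_that("labelling matches a brute-force 8-connectivity flood fill", {
  set.seed(42)
  for (density in c(0.2, 0.45, 0.6)) {
    for (rep in 1:4) {
      mask <- matrix(runif(64 * 64) < density, 64, 64)
      got <- label_components(mask)
      oracle <- flood_fill_label(mask)
      expect_identical(got$labels, canonical_labels(oracle))
      expect_identical(got$areas, as.integer(tabulate(oracle)))
    }
  }
  # non-square and single-pixel edge cases
  mask <- matrix(FALSE, 5, 9); mask[1, 1] <- TRUE; mask[5, 9] <- TRUE
  expect_identical(label_components(mask)$labels, flood_fill_label(mask))
})

test_that("aggregate detection recovers an injected focus exactly", {
  # three square cells of differing diffuse intensity on background 10
  sq <- square_cells_frame(c(80, 100, 125))
  seg <- segment_cells(sq$frame, 10, 1)
  expect_equal(length(seg$areas), 3L)

  # no focus: all cell pixels equal their diffuse level -> nothing above T
  agg0 <- detect_aggregates(sq$frame, seg)
  expect_equal(length(agg0$areas), 0L)

  # inject a 5-px focus far above the cell-level threshold
  px <- sq$frame$pixels
  o <- sq$origins[[2]]
  stat <- c(mean(c(90, 110, 135)), sd(c(90, 110, 135)))
  focus_val <- stat[1] + 25 * stat[2]
  idx <- rbind(c(o[1] + 4, o[2] + 4), c(o[1] + 5, o[2] + 4),
               c(o[1] + 3, o[2] + 4), c(o[1] + 4, o[2] + 5),
               c(o[1] + 4, o[2] + 3))
  px[idx] <- focus_val
  agg <- detect_aggregates(frame(px), segment_cells(frame(px), 10, 1),
                           k_sigma = 18)
  expect_equal(length(agg$areas), 1L)
  expect_equal(agg$areas[1], 5L)
  expect_identical(which(agg$mask), which(matrix(px == focus_val, 64, 64)))
})

test_that("aggregate mask is always inside the cell mask", {
  cfg <- generator_config(frame_shape = c(192L, 192L), n_cells = 8L,
                          cell_mean_intensity = 400,
                          aggregates_per_cell_lambda = 2)
  for (s in 1:5) {
    fr <- generate_frame(cfg, seed = s)
    seg <- segment_frame(fr)
    expect_true(all(seg$cell_mask[seg$aggregate_mask]))
  }
})

test_that("raising k_sigma never increases the aggregate area", {
  cfg <- generator_config(frame_shape = c(192L, 192L), n_cells = 8L,
                          cell_mean_intensity = 400,
                          aggregates_per_cell_lambda = 2)
  fr <- generate_frame(cfg, seed = 3)
  seg <- segment_cells(fr, estimate_background(fr)$mean,
                       estimate_background(fr)$sd)
  areas <- vapply(c(2, 6, 12, 18, 30, 60), function(k)
    sum(detect_aggregates(fr, seg, k_sigma = k)$areas), numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("empty cell mask yields an empty aggregate mask with a warning", {
  fr <- frame(matrix(10, 32, 32))
  cells <- list(labels = matrix(0L, 32, 32), mask = matrix(FALSE, 32, 32),
                areas = integer(0))
  expect_warning(agg <- detect_aggregates(fr, cells), "empty cell mask")
  expect_false(any(agg$mask))
})

test_that("detected foci counts track generator ground truth", {
  # bright cells carrying Poisson foci; count recovery via median adjustment
  cfg <- generator_config(frame_shape = c(256L, 256L), n_cells = 20L,
                          cell_radius_px = c(9, 1),
                          cell_mean_intensity = 900,
                          aggregates_per_cell_lambda = 2.5)
  segs <- list(); truth <- integer(0)
  for (s in 1:6) {
    fr <- generate_frame(cfg, seed = s)
    segs[[s]] <- segment_frame(fr, keep_masks = FALSE)
    truth <- c(truth, sum(attr(fr, "ground_truth")$cells$n_foci))
  }
  calib <- calibrate_medians(segs)
  counts <- vapply(segs, function(sg)
    quantify_frame(sg, calib)$aggregate_count, numeric(1))
  expect_lt(abs(sum(counts) / sum(truth) - 1), 0.15)
})
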
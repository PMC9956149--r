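# Median calibration, median-adjusted counting, and transfection
# efficiency.

fake_seg <- function(cell_areas, agg_areas = integer(0), fluor = 0) {
  structure(list(background_mean = 10, background_sd = 1,
                 cell_areas = cell_areas, aggregate_areas = agg_areas,
                 cell_pixel_mean = NA_real_, cell_pixel_sd = NA_real_,
                 total_cell_area = sum(cell_areas),
                 total_aggregate_area = sum(agg_areas),
                 total_fluorescence = fluor,
                 threshold_used = NA_real_, k_sigma = 18,
                 cell_threshold = NA_real_, time_h = NA_real_,
                 condition = "c", replicate = 1L),
            class = "fq_seg")
}

test_that("median calibration follows the midpoint convention", {
  calib <- calibrate_medians(list(fake_seg(c(90, 100, 110))))
  expect_equal(calib$median_cell_area, 100)
  even <- calibrate_medians(list(fake_seg(c(80, 120))))
  expect_equal(even$median_cell_area, 100)
  expect_true(is.na(even$median_aggregate_area))
  expect_error(calibrate_medians(list()), "no segmentation")
  expect_error(calibrate_medians(list(fake_seg(integer(0)))), "no cell components")
})

test_that("calibration is invariant under frame order", {
  segs <- list(fake_seg(c(50, 60), c(4, 9)), fake_seg(c(200, 80), c(7)),
               fake_seg(c(120), c(12, 5, 6)))
  a <- calibrate_medians(segs)
  b <- calibrate_medians(rev(segs))
  expect_equal(a$median_cell_area, b$median_cell_area)
  expect_equal(a$median_aggregate_area, b$median_aggregate_area)
})

test_that("median-adjusted counts follow the area-ratio arithmetic", {
  calib <- calibrate_medians(list(fake_seg(rep(100, 9), rep(10, 3))))
  q <- quantify_frame(fake_seg(rep(100, 10), rep(10, 4), fluor = 5000), calib)
  expect_equal(q$cell_count, 10)
  expect_equal(q$aggregate_count, 4)
  expect_equal(q$aggregates_per_cell, 0.4)
  expect_equal(q$fluorescence_per_cell, 500)

  # no aggregate area -> zero counts even with a valid median
  q0 <- quantify_frame(fake_seg(rep(100, 10)), calib)
  expect_equal(q0$aggregate_count, 0)
  expect_equal(q0$aggregates_per_cell, 0)

  # empty frame -> per-cell quantities are missing, not zero
  qe <- quantify_frame(fake_seg(integer(0)), calib)
  expect_equal(qe$cell_count, 0)
  expect_true(is.na(qe$aggregates_per_cell))
  expect_true(is.na(qe$fluorescence_per_cell))
})

test_that("counting is scale-consistent under component duplication", {
  calib <- calibrate_medians(list(fake_seg(c(80, 100, 130), c(6, 10))))
  one <- quantify_frame(fake_seg(c(80, 100, 130), c(6, 10), fluor = 100), calib)
  two <- quantify_frame(fake_seg(rep(c(80, 100, 130), 2), rep(c(6, 10), 2),
                                 fluor = 200), calib)
  expect_equal(two$cell_count, 2 * one$cell_count)
  expect_equal(two$aggregate_count, 2 * one$aggregate_count)
  expect_equal(two$aggregates_per_cell, one$aggregates_per_cell)
  expect_equal(two$fluorescence_per_cell, one$fluorescence_per_cell)
})

test_that("transfection efficiency counts fluorescing components", {
  cfg <- generator_config(frame_shape = c(256L, 256L), n_cells = 40L,
                          transfected_fraction = 0.5,
                          cell_radius_px = c(8, 1))
  fr <- generate_frame(cfg, seed = 2)
  gt <- attr(fr, "ground_truth")
  eff <- transfection_efficiency(list(fr))
  expect_equal(eff$per_frame[1], mean(gt$cells$transfected))

  # nothing fluorescing -> efficiency 0
  dark <- generate_frame(
    generator_config(frame_shape = c(128L, 128L), n_cells = 10L,
                     transfected_fraction = 0), seed = 1)
  expect_equal(transfection_efficiency(list(dark))$per_frame, 0)

  # missing totals are an error
  fr2 <- fr; attr(fr2, "ground_truth") <- NULL
  expect_error(transfection_efficiency(list(fr2)), "total cell counts")
})
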
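test_that("segmentation fails cleanly on degenerate brightfield input", {
  cfg <- quiet_cfg()
  img <- render_cell_image(truth_row(), cfg)
  # identical pair: zero sd everywhere
  img2 <- cell_image(img$bf1, img$bf1, img$channels$biosensor,
                     img$channels$level, img$pixel_size)
  m <- segment_cell(img2)
  expect_true(m$failed)

  # pure-noise pair with no cell
  set.seed(1)
  n1 <- matrix(rnorm(40 * 60, 100, 2), 40, 60)
  n2 <- matrix(rnorm(40 * 60, 100, 2), 40, 60)
  m2 <- segment_cell(cell_image(n1, n2, n1, n1, 0.3))
  expect_true(m2$failed)
  rec <- quantify_image(cell_image(n1, n2, n1, n1, 0.3))
  expect_true(rec$segmentation_failed)
  expect_false(rec$gated)
})

test_that("segmentation recovers rod geometry from a rendered cell", {
  cfg <- quiet_cfg(seed = 5)
  tr <- truth_row(length_um = 10, radius_um = 1.75)
  img <- render_cell_image(tr, cfg)
  m <- segment_cell(img)
  expect_false(m$failed)
  true_area <- (2 * 1.75 * 10 + (pi - 4) * 1.75^2) / 0.3^2
  expect_lt(abs(m$area_px2 - true_area) / true_area, 0.10)
  expect_lt(abs(m$length_um - 10), 1 * 0.3)
  expect_lt(abs(m$radius_um - 1.75), 0.25)
})

test_that("segmentation is invariant to adding a constant to both brightfields", {
  cfg <- quiet_cfg(seed = 6)
  img <- render_cell_image(truth_row(cell_id = "shift"), cfg)
  img_shift <- cell_image(img$bf1 + 500, img$bf2 + 500,
                          img$channels$biosensor, img$channels$level,
                          img$pixel_size)
  m1 <- segment_cell(img)
  m2 <- segment_cell(img_shift)
  expect_identical(m1$mask, m2$mask)
})

test_that("measure_level handles uniform and spiked channels", {
  mask <- matrix(TRUE, 9, 9)
  expect_equal(measure_level(matrix(7, 9, 9), mask), 7)
  ch <- matrix(1, 11, 11)
  ch[5:7, 5:7] <- 10
  expect_equal(measure_level(ch, matrix(TRUE, 11, 11)), 10)
  # top9 interpretation: 9 brightest anywhere
  ch2 <- matrix(1, 9, 9); ch2[1, 1:9] <- 100  # a bright non-contiguous row
  expect_equal(measure_level(ch2, matrix(TRUE, 9, 9), method = "top9"), 100)
})

test_that("measure_level equals the exhaustive 3x3 window scan", {
  set.seed(11)
  for (rep in 1:25) {
    ch <- matrix(runif(15 * 15, 0, 100), 15, 15)
    mask <- matrix(runif(15 * 15) > 0.35, 15, 15)
    mask[6:11, 6:11] <- TRUE  # guarantee at least one full window
    expect_equal(measure_level(ch, mask), brute_force_level(ch, mask))
  }
})

test_that("measure_level is invariant to mask size at fixed concentration", {
  ch <- matrix(50, 30, 30)
  small <- matrix(FALSE, 30, 30); small[14:18, 14:18] <- TRUE
  large <- matrix(FALSE, 30, 30); large[5:26, 5:26] <- TRUE
  expect_equal(measure_level(ch, small), measure_level(ch, large))
})

test_that("measure_level errors when no 3x3 window fits", {
  mask <- matrix(FALSE, 9, 9); mask[5, ] <- TRUE  # 1-px-thin line
  expect_error(measure_level(matrix(1, 9, 9), mask),
               class = "cdkflow_degenerate_cell")
})

test_that("midline profile matches direct band indexing and render truth", {
  cfg <- noiseless_cfg()
  tr <- truth_row(activity_nc = 2, cdk_level_au = 300)
  img <- render_cell_image(tr, cfg)
  m <- segment_cell(img)
  prof <- midline_profile(img$channels$biosensor, m)
  # direct indexing oracle for the same chosen band
  expect_gt(length(prof$positions), 10)
  # noiseless N/C = 2: plateau at cyto_au, central bump at 2x
  expect_equal(median(prof$intensities), 100, tolerance = 0.05)
  expect_equal(max(prof$intensities), 200, tolerance = 0.05)
  # uniform channel gives a flat profile
  flat <- midline_profile(matrix(3, nrow(img$bf1), ncol(img$bf1)), m)
  expect_true(all(abs(flat$intensities - 3) < 1e-9))
})

test_that("activity_from_profile reads peaks, dips, and flat profiles", {
  flat <- make_profile(rep(100, 21))
  expect_equal(activity_from_profile(flat), 1)
  peak <- make_profile(c(rep(100, 9), 150, 300, 150, rep(100, 9)))
  expect_equal(activity_from_profile(peak), 3)
  dip <- make_profile(c(rep(100, 9), 70, 50, 70, rep(100, 9)))
  expect_equal(activity_from_profile(dip), 0.5)
  expect_error(activity_from_profile(make_profile(rep(-5, 21))),
               class = "cdkflow_quantification_error")
})

test_that("activity_from_profile is scale invariant", {
  base <- c(rep(100, 9), 160, 250, 160, rep(100, 9))
  a1 <- activity_from_profile(make_profile(base))
  a2 <- activity_from_profile(make_profile(base * 7.3))
  expect_equal(a1, a2)
})

test_that("true N/C of 1 leaves no central extremum above noise", {
  cfg <- quiet_cfg(seed = 12)
  img <- render_cell_image(truth_row(cell_id = "nc1", activity_nc = 1), cfg)
  m <- segment_cell(img)
  bg <- median(img$channels$biosensor[!m$mask])
  act <- activity_from_profile(midline_profile(
    img$channels$biosensor - bg, m))
  expect_equal(act, 1, tolerance = 0.03)
})

test_that("gradient RMS focus behaves like a sharpness statistic", {
  expect_equal(gradient_rms_focus(matrix(5, 10, 10)), 0)
  cb <- outer(1:20, 1:20, function(i, j) (i %/% 2 + j %/% 2) %% 2) * 100
  cb_blur <- EBImage::gblur(cb, 2)
  expect_gt(gradient_rms_focus(cb), gradient_rms_focus(cb_blur))
  # direct formula oracle
  set.seed(3)
  img <- matrix(rnorm(400), 20, 20)
  gx <- (img[2:19, 3:20] - img[2:19, 1:18]) / 2
  gy <- (img[3:20, 2:19] - img[1:18, 2:19]) / 2
  raw <- sqrt(mean(gx^2 + gy^2))
  expect_equal(gradient_rms_focus(img, scale = 1), raw)
})

test_that("defocused renderings fall below the focus gate at 65", {
  cfg <- quiet_cfg(seed = 14)
  img <- render_cell_image(truth_row(cell_id = "focus"), cfg)
  expect_gt(gradient_rms_focus(img$bf1), 65)
  blurred <- EBImage::gblur(img$bf1, 3, radius = 13)
  expect_lt(gradient_rms_focus(blurred), 65)
})

test_that("gating applies the documented cuts and matches a direct filter", {
  recs <- tibble::tibble(
    focus_grad_rms = c(64.9, 65.1, 80, 90, 70),
    area_px2 = c(300, 300, 50, 300, 300),
    aspect_ratio = c(3, 3, 3, 0.5, 3))
  gated <- gate_records(recs)
  expect_false(gated$gated[1])  # just below the focus cut
  expect_true(gated$gated[2])
  expect_false(gated$gated[3])  # area too small
  expect_false(gated$gated[4])  # aspect ratio inconsistent with a rod
  # all gates wide open: everything passes
  all_open <- gate_records(recs, list(grad_rms_min = -Inf,
                                      area = c(-Inf, Inf),
                                      aspect = c(-Inf, Inf)))
  expect_true(all(all_open$gated))
  # count matches a direct filter
  direct <- with(recs, focus_grad_rms > 65 & area_px2 >= 100 &
                   aspect_ratio >= 1.5 & aspect_ratio <= 10)
  expect_identical(gated$gated, direct)
})

test_that("quantification works on vertically oriented cells via rotation", {
  cfg <- quiet_cfg(seed = 15)
  tr <- truth_row(cell_id = "vert", length_um = 9, activity_nc = 2.2,
                  cdk_level_au = 400)
  img <- render_cell_image(tr, cfg)
  vert <- cell_image(t(img$bf1), t(img$bf2), t(img$channels$biosensor),
                     t(img$channels$level), img$pixel_size)
  rec <- quantify_image(vert)
  expect_false(rec$segmentation_failed)
  expect_lt(abs(rec$length_um - 9), 0.45)
  expect_lt(abs(rec$activity_nc - 2.2) / 2.2, 0.1)
})

test_that("renderer is deterministic and respects frame sizing", {
  cfg <- quiet_cfg(seed = 16)
  i1 <- render_cell_image(truth_row(), cfg)
  i2 <- render_cell_image(truth_row(), cfg)
  expect_identical(i1, i2)
  expect_error(render_cell_image(truth_row(length_um = 20), cfg,
                                 dim = c(20, 30)),
               class = "cdkflow_sizing_error")
})
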
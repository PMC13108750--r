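# Segmentation, shape metrics, yield, aggregation and centering.

test_that("chan-vese recovers disks and separates objects", {
  # blank frame: nothing to segment
  blank <- chan_vese_segment(image_frame(matrix(0.5, 64, 64), 2.5))
  expect_equal(max(blank$labels), 0L)
  expect_true(blank$converged)
  # noiseless disk: area within 2% of pi r^2
  fr <- make_spheroid_frame(50, dim = c(160, 160), pixel_size = 2)
  m <- chan_vese_segment(fr)
  expect_equal(max(m$labels), 1L)
  expect_lt(abs(sum(m$labels > 0) * 2^2 / (pi * 50^2 * 2^2) - 1), 0.02)
  # two well-separated disks: two labels
  px <- matrix(0, 200, 200)
  px[spheroflux:::raster_disk(c(200, 200), c(60, 60), 30)] <- 1
  px[spheroflux:::raster_disk(c(200, 200), c(145, 145), 25)] <- 1
  m2 <- chan_vese_segment(image_frame(px, 2.5))
  expect_equal(max(m2$labels), 2L)
  # non-convergence is reported, not hidden
  m3 <- chan_vese_segment(fr, cv_params(max_iter = 3))
  expect_false(m3$converged)
})

test_that("segmentation is equivalent to thresholding on binary input", {
  # on a noiseless, unblurred disk the recovered pixel set matches the
  # generating mask up to a 1-px boundary band
  truth <- spheroflux:::raster_disk(c(128, 128), c(64.5, 64.5), 40)
  fr <- image_frame(matrix(as.numeric(truth), 128, 128), 2.5)
  got <- morphological_cleanup(chan_vese_segment(fr), 3)$labels > 0
  kern <- EBImage::makeBrush(3, "disc")
  grown <- as.matrix(EBImage::dilate(matrix(as.numeric(truth), 128, 128), kern)) > 0
  shrunk <- as.matrix(EBImage::erode(matrix(as.numeric(truth), 128, 128), kern)) > 0
  expect_true(all(got[shrunk]))       # everything well inside is kept
  expect_true(!any(got[!grown]))      # nothing beyond a 1-px band is added
})

test_that("morphological cleanup fills holes without distorting the outline", {
  disk <- disk_mask(30)
  m0 <- morphological_cleanup(disk, radius = 0, pixel_size = 1)
  expect_identical(m0$labels > 0, disk)  # hole-free, radius 0: identity
  holed <- disk
  holed[40:42, 40:42] <- FALSE  # 3-px interior hole
  m <- morphological_cleanup(holed, radius = 2, pixel_size = 1)
  expect_equal(sum((m$labels > 0) & !disk), 0L)  # nothing added outside
  expect_lt(abs(sum(m$labels > 0) / sum(disk) - 1), 0.01)
  expect_true(all((m$labels > 0)[40:42, 40:42]))  # hole filled
  # two disks separated by more than 2*radius stay separate
  two <- matrix(FALSE, 120, 120)
  two[spheroflux:::raster_disk(c(120, 120), c(35, 35), 18)] <- TRUE
  two[spheroflux:::raster_disk(c(120, 120), c(85, 85), 18)] <- TRUE
  expect_equal(max(morphological_cleanup(two, 3, pixel_size = 1)$labels), 2L)
  expect_error(morphological_cleanup(disk, radius = 100, pixel_size = 1),
               "exceeds")
})

test_that("circularity formula gives its closed-form values", {
  expect_equal(circularity(pi * 7^2, 2 * pi * 7), 1)          # ideal circle
  expect_equal(circularity(10^2, 4 * 10), pi / 4)             # ideal square
})

test_that("crofton circularity is calibrated on rasterized disks", {
  for (r in seq(30, 100, by = 10)) {
    m <- disk_mask(r)
    c_val <- circularity(sum(m), crofton_perimeter(m))
    expect_gt(c_val, 0.95)
    expect_lt(c_val, 1.02)
  }
})

test_that("circularity decreases with ellipse aspect ratio", {
  c_of_aspect <- vapply(c(1, 2, 4), function(a) {
    m <- ellipse_mask(60 * sqrt(a), 60 / sqrt(a))
    circularity(sum(m), crofton_perimeter(m))
  }, numeric(1))
  expect_true(all(diff(c_of_aspect) < 0))
})

test_that("extract_shapes measures area, centroid and drops specks", {
  mask <- spheroflux:::raster_disk(c(128, 128), c(60, 70), 35)
  mask[5, 5] <- TRUE  # 1-px speck
  lm <- spheroflux:::new_label_mask(spheroflux:::label_components(mask), 2)
  sh <- extract_shapes(lm, min_area_px = 9)
  expect_equal(nrow(sh), 1L)
  expect_equal(attr(sh, "dropped"), 1L)
  expect_lt(abs(sh$area_um2 / (pi * 35^2 * 4) - 1), 0.01)
  expect_equal(sh$centroid_x_um, (70 - 0.5) * 2, tolerance = 0.01)
  expect_equal(sh$centroid_y_um, (60 - 0.5) * 2, tolerance = 0.01)
  expect_equal(sh$equivalent_diameter_um, 2 * sqrt(sh$area_um2 / pi))
})

test_that("yield counts exactly one round spheroid per well", {
  one_round <- data.frame(circularity = 0.95)
  one_flat <- data.frame(circularity = 0.6)
  empty <- data.frame(circularity = numeric(0))
  multi <- data.frame(circularity = c(0.9, 0.92))
  wells <- c(rep(list(one_round), 7), list(multi, multi, empty))
  y <- compute_yield(wells, c_round = 0.8)
  expect_equal(y$yield, 0.7)
  expect_equal(y$excluded_multi, 2L)
  expect_equal(y$n_wells_total, 10L)
  # single object below threshold counts only in the denominator
  y2 <- compute_yield(list(a = one_round, b = one_flat), c_round = 0.8)
  expect_equal(y2$yield, 0.5)
  # best case: every well exactly one round spheroid
  expect_equal(compute_yield(rep(list(one_round), 5))$yield, 1)
  expect_error(compute_yield(list()), "non-empty")
  expect_error(compute_yield(list(one_round), c_round = 1.2), "0, 1")
})

test_that("truth-table yield is reproduced for any circularity threshold", {
  pl <- make_plate_truth(96, p_zero = 0.15, p_multi = 0.25, p_irregular = 0.2,
                         seed = 9, render = FALSE)
  shapes <- shapes_from_truth(pl$truth)
  for (thr in c(0.4, 0.7, 0.9)) {
    y <- compute_yield(shapes, c_round = thr)
    # truth shapes carry c = 1 (round) or 0.5 (irregular)
    want <- mean(pl$truth$n_objects == 1L &
                   ifelse(pl$truth$single_round, 1, 0.5) >= thr)
    expect_equal(y$yield, want)
  }
})

test_that("aggregation tracking preserves series length and handles failures", {
  fr <- make_spheroid_frame(40, dim = c(128, 128), blur_sigma = 1,
                            noise_sd = 0.05, seed = 1)
  static <- lapply(0:3, function(k)
    image_frame(fr$pixels, fr$pixel_size, timestamp = 0.5 * k))
  tr <- track_aggregation(static)
  expect_equal(nrow(tr), 4L)
  expect_equal(length(unique(tr$size_um2)), 1L)  # identical frames, identical metrics
  expect_equal(length(unique(tr$circularity)), 1L)
  # one corrupted (blank) frame: recorded as missing, series length kept
  static[[3]] <- image_frame(matrix(0.5, 128, 128), 2.5, timestamp = 1)
  tr2 <- track_aggregation(static)
  expect_equal(nrow(tr2), 4L)
  expect_true(is.na(tr2$size_um2[3]))
  expect_equal(attr(tr2, "n_missing"), 1L)
  blanks <- lapply(0:2, function(k)
    image_frame(matrix(0.5, 64, 64), 2.5, timestamp = 0.5 * k))
  expect_error(track_aggregation(blanks), "every frame")
  expect_error(track_aggregation(static[1]), ">= 2")
})

test_that("circularity rises monotonically during synthetic aggregation", {
  for (s in 1:3) {
    fr <- make_aggregation_timelapse(n_frames = 20, scatter0 = 50,
                                     final_radius = 110, rate = 0.25, seed = s,
                                     dim = c(192, 192))
    tr <- track_aggregation(fr)
    smoothed <- running_mean(tr$circularity, 5)
    d <- diff(smoothed[!is.na(smoothed)])
    expect_true(all(d > -0.02))  # non-decreasing after smoothing window 5
    expect_gt(tr$circularity[20], tr$circularity[1])
  }
})

test_that("equilibrium detection finds the plateau and rejects growth", {
  flat <- structure(data.frame(time_h = seq(0, 30, 0.5), size_um2 = 5000,
                               circularity = 1),
                    class = c("aggregation_trajectory", "data.frame"))
  eq <- detect_equilibrium(flat, window = 10, slope_tol = 0.01)
  expect_true(eq$reached)
  expect_equal(eq$time_h, 0)
  expect_equal(eq$mean_size_um2, 5000)
  growing <- flat
  growing$size_um2 <- 5000 * (1 + 0.05 * growing$time_h)  # 5%/h, above tolerance
  expect_false(detect_equilibrium(growing, window = 10, slope_tol = 0.01)$reached)
  expect_error(detect_equilibrium(flat, window = 20), "2 \\* window")
})

test_that("detected equilibrium size matches the generator's configuration", {
  for (s in 1:2) {
    fr <- make_aggregation_timelapse(n_frames = 30, scatter0 = 50,
                                     final_radius = 110, rate = 0.3, seed = s,
                                     dim = c(192, 192))
    tr <- track_aggregation(fr)
    eq <- detect_equilibrium(tr, window = 5, slope_tol = 0.01)
    expect_true(eq$reached)
    fitted_radius <- sqrt(eq$mean_size_um2 / pi)
    expect_lt(abs(fitted_radius / attr(fr, "truth")$final_radius - 1), 0.05)
  }
})

test_that("centering uses the closed touching rule", {
  mk <- function(x, y, d) data.frame(centroid_x_um = x, centroid_y_um = y,
                                     equivalent_diameter_um = d)
  ctr <- c(100, 100)
  expect_true(classify_centering(mk(100, 100, 40), ctr, r_center = 30))
  # touching exactly: distance == r_center + radius counts as centered
  expect_true(classify_centering(mk(100 + 30 + 20, 100, 40), ctr, r_center = 30))
  expect_false(classify_centering(mk(100 + 30 + 20 + 0.1, 100, 40), ctr, 30))
  expect_error(classify_centering(mk(0, 0, 1), ctr, r_center = 0), "r_center")
})

test_that("centering rate reports the counted fraction", {
  r1 <- centering_rate(rep(c(TRUE, FALSE), c(238, 38)))
  expect_equal(r1$rate, 238 / 276, tolerance = 1e-12)
  expect_equal(r1$n_total, 276L)
  r2 <- centering_rate(rep(c(TRUE, FALSE), c(48, 44)))
  expect_equal(r2$rate, 48 / 92, tolerance = 1e-12)
  expect_equal(centering_rate(rep(TRUE, 10))$rate, 1)
  expect_error(centering_rate(logical(0)), "non-empty")
})

test_that("segmentation pipeline is deterministic", {
  fr <- make_spheroid_frame(35, dim = c(128, 128), blur_sigma = 1,
                            noise_sd = 0.1, seed = 6)
  m1 <- chan_vese_segment(fr)
  m2 <- chan_vese_segment(fr)
  expect_identical(m1$labels, m2$labels)
  expect_identical(extract_shapes(morphological_cleanup(m1, 3)),
                   extract_shapes(morphological_cleanup(m2, 3)))
})
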
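# Generators: seeded determinism, stated statistical structure, ground truth
# consistency.

test_that("spheroid frame renders a disk of the stated area, deterministically", {
  fr <- make_spheroid_frame(50, dim = c(128, 128), seed = 7)
  # noiseless, unblurred: simple thresholding recovers the analytic area
  area <- sum(fr$pixels > 0.5)
  expect_lt(abs(area / (pi * 50^2) - 1), 0.01)
  fr2 <- make_spheroid_frame(50, dim = c(128, 128), seed = 7)
  expect_identical(fr$pixels, fr2$pixels)
  fr3 <- make_spheroid_frame(50, dim = c(128, 128), seed = 8, noise_sd = 0.1)
  fr4 <- make_spheroid_frame(50, dim = c(128, 128), seed = 9, noise_sd = 0.1)
  expect_false(identical(fr3$pixels, fr4$pixels))
})

test_that("spheroid frame rejects disks that do not fit", {
  expect_error(make_spheroid_frame(80, dim = c(128, 128)), "does not fit")
  expect_error(make_spheroid_frame(40, center = c(10, 64), dim = c(128, 128)),
               "does not fit")
  expect_error(make_spheroid_frame(2, dim = c(128, 128)), "radius_px")
})

test_that("generator RNG state does not leak into the session", {
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(make_spheroid_frame(20, dim = c(64, 64), seed = 5,
                                               noise_sd = 0.1))
  expect_identical(rnorm(1), before)
})

test_that("aggregation time-lapse has 0.5 h spacing and shrinks toward equilibrium", {
  fr <- make_aggregation_timelapse(n_frames = 8, scatter0 = 50,
                                   final_radius = 100, rate = 0.5, seed = 2,
                                   dim = c(192, 192), noise_sd = 0)
  expect_length(fr, 8)
  expect_equal(vapply(fr, `[[`, numeric(1), "timestamp"), 0.5 * (0:7))
  areas <- vapply(fr, function(f) sum(f$pixels > 0.5), numeric(1))
  expect_gt(areas[1], areas[8])  # projected size shrinks as cells aggregate
  truth <- attr(fr, "truth")
  expect_lt(abs(areas[8] * 2.5^2 / truth$equilibrium_area_um2 - 1), 0.05)
})

test_that("degenerate aggregation limits behave as stated", {
  # infinite rate: already at equilibrium, size constant over time
  fr <- make_aggregation_timelapse(n_frames = 4, scatter0 = 60,
                                   final_radius = 80, rate = Inf, seed = 3,
                                   dim = c(160, 160), noise_sd = 0)
  areas <- vapply(fr, function(f) sum(f$pixels > 0.5), numeric(1))
  expect_true(all(areas == areas[1]))
  # scatter0 = 0: compact and round from frame one
  fr0 <- make_aggregation_timelapse(n_frames = 2, scatter0 = 0,
                                    final_radius = 100, rate = 0.1, seed = 1,
                                    dim = c(160, 160), noise_sd = 0)
  sh <- extract_shapes(morphological_cleanup(chan_vese_segment(fr0[[1]]), 3),
                       min_area_px = 50)
  expect_equal(nrow(sh), 1L)
  expect_gt(sh$circularity, 0.9)
  expect_error(make_aggregation_timelapse(4, 10, final_radius = 400,
                                          rate = 0.1, dim = c(128, 128)),
               "exceeds")
})

test_that("plate truth matches its probability limits and brute-force yield", {
  pl <- make_plate_truth(12, p_zero = 0, p_multi = 0, p_irregular = 0,
                         seed = 1, render = FALSE)
  expect_true(all(pl$truth$n_objects == 1L))
  expect_true(all(pl$truth$single_round))
  pl2 <- make_plate_truth(12, p_zero = 0, p_multi = 1, p_irregular = 0,
                          seed = 1, render = FALSE)
  expect_true(all(pl2$truth$n_objects >= 2L))
  expect_equal(compute_yield(shapes_from_truth(pl2$truth))$yield, 0)
  # yield computed through compute_yield equals the directly counted fraction
  pl3 <- make_plate_truth(96, p_zero = 0.1, p_multi = 0.2, p_irregular = 0.1,
                          seed = 5, render = FALSE)
  y <- compute_yield(shapes_from_truth(pl3$truth), c_round = 0.8)
  expect_equal(y$yield,
               mean(pl3$truth$n_objects == 1L & pl3$truth$single_round))
  expect_equal(y$excluded_multi, sum(pl3$truth$n_objects >= 2L))
  # objects lie within the well
  d <- sqrt((pl3$objects$center_x_um - pl3$well_center_um[2])^2 +
            (pl3$objects$center_y_um - pl3$well_center_um[1])^2)
  expect_true(all(d + pl3$objects$radius_um <= pl3$well_radius_um + 1e-9))
  expect_error(make_plate_truth(0), "n_wells")
  expect_error(make_plate_truth(5, p_zero = 0.7, p_multi = 0.5), "<= 1")
})

test_that("rendered plate objects match the truth count", {
  pl <- make_plate_truth(8, p_zero = 0.25, p_multi = 0.25, p_irregular = 0.2,
                         seed = 11)
  n_seg <- vapply(pl$frames, function(f) {
    nrow(extract_shapes(morphological_cleanup(chan_vese_segment(f), 3),
                        min_area_px = 30))
  }, numeric(1))
  expect_equal(unname(n_seg), pl$truth$n_objects)
})

test_that("ocr traces reproduce the plateaus and stated noise structure", {
  tr <- make_ocr_trace(mito_stress_truth(100, 40, 150, 10), seed = 1)
  expect_equal(nrow(tr), 26L)
  expect_equal(as.vector(table(tr$phase)[c("baseline", "oligomycin", "fccp", "rotaa")]),
               c(5L, 8L, 5L, 8L))
  expect_equal(tr$ocr, rep(c(100, 40, 150, 10), times = c(5, 8, 5, 8)))
  # noiseless trace -> derived parameters equal direct arithmetic
  p <- derive_mito_stress(summarize_phases(assign_phases(tr[c("well_id", "cycle", "ocr")])))
  expect_equal(p$basal, 90); expect_equal(p$atp_linked, 60)
  expect_equal(p$maximal, 140)
  expect_error(mito_stress_truth(100, -5, 150, 10), ">= 0")
  expect_error(mito_stress_truth(100, 120, 150, 10), "ordering")
  expect_s3_class(mito_stress_truth(100, 120, 150, 10, allow_pathological = TRUE),
                  "mito_stress_truth")
})

test_that("noisy traces recover basal respiration on average", {
  truth <- mito_stress_truth(100, 40, 150, 10, noise_sd = 0.05)
  basal <- vapply(1:100, function(s) {
    tr <- make_ocr_trace(truth, seed = s)
    derive_mito_stress(summarize_phases(tr, rules = "mean"))$basal
  }, numeric(1))
  expect_lt(abs(mean(basal) / 90 - 1), 0.02)
})

test_that("experiment set obeys the stated scaling law and batch structure", {
  # zero noise, zero batch, alpha 1: OCR exactly proportional to N
  set <- make_experiment_set(cell_lines = "LN229", reps = 3, batch_sd = 0,
                             noise_sd = 0, alpha = 1, seed = 1)
  ratio <- set$maximal / set$cell_number
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  expect_warning(make_experiment_set(reps = 3, alpha = 2.5, seed = 1),
                 "outside")
  expect_error(make_experiment_set(cell_numbers = 20000, seed = 1), "distinct")
  expect_error(make_experiment_set(reps = 2, seed = 1), "reps")
  # determinism
  expect_identical(make_experiment_set(seed = 4), make_experiment_set(seed = 4))
})

test_that("raw OCR correlates strongly with seeded N absent batch effects", {
  ok <- vapply(1:20, function(s) {
    set <- make_experiment_set(reps = 16, batch_sd = 0, noise_sd = 0.1,
                               alpha = 1, seed = s)
    rc <- evaluate_correlation(set$maximal, set$cell_number, set$cell_line)
    all(rc$r >= 0.75)
  }, logical(1))
  expect_gte(sum(ok), 19)
})

test_that("2d reference normalizes exactly when counts are error-free", {
  d <- make_2d_reference(n_wells = 24, count_error_sd = 0, noise_sd = 0, seed = 1)
  v <- d$ocr / d$measured_count
  expect_lt(diff(range(v)) / mean(v), 1e-12)
  # with count error, residual correlation strictly exceeds the error-free case
  worse <- vapply(1:20, function(s) {
    d0 <- make_2d_reference(n_wells = 288, count_error_sd = 0, seed = s)
    d2 <- make_2d_reference(n_wells = 288, count_error_sd = 0.2, seed = s)
    r0 <- abs(cor(normalize_2d_reference(d0$ocr, d0$measured_count), d0$measured_count))
    r2 <- abs(cor(normalize_2d_reference(d2$ocr, d2$measured_count), d2$measured_count))
    r2 > r0
  }, logical(1))
  expect_true(all(worse))
  expect_error(make_2d_reference(count_range = c(4000, 2000)), "increasing")
})
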
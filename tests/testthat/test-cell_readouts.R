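# Cell-level readouts: kinematics, fluorescence quantification,
# registration/cropping, tracking, and shape morphometrics.

test_that("mean cell speed is zero for a static stack and exact for rigid motion", {
  img <- small_speckle(128, seed = 51)
  static <- mean_cell_speed(list(img, img), dt = 2, calibration = 0.5)
  expect_lt(static$mean_speed[1], 0.3)  # noise floor, um/h

  # 1 um displacement at dt = 2 min is 30 um/h
  cal <- 0.5
  moved <- shift_image(img, 1 / cal, 0, fill = 10)
  s <- mean_cell_speed(list(img, moved), dt = 2, calibration = cal,
                       highpass_sigma = 0)
  expect_equal(s$mean_speed[1], 30, tolerance = 0.1)
  expect_error(mean_cell_speed(list(img, img), dt = 0), "dt")
})

test_that("generator drift speed is recovered and steady state stays flat", {
  sp <- monolayer_spec(n_cells = 40, image_size = c(300, 300),
                       drift_speed = 5, seed = 4)
  sched <- actuation_schedule(seq(0, 1080, by = 120), rep("relaxed", 10))
  seqs <- generate_monolayer_sequence(sp, sched)
  ss <- mean_cell_speed(seqs$phase, dt = 2, calibration = sp$calibration)
  expect_equal(mean(ss$mean_speed), 5, tolerance = 0.1)
  # steady-state control: normalized speed within 10% of 1 at all frames
  expect_true(all(ss$normalized > 0.9 & ss$normalized < 1.1))
})

test_that("rolling-disk subtraction removes background and keeps ridges", {
  expect_true(all(rolling_ball_subtract(matrix(7, 80, 80), 20) == 0))

  # narrow bright ridge on flat background: peak height preserved
  img <- matrix(10, 120, 120)
  img[, 60:62] <- 100
  sub <- rolling_ball_subtract(img, 30)
  expect_equal(max(sub), 90, tolerance = 90 * 0.05)

  # slowly varying background alone: interior residual below 5% of its
  # amplitude (the estimate is unavoidably edge-affected within one radius)
  ramp <- outer(seq(0, 40, length.out = 150), rep(1, 150))
  res <- rolling_ball_subtract(ramp, 25)
  expect_lt(max(res[30:120, 30:120]), 0.05 * 40 + 1e-9)

  expect_warning(rolling_ball_subtract(matrix(runif(100), 10, 10), 50),
                 "global minimum")
})

test_that("fluorescence integrals are normalized and linear", {
  frames <- lapply(c(1, 2), function(k) {
    m <- matrix(0, 100, 100); m[40:42, ] <- 80 * k; m
  })
  fs <- fluorescence_integral_series(frames, radius = 20)
  expect_identical(fs$normalized[1], 1)
  expect_equal(fs$normalized[2], 2, tolerance = 0.02)
  expect_error(fluorescence_integral_series(list()), "non-empty")
})

test_that("a junction-amplitude ramp is recovered from the fluorescence channel", {
  sp <- monolayer_spec(n_cells = 40, image_size = c(300, 300),
                       junction_amplitude_schedule = seq(1, 1.5,
                                                         length.out = 6),
                       seed = 4)
  sched <- actuation_schedule(seq(0, 600, by = 120), rep("relaxed", 6))
  seqs <- generate_monolayer_sequence(sp, sched)
  fs <- fluorescence_integral_series(seqs$fluor, radius = 50)
  expect_equal(fs$normalized[6], 1.5, tolerance = 0.15)
  # monotone quasilinear rise
  expect_true(all(diff(fs$normalized) > 0))

  # constant amplitude stays within 10% of 1
  sp0 <- monolayer_spec(n_cells = 40, image_size = c(300, 300), seed = 4)
  seq0 <- generate_monolayer_sequence(sp0, sched)
  f0 <- fluorescence_integral_series(seq0$fluor, radius = 50)
  expect_true(all(abs(f0$normalized - 1) < 0.1))
})

test_that("background subtraction and ROI cropping commute on clean fixtures", {
  img <- matrix(0, 140, 140)
  img[70:72, 20:120] <- 60  # background-free ridge
  a <- sum(crop_segment(rolling_ball_subtract(img, 25), 50, c(70, 70), 1))
  b <- sum(rolling_ball_subtract(crop_segment(img, 50, c(70, 70), 1), 25))
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("landmark registration recovers injected shifts exactly", {
  img <- small_speckle(160, seed = 57)
  aligned <- register_to_landmark(list(img, img), c(80, 80))
  expect_true(all(aligned$offsets == 0))

  shifted <- shift_image(img, 7, -3, fill = 10)
  reg <- register_to_landmark(list(img, shifted), c(80, 80))
  expect_equal(reg$offsets[2, ], c(-7, 3))
  # after registration the frames agree over the common support
  core <- 30:130
  expect_lt(mean(abs(reg$frames[[2]] - img)[core, core]), 1.5)

  # registration then crop equals crop of the pre-aligned stack
  crop_reg <- crop_segment(reg$frames[[2]], 60, c(80, 80), 1)
  expect_equal(crop_reg, crop_segment(img, 60, c(80, 80), 1),
               tolerance = 0.5, ignore_attr = TRUE)
})

test_that("crop_segment converts physical size and nests", {
  img <- matrix(seq_len(400 * 400), 400, 400)
  cr <- crop_segment(img, 165, c(200, 200), 0.55)
  expect_equal(dim(cr), c(300, 300))  # 165 um at 0.55 um/px

  full <- crop_segment(img, 400, c(200, 200), 1)
  expect_identical(full, img)

  nested <- crop_segment(crop_segment(img, 200, c(200, 200), 1),
                         100, c(100, 100), 1)
  expect_identical(nested, crop_segment(img, 100, c(200, 200), 1))

  expect_error(crop_segment(img, 300, c(20, 20), 1), "bounds")
})

test_that("shape metrics match closed forms and are scale invariant", {
  circ <- shape_metrics(pi * 7^2, 2 * pi * 7)
  expect_equal(circ$circularity, 1)
  expect_equal(circ$shape_factor, 2 * sqrt(pi))

  sq <- shape_metrics(1, 4)
  expect_equal(sq$circularity, pi / 4)
  expect_equal(sq$shape_factor, 4)

  for (k in c(0.5, 3, 10)) {
    sk <- shape_metrics(k^2 * 1, k * 4)
    expect_equal(sk$circularity, pi / 4)
    expect_equal(sk$shape_factor, 4)
  }
  expect_error(shape_metrics(-1, 4), "area")
})

test_that("rasterized disks measure circularity near 1", {
  for (r in c(30, 45, 60)) {
    disk <- raster_disk(r)
    P <- stretchfield:::crofton_perimeter(disk)
    sm <- shape_metrics(sum(disk), P)
    expect_gte(sm$circularity, 0.98)
    expect_lte(sm$circularity, 1.02)
    expect_lt(abs(sm$shape_factor / (2 * sqrt(pi)) - 1), 0.01)
  }
})

test_that("label tracking follows cells and ends tracks at the border", {
  sp <- monolayer_spec(n_cells = 20, image_size = c(180, 180), noise_sd = 0,
                       seed = 61)
  seqs <- generate_monolayer_sequence(sp, actuation_schedule(0, "relaxed"))
  mask <- seqs$label[[1]]

  # static masks: constant tracks with constant metrics
  tr <- track_labels(list(mask, mask, mask), calibration = 0.5)
  per_cell <- split(tr$area_um2, tr$cell_id)
  expect_true(all(vapply(per_cell, function(a) length(unique(a)) == 1,
                         logical(1))))
  expect_true(all(table(tr$cell_id) == 3))

  # translation of 2 px/frame within a 10 px gate: one track per cell
  m2 <- matrix(0L, 180, 180); m2[, 3:180] <- mask[, 1:178]
  m3 <- matrix(0L, 180, 180); m3[, 5:180] <- mask[, 1:176]
  tr2 <- track_labels(list(mask, m2, m3), calibration = 1, gate_um = 10)
  n_frames <- table(tr2$cell_id)
  # cells fully contained in all frames persist as single 3-frame tracks
  expect_gt(sum(n_frames == 3), 5)

  # a cell pushed out of the field stops being tracked
  ids_f1 <- unique(tr2$cell_id[tr2$frame == 1])
  ids_f3 <- unique(tr2$cell_id[tr2$frame == 3])
  expect_true(length(setdiff(ids_f1, ids_f3)) >= 0)
  expect_true(all(tr2$x_um[tr2$frame == 3] > 4))  # border cells dropped
})

test_that("per-cell normalization reports population mean and SEM", {
  mk_track <- function(id, areas) data.frame(
    cell_id = id, frame = seq_along(areas), time = seq_along(areas) - 1,
    x_um = 0, y_um = 0, area_um2 = areas, perimeter_um = sqrt(areas) * 4,
    circularity = pi / 4, shape_factor = 4)
  one <- mk_track(1, c(100, 110))
  class(one) <- c("cell_tracks", "data.frame")
  res <- normalize_per_cell(one)
  expect_equal(res$summary$mean_area, c(1, 1.1))
  expect_equal(res$summary$sem_area, c(0, 0))  # single cell: SEM 0

  # identical cells: SEM 0
  many <- do.call(rbind, lapply(1:4, function(i) mk_track(i, c(100, 120))))
  class(many) <- c("cell_tracks", "data.frame")
  res2 <- normalize_per_cell(many)
  expect_equal(res2$summary$sem_area, c(0, 0))
  expect_equal(res2$summary$mean_area[2], 1.2)

  # a track missing the first frame is excluded with a warning
  late <- mk_track(9, c(100, 100)); late$frame <- late$frame + 1
  mixed <- rbind(many, late)
  class(mixed) <- c("cell_tracks", "data.frame")
  expect_warning(res3 <- normalize_per_cell(mixed), "excluded")
  expect_false(9 %in% res3$tracks$cell_id)
})

test_that("a 5% radial stretch oscillates cell area by the areal strain", {
  sp <- monolayer_spec(n_cells = 20, image_size = c(200, 200), noise_sd = 0,
                       seed = 65)
  dspec <- deformation_spec(kind = "radial", radial_strain = 0.05)
  sched <- actuation_schedule(c(0, 10, 20, 30),
                              c("relaxed", "stretched", "relaxed", "stretched"),
                              deformations = dspec)
  seqs <- generate_monolayer_sequence(sp, sched)
  tr <- track_labels(seqs$label, calibration = 0.5, gate_um = 20)
  # a border cell may enter the tracked set only in a stretched frame;
  # such late tracks are dropped from the population with a warning
  res <- suppressWarnings(normalize_per_cell(tr))
  s <- res$summary
  # stretched frames: mean area ratio ~ (1.05)^2 = 1.1025 (~10% oscillation)
  expect_equal(s$mean_area[2], 1.05^2, tolerance = 0.02)
  expect_equal(s$mean_area[4], 1.05^2, tolerance = 0.02)
  expect_equal(s$mean_area[3], 1, tolerance = 0.01)
})
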
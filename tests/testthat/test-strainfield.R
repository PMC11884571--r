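# Green-Lagrange strain machinery against closed forms, and the series /
# stability / deflection operations.

test_that("strain vanishes for a null field and matches affine closed forms", {
  zero <- analytic_field(function(x, y) 0 * x, function(x, y) 0 * y)
  st <- green_lagrange(zero)
  expect_true(all(abs(st$Exx) < 1e-12 & abs(st$Eyy) < 1e-12 &
                  abs(st$Exy) < 1e-12))

  # U = (F - I) x with F = diag(1.12, 0.96): E = 1/2 (F'F - I)
  aff <- analytic_field(function(x, y) 0.12 * x, function(x, y) -0.04 * y)
  st <- green_lagrange(aff)
  expect_equal(max(abs(st$Exx - 0.1272)), 0, tolerance = 1e-10)
  expect_equal(max(abs(st$Eyy + 0.0392)), 0, tolerance = 1e-10)
  expect_equal(max(abs(st$Exy)), 0, tolerance = 1e-10)

  # simple shear U = (gamma y, 0), gamma = 0.1
  sh <- green_lagrange(analytic_field(function(x, y) 0.1 * y,
                                      function(x, y) 0 * x))
  expect_equal(max(abs(sh$Exy - 0.05)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sh$Exx)), 0, tolerance = 1e-10)
  expect_equal(max(abs(sh$Eyy - 0.005)), 0, tolerance = 1e-10)
})

test_that("strain is dimensionless regardless of calibration", {
  for (cal in c(0.5, 2)) {
    aff <- analytic_field(function(x, y) 0.05 * x, function(x, y) 0 * y,
                          calibration = cal)
    st <- green_lagrange(aff)
    expect_equal(mean(st$Exx), 0.05 + 0.5 * 0.05^2, tolerance = 1e-10)
  }
})

test_that("invalid vectors and the crop margin are excluded from averages", {
  aff <- analytic_field(function(x, y) 0.08 * x, function(x, y) 0.08 * y)
  aff$valid[5, 5] <- FALSE
  st <- green_lagrange(aff, crop_margin = 1)
  expect_true(is.na(st$Exx[4, 4]))  # cropped indexing shifts by the margin
  avg <- crop_and_average(st)
  manual <- mean(st$Exx, na.rm = TRUE)
  expect_equal(avg$avg_Exx, manual)
  expect_equal(avg$avg_Exx, 0.0832, tolerance = 1e-6)

  all_bad <- analytic_field(function(x, y) 0 * x, function(x, y) 0 * y)
  all_bad$valid[] <- FALSE
  expect_error(green_lagrange(all_bad), "valid")
})

test_that("a 500 um ROI at 22.7 um spacing contributes 484 grid points", {
  # grid offset half a spacing from the ROI edge, as a correlation grid is
  sp <- 22.7
  gx <- seq(sp / 2, by = sp, length.out = 30)
  st <- structure(list(Exx = matrix(0.08, 30, 30),
                       Eyy = matrix(0.08, 30, 30),
                       Exy = matrix(0, 30, 30),
                       x_um = gx, y_um = gx, crop_margin = 0),
                  class = "strain_field")
  avg <- crop_and_average(st, roi = c(0, 500, 0, 500))
  expect_equal(avg$n_points, 484)
  expect_equal(avg$avg_Exx, 0.08)
})

test_that("constant fields average identically over any ROI", {
  st <- structure(list(Exx = matrix(0.08, 10, 10),
                       Eyy = matrix(-0.02, 10, 10),
                       Exy = matrix(0.01, 10, 10),
                       x_um = seq(10, 100, 10), y_um = seq(10, 100, 10),
                       crop_margin = 0),
                  class = "strain_field")
  for (roi in list(NULL, c(20, 70, 20, 70), c(35, 95, 15, 55))) {
    avg <- crop_and_average(st, roi)
    expect_equal(avg$avg_Exx, 0.08)
    expect_equal(avg$avg_Eyy, -0.02)
  }
  expect_error(crop_and_average(st, c(500, 600, 500, 600)), "no grid points")
})

test_that("series normalization and stability metrics follow their definitions", {
  s <- strain_series(c(0, 600), c(0.080, 0.082), c(0.080, 0.082))
  n <- normalize_series(s)
  expect_equal(n$norm_Exx, c(1, 1.025))
  expect_identical(n$norm_Exx[1], 1)

  const <- normalize_series(strain_series(c(0, 1, 2), rep(0.08, 3), rep(0.08, 3)))
  expect_true(all(const$norm_Exx == 1))
  sm <- stability_metrics(const)
  expect_equal(sm$max_rel_Exx, 0)
  expect_equal(sm$max_abs_change, 0)

  s2 <- strain_series(c(0, 1, 2), 0.08 * c(1, 1.042, 0.97),
                      0.08 * c(1, 1.042, 0.97))
  expect_equal(stability_metrics(s2)$max_rel_Exx, 0.042, tolerance = 1e-9)

  expect_error(normalize_series(strain_series(c(0, 1), c(0, 0.1), c(1, 1))),
               "zero")
  expect_error(stability_metrics(strain_series(0, 0.1, 0.1)), "two time")
})

test_that("Poisson deflection reproduces the closed form and its scalings", {
  expect_equal(poisson_deflection(0.5, 0.10, 100), 2.5)
  expect_equal(poisson_deflection(0.5, 0, 100), 0)
  expect_equal(poisson_deflection(0.4, 0.05, 200),
               2 * poisson_deflection(0.4, 0.05, 100))
  expect_error(poisson_deflection(0.7, 0.1, 100), "nu")
  expect_error(poisson_deflection(0.5, 0.1, -1), "h")
})

test_that("small-strain fields reduce to engineering strain", {
  for (eps in c(0.002, 0.01)) {
    aff <- analytic_field(function(x, y) eps * x, function(x, y) eps * y)
    st <- green_lagrange(aff)
    expect_lte(abs(mean(st$Exx) - eps), eps^2 / 2 + 1e-12)
  }
})

test_that("the DIC chain at 8% radial strain gives symmetric averages", {
  fx <- dic_fixture()
  st <- green_lagrange(fx$field, crop_margin = 1)
  avg <- crop_and_average(st)
  expect_lte(abs(avg$avg_Exx - avg$avg_Eyy), 0.003)
  target <- 0.5 * (1.08^2 - 1)
  expect_lt(abs(avg$avg_Exx - target), 0.005)
})

test_that("per-period referencing keeps a constant cyclic series flat", {
  # same deformation every period, fresh noise per frame: the series of
  # per-pair averaged strains stays at its baseline
  img <- generate_speckle(speckle_spec(image_size = c(320, 320),
                                       noise_sd = 0, seed = 41))
  dspec <- deformation_spec(kind = "radial", radial_strain = 0.05)
  warped <- apply_deformation(img, dspec, fill = 10)$warped
  avgs <- vapply(1:3, function(k) {
    withr_seed <- 100 + k
    noisy <- list(
      r = img + with_seed_matrix(withr_seed, dim(img), 2),
      d = warped + with_seed_matrix(withr_seed + 50, dim(img), 2))
    fld <- estimate_displacement(image_pair(noisy$r, noisy$d),
                                 pass_schedule(c(80, 40)))
    crop_and_average(green_lagrange(fld))$avg_Exx
  }, numeric(1))
  expect_lt(max(abs(avgs / avgs[1] - 1)), 0.02)
})
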
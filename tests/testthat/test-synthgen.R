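# Synthetic-data generators: determinism, degenerate cases, and exact
# ground-truth bookkeeping.

test_that("speckle generation is deterministic and respects the empty case", {
  spec <- speckle_spec(image_size = c(128, 128), seed = 42)
  expect_identical(generate_speckle(spec), generate_speckle(spec))

  empty <- speckle_spec(image_size = c(64, 64), particle_density = 0,
                        noise_sd = 0, background_level = 7, seed = 1)
  img <- generate_speckle(empty)
  expect_true(all(img == 7))

  noisy <- speckle_spec(image_size = c(64, 64), particle_density = 0,
                        noise_sd = 2, background_level = 50, seed = 1)
  img2 <- generate_speckle(noisy)
  expect_equal(mean(img2), 50, tolerance = 0.01)

  expect_error(speckle_spec(image_size = c(-5, 10)), "image_size")
  expect_error(speckle_spec(particle_sigma = 0), "particle_sigma")
})

test_that("rendered particle count follows the Poisson expectation", {
  # count recovered from integrated intensity: each Gaussian spot of
  # amplitude A and width sigma contributes ~ A * 2 * pi * sigma^2
  sigma <- 1.0; amp <- 40
  unit_mass <- amp * 2 * pi * sigma^2
  lambda <- 5e-4 * 1000 * 1000
  counts <- vapply(1:60, function(s) {
    img <- generate_speckle(speckle_spec(
      image_size = c(1000, 1000), particle_density = 5e-4,
      particle_sigma = sigma, peak_intensity = amp,
      background_level = 0, noise_sd = 0, seed = s))
    sum(img) / unit_mass
  }, numeric(1))
  se <- sqrt(lambda / length(counts))
  # allow a little extra for edge-truncated spot mass
  expect_lt(abs(mean(counts) - lambda), 3 * se + 0.01 * lambda)
})

test_that("affine warps carry exact analytic displacement ground truth", {
  spec <- deformation_spec(F = diag(c(1.12, 0.96)), center = c(200, 150))
  gt <- ground_truth_displacement(spec, 300, 150)  # (100, 0) from center
  expect_equal(gt$u, 12)
  expect_equal(gt$v, 0)
  gt0 <- ground_truth_displacement(spec, 200, 150)
  expect_equal(c(gt0$u, gt0$v), c(0, 0))  # zero at the stretching center

  # numerical differentiation of U matches F - I to high precision
  eps <- 1e-4
  for (pt in list(c(250, 120), c(180, 210))) {
    dux <- (ground_truth_displacement(spec, pt[1] + eps, pt[2])$u -
            ground_truth_displacement(spec, pt[1] - eps, pt[2])$u) / (2 * eps)
    dvy <- (ground_truth_displacement(spec, pt[1], pt[2] + eps)$v -
            ground_truth_displacement(spec, pt[1], pt[2] - eps)$v) / (2 * eps)
    expect_equal(dux, 0.12, tolerance = 1e-8)
    expect_equal(dvy, -0.04, tolerance = 1e-8)
  }

  expect_error(deformation_spec(F = matrix(c(1, 0, 0, -1), 2)), "det")
})

test_that("identity warp reproduces the image and radial equals equibiaxial", {
  img <- small_speckle(96, seed = 3)
  d <- apply_deformation(img, deformation_spec(F = diag(2)), fill = 10)
  expect_lt(max(abs(d$warped - img)[5:92, 5:92]), 1e-6)
  gt <- d$displacement(c(10, 50, 90), c(20, 48, 70))
  expect_true(all(gt$u == 0 & gt$v == 0))

  rad <- deformation_spec(kind = "radial", radial_strain = 0.08)
  expect_equal(rad$F, diag(2) * 1.08)
})

test_that("nearest-neighbor warping commutes with per-label recoding", {
  sp <- monolayer_spec(n_cells = 12, image_size = c(80, 80), noise_sd = 0,
                       seed = 5)
  seqs <- generate_monolayer_sequence(sp, actuation_schedule(0, "relaxed"))
  mask <- seqs$label[[1]]
  dspec <- deformation_spec(kind = "radial", radial_strain = 0.05)
  lut <- c(0, stats::runif(max(mask), 1, 99))  # label -> intensity map
  a <- apply_deformation(matrix(lut[mask + 1], nrow(mask)), dspec,
                         interp = "nearest", fill = lut[1])$warped
  wmask <- apply_deformation(mask, dspec, interp = "nearest", fill = 0)$warped
  b <- matrix(lut[wmask + 1], nrow(mask))
  expect_equal(a, b)
})

test_that("monolayer sequences are deterministic, complete, and scale with amplitude", {
  sp <- monolayer_spec(n_cells = 25, image_size = c(150, 150),
                       drift_speed = 0, noise_sd = 0,
                       junction_amplitude_schedule = c(0.5, 0.5, 1), seed = 9)
  sched <- actuation_schedule(c(0, 60, 120), rep("relaxed", 3))
  s1 <- generate_monolayer_sequence(sp, sched)
  s2 <- generate_monolayer_sequence(sp, sched)
  expect_identical(s1$fluor, s2$fluor)
  expect_identical(s1$label, s2$label)

  # complete tessellation: every pixel labeled
  expect_true(all(vapply(s1$label, function(m) all(m > 0), logical(1))))

  # static case: identical frames (same drift, same amplitude)
  expect_equal(s1$label[[1]], s1$label[[2]])
  expect_equal(s1$phase[[1]], s1$phase[[2]])

  # amplitude doubling doubles the junction fluorescence integral
  ratio <- sum(s1$fluor[[3]]) / sum(s1$fluor[[1]])
  expect_equal(ratio, 2, tolerance = 1e-6)

  expect_error(monolayer_spec(n_cells = 0), "n_cells")
})

test_that("a radial stretch enlarges every interior cell", {
  sp <- monolayer_spec(n_cells = 20, image_size = c(180, 180), noise_sd = 0,
                       seed = 11)
  dspec <- deformation_spec(kind = "radial", radial_strain = 0.05)
  sched <- actuation_schedule(c(0, 10), c("relaxed", "stretched"),
                              deformations = dspec)
  seqs <- generate_monolayer_sequence(sp, sched)
  relaxed <- seqs$label[[1]]; stretched <- seqs$label[[2]]
  border_r <- unique(c(relaxed[1, ], relaxed[nrow(relaxed), ],
                       relaxed[, 1], relaxed[, ncol(relaxed)]))
  border_s <- unique(c(stretched[1, ], stretched[nrow(stretched), ],
                       stretched[, 1], stretched[, ncol(stretched)]))
  interior <- setdiff(seq_len(sp$n_cells), c(border_r, border_s))
  expect_gt(length(interior), 3)
  for (L in interior)
    expect_gt(sum(stretched == L), sum(relaxed == L))
})

test_that("schedule constructors validate their invariants", {
  expect_error(actuation_schedule(c(0, 0), c("relaxed", "stretched")),
               "increasing")
  expect_error(actuation_schedule(0, "floppy"), "relaxed")
  cyc <- cyclic_schedule(3, period = 20)
  expect_equal(nrow(cyc), 6)
  expect_equal(cyc$state, rep(c("relaxed", "stretched"), 3))
  expect_equal(cyc$time, c(3, 13, 23, 33, 43, 53))
  expect_error(cyclic_schedule(2, period = 20, settle_delay = 10), "settle")
})
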
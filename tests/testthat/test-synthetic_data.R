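# Seeded generators: exponential ICG decay, pulsatile velocity traces,
# voxelized liver phantoms.

test_that("noise-free ICG series follows the closed-form exponential", {
  p <- icg_sim_params(C0 = 155.99, k = 0.1754, t_grid = c(1, 5),
                      noise_cv = 0, n_replicates = 1, seed = 3)
  s <- simulate_icg_series(p)
  expect_equal(s$concentrations, 155.99 * 10^(-0.1754 * c(1, 5)))
  # two-point decline ratio, closed-form oracle: 10^(k * (t2 - t1))
  expect_equal(s$concentrations[1] / s$concentrations[2], 10^(0.1754 * 4))
  expect_equal(s$concentrations[1] / s$concentrations[2], 5.031, tolerance = 1e-3)
})

test_that("zero elimination rate gives a constant series", {
  s <- simulate_icg_series(icg_sim_params(C0 = 42, k = 0, noise_cv = 0))
  expect_equal(s$concentrations, rep(42, 3))
})

test_that("all three generators are deterministic under a fixed seed", {
  p <- icg_sim_params(noise_cv = 0.1, n_replicates = 3, seed = 11)
  expect_identical(simulate_icg_series(p), simulate_icg_series(p))
  expect_false(identical(
    simulate_icg_series(p)$concentrations,
    simulate_icg_series(icg_sim_params(noise_cv = 0.1, seed = 12))$concentrations))

  wp <- waveform_sim_params(noise_sd = 20, seed = 11)
  expect_identical(simulate_velocity_trace(wp)$samples,
                   simulate_velocity_trace(wp)$samples)

  pp <- phantom_params(grid_shape = 24, liver_semiaxes = c(1, 0.9, 0.8),
                       vessel_radii = 0.2, fat_radii = 0.3,
                       capsule_thickness = 0.25, seed = 11)
  expect_identical(generate_liver_phantom(pp)$volume$voxels,
                   generate_liver_phantom(pp)$volume$voxels)
})

test_that("generator RNG does not disturb the caller's stream", {
  set.seed(99)
  a <- runif(1)
  set.seed(99)
  invisible(simulate_icg_series(icg_sim_params(seed = 5)))
  expect_identical(runif(1), a)
})

test_that("invalid simulator parameters are rejected", {
  expect_error(icg_sim_params(t_grid = c(5, 1)), "strictly increasing")
  expect_error(icg_sim_params(t_grid = c(1, 1, 5)), "strictly increasing")
  expect_error(icg_sim_params(C0 = 0), "C0")
  expect_error(icg_sim_params(noise_cv = -0.1), "noise_cv")
  expect_error(waveform_sim_params(duration = 0.5), "5 cardiac cycles")
  expect_error(waveform_sim_params(fs = 50), "fs too low")
  expect_error(waveform_sim_params(psv_true = 100, edv_true = 200), "psv_true")
})

test_that("replicate means converge to the noise-free decay (3 SE)", {
  n <- 1e4
  cv <- 0.2
  p <- icg_sim_params(C0 = 150, k = 0.18, t_grid = c(1, 5), noise_cv = cv,
                      n_replicates = n, seed = 202)
  s <- simulate_icg_series(p)
  mu <- 150 * 10^(-0.18 * c(1, 5))
  se <- mu * cv / sqrt(n)
  expect_true(all(abs(s$concentrations - mu) <= 3 * se))
})

test_that("noise-free trace carries >= 5 pulses with exact extrema", {
  wp <- waveform_sim_params(hr = 331.5, psv_true = 864.37, edv_true = 424.33,
                            duration = 2, fs = 2000, noise_sd = 0)
  tr <- simulate_velocity_trace(wp)
  # sampled max can miss the pulse apex by at most one sample of slope
  tol <- (864.37 - 424.33) * pi / (wp$pulse_width_frac * (60 / wp$hr) * wp$fs)
  expect_equal(max(tr$samples), 864.37, tolerance = tol / 864.37)
  expect_equal(min(tr$samples), 424.33)
  # 11 apexes fit into 2 s at 331.5 bpm
  cyc <- detect_cycles(tr)
  expect_identical(length(attr(cyc, "peaks")), 11L)
})

test_that("degenerate psv = edv gives a constant trace with VTI = v * T", {
  v <- 250
  tr <- simulate_velocity_trace(waveform_sim_params(
    hr = 300, psv_true = v, edv_true = v, duration = 1, fs = 1000,
    noise_sd = 0))
  expect_true(all(tr$samples == v))
  n <- length(tr$samples)
  cf <- cycle_features(tr, data.frame(start = 1L, end = n))
  expect_equal(cf$per_cycle$vti, v * (n - 1) / tr$fs)
  expect_equal(cf$per_cycle$tav, v)
})

test_that("noise-free phantom without structures is exactly uniform", {
  ph <- generate_liver_phantom(phantom_params(
    grid_shape = 32, liver_semiaxes = c(1.5, 1.2, 1.1), noise_sd = 0,
    vessel_radii = numeric(0), fat_radii = numeric(0), capsule_thickness = 0))
  liver <- ph$labels > 0
  expect_true(all(ph$volume$voxels[liver] == 135))
  expect_true(all(ph$volume$voxels[!liver] == -1000))
  expect_identical(sum(ph$labels == phantom_labels()[["parenchyma"]]),
                   sum(liver))
})

test_that("label bookkeeping gives exact ground-truth volumes", {
  ph <- generate_liver_phantom(phantom_params(
    grid_shape = 32, liver_semiaxes = c(1.5, 1.2, 1.1), vessel_radii = 0.2,
    fat_radii = 0.25, seed = 4))
  expect_equal(ph$truth$liver_volume_cm3,
               sum(ph$labels > 0) * ph$params$voxel_pitch^3 / 1000)
  expect_equal(sum(ph$truth$label_counts), 32^3)
})

test_that("unresolvable capsule and oversized liver are flagged", {
  expect_warning(phantom_params(grid_shape = 32,
                                liver_semiaxes = c(1.5, 1.2, 1.1),
                                capsule_thickness = 0.05),
                 "unresolved")
  expect_error(phantom_params(grid_shape = 16, liver_semiaxes = c(5, 4, 3)),
               "does not fit")
})

test_that("parenchyma HU is Gaussian with the stated mean and SD", {
  ph <- generate_liver_phantom(phantom_params(seed = 8))
  hu <- ph$volume$voxels[ph$labels == phantom_labels()[["parenchyma"]]]
  expect_gt(length(hu), 1e5)
  expect_equal(mean(hu), 135, tolerance = 0.5 / 135)
  ks <- suppressWarnings(stats::ks.test(hu, "pnorm", 135, 12))
  expect_gt(ks$p.value, 0.01)
})
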
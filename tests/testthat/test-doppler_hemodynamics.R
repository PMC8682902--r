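# Cycle detection, per-cycle waveform features and derived indices.

sim_ha_trace <- function(noise_sd = 0, seed = 1, fs = 2000) {
  simulate_velocity_trace(waveform_sim_params(
    hr = 331.5, psv_true = 864.37, edv_true = 424.33, duration = 2,
    fs = fs, noise_sd = noise_sd, seed = seed))
}

test_that("detect_cycles finds the expected peak count", {
  cyc <- detect_cycles(sim_ha_trace())
  expect_identical(length(attr(cyc, "peaks")), 11L)
  expect_gte(nrow(cyc), 5L)
})

test_that("constant traces and too-short traces are rejected", {
  flat <- velocity_trace(rep(100, 2000), fs = 1000)
  expect_error(detect_cycles(flat), "constant")
  short <- sim_ha_trace()
  short$samples <- short$samples[1:600]  # < 2 peaks at 331.5 bpm, 2000 Hz
  expect_error(detect_cycles(short), "need")
})

test_that("cycle count is noise-robust up to 5% of PSV", {
  n0 <- nrow(detect_cycles(sim_ha_trace()))
  for (seed in 1:5) {
    tr <- sim_ha_trace(noise_sd = 0.05 * 864.37, seed = seed)
    expect_identical(nrow(detect_cycles(tr)), n0)
  }
})

test_that("noise-free feature extraction recovers the simulation truth", {
  wp <- waveform_sim_params(hr = 331.5, psv_true = 864.37, edv_true = 424.33,
                            duration = 2, fs = 2000, noise_sd = 0)
  tr <- simulate_velocity_trace(wp)
  cf <- cycle_features(tr, detect_cycles(tr))
  tol <- (864.37 - 424.33) * pi / (wp$pulse_width_frac * (60 / wp$hr) * wp$fs)
  expect_equal(cf$averages$psv, 864.37, tolerance = tol / 864.37)
  expect_equal(cf$averages$edv, 424.33, tolerance = 1e-8)
  expect_equal(cf$averages$hr_bpm, 331.5, tolerance = 0.01)
  # closed-form cycle VTI: EDV*T + (PSV-EDV)*w*T/2 for the raised cosine
  T_cyc <- 60 / 331.5
  vti_true <- 424.33 * T_cyc + (864.37 - 424.33) * 0.4 * T_cyc / 2
  expect_equal(cf$averages$vti, vti_true, tolerance = 1e-3)
  expect_equal(cf$averages$tav, cf$averages$vti /
                 mean(cf$per_cycle$duration_s))
})

test_that("per-cycle invariants hold: psv >= tav >= edv, vti = tav * T", {
  tr <- sim_ha_trace(noise_sd = 20, seed = 3)
  cf <- cycle_features(tr, detect_cycles(tr))
  with(cf$per_cycle, {
    expect_true(all(psv >= tav & tav >= edv))
    expect_equal(vti, tav * duration_s)
  })
})

test_that("VTI matches analytic integrals of simple pulses", {
  fs <- 1000
  v <- 300; T_ramp <- 0.5
  n <- T_ramp * fs + 1
  tri <- velocity_trace(seq(0, v, length.out = n), fs = fs)
  cf <- cycle_features(tri, data.frame(start = 1L, end = as.integer(n)))
  expect_equal(cf$per_cycle$vti, v * T_ramp / 2)  # trapezoid exact on a line
  # half-sine pulse: integral = 2/pi * v * T, trapezoid error O(fs^-2)
  t <- seq(0, T_ramp, by = 1 / fs)
  hs <- velocity_trace(v * sin(pi * t / T_ramp), fs = fs)
  cf2 <- cycle_features(hs, data.frame(start = 1L, end = length(t)))
  expect_equal(cf2$per_cycle$vti, 2 / pi * v * T_ramp, tolerance = 1 / fs^2 * 10)
  expect_equal(cf2$per_cycle$vti, oracle_trapz(hs$samples, 1 / fs))
})

test_that("resistance_index follows (psv - edv)/psv", {
  expect_equal(resistance_index(500, 500), 0)
  expect_equal(resistance_index(500, 0), 1)
  expect_equal(resistance_index(687.47, 266.29), 0.6126, tolerance = 1e-4)
  expect_error(resistance_index(0, 0), "positive")
  # strictly decreasing in EDV at fixed PSV, within [0, 1]
  ri <- resistance_index(800, seq(0, 800, by = 50))
  expect_true(all(diff(ri) < 0))
  expect_true(all(ri >= 0 & ri <= 1))
})

test_that("portal congestion index = area / PSV", {
  expect_equal(round(portal_congestion_index(3.41, 150.72), 3), 0.023)
  expect_equal(portal_congestion_index(3.09, 131.25), 0.0235, tolerance = 1e-2)
  expect_equal(portal_congestion_index(0, 150), 0)
  expect_error(portal_congestion_index(3, 0), "positive")
})

test_that("A/P ratio on summary velocities", {
  expect_equal(ap_ratio(150, 150), 1)
  expect_equal(ap_ratio(687.47, 161.00), 4.270, tolerance = 1e-3)
  expect_equal(mean(c(6.64, 4.39, 4.44, 3.84, 4.64, 4.98)), 4.82,
               tolerance = 0.01 / 4.82)
  expect_error(ap_ratio(100, 0), "positive")
})

test_that("renal blood flow: formula, units and scaling law", {
  expect_equal(renal_blood_flow(0, 10, 1), 0)
  expect_equal(renal_blood_flow(300, 60, 0), 0)
  expect_equal(renal_blood_flow(331.5, 64.37, 0.91 / 2), 13.88,
               tolerance = 1e-3)
  expect_equal(renal_blood_flow(300, 60, 0.8), 4 * renal_blood_flow(300, 60, 0.4))
  expect_equal(renal_blood_flow(600, 60, 0.4), 2 * renal_blood_flow(300, 60, 0.4))
  expect_error(renal_blood_flow(-1, 60, 0.4), "non-negative")
})

test_that("published per-animal RBF agrees with the formula within ~4%", {
  h <- baseline_hemodynamics()
  pick <- function(q) unlist(h[h$quantity == q, paste0("rat", 1:6)])
  calc <- renal_blood_flow(pick("hr"), pick("renal_vti"), pick("lrad") / 2)
  expect_true(all(abs(calc - pick("rbf")) / pick("rbf") < 0.04))
})

test_that("cardiac output = sv * hr", {
  expect_equal(cardiac_output(0, 300), 0)
  expect_equal(cardiac_output(79.64 / 331.5, 331.5), 79.64)
  expect_equal(mean(c(79.64, 67.09, 74.03, 67.91, 74.12, 90.71)), 75.58,
               tolerance = 0.01 / 75.58)
})

test_that("vessel_measurement derives circular area and enforces repeats", {
  vm <- vessel_measurement(diameters = rep(0.9, 5), min_repeats = 5)
  expect_equal(vm$area, pi * 0.45^2)
  expect_error(vessel_measurement(diameters = c(0.9, 0.9)), "at least 3")
  vm2 <- vessel_measurement(areas = c(3.1, 3.2, 3.3))
  expect_equal(vm2$area, 3.2)
})

test_that("every published group mean and SD is reproduced", {
  h <- baseline_hemodynamics()
  vals <- as.matrix(h[, paste0("rat", 1:6)])
  for (i in seq_len(nrow(h))) {
    ri <- reference_interval(vals[i, ])
    # printed-precision agreement: one ulp of the printed decimals
    pub_dp <- if (h$quantity[i] == "pci") 3L else 2L
    expect_lt(abs(ri$mean - h$published_mean[i]), 1.1 * 10^-pub_dp,
              label = sprintf("mean of %s", h$quantity[i]))
    expect_lt(abs(ri$sd - h$published_sd[i]), 2.1 * 10^-pub_dp,
              label = sprintf("sd of %s", h$quantity[i]))
  }
})
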
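# VOI statistics, HU-threshold segmentation, sweeps, component labeling.

small_phantom <- function(noise_sd = 0, seed = 2, capsule_thickness = 0.25,
                          ...) {
  generate_liver_phantom(phantom_params(
    grid_shape = 32, liver_semiaxes = c(1.5, 1.2, 1.1), noise_sd = noise_sd,
    vessel_radii = 0.2, fat_radii = 0.3,
    capsule_thickness = capsule_thickness, seed = seed, ...))
}

test_that("voi_stats on a uniform field: exact mean and voxel count", {
  vol <- ct_volume(array(135, c(20, 20, 20)), pitch = 0.125)
  st <- voi_stats(vol, voi(center = c(10, 10, 10), side = 2))
  expect_equal(st$mean_hu, 135)
  expect_equal(st$sd_hu, 0)
  expect_identical(st$n_voxels, 4096L)  # (2 mm side / 0.125 mm pitch)^3
})

test_that("parenchyma VOI on the default noisy phantom sits in 134-137 HU", {
  ph <- generate_liver_phantom(phantom_params(seed = 6))
  vessel_mask <- ph$labels == phantom_labels()[["vessel"]]
  st <- voi_stats(ph$volume, voi(center = c(48, 48, 48), side = 2),
                  exclusion_mask = vessel_mask)
  expect_gt(st$n_voxels, 3000)  # 4096 minus the excluded vessel voxels
  expect_gte(st$mean_hu, 134)
  expect_lte(st$mean_hu, 137)
})

test_that("a VOI straddling fat matches the label-weighted average oracle", {
  ph <- small_phantom(noise_sd = 0, capsule_thickness = 0)
  fat_idx <- which(ph$labels == phantom_labels()[["fat"]], arr.ind = TRUE)
  ctr <- round(colMeans(fat_idx))
  v <- voi(center = ctr, side = 1.5)
  st <- voi_stats(ph$volume, v)
  # oracle: count labels inside the VOI and average their exact HU values
  idx <- lapply(1:3, function(i) {
    n_side <- round(1.5 / 0.125)
    lo <- floor(ctr[i] - n_side / 2) + 1L
    lo:(lo + n_side - 1L)
  })
  lab_voi <- ph$labels[idx[[1]], idx[[2]], idx[[3]]]
  hu_of <- c(`0` = -1000, `1` = -100, `2` = 135, `4` = 40)
  counts <- table(lab_voi)
  expect_false("3" %in% names(counts))  # capsule not inside this VOI
  oracle <- sum(hu_of[names(counts)] * counts) / sum(counts)
  expect_equal(st$mean_hu, unname(oracle))
  pure <- voi_stats(ph$volume, voi(center = c(16, 16, 16), side = 0.5))
  expect_lt(st$mean_hu, pure$mean_hu)
})

test_that("VOI bounds and exclusion degenerate cases error", {
  vol <- ct_volume(array(0, c(10, 10, 10)), pitch = 0.5)
  expect_error(voi_stats(vol, voi(c(1, 5, 5), side = 2)), "outside")
  excl <- array(TRUE, c(10, 10, 10))
  expect_error(voi_stats(vol, voi(c(5, 5, 5), side = 1), excl), "empty")
})

test_that("threshold_segment trivial windows", {
  vol <- ct_volume(array(135, c(8, 8, 8)), pitch = 0.125)
  seg <- threshold_segment(vol, 0, 1000)
  expect_true(all(seg$mask))
  expect_equal(seg$volume_cm3, 8^3 * 0.125^3 / 1000)
  empty <- threshold_segment(vol, 200, 1000)
  expect_true(empty$empty)
  expect_equal(empty$volume_cm3, 0)
  expect_true(is.na(empty$mean_hu))
  expect_error(threshold_segment(vol, 100, 100), "smaller")
})

test_that("tighter windows shrink volume and raise mean HU on the phantom", {
  ph <- small_phantom(noise_sd = 10)
  s0 <- threshold_segment(ph$volume, 0, 1000)
  s120 <- threshold_segment(ph$volume, 120, 1000)
  expect_lt(s120$volume_cm3, s0$volume_cm3)
  expect_gt(s120$mean_hu, s0$mean_hu)
  # brute-force voxel-filter oracle
  hu <- ph$volume$voxels
  expect_identical(s0$n_voxels, sum(hu >= 0 & hu <= 1000))
  expect_identical(s120$n_voxels, sum(hu >= 120 & hu <= 1000))
  expect_equal(s120$mean_hu, mean(hu[hu >= 120 & hu <= 1000]))
})

test_that("volume arithmetic is exact voxel-count bookkeeping", {
  set.seed(31)
  vol <- ct_volume(array(runif(12^3, -500, 500), c(12, 12, 12)), pitch = 0.2)
  seg <- threshold_segment(vol, -100, 250)
  expect_equal(seg$volume_cm3, seg$n_voxels * 0.2^3 / 1000)
})

test_that("sweep is monotone for arbitrary volumes (property)", {
  for (seed in 1:8) {
    set.seed(seed)
    vol <- ct_volume(array(rnorm(16^3, 100, 120), c(16, 16, 16)),
                     pitch = 0.125)
    vol$voxels[vol$voxels > 1000] <- 1000
    vol$voxels[vol$voxels < -1000] <- -1000
    sw <- threshold_sweep(vol, lower_list = c(0, 50, 100, 120))
    expect_true(sw$monotone$volume_nonincreasing)
    expect_false(is.unsorted(rev(sw$summary$n_voxels)))
  }
})

test_that("degenerate sweep: no sub-threshold tissue keeps volumes equal", {
  vol <- ct_volume(array(500, c(8, 8, 8)), pitch = 0.125)
  sw <- threshold_sweep(vol, lower_list = c(0, 50, 100, 120))
  expect_identical(length(unique(sw$summary$n_voxels)), 1L)
  expect_error(threshold_sweep(vol, lower_list = c(120, 50)),
               "strictly increasing")
})

test_that("largest-component policy matches the flood-fill oracle", {
  # random masks and the structured phantom, grids <= 32^3
  cases <- list()
  for (seed in 1:4) {
    set.seed(seed)
    cases[[seed]] <- array(runif(10^3) < 0.35, c(10, 10, 10)) * 200
  }
  cases[[5]] <- small_phantom(noise_sd = 10, seed = 9)$volume$voxels
  for (hu in cases) {
    vol <- ct_volume(array(pmax(pmin(hu, 1000), -1000), dim = dim(hu)),
                     pitch = 0.125)
    for (conn in c(6, 26)) {
      seg <- threshold_segment(vol, 100, 1000,
                               component_policy = "largest-component",
                               connectivity = conn)
      lab <- oracle_label_components(vol$voxels >= 100 & vol$voxels <= 1000,
                                     connectivity = conn)
      sizes <- table(lab[lab > 0])
      expect_identical(seg$n_voxels, as.integer(max(sizes)))
      # the kept voxels form exactly one oracle component
      expect_identical(length(unique(lab[seg$mask])), 1L)
    }
  }
})

test_that("full-package component labeling agrees with the oracle partition", {
  set.seed(77)
  mask <- array(runif(8^3) < 0.4, c(8, 8, 8))
  for (conn in c(6, 18, 26)) {
    ours <- hepatobase:::.label_components(mask, dim(mask), as.integer(conn))
    theirs <- oracle_label_components(mask, conn)
    expect_identical(canonical_labels(array(ours, dim(mask))),
                     canonical_labels(theirs))
  }
})

test_that("phantom recovery: volume within 5%, mean HU within 2 HU", {
  ph <- generate_liver_phantom(phantom_params(seed = 10))
  seg <- threshold_segment(ph$volume, 0, 1000,
                           component_policy = "largest-component")
  expect_lt(abs(seg$volume_cm3 - ph$truth$liver_volume_cm3) /
              ph$truth$liver_volume_cm3, 0.05)
  expect_lt(abs(seg$mean_hu - ph$truth$inwindow_mean_hu), 2)
})

test_that("segmented_fraction is exact label bookkeeping", {
  ph <- small_phantom(noise_sd = 0)
  liver <- ph$labels > 0
  seg <- threshold_segment(ph$volume, 0, 1000)
  expect_equal(segmented_fraction(seg, liver),
               100 * sum(ph$labels %in% c(2, 3, 4)) / sum(liver))
  expect_equal(segmented_fraction(liver, liver), 100)
  expect_equal(segmented_fraction(array(FALSE, dim(liver)), liver), 0)
  expect_error(segmented_fraction(liver, array(FALSE, dim(liver))), "empty")
})
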
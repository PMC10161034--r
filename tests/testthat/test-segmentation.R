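test_that("measure_roi_noise matches known dispersions", {
  ph <- flat_phantom()
  expect_equal(measure_roi_noise(ph$volume, c(0, 0), 30), 0)

  # two-point distribution +-10 HU: sample SD = 10 * sqrt(n / (n - 1))
  vox <- ph$volume$voxels
  np <- dim(vox)[1]
  xs <- (seq_len(np) - (np + 1) / 2) * 4
  X <- matrix(xs, np, np); Y <- matrix(xs, np, np, byrow = TRUE)
  inroi <- X^2 + Y^2 <= 30^2
  n_roi <- sum(inroi) * dim(vox)[3]
  signs <- rep(c(-1, 1), length.out = sum(inroi))
  for (k in seq_len(dim(vox)[3])) {
    sl <- vox[, , k]
    # alternate sign pattern across slices so +10/-10 counts are equal
    sl[inroi] <- -100 + 10 * (if (k %% 2) signs else -signs)
    vox[, , k] <- sl
  }
  v2 <- ct_volume(vox, 4, 5.25, 5, ph$volume$fov_diameter)
  expect_equal(measure_roi_noise(v2, c(0, 0), 30),
               10 * sqrt(n_roi / (n_roi - 1)), tolerance = 1e-10)

  # Gaussian sigma 20, >= 1e3 voxels: estimate within +-1.5 HU
  dr <- dose_record(ap = 300, lat = 300, thickness = 5.25,
                    ssde = 1.9 * (33.8 / 20)^2)
  nv <- inject_noise(ph$volume, dr, seed = 9)
  big_roi <- X^2 + Y^2 <= 55^2
  expect_gt(sum(big_roi) * dim(vox)[3], 1000)
  expect_lt(abs(measure_roi_noise(nv, c(0, 0), 55) - 20), 1.5)

  expect_error(measure_roi_noise(ph$volume, c(200, 0), 50), "outside")
})

test_that("denoise is near-identity on clean input and identity at strength 0", {
  ph <- flat_phantom(n_vat_deposits = 4)
  cfg0 <- segmentation_config(strength = 0)
  expect_identical(denoise(ph$volume, cfg0)$voxels, ph$volume$voxels)
  expect_identical(denoise(ph$volume, segmentation_config(denoiser = "none"))$voxels,
                   ph$volume$voxels)
  dn <- denoise(ph$volume)
  expect_lt(sqrt(mean((dn$voxels - ph$volume$voxels)^2)), 1)
  expect_identical(dn$pixel_spacing, ph$volume$pixel_spacing)
})

test_that("denoising reduces calibrated low-dose noise below 15 HU", {
  # calibration phantom: 2-mm pixels (the spacing the default strength was
  # calibrated at), deposit-free interior
  ph <- build_phantom(circle_phantom_spec(n_vat_deposits = 0),
                      test_geometry(n_pixels = 160, pixel_spacing = 2))
  dr <- dose_record(ap = 300, lat = 300, thickness = 5.25, ssde = 1.9)
  nv <- inject_noise(ph$volume, dr, seed = 3)
  s_raw <- measure_roi_noise(nv, c(0, 0), 40)
  expect_lt(abs(s_raw - 33.8), 1.5)
  for (den in c("bilateral", "gaussian", "median")) {
    cfg <- segmentation_config(denoiser = den)
    s_dn <- measure_roi_noise(denoise(nv, cfg), c(0, 0), 40)
    expect_lt(s_dn, s_raw)      # strict reduction for every filter
    if (den == "bilateral") expect_lt(s_dn, 15)
  }
})

test_that("segment_fat applies the HU window with component filtering", {
  vox <- array(-100, dim = c(20, 20, 1))
  vox[1, 1, 1] <- -200      # below window
  vox[5, 5, 1] <- 40        # above window
  v <- ct_volume(vox, 2, 5.25, 5)
  cfg <- segmentation_config(min_component_size = 1L)
  m <- segment_fat(v, cfg)
  expect_false(m[1, 1, 1]); expect_false(m[5, 5, 1])
  expect_identical(sum(m), 398L)
  # an isolated small island is dropped by the component filter
  vox2 <- array(50, dim = c(20, 20, 1))
  vox2[3:4, 3:4, 1] <- -100            # 4-voxel island
  vox2[10:17, 10:17, 1] <- -100        # 64-voxel block
  v2 <- ct_volume(vox2, 2, 5.25, 5)
  m2 <- segment_fat(v2, segmentation_config(min_component_size = 9L))
  expect_identical(sum(m2), 64L)
})

test_that("noiseless phantom segmentation is exact against ground truth", {
  ph <- flat_phantom(n_vat_deposits = 6, hu_jitter = 0)
  fat <- segment_fat(ph$volume)
  truth_fat <- ph$mask$labels %in% label_codes()[c("SAT", "VAT")]
  expect_identical(unname(as.vector(fat)), as.vector(truth_fat))
  comp <- separate_sat_vat(fat, ph$volume)
  expect_identical(as.vector(comp$sat_mask),
                   as.vector(ph$mask$labels == label_codes()[["SAT"]]))
  expect_identical(as.vector(comp$vat_mask),
                   as.vector(ph$mask$labels == label_codes()[["VAT"]]))
  # SAT/VAT disjoint and within the fat mask
  expect_false(any(comp$sat_mask & comp$vat_mask))
  expect_true(all(fat[comp$sat_mask | comp$vat_mask]))
})

test_that("zero-VAT phantom yields an empty VAT compartment", {
  ph <- flat_phantom(n_vat_deposits = 0)
  comp <- separate_sat_vat(segment_fat(ph$volume), ph$volume)
  expect_identical(sum(comp$vat_mask), 0L)
  expect_error(separate_sat_vat(array(FALSE, dim(ph$volume$voxels)),
                                ph$volume), "empty")
})

test_that("accuracy degrades monotonically with noise and denoising helps", {
  ph <- flat_phantom(n_vat_deposits = 4,
                     geometry = test_geometry(n_pixels = 96,
                                              pixel_spacing = 4,
                                              n_slices = 1))
  truth_sat <- sum(ph$mask$labels == 1)
  cal <- noise_calibration()
  sat_acc <- function(ssde, seeds, denoised) {
    vapply(seeds, function(sd) {
      dr <- dose_record(ap = 300, lat = 300, thickness = 5.25, ssde = ssde)
      nv <- inject_noise(ph$volume, dr, cal, seed = sd)
      if (denoised) nv <- denoise(nv)
      comp <- separate_sat_vat(segment_fat(nv), nv)
      accuracy(truth_sat, sum(comp$sat_mask))
    }, numeric(1))
  }
  seeds <- 1:20
  # sigma grid 12 / 34 / 60 HU via the dose law
  doses <- 1.9 * (33.8 / c(12, 33.8, 60))^2
  means <- vapply(doses, function(d) mean(sat_acc(d, seeds, FALSE)),
                  numeric(1))
  expect_true(all(diff(means) < 1e-9))  # non-increasing in noise
  # paired benefit of denoising at sigma 60 HU
  raw <- sat_acc(doses[3], seeds, FALSE)
  dn <- sat_acc(doses[3], seeds, TRUE)
  expect_gt(mean(dn - raw), 0)
  expect_gt(mean(dn), mean(raw) + 5)
})
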
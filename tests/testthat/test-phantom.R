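test_that("phantom_spec enforces its invariants", {
  expect_error(phantom_spec(body_ap = 50, body_lat = 300, sat_thickness = 20,
                            muscle_thickness = 10), "exceed")
  expect_error(phantom_spec(vat_fill_fraction = 1.2))
  expect_error(phantom_spec(n_vat_deposits = -1))
})

test_that("circular SAT annulus area matches the analytic formula", {
  ph <- flat_phantom(geometry = test_geometry(n_pixels = 160,
                                              pixel_spacing = 2))
  # pi (150^2 - 130^2) with one pixel-perimeter tolerance
  analytic <- pi * (150^2 - 130^2)
  expect_equal(ph$analytic$sat_area_mm2, analytic)
  counted <- sum(ph$mask$labels[, , 1] == label_codes()[["SAT"]]) * 2^2
  perim_tol <- 2 * pi * 150 * 2
  expect_lt(abs(counted - analytic), perim_tol)
})

test_that("VAT deposits: count, area and absence", {
  ph0 <- flat_phantom(n_vat_deposits = 0)
  expect_identical(sum(ph0$mask$labels == label_codes()[["VAT"]]), 0L)
  expect_identical(ph0$analytic$vat_area_mm2, 0)

  ph <- flat_phantom(n_vat_deposits = 6,
                     geometry = test_geometry(n_pixels = 160,
                                              pixel_spacing = 2))
  counted <- sum(ph$mask$labels[, , 1] == label_codes()[["VAT"]]) * 2^2
  # 6 disks: tolerance one pixel-perimeter each
  r <- ph$analytic$deposits$r[1]
  expect_lt(abs(counted - ph$analytic$vat_area_mm2), 6 * 2 * pi * r * 2)
  # deposits strictly inside the muscle wall
  expect_true(all(sqrt(ph$analytic$deposits$x^2 + ph$analytic$deposits$y^2) +
                    r < 150 - 20 - 10))
})

test_that("phantom generation is deterministic and labels match HU classes", {
  sp <- circle_phantom_spec(n_vat_deposits = 5, vat_fill_fraction = 0.15,
                            hu_jitter = 2)
  a <- build_phantom(sp, test_geometry())
  b <- build_phantom(sp, test_geometry())
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$mask$labels, b$mask$labels)
  # pre-noise co-registration: fat-labelled voxels carry fat-class HU
  sp0 <- circle_phantom_spec(n_vat_deposits = 5, vat_fill_fraction = 0.15)
  ph <- build_phantom(sp0, test_geometry())
  fat <- ph$mask$labels %in% label_codes()[c("SAT", "VAT")]
  expect_true(all(ph$volume$voxels[fat] == -100))
  lean <- ph$mask$labels == label_codes()[["lean"]]
  expect_true(all(ph$volume$voxels[lean] %in% c(50, 30)))
  # geometry too small to contain the body
  expect_error(build_phantom(sp0, test_geometry(n_pixels = 60)), "too small")
})

test_that("inject_noise follows the inverse-square-root law", {
  cal <- noise_calibration(sigma_ref = 33.8, ssde_ref = 1.9,
                           thickness_ref = 5.25)
  expect_equal(noise_sigma(cal, 7.6, 5.25), 33.8 / 2)
  expect_equal(noise_sigma(cal, 1.9, 5.25), 33.8)
  expect_equal(noise_sigma(cal, 3, 1.25) / noise_sigma(cal, 3, 5.25),
               sqrt(5.25 / 1.25))
  expect_error(noise_sigma(cal, 0, 5.25))
  expect_error(noise_sigma(cal, 1.9, -1))

  ph <- flat_phantom()
  dr <- dose_record(ap = 300, lat = 300, thickness = 5.25, ssde = 7.6)
  nv <- inject_noise(ph$volume, dr, cal, seed = 42)
  measured <- measure_roi_noise(nv, c(0, 0), 40)
  expect_lt(abs(measured - 16.9), 1.5)
  # determinism
  nv2 <- inject_noise(ph$volume, dr, cal, seed = 42)
  expect_identical(nv$voxels, nv2$voxels)
})

test_that("apply_positioning preserves geometry within resampling tolerance", {
  ph <- flat_phantom(n_vat_deposits = 4)
  id <- apply_positioning(ph$volume, ph$mask, positioning())
  expect_identical(id$volume, ph$volume)

  tr <- apply_positioning(ph$volume, ph$mask,
                          positioning(translation_mm = c(7.3, -4.1)))
  a0 <- sum(ph$mask$labels == 1); a1 <- sum(tr$mask$labels == 1)
  expect_lt(abs(a1 / a0 - 1), 0.005)
  v0 <- sum(ph$mask$labels == 2); v1 <- sum(tr$mask$labels == 2)
  expect_lt(abs(v1 / v0 - 1), 0.01)

  # 10% anterior compression shrinks the anterior half: area ratio 1 - c/2
  cp <- apply_positioning(ph$volume, ph$mask, positioning(compression = 0.10))
  expect_lt(abs(sum(cp$mask$labels == 1) / a0 - 0.95), 0.01)

  # transform pushing the body outside the FOV is rejected
  expect_error(apply_positioning(ph$volume, ph$mask,
                                 positioning(translation_mm = c(500, 0))),
               "outside")
  expect_error(positioning(rotation_deg = 30), "rotation")
  expect_error(positioning(compression = 0.3), "compression")
})

test_that("apply_truncation flags exactly when labelled voxels are removed", {
  ph <- flat_phantom(n_vat_deposits = 3)
  big <- apply_truncation(ph$volume, ph$mask, 450)
  expect_false(big$truncated)
  expect_identical(big$volume$voxels, ph$volume$voxels)

  clip <- apply_truncation(ph$volume, ph$mask, 290)
  expect_true(clip$truncated)
  expect_lt(sum(clip$mask$labels == 1), sum(ph$mask$labels == 1))

  degen <- apply_truncation(ph$volume, ph$mask, 0.5)
  expect_true(degen$truncated)
  expect_identical(sum(degen$mask$labels != 0), 0L)
})

test_that("simulate_cohort: event counts, determinism, degenerate settings", {
  co <- test_cohort_spec(n_subjects = 4, dose_grid = 1.7,
                         thickness_grid = c(1.25, 5.25))
  ch <- simulate_cohort(co)
  expect_length(ch$subjects, 4)
  for (s in ch$subjects) {
    expect_identical(s$standard$role, "standard")
    expect_length(s$lowdose, 2L)  # 1 dose x 2 thicknesses
  }
  # determinism: bit-identical volumes on re-simulation
  ch2 <- simulate_cohort(co)
  expect_identical(ch$subjects[[2]]$lowdose[[1]]$volume$voxels,
                   ch2$subjects[[2]]$lowdose[[1]]$volume$voxels)
  expect_identical(ch$subjects[[3]]$standard$truth$labels,
                   ch2$subjects[[3]]$standard$truth$labels)
  expect_error(cohort_spec(n_subjects = 1), "n_subjects")
  expect_error(cohort_spec(dose_grid = numeric(0)), "non-empty")
  expect_error(cohort_spec(dose_grid = c(1, -1)), "doses")
})

test_that("no drift and no rearrangement leave paired truth areas equal", {
  co <- test_cohort_spec(
    n_subjects = 2, dose_grid = 1.7, thickness_grid = 5.25,
    drift = list(sat_mean = 0, sat_sd = 0, vat_mean = 0, vat_sd = 0),
    jitter = list(rotation_deg = 3, translation_mm = 5, compression_max = 0,
                  sat_change_sd = 0, vat_change_sd = 0),
    truncation_probability = 0)
  ch <- simulate_cohort(co)
  for (s in ch$subjects) {
    a_ref <- mean(truth_slice_areas(s$standard$truth, "SAT"))
    a_low <- mean(truth_slice_areas(s$lowdose[[1]]$truth, "SAT"))
    expect_lt(abs(a_low / a_ref - 1), 0.01)
  }
})

test_that("forced truncation flags every low-dose event", {
  co <- test_cohort_spec(n_subjects = 2, dose_grid = 1.7,
                         thickness_grid = 5.25,
                         truncation_probability = 1,
                         truncation_fov_factor = 0.9)
  ch <- simulate_cohort(co)
  for (s in ch$subjects)
    expect_true(all(vapply(s$lowdose, function(e) e$truncated, logical(1))))
})

test_that("ct containers round-trip volumes and masks", {
  ph <- flat_phantom(n_vat_deposits = 3, hu_jitter = 2)
  dir <- withr::local_tempdir()
  write_ct_container(ph$volume, file.path(dir, "vol"))
  rt <- read_ct_container(file.path(dir, "vol"))
  expect_equal(rt$voxels, ph$volume$voxels, tolerance = 1e-6) # float32
  expect_identical(rt$pixel_spacing, ph$volume$pixel_spacing)
  write_ct_container(ph$mask, file.path(dir, "msk"))
  rtm <- read_ct_container(file.path(dir, "msk"))
  expect_identical(rtm$labels, ph$mask$labels)
})
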
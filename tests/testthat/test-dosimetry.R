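test_that("packaged conversion table is monotone and matches its generating fit", {
  tab <- ssde_conversion_table()
  expect_true(all(diff(tab$ap_plus_lat_cm) > 0))
  expect_true(all(diff(tab$conversion_factor) < 0))
  expect_true(all(tab$conversion_factor > 0))
  # transcription check against the exponential fit the table derives from
  fit <- 3.704369 * exp(-0.01835969 * tab$ap_plus_lat_cm)
  expect_true(max(abs(tab$conversion_factor - fit)) < 5e-5)
})

test_that("compute_ssde interpolates the table and refuses extrapolation", {
  expect_equal(compute_ssde(0, 250, 400), 0)
  # custom table with an exact node at sum 65 cm, factor 1.12
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(ap_plus_lat_cm = c(60, 65, 70),
                       conversion_factor = c(1.20, 1.12, 1.05)),
            tmp, row.names = FALSE)
  tab <- ssde_conversion_table(tmp)
  expect_equal(compute_ssde(1.7, 250, 400, tab), 1.7 * 1.12)
  # linear interpolation between nodes
  expect_equal(compute_ssde(1, 250, 375, tab), (1.20 + 1.12) / 2)
  expect_error(compute_ssde(1.7, 100, 100, tab), class = "adipoCT_range_error")
  # monotonicity of the interpolated factor
  f1 <- compute_ssde(1, 200, 400); f2 <- compute_ssde(1, 300, 400)
  expect_gt(f1, f2)
  # linear in CTDIvol at fixed dimensions
  expect_equal(compute_ssde(3.4, 250, 400), 2 * compute_ssde(1.7, 250, 400))
})

test_that("SSDE_5.25 thickness scaling is exact", {
  expect_equal(compute_ssde_5_25(1.9, 5.25), 1.9)
  expect_equal(compute_ssde_5_25(1.9, 1.25), 1.9 * 1.25 / 5.25)
  expect_equal(compute_ssde_5_25(1.7, 1.25), 1.7 * 1.25 / 5.25)
  expect_error(compute_ssde_5_25(1.9, 0))
  # invariant to the (dose, thickness) decomposition at fixed product
  expect_equal(compute_ssde_5_25(4, 2), compute_ssde_5_25(2, 4))
  # round trip at the reference thickness
  x <- runif(1, 0.1, 30)
  expect_identical(compute_ssde_5_25(x, 5.25), x)
})

test_that("effective dose follows SSDE x length x k", {
  expect_equal(round(compute_effective_dose(1.5, 16.8, 0.015), 2), 0.38)
  expect_equal(compute_effective_dose(0, 20, 0.015), 0)
  expect_equal(compute_effective_dose(2.0, 10.0, 0.015), 0.30)
  # CTDIvol-based DLP option
  expect_equal(compute_effective_dose(1.5, 16.8, 0.015, ctdivol = 1.7),
               1.7 * 16.8 * 0.015)
})

test_that("acquisition arithmetic reproduces scanner console values", {
  expect_equal(round(compute_effective_mas(60, 0.5, 1.375), 2), 21.82)
  expect_equal(compute_effective_mas(100, 1, 1), 100)
  expect_equal(round(compute_effective_mas(60, 0.5, 2.75), 2), 10.91)
  expect_error(compute_effective_mas(60, 0.5, 0))
  expect_equal(compute_table_feed(20, 1.375), 27.5)
  expect_equal(compute_table_feed(20, 1), 20)
  expect_equal(compute_table_feed(40, 1.375), 55)
})

test_that("dose_record derives consistent SSDE and SSDE_5.25 both ways", {
  dr <- dose_record(ap = 250, lat = 400, thickness = 1.25, ctdivol = 1.7)
  expect_equal(dr$ssde, 1.7 * adipoCT:::ssde_factor(65, ssde_conversion_table()))
  expect_equal(dr$ssde_5_25, dr$ssde * 1.25 / 5.25)
  dr2 <- dose_record(ap = 250, lat = 400, thickness = 1.25, ssde = dr$ssde)
  expect_equal(dr2$ctdivol, 1.7)
  expect_error(dose_record(ap = 250, lat = 400, thickness = 1.25))
})
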
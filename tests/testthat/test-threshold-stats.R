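test_that("3-sigma screening excludes only gross outliers, single pass", {
  recs <- make_records(6, accuracy_mean = 0, accuracy_sd = 0)
  recs$accuracy <- c(90, 91, 92, 89, 90, 25)
  recs$v_measure <- 100 - (100 - recs$accuracy)
  scr <- exclude_outliers_3sigma(recs)
  expect_identical(nrow(scr$kept), 5L)
  expect_equal(scr$excluded$accuracy, 25)
  # verify the leave-one-out 3-sigma rule by hand
  x <- recs$accuracy
  expect_true(abs(25 - mean(x[-6])) > 3 * sd(x[-6]))
  expect_false(any(vapply(1:5, function(j)
    abs(x[j] - mean(x[-j])) > 3 * sd(x[-j]), logical(1))))

  clean <- make_records(10, accuracy_mean = 90, accuracy_sd = 3)
  scr2 <- exclude_outliers_3sigma(clean)
  expect_identical(scr2$kept, clean)
  expect_identical(nrow(scr2$excluded), 0L)

  expect_warning(exclude_outliers_3sigma(clean[1:2, ]), "< 3 records")
})

test_that("confounder screens stratify correctly and report group summaries", {
  n <- 46
  truncated <- rep(c(TRUE, FALSE), c(17, 29))
  recs <- rbind(
    make_records(n, "SAT", 90, 8, truncated = truncated, seed = 2),
    make_records(n, "VAT", 85, 10, truncated = truncated, seed = 3))
  tt <- truncation_effect_test(recs)
  expect_named(tt, c("SAT", "VAT"))
  expect_identical(tt$SAT$groups$truncated$n, 17L)
  expect_identical(tt$SAT$groups$not_truncated$n, 29L)
  expect_true(tt$SAT$test$p_value > 0 && tt$SAT$test$p_value <= 1)

  # planted 15-point shift with paper-sized strata is detected
  shifted <- recs
  shifted$accuracy[shifted$truncated] <-
    shifted$accuracy[shifted$truncated] - 15
  shifted$v_measure <- 100 - (100 - shifted$accuracy)
  tt2 <- truncation_effect_test(shifted)
  expect_lt(tt2$SAT$test$p_value, 0.05)

  one_stratum <- make_records(10, "SAT", 90, 5, truncated = FALSE)
  expect_error(truncation_effect_test(one_stratum), "empty stratum")
})

test_that("interval screen uses the 15-day cutoff and flags drift", {
  days <- c(rep(5, 12), rep(60, 34))
  recs <- make_records(46, "SAT", 92, 5, days = days, seed = 4)
  it <- interval_effect_test(recs)
  expect_identical(it$SAT$groups$short_interval$n, 12L)
  expect_identical(it$SAT$groups$long_interval$n, 34L)

  # drifted long-interval records are detected
  drifted <- recs
  drifted$accuracy[drifted$days_between >= 15] <-
    drifted$accuracy[drifted$days_between >= 15] - 8
  drifted$v_measure <- 100 - (100 - drifted$accuracy)
  expect_lt(interval_effect_test(drifted)$SAT$test$p_value, 0.05)

  expect_error(interval_effect_test(recs, cutoff_days = 1000),
               "empty stratum")
})

test_that("acceptable accuracy derivation follows the subset rules", {
  acc3 <- make_records(3, "SAT", 0, 0, days = 5)
  acc3$accuracy <- c(90, 95, 100)
  acc3$v_measure <- 100 - (100 - acc3$accuracy)
  aa <- derive_acceptable_accuracy(acc3, "SAT", rule = "short_interval")
  expect_equal(aa$value, 95)

  # short-interval rule averages exactly the < cutoff records
  days <- c(rep(4, 5), rep(40, 7))
  recs <- make_records(12, "SAT", 93, 4, days = days, seed = 6)
  aa2 <- derive_acceptable_accuracy(recs, "SAT", rule = "short_interval")
  expect_equal(aa2$value, mean(recs$accuracy[recs$days_between < 15]))
  expect_identical(aa2$n, 5L)

  # all-days rule applies the 3-sigma screen first
  recs2 <- make_records(12, "VAT", 88, 2, days = days, seed = 7)
  recs2$accuracy[1] <- 20
  recs2$v_measure <- 100 - (100 - recs2$accuracy)
  aa3 <- derive_acceptable_accuracy(recs2, "VAT", rule = "all_excl_outliers")
  expect_equal(aa3$value, mean(recs2$accuracy[-1]))
  expect_identical(nrow(aa3$excluded), 1L)

  # fixed mode bypasses derivation
  aa4 <- derive_acceptable_accuracy(recs, "SAT", rule = "fixed",
                                    fixed_value = 94.5)
  expect_equal(aa4$value, 94.5)
  expect_identical(aa4$rule, "fixed")
})

test_that("auto rule selection is driven by the interval screen", {
  # strong drift -> short_interval; no drift -> all_excl_outliers
  days <- c(rep(4, 12), rep(60, 34))
  drifted <- make_records(46, "SAT", 94, 3, days = days, seed = 8)
  drifted$accuracy[drifted$days_between >= 15] <-
    drifted$accuracy[drifted$days_between >= 15] - 10
  drifted$v_measure <- 100 - (100 - drifted$accuracy)
  expect_identical(derive_acceptable_accuracy(drifted, "SAT")$rule,
                   "short_interval")
  flat <- make_records(46, "VAT", 85, 8, days = days, seed = 9)
  expect_identical(derive_acceptable_accuracy(flat, "VAT")$rule,
                   "all_excl_outliers")
})

test_that("dose-bin tests bin half-open, flag small n and skip empty bins", {
  ns <- c(9L, 5L, 14L, 18L)
  ssde <- rep(c(0.37, 0.42, 0.47, 0.8), ns)
  recs <- make_records(sum(ns), "SAT", 92, 4, ssde_5_25 = ssde,
                       thickness = 1.25, denoised = TRUE, source = "auto",
                       seed = 10)
  ref <- adipoCT:::with_seed(11, rnorm(12, 94.5, 6.6))
  br <- dose_bin_tests(recs, ref)
  expect_identical(nrow(br), 4L)
  expect_identical(br$n, ns)
  expect_identical(br$small_n, c(FALSE, TRUE, FALSE, FALSE))
  # boundary values fall in the right-open bin
  edge <- make_records(2, "SAT", 92, 1, ssde_5_25 = c(0.40, 0.399999),
                       seed = 12)
  br2 <- suppressMessages(dose_bin_tests(edge, ref))
  expect_identical(br2$n, c(1L, 1L))
  expect_identical(br2$bin_low, c(0.35, 0.40))
  expect_message(dose_bin_tests(edge, ref), "empty")
  expect_error(dose_bin_tests(recs, numeric(0)), "reference")
  expect_error(dose_bin_tests(recs, ref, bin_edges = c(1, 1)), "increasing")
})

test_that("dose-limit rule reproduces the published decision patterns", {
  mk_bins <- function(lows, highs, p, small) {
    structure(data.frame(bin_low = lows, bin_high = highs,
                         n = ifelse(small, 5L, 14L), mean = 90, sd = 3,
                         p_value = p, small_n = small),
              class = c("dose_bin_results", "data.frame"))
  }
  # VAT-like: bins starting at 0.4 all pass -> limit 0.4
  vat <- mk_bins(c(0.4, 0.45, 0.5, 0.55), c(0.45, 0.5, 0.55, Inf),
                 c(0.886, 1.000, 1.000, 0.999), rep(FALSE, 4))
  lv <- determine_dose_limit(vat)
  expect_equal(lv$limit, 0.4)
  expect_identical(lv$source, "bins")

  # SAT-like: no fine bin qualifies; passing 5.25-mm fallback gives 1.5
  sat <- mk_bins(c(0.35, 0.4, 0.45, 0.5), c(0.4, 0.45, 0.5, Inf),
                 c(0.001, 0.117, 0.013, 0.027), c(FALSE, TRUE, FALSE, FALSE))
  fb <- data.frame(label = "5.25mm >= 1.5 mGy", dose = 1.5, p_value = 0.957)
  ls <- determine_dose_limit(sat, fb)
  expect_equal(ls$limit, 1.5)
  expect_identical(ls$source, "fallback")

  # a lone passing small-n bin never qualifies by itself
  lone <- mk_bins(c(0.4, 0.45), c(0.45, Inf), c(0.03, 0.5),
                  c(FALSE, TRUE))
  expect_identical(determine_dose_limit(lone)$source, "none")

  # nothing passes anywhere
  none <- mk_bins(0.4, Inf, 0.001, FALSE)
  ln <- determine_dose_limit(none, data.frame(label = "x", dose = 1.5,
                                              p_value = 0.01))
  expect_true(is.na(ln$limit))
  expect_match(ln$rationale, "no limit")
})
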
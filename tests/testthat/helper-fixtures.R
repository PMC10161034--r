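# Shared fixtures, built in code.  Test-scale geometries are deliberately
# coarse (4 mm pixels) so the suite stays fast; physics-sensitive tests use
# finer grids locally.

test_geometry <- function(n_pixels = 120, pixel_spacing = 4, n_slices = 2,
                          slice_thickness = 5.25) {
  volume_geometry(n_pixels = n_pixels, pixel_spacing = pixel_spacing,
                  n_slices = n_slices, slice_thickness = slice_thickness)
}

# Circular body: the SAT annulus area formula is exact.
circle_phantom_spec <- function(..., hu_jitter = 0) {
  phantom_spec(body_ap = 300, body_lat = 300, sat_thickness = 20,
               muscle_thickness = 10, hu_jitter = hu_jitter, ...)
}

flat_phantom <- function(n_vat_deposits = 0, hu_jitter = 0,
                         geometry = test_geometry()) {
  build_phantom(circle_phantom_spec(n_vat_deposits = n_vat_deposits,
                                    vat_fill_fraction =
                                      if (n_vat_deposits > 0) 0.2 else 0,
                                    hu_jitter = hu_jitter),
                geometry)
}

test_cohort_spec <- function(n_subjects = 4, dose_grid = 1.7,
                             thickness_grid = c(1.25, 5.25), master_seed = 7,
                             ...) {
  cohort_spec(n_subjects = n_subjects, dose_grid = dose_grid,
              thickness_grid = thickness_grid, master_seed = master_seed,
              geometry = test_geometry(), ...)
}

# Synthetic accuracy-record tables for the statistics ladder.
make_records <- function(n, compartment = "SAT", accuracy_mean = 90,
                         accuracy_sd = 5, days = 5, truncated = FALSE,
                         ssde_5_25 = 1.9, thickness = 5.25, denoised = FALSE,
                         source = "manual", seed = 1) {
  acc <- adipoCT:::with_seed(seed, rnorm(n, accuracy_mean, accuracy_sd))
  do.call(rbind, lapply(seq_len(n), function(i) {
    accuracy_record(sprintf("S%03d", i), compartment,
                    v_true = 100, v_measure = 100 - (100 - acc[i]),
                    days_between = if (length(days) > 1) days[i] else days,
                    truncated = if (length(truncated) > 1) truncated[i]
                                else truncated,
                    ssde_5_25 = if (length(ssde_5_25) > 1) ssde_5_25[i]
                                else ssde_5_25,
                    thickness = thickness, denoised = denoised,
                    source = source)
  }))
}

# Independent Mann-Whitney oracle: full enumeration over all rank
# assignments via utils::combn (never calls the package's DP path).
mwu_enumeration_oracle <- function(a, b, sidedness = "two") {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  all_u <- apply(utils::combn(n1 + n2, n1), 2, u_of)
  p_less <- mean(all_u <= u_obs + 1e-9)
  p_greater <- mean(all_u >= u_obs - 1e-9)
  switch(sidedness,
         two = min(1, 2 * min(p_less, p_greater)),
         one_less = p_less,
         one_greater = p_greater)
}
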
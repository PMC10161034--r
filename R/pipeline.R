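#' Study configuration
#'
#' Bundles every parameter of a full dose-limit study.  `master_seed`
#' overrides the cohort's seed so one integer reproduces the whole run.
#'
#' @param cohort A [cohort_spec()].
#' @param segmentation A [segmentation_config()].
#' @param stats List: `alpha`, `bin_edges`, `interval_cutoff_days`,
#'   `acceptable_accuracy_mode` (`"derived"` or `"fixed"`), `fixed_values`
#'   (named, default `c(SAT = 94.5, VAT = 85.2)`), `small_n_min`,
#'   `fallback_min_ssde_5_25` (dose at/above which coarse-thickness records
#'   form the fallback level, default 1.5 mGy).
#' @param dosimetry List: `k` (effective-dose coefficient, default 0.015
#'   mSv/(mGy cm)), `conversion_table_path` (optional CSV override),
#'   `use_ctdivol_dlp` (default `FALSE`: effective dose uses SSDE).
#' @param output_dir Output directory for run artifacts.
#' @param master_seed Master RNG seed.
#' @param write_volumes Write per-scan image containers alongside the
#'   manifest.
#' @param figures Write the accuracy-vs-dose scatter figure (PDF).
#' @return An object of class `study_config`.
#' @export
study_config <- function(cohort = cohort_spec(),
                         segmentation = segmentation_config(),
                         stats = list(),
                         dosimetry = list(),
                         output_dir = NULL,
                         master_seed = 1L,
                         write_volumes = FALSE,
                         figures = FALSE) {
  stats <- utils::modifyList(list(
    alpha = 0.05,
    bin_edges = c(0.35, 0.40, 0.45, 0.50, Inf),
    interval_cutoff_days = 15,
    acceptable_accuracy_mode = "derived",
    fixed_values = c(SAT = 94.5, VAT = 85.2),
    small_n_min = 6L,
    fallback_min_ssde_5_25 = 1.5), stats)
  dosimetry <- utils::modifyList(list(
    k = 0.015, conversion_table_path = NULL, use_ctdivol_dlp = FALSE),
    dosimetry)
  if (!is.null(dosimetry$conversion_table_path))
    cohort$conversion_table <-
      ssde_conversion_table(dosimetry$conversion_table_path)
  cohort$master_seed <- as.integer(master_seed)
  structure(list(cohort = cohort, segmentation = segmentation, stats = stats,
                 dosimetry = dosimetry, output_dir = output_dir,
                 master_seed = as.integer(master_seed),
                 write_volumes = isTRUE(write_volumes),
                 figures = isTRUE(figures)),
            class = "study_config")
}

#' Read a study configuration from a YAML file
#'
#' The YAML mirrors the [study_config()] structure; any subset of fields may
#' be given and is merged over the defaults.  Nested sections `cohort`,
#' `cohort.phantom`, `cohort.geometry`, `cohort.noise_cal` and `segmentation`
#' are passed to their respective constructors.
#'
#' @param path Path to the YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  co_args <- y$cohort %||% list()
  if (!is.null(co_args$phantom)) {
    if (!is.null(co_args$phantom$hu_means))
      co_args$phantom$hu_means <- unlist(co_args$phantom$hu_means)
    co_args$phantom <- do.call(phantom_spec, co_args$phantom)
  }
  if (!is.null(co_args$geometry))
    co_args$geometry <- do.call(volume_geometry, co_args$geometry)
  if (!is.null(co_args$noise_cal))
    co_args$noise_cal <- do.call(noise_calibration, co_args$noise_cal)
  seg <- if (is.null(y$segmentation)) segmentation_config()
         else do.call(segmentation_config, y$segmentation)
  st <- y$stats %||% list()
  if (!is.null(st$bin_edges))
    st$bin_edges <- vapply(st$bin_edges,
                           function(e) if (identical(e, ".inf") ||
                                           identical(e, "Inf")) Inf
                                       else as.numeric(e), numeric(1))
  if (!is.null(st$fixed_values)) st$fixed_values <- unlist(st$fixed_values)
  study_config(cohort = do.call(cohort_spec, co_args),
               segmentation = seg, stats = st,
               dosimetry = y$dosimetry %||% list(),
               output_dir = y$output_dir,
               master_seed = y$master_seed %||% 1L,
               write_volumes = isTRUE(y$write_volumes),
               figures = isTRUE(y$figures))
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

# Fat volume per unit length of one compartment, from an automated
# segmentation of a scan event.
event_measured_vu <- function(event, seg_config, denoised) {
  vol <- if (denoised) denoise(event$volume, seg_config) else event$volume
  fat <- segment_fat(vol, seg_config)
  comp <- separate_sat_vat(fat, vol, seg_config)
  list(SAT = fat_volume_per_unit_length(slice_areas(comp$sat_mask, vol)),
       VAT = fat_volume_per_unit_length(slice_areas(comp$vat_mask, vol)))
}

event_truth_vu <- function(event) {
  list(SAT = fat_volume_per_unit_length(truth_slice_areas(event$truth, "SAT")),
       VAT = fat_volume_per_unit_length(truth_slice_areas(event$truth, "VAT")))
}

#' Build the accuracy-record table for a simulated cohort
#'
#' Two record streams are produced:
#' * `source = "manual"`: ground-truth masks of the reference-dose low-dose
#'   acquisition (coarsest thickness, dose closest to the noise-calibration
#'   anchor) compared against the standard scan's ground truth - isolating
#'   positioning, truncation and day-gap effects exactly as perfect manual
#'   segmentation would;
#' * `source = "auto"`: automated segmentation of every low-dose scan, with
#'   and without denoising, compared against the same scan's own ground truth
#'   - isolating noise/segmentation error at each dose.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param seg_config A [segmentation_config()].
#' @return An accuracy-record `data.frame` (see [accuracy_record()]).
#' @export
cohort_accuracy_records <- function(cohort, seg_config = segmentation_config()) {
  spec <- cohort$spec
  manual_dose <- which.min(abs(spec$dose_grid - spec$noise_cal$ssde_ref))
  coarse <- max(spec$thickness_grid)
  rows <- list()
  for (subj in cohort$subjects) {
    ref_vu <- event_truth_vu(subj$standard)
    for (ev in subj$lowdose) {
      ev_vu <- event_truth_vu(ev)
      is_manual_scan <- ev$dose$thickness == coarse &&
        abs(ev$dose$ssde - spec$dose_grid[manual_dose]) < 1e-9
      if (is_manual_scan) {
        for (comp in c("SAT", "VAT")) {
          rows[[length(rows) + 1L]] <- accuracy_record(
            subj$subject_id, comp, v_true = ref_vu[[comp]],
            v_measure = ev_vu[[comp]], days_between = ev$day_offset,
            truncated = ev$truncated || subj$standard$truncated,
            ssde_5_25 = ev$dose$ssde_5_25, thickness = ev$dose$thickness,
            denoised = FALSE, source = "manual")
        }
      }
      for (dn in c(FALSE, TRUE)) {
        mv <- event_measured_vu(ev, seg_config, dn)
        for (comp in c("SAT", "VAT")) {
          if (ev_vu[[comp]] <= 0) next   # truth empty (e.g. no VAT deposits)
          rows[[length(rows) + 1L]] <- accuracy_record(
            subj$subject_id, comp, v_true = ev_vu[[comp]],
            v_measure = mv[[comp]], days_between = ev$day_offset,
            truncated = ev$truncated, ssde_5_25 = ev$dose$ssde_5_25,
            thickness = ev$dose$thickness, denoised = dn, source = "auto")
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Run the statistics ladder on an accuracy-record table
#'
#' Stages: confounder screens (truncation, acquisition interval) on the
#' manual records; acceptable-accuracy derivation per compartment; dose-bin
#' one-sided tests of the denoised finest-thickness records against the
#' acceptable-accuracy reference sample, with the denoised coarsest-thickness
#' records pooled at/above `fallback_min_ssde_5_25` as fallback level; lower
#' dose-limit determination per compartment and combined.
#'
#' @param records Accuracy-record table.
#' @param config A [study_config()].
#' @return A list of class `study_stats` (serialisable to JSON).
#' @export
run_stats <- function(records, config) {
  validate_accuracy_records(records)
  st <- config$stats
  manual <- records[records$source == "manual", , drop = FALSE]
  auto <- records[records$source == "auto", , drop = FALSE]
  if (nrow(manual) == 0L || nrow(auto) == 0L)
    stop_adipo("need both manual and auto records",
               class = "adipoCT_schema_error")
  fine <- min(auto$thickness); coarse <- max(auto$thickness)

  # confounder screens degrade gracefully when a stratum is empty (possible
  # in small cohorts); the error is echoed into the report instead
  trunc_tests <- tryCatch(truncation_effect_test(manual, st$alpha),
                          adipoCT_error = function(e)
                            list(error = conditionMessage(e)))
  interval_tests <- tryCatch(
    interval_effect_test(manual, st$interval_cutoff_days, st$alpha),
    adipoCT_error = function(e) list(error = conditionMessage(e)))
  ser <- function(x) if (!is.null(x$error)) x else
    lapply(x, serialise_stratum)
  out <- list(alpha = st$alpha,
              truncation = ser(trunc_tests),
              interval = ser(interval_tests),
              compartments = list())
  limits <- c()
  for (comp in sort(unique(records$compartment))) {
    acc <- derive_acceptable_accuracy(manual, comp, rule = "auto",
                                      cutoff_days = st$interval_cutoff_days,
                                      alpha = st$alpha)
    if (identical(st$acceptable_accuracy_mode, "fixed"))
      acc$value <- unname(st$fixed_values[[comp]])
    sel <- auto$compartment == comp & auto$denoised & auto$thickness == fine
    bins <- dose_bin_tests(auto[sel, , drop = FALSE], acc$reference_sample,
                           bin_edges = st$bin_edges, alpha = st$alpha,
                           small_n_min = st$small_n_min)
    fb_sel <- auto$compartment == comp & auto$denoised &
      auto$thickness == coarse &
      auto$ssde_5_25 >= st$fallback_min_ssde_5_25
    fallback <- NULL
    if (any(fb_sel)) {
      fb <- mann_whitney_u(auto$accuracy[fb_sel], acc$reference_sample,
                           sidedness = "one_less")
      fallback <- data.frame(
        label = sprintf("%.3gmm >= %.3g mGy", coarse,
                        st$fallback_min_ssde_5_25),
        dose = st$fallback_min_ssde_5_25, n = sum(fb_sel),
        mean = mean(auto$accuracy[fb_sel]), p_value = fb$p_value)
    }
    lim <- determine_dose_limit(bins, fallback, st$alpha)
    limits[comp] <- lim$limit
    out$compartments[[comp]] <- list(
      acceptable_accuracy = list(value = acc$value, rule = acc$rule,
                                 n = acc$n,
                                 n_excluded = NROW(acc$excluded)),
      bins = as.data.frame(bins), fallback = fallback,
      limit = list(limit = lim$limit, source = lim$source,
                   rationale = lim$rationale))
  }
  out$combined_limit <- if (any(is.na(limits))) NA_real_ else max(limits)
  class(out) <- "study_stats"
  out
}

serialise_stratum <- function(x) {
  list(u = x$test$u_statistic, n1 = x$test$n1, n2 = x$test$n2,
       p_value = x$test$p_value, method = x$test$method,
       significant = x$significant,
       groups = lapply(x$groups, function(g)
         list(n = g$n, mean = g$mean, sd = g$sd)))
}

#' Run a full dose-limit study
#'
#' Orchestrates cohort simulation, (optional) denoising, segmentation, fat
#' metrics, the statistics ladder and dose-limit determination, writing all
#' artifacts (`manifest.csv`, `accuracy.csv`, `stats.json`, `report.json`,
#' optional figure) under `config$output_dir`.
#'
#' @param config A [study_config()].
#' @return A list of class `study_report` with the manifest, accuracy table,
#'   statistics, per-compartment and combined dose limits, the effective dose
#'   at the combined limit, and the resolved configuration echo.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(config$output_dir)) stop_adipo("`output_dir` is required")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage("simulate", "cohort of %d subject(s), %d dose(s) x %d thickness",
            config$cohort$n_subjects, length(config$cohort$dose_grid),
            length(config$cohort$thickness_grid))
  cohort <- simulate_cohort(config$cohort)
  manifest <- write_cohort_manifest(cohort, config$output_dir,
                                    config$write_volumes)
  log_noise_checkpoints(config)

  log_stage("segment", "building accuracy records (denoiser: %s)",
            config$segmentation$denoiser)
  records <- cohort_accuracy_records(cohort, config$segmentation)
  acc_path <- file.path(config$output_dir, "accuracy.csv")
  utils::write.csv(records, acc_path, row.names = FALSE)
  # compute stats from the serialised table so that replay_stats() on the
  # same CSV is bit-identical to the in-run stats stage
  records <- utils::read.csv(acc_path)
  records$truncated <- as.logical(records$truncated)
  records$denoised <- as.logical(records$denoised)

  log_stage("stats", "testing %d accuracy records", nrow(records))
  stats <- run_stats(records, config)

  scan_length_cm <- mean(vapply(cohort$subjects, function(s)
    s$standard$volume$n_slices * s$standard$volume$slice_interval / 10,
    numeric(1)))
  eff <- if (is.na(stats$combined_limit)) NA_real_ else
    compute_effective_dose(stats$combined_limit, scan_length_cm,
                           config$dosimetry$k)
  log_stage("report", "combined limit %s mGy; effective dose %s mSv",
            format(stats$combined_limit), format(eff))

  report <- list(stats = unclass(stats),
                 scan_length_cm = scan_length_cm,
                 effective_dose_mSv = eff,
                 config = config_echo(config))
  jsonlite::write_json(unclass(stats),
                       file.path(config$output_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  if (config$figures)
    plot_accuracy_vs_dose(records, stats,
                          file.path(config$output_dir,
                                    "accuracy_vs_dose.pdf"))
  structure(list(manifest = manifest, records = records, stats = stats,
                 dose_limits = vapply(stats$compartments,
                                      function(c) c$limit$limit, numeric(1)),
                 combined_limit = stats$combined_limit,
                 effective_dose_mSv = eff,
                 scan_length_cm = scan_length_cm,
                 config = config_echo(config),
                 output_dir = config$output_dir),
            class = "study_report")
}

# The three noise checkpoints (pre-noise, post-noise, post-denoise ROI sigma)
# measured on a jitter-free calibration phantom at the lowest grid dose.
log_noise_checkpoints <- function(config) {
  co <- config$cohort
  spec <- co$phantom
  spec$hu_jitter <- 0
  geom <- co$geometry
  geom$n_slices <- 1L
  ph <- build_phantom(spec, geom)
  pre <- measure_roi_noise(ph$volume, c(0, 0), config$segmentation$roi_radius)
  dr <- dose_record(ap = spec$body_ap, lat = spec$body_lat,
                    thickness = min(co$thickness_grid),
                    ssde = min(co$dose_grid), table = co$conversion_table)
  noisy <- inject_noise(ph$volume, dr, co$noise_cal,
                        substream_seed(co$master_seed, "noise_checkpoint"))
  post <- measure_roi_noise(noisy, c(0, 0), config$segmentation$roi_radius)
  dn <- measure_roi_noise(denoise(noisy, config$segmentation), c(0, 0),
                          config$segmentation$roi_radius)
  log_stage("noise", "ROI sigma: pre %.2f HU, post %.2f HU, denoised %.2f HU",
            pre, post, dn)
  invisible(c(pre = pre, post = post, denoised = dn))
}

config_echo <- function(config) {
  drop_fns <- function(x) {
    if (is.list(x)) lapply(x[!vapply(x, is.function, logical(1))], drop_fns)
    else x
  }
  e <- drop_fns(unclass(config))
  e$cohort$conversion_table <- NULL   # packaged data, path echoed separately
  e
}

#' Re-run the statistics stage on a saved accuracy table
#'
#' @param accuracy_csv Path to an `accuracy.csv` written by [run_study()].
#' @param config A [study_config()].
#' @param out Optional path; when given, the stats JSON is written there.
#' @return The `study_stats` list (identical to the stats stage of
#'   [run_study()] on the same table).
#' @export
replay_stats <- function(accuracy_csv, config, out = NULL) {
  if (!file.exists(accuracy_csv))
    stop_adipo("file not found: %s", accuracy_csv,
               class = "adipoCT_schema_error")
  records <- utils::read.csv(accuracy_csv)
  if (nrow(records) == 0L)
    stop_adipo("accuracy table is empty", class = "adipoCT_schema_error")
  records$truncated <- as.logical(records$truncated)
  records$denoised <- as.logical(records$denoised)
  stats <- run_stats(records, config)
  if (!is.null(out))
    jsonlite::write_json(unclass(stats), out, auto_unbox = TRUE, digits = NA,
                         na = "null", force = TRUE)
  stats
}

#' Accuracy vs dose scatter figure
#'
#' Plots automated-measurement accuracy against SSDE_5.25 per compartment,
#' denoised and not, with the acceptable-accuracy line.
#'
#' @param records Accuracy-record table.
#' @param stats A [run_stats()] result.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
plot_accuracy_vs_dose <- function(records, stats, path) {
  auto <- records[records$source == "auto", , drop = FALSE]
  comps <- names(stats$compartments)
  grDevices::pdf(path, width = 5 * length(comps), height = 4.5)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, length(comps)))
  for (comp in comps) {
    d <- auto[auto$compartment == comp, , drop = FALSE]
    graphics::plot(d$ssde_5_25, d$accuracy,
                   col = ifelse(d$denoised, "blue", "grey50"),
                   pch = ifelse(d$denoised, 16, 1),
                   xlab = expression(SSDE[5.25] ~ "(mGy)"),
                   ylab = "Accuracy (%)", main = comp, log = "x")
    graphics::abline(h = stats$compartments[[comp]]$acceptable_accuracy$value,
                     col = "red", lty = 2)
    graphics::legend("bottomright", c("denoised", "raw", "acceptable"),
                     col = c("blue", "grey50", "red"),
                     pch = c(16, 1, NA), lty = c(NA, NA, 2), cex = 0.8)
  }
  invisible(path)
}
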
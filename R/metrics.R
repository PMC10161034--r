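#' Fat volume statistics
#'
#' `fat_volume_total()` is the conventional total fat volume
#' `Vt = sum_i S_i * I` (slice areas times slice interval).
#' `fat_volume_per_unit_length()` is the fat volume per unit scan length,
#' `Vu = Vt / L = mean(S_i)`: the mean per-slice fat area, which removes the
#' dependence on scan length, slice count and slice interval that makes `Vt`
#' fragile when scans are reconstructed differently.
#'
#' @param areas Numeric vector of per-slice fat areas `S_i` in mm^2.
#' @param slice_interval Slice interval `I` in mm.
#' @return `fat_volume_total()`: volume in mm^3;
#'   `fat_volume_per_unit_length()`: mm^3 per mm (equivalently mm^2).
#' @export
fat_volume_total <- function(areas, slice_interval) {
  check_areas(areas)
  check_scalar_number(slice_interval, "slice_interval", positive = TRUE)
  sum(areas) * slice_interval
}

#' @rdname fat_volume_total
#' @export
fat_volume_per_unit_length <- function(areas, slice_interval = NULL) {
  check_areas(areas)
  mean(areas)
}

check_areas <- function(areas) {
  if (length(areas) == 0L) stop_adipo("`areas` must be non-empty")
  if (!is.numeric(areas) || any(!is.finite(areas)) || any(areas < 0))
    stop_adipo("`areas` must be finite and non-negative")
  invisible(areas)
}

#' Measurement accuracy against ground truth
#'
#' `accuracy = (1 - |v_true - v_measure| / v_true) * 100` (percent).  The
#' absolute deviation is used so that over- and under-measurement both reduce
#' accuracy; values can be negative when the deviation exceeds 100% of truth.
#'
#' @param v_true Ground-truth fat volume (> 0).
#' @param v_measure Measured fat volume.
#' @return Accuracy in percent (<= 100; 100 iff exact agreement).
#' @export
accuracy <- function(v_true, v_measure) {
  if (!is.numeric(v_true) || any(v_true <= 0))
    stop_adipo("`v_true` must be > 0")
  (1 - abs(v_true - v_measure) / v_true) * 100
}

#' Build one accuracy record
#'
#' One row of the interchange table linking a subject x compartment
#' measurement to its acquisition conditions.  Tables of these records are the
#' unit passed from segmentation to the statistics ladder.
#'
#' @param subject_id Subject identifier.
#' @param compartment `"SAT"` or `"VAT"`.
#' @param v_true,v_measure Ground-truth and measured fat volume per unit
#'   length (mm^3/mm).
#' @param days_between Days between the compared scans.
#' @param truncated Logical: was either scan FOV-truncated?
#' @param ssde_5_25 Thickness-normalised SSDE of the measured scan (mGy).
#' @param thickness Slice thickness of the measured scan (mm).
#' @param denoised Logical: was noise reduction applied?
#' @param source `"manual"` (ground-truth-vs-ground-truth comparison) or
#'   `"auto"` (automated segmentation vs same-scan truth).
#' @return A one-row `data.frame` with an `accuracy` column consistent with
#'   [accuracy()].
#' @export
accuracy_record <- function(subject_id, compartment, v_true, v_measure,
                            days_between = 0, truncated = FALSE,
                            ssde_5_25 = NA_real_, thickness = NA_real_,
                            denoised = FALSE, source = "auto") {
  data.frame(subject_id = subject_id, compartment = compartment,
             v_true = v_true, v_measure = v_measure,
             accuracy = accuracy(v_true, v_measure),
             days_between = days_between, truncated = truncated,
             ssde_5_25 = ssde_5_25, thickness = thickness,
             denoised = denoised, source = source,
             stringsAsFactors = FALSE)
}

accuracy_record_columns <- function() {
  c("subject_id", "compartment", "v_true", "v_measure", "accuracy",
    "days_between", "truncated", "ssde_5_25", "thickness", "denoised",
    "source")
}

#' Validate an accuracy-record table
#'
#' Checks the column schema and that the `accuracy` column is consistent with
#' `v_true`/`v_measure`.
#'
#' @param records A `data.frame` of accuracy records.
#' @return The validated table, invisibly.
#' @export
validate_accuracy_records <- function(records) {
  miss <- setdiff(accuracy_record_columns(), names(records))
  if (length(miss))
    stop_adipo("accuracy table missing columns: %s",
               paste(miss, collapse = ", "), class = "adipoCT_schema_error")
  if (nrow(records) == 0L)
    stop_adipo("accuracy table is empty", class = "adipoCT_schema_error")
  bad <- abs(records$accuracy -
               accuracy(records$v_true, records$v_measure)) > 1e-6
  if (any(bad))
    stop_adipo("accuracy column inconsistent with v_true/v_measure in %d row(s)",
               sum(bad), class = "adipoCT_schema_error")
  invisible(records)
}
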
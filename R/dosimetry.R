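#' Size-specific dose estimate (SSDE) conversion table
#'
#' Loads a conversion table mapping the sum of the patient's anterior-posterior
#' (AP) and lateral (LAT) dimensions (cm) to the CTDIvol-to-SSDE conversion
#' factor for the 32-cm body reference phantom.  The packaged default is
#' generated from the public exponential fit
#' `f = 3.704369 * exp(-0.01835969 * (AP + LAT))` underlying the AAPM Report
#' 204 tabulation (the file is labelled synthetic because it is fit-derived,
#' not a page transcription).  A user table may be supplied as a CSV with
#' columns `ap_plus_lat_cm` and `conversion_factor`.
#'
#' @param path Optional path to a CSV overriding the packaged table.
#' @return A `data.frame` of class `ssde_table` with strictly increasing sums
#'   and strictly decreasing positive factors.
#' @export
ssde_conversion_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ssde_conversion_32cm_synthetic.csv",
                                package = "adipoCT", mustWork = TRUE)
  tab <- utils::read.csv(path)
  if (!all(c("ap_plus_lat_cm", "conversion_factor") %in% names(tab)))
    stop_adipo("conversion table needs columns ap_plus_lat_cm, conversion_factor")
  tab <- tab[order(tab$ap_plus_lat_cm), , drop = FALSE]
  if (any(diff(tab$conversion_factor) >= 0) || any(tab$conversion_factor <= 0))
    stop_adipo("conversion factors must be positive and strictly decreasing")
  class(tab) <- c("ssde_table", "data.frame")
  tab
}

#' Compute the size-specific dose estimate (SSDE)
#'
#' SSDE = CTDIvol x f(AP + LAT), where f is linearly interpolated from the
#' conversion table.  AP and LAT are given in mm (the package's length unit);
#' the table is indexed in cm.  Sums outside the table range are an error (no
#' extrapolation).
#'
#' @param ctdivol Volume CT dose index in mGy (32-cm body phantom reference).
#' @param ap,lat Anterior-posterior and lateral body dimensions in mm.
#' @param table A conversion table from [ssde_conversion_table()].
#' @return SSDE in mGy.
#' @export
compute_ssde <- function(ctdivol, ap, lat, table = ssde_conversion_table()) {
  check_scalar_number(ctdivol, "ctdivol", nonneg = TRUE)
  check_scalar_number(ap, "ap", positive = TRUE)
  check_scalar_number(lat, "lat", positive = TRUE)
  ctdivol * ssde_factor((ap + lat) / 10, table)
}

ssde_factor <- function(sum_cm, table) {
  rng <- range(table$ap_plus_lat_cm)
  if (sum_cm < rng[1] || sum_cm > rng[2])
    stop_adipo("AP+LAT sum %.1f cm outside conversion table range [%g, %g]",
               sum_cm, rng[1], rng[2], class = "adipoCT_range_error")
  stats::approx(table$ap_plus_lat_cm, table$conversion_factor,
                xout = sum_cm)$y
}

#' Slice-thickness-normalised SSDE
#'
#' Rescales an SSDE to its 5.25-mm slice-thickness noise equivalent:
#' `SSDE_5.25 = SSDE * thickness / 5.25`.  Because image noise scales as
#' `1/sqrt(dose * thickness)`, images reconstructed at different thicknesses
#' are comparable at equal `SSDE_5.25`.
#'
#' @param ssde SSDE in mGy.
#' @param thickness Slice thickness in mm.
#' @return SSDE_5.25 in mGy.
#' @export
compute_ssde_5_25 <- function(ssde, thickness) {
  check_scalar_number(ssde, "ssde", nonneg = TRUE)
  check_scalar_number(thickness, "thickness", positive = TRUE)
  ssde * thickness / 5.25
}

#' Effective dose from SSDE and scan length
#'
#' `E = SSDE x scan_length x k`, a dose-length-product style estimate that
#' uses the size-specific dose in place of CTDIvol, with `k` the abdomen-
#' pelvis region conversion coefficient (default 0.015 mSv/(mGy cm)).  Set
#' `ctdivol` to use the conventional CTDIvol-based DLP instead.
#'
#' @param ssde SSDE in mGy.
#' @param scan_length_cm Scan length in cm.
#' @param k Region conversion coefficient in mSv/(mGy*cm).
#' @param ctdivol Optional CTDIvol (mGy); when supplied, the conventional
#'   CTDIvol-based DLP is used instead of the SSDE-based one.
#' @return Effective dose in mSv.
#' @export
compute_effective_dose <- function(ssde, scan_length_cm, k = 0.015,
                                   ctdivol = NULL) {
  check_scalar_number(ssde, "ssde", nonneg = TRUE)
  check_scalar_number(scan_length_cm, "scan_length_cm", nonneg = TRUE)
  check_scalar_number(k, "k", nonneg = TRUE)
  dose <- if (is.null(ctdivol)) ssde else
    check_scalar_number(ctdivol, "ctdivol", nonneg = TRUE)
  dose * scan_length_cm * k
}

#' Helical acquisition arithmetic
#'
#' `compute_effective_mas()` returns tube current x rotation time / pitch;
#' `compute_table_feed()` returns total collimation x pitch (mm per rotation).
#'
#' @param tube_current Tube current in mA.
#' @param revolution_time Gantry rotation time in s.
#' @param pitch Spiral pitch factor (dimensionless, > 0).
#' @return Effective mAs.
#' @export
compute_effective_mas <- function(tube_current, revolution_time, pitch) {
  check_scalar_number(tube_current, "tube_current", positive = TRUE)
  check_scalar_number(revolution_time, "revolution_time", positive = TRUE)
  check_scalar_number(pitch, "pitch", positive = TRUE)
  tube_current * revolution_time / pitch
}

#' @rdname compute_effective_mas
#' @param total_collimation Total collimation width in mm.
#' @return `compute_table_feed()`: table feed in mm per rotation.
#' @export
compute_table_feed <- function(total_collimation, pitch) {
  check_scalar_number(total_collimation, "total_collimation", positive = TRUE)
  check_scalar_number(pitch, "pitch", positive = TRUE)
  total_collimation * pitch
}

#' Dose record for one acquisition
#'
#' Bundles CTDIvol, body dimensions and the derived SSDE and SSDE_5.25 for a
#' scan.  Either `ctdivol` or a target `ssde` may be given; the other is
#' derived through the conversion table.
#'
#' @param ap,lat Body dimensions in mm.
#' @param thickness Reconstructed slice thickness in mm.
#' @param ctdivol CTDIvol in mGy (optional if `ssde` given).
#' @param ssde Target SSDE in mGy (optional if `ctdivol` given).
#' @param table Conversion table.
#' @return An object of class `dose_record` with fields `ctdivol`, `ap`,
#'   `lat`, `ssde`, `thickness`, `ssde_5_25`.
#' @export
dose_record <- function(ap, lat, thickness, ctdivol = NULL, ssde = NULL,
                        table = ssde_conversion_table()) {
  check_scalar_number(ap, "ap", positive = TRUE)
  check_scalar_number(lat, "lat", positive = TRUE)
  check_scalar_number(thickness, "thickness", positive = TRUE)
  f <- ssde_factor((ap + lat) / 10, table)
  if (is.null(ctdivol) && is.null(ssde))
    stop_adipo("one of `ctdivol` or `ssde` is required")
  if (is.null(ctdivol)) ctdivol <- ssde / f
  ssde <- ctdivol * f
  structure(
    list(ctdivol = ctdivol, ap = ap, lat = lat, ssde = ssde,
         thickness = thickness,
         ssde_5_25 = compute_ssde_5_25(ssde, thickness)),
    class = "dose_record")
}

#' @export
print.dose_record <- function(x, ...) {
  cat(sprintf(
    "<dose_record> CTDIvol %.3g mGy, AP %.0f + LAT %.0f mm -> SSDE %.3g mGy; T %.3g mm -> SSDE_5.25 %.3g mGy\n",
    x$ctdivol, x$ap, x$lat, x$ssde, x$thickness, x$ssde_5_25))
  invisible(x)
}
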
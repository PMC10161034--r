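#' Configuration of the fat segmenter and denoiser
#'
#' The segmenter is a deliberately simple, fully deterministic stand-in for
#' learned fat-quantification systems: voxels are classified as fat by a
#' Hounsfield window (default the conventional adipose window -190 to -30 HU),
#' small connected components are discarded, and the SAT/VAT split is obtained
#' by morphologically closing the muscle wall and filling its interior.  The
#' denoiser stands in for post-reconstruction noise-reduction products; the
#' default edge-preserving bilateral filter at `strength = 2.5` mm was
#' calibrated once on the deposit-free calibration phantom at 2-mm pixel
#' spacing so that 33.8 HU of injected noise is reduced to roughly 11 HU,
#' matching the effect size of a commercial noise-reduction technique (the
#' reduction is governed by the spatial sigma in pixels, so coarser grids
#' denoise less at the same physical strength).
#'
#' @param fat_window Length-2 HU window `(low, high)` classifying fat.
#' @param min_component_size Minimum in-plane connected-component size
#'   (voxels) retained in the fat mask.
#' @param wall_closing_radius Morphological closing radius (mm) used to bridge
#'   gaps in the detected muscle wall.
#' @param denoiser One of `"none"`, `"gaussian"`, `"bilateral"`, `"median"`.
#' @param strength Denoiser strength: the spatial smoothing scale in mm
#'   (Gaussian/bilateral sigma, median window radius).  `0` is the identity.
#' @param range_sigma_hu Bilateral range (intensity) sigma in HU, or `NULL`
#'   (default) for the adaptive rule `2.2 x` the slice's estimated noise
#'   standard deviation (Immerkaer Laplacian estimator, floored at 20 HU),
#'   which reproduces the 33.8 -> ~11 HU calibration anchor and keeps the
#'   filter effective at far higher noise levels.
#' @param body_threshold_hu HU above which a voxel counts as body (not air)
#'   for body-contour detection.
#' @param roi_radius Default radius (mm) of circular noise-measurement ROIs.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(fat_window = c(-190, -30),
                                min_component_size = 9L,
                                wall_closing_radius = 5,
                                denoiser = c("bilateral", "gaussian",
                                             "median", "none"),
                                strength = 2.5,
                                range_sigma_hu = NULL,
                                body_threshold_hu = -500,
                                roi_radius = 15) {
  denoiser <- match.arg(denoiser)
  if (length(fat_window) != 2L || fat_window[1] >= fat_window[2])
    stop_adipo("`fat_window` must be (low, high) with low < high")
  check_scalar_number(wall_closing_radius, "wall_closing_radius", positive = TRUE)
  check_scalar_number(strength, "strength", nonneg = TRUE)
  check_scalar_number(roi_radius, "roi_radius", positive = TRUE)
  structure(
    list(fat_window = as.numeric(fat_window),
         min_component_size = as.integer(min_component_size),
         wall_closing_radius = wall_closing_radius,
         denoiser = denoiser, strength = strength,
         range_sigma_hu = range_sigma_hu,
         body_threshold_hu = body_threshold_hu,
         roi_radius = roi_radius),
    class = "segmentation_config")
}

#' Denoise a CT volume
#'
#' Applies the configured classical filter slice by slice (2-D processing, in
#' keeping with slice-based area measurement).  Geometry metadata is
#' unchanged; `strength = 0` or `denoiser = "none"` returns the input.
#'
#' @param volume A `ct_volume`.
#' @param config A [segmentation_config()].
#' @return A denoised `ct_volume`.
#' @export
denoise <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (config$denoiser == "none" || config$strength == 0) return(volume)
  sigma_px <- config$strength / volume$pixel_spacing
  out <- volume
  for (k in seq_len(volume$n_slices)) {
    sl <- volume$voxels[, , k]
    sigma_r <- config$range_sigma_hu %||%
      max(20, 2.2 * estimate_noise_sigma(sl))
    out$voxels[, , k] <- switch(
      config$denoiser,
      gaussian = gaussian_blur(sl, sigma_px),
      bilateral = bilateral_filter(sl, sigma_px, sigma_r),
      median = median_filter(sl, max(1L, round(sigma_px))))
  }
  out$voxels <- clamp(out$voxels, -1024, 3071)
  out
}

# Robust white-noise sigma estimate from the discrete Laplacian residual
# (Immerkaer): structure-blind for smooth images, median-based against edges.
estimate_noise_sigma <- function(img) {
  L <- 4 * img -
    shift_img(img, 1, 0) - shift_img(img, -1, 0) -
    shift_img(img, 0, 1) - shift_img(img, 0, -1)
  L <- 2 * L +
    shift_img(img, 1, 1) + shift_img(img, 1, -1) +
    shift_img(img, -1, 1) + shift_img(img, -1, -1) -
    4 * img  # net kernel: [1 -2 1; -2 4 -2; 1 -2 1], L2 norm 6
  v <- abs(L[!is.na(L)])
  stats::median(v) / (0.6745 * 6)
}

bilateral_filter <- function(img, sigma_px, sigma_r) {
  half <- max(1L, ceiling(2.5 * sigma_px))
  num <- matrix(0, nrow(img), ncol(img))
  den <- num
  for (di in -half:half) for (dj in -half:half) {
    d2 <- di^2 + dj^2
    if (d2 > half^2) next
    ws <- exp(-d2 / (2 * sigma_px^2))
    sh <- shift_img(img, di, dj)
    w <- ws * exp(-(sh - img)^2 / (2 * sigma_r^2))
    w[is.na(sh)] <- 0
    sh[is.na(sh)] <- 0
    num <- num + w * sh
    den <- den + w
  }
  num / den
}

shift_img <- function(m, di, dj) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  si <- seq_len(nr) - di; sj <- seq_len(nc) - dj
  oi <- si >= 1 & si <= nr; oj <- sj >= 1 & sj <= nc
  out[oi, oj] <- m[si[oi], sj[oj]]
  out
}

median_filter <- function(img, r) {
  offs <- expand.grid(di = -r:r, dj = -r:r)
  stack <- vapply(seq_len(nrow(offs)),
                  function(i) shift_img(img, offs$di[i], offs$dj[i]),
                  img)
  out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
  matrix(out, nrow(img), ncol(img))
}

#' Measure noise in a circular region of interest
#'
#' Returns the sample standard deviation (n - 1 denominator) of HU values in
#' the in-plane circular ROI centred at `center_mm = (x, y)` with radius
#' `radius_mm`, pooled over the requested slices.
#'
#' @param volume A `ct_volume`.
#' @param center_mm Length-2 in-plane ROI centre in mm (origin image centre,
#'   x lateral, y anterior-posterior).
#' @param radius_mm ROI radius in mm.
#' @param slices Slice indices (default: all).
#' @return Standard deviation in HU.
#' @export
measure_roi_noise <- function(volume, center_mm = c(0, 0), radius_mm = 15,
                              slices = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  check_scalar_number(radius_mm, "radius_mm", positive = TRUE)
  np <- dim(volume$voxels)[1L]
  half_fov <- np * volume$pixel_spacing / 2
  if (sqrt(sum(center_mm^2)) + radius_mm > half_fov)
    stop_adipo("ROI extends outside the volume")
  xs <- plane_coords(np, volume$pixel_spacing)
  X <- matrix(xs, np, np); Y <- matrix(xs, np, np, byrow = TRUE)
  inroi <- (X - center_mm[1])^2 + (Y - center_mm[2])^2 <= radius_mm^2
  slices <- slices %||% seq_len(volume$n_slices)
  vals <- unlist(lapply(slices, function(k) volume$voxels[, , k][inroi]))
  if (length(vals) < 2L) stop_adipo("ROI contains fewer than 2 voxels")
  stats::sd(vals)
}

#' Segment fat voxels by Hounsfield window
#'
#' A voxel enters the fat mask iff its HU lies inside `config$fat_window`
#' (inclusive); in-plane connected components smaller than
#' `config$min_component_size` voxels are then discarded.
#'
#' @param volume A `ct_volume` in HU.
#' @param config A [segmentation_config()].
#' @return A logical 3-D array, the fat mask.
#' @export
segment_fat <- function(volume, config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  w <- config$fat_window
  mask <- volume$voxels >= w[1] & volume$voxels <= w[2]
  if (config$min_component_size > 1L) {
    for (k in seq_len(volume$n_slices))
      mask[, , k] <- filter_small_components(mask[, , k],
                                             config$min_component_size)
  }
  mask
}

#' Separate a fat mask into SAT and VAT compartments
#'
#' Per slice: the body contour is the largest connected component of voxels
#' above `body_threshold_hu`, hole-filled; the muscle wall and interior tissue
#' are the non-fat-window body voxels, bridged by morphological closing with
#' `wall_closing_radius`; the filled wall region defines "inside".  Fat inside
#' is visceral (VAT), fat outside but within the body is subcutaneous (SAT).
#'
#' @param fat_mask Logical 3-D array from [segment_fat()].
#' @param volume The `ct_volume` the mask was computed from.
#' @param config A [segmentation_config()].
#' @return A list of class `compartment_masks` with disjoint logical arrays
#'   `sat_mask` and `vat_mask` (both subsets of `fat_mask`).
#' @export
separate_sat_vat <- function(fat_mask, volume,
                             config = segmentation_config()) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!any(fat_mask)) stop_adipo("fat mask is empty")
  r_px <- max(1L, round(config$wall_closing_radius / volume$pixel_spacing))
  sat <- array(FALSE, dim = dim(fat_mask))
  vat <- sat
  for (k in seq_len(dim(fat_mask)[3L])) {
    sl_hu <- volume$voxels[, , k]
    sl_fat <- fat_mask[, , k]
    body_raw <- sl_hu > config$body_threshold_hu
    if (!any(body_raw)) stop_adipo("no body contour found in slice %d", k)
    body <- fill_holes(largest_component(body_raw))
    wall <- body & (sl_hu > config$fat_window[2])
    inside <- fill_holes(morph_close(wall, r_px))
    vat[, , k] <- sl_fat & inside
    sat[, , k] <- sl_fat & body & !inside
  }
  structure(list(sat_mask = sat, vat_mask = vat), class = "compartment_masks")
}

#' Per-slice compartment areas
#'
#' Areas are labelled-pixel counts times `pixel_spacing^2` (no partial-volume
#' weighting).
#'
#' @param mask Logical 3-D array (one compartment) or a `label_mask` plus
#'   `compartment` name.
#' @param geometry A `ct_volume`/`label_mask` supplying `pixel_spacing`.
#' @return Numeric vector of per-slice areas in mm^2.
#' @export
slice_areas <- function(mask, geometry) {
  arr <- if (is.array(mask)) mask else mask$labels
  apply(arr, 3L, sum) * geometry$pixel_spacing^2
}

#' @rdname slice_areas
#' @param label_mask A `label_mask`.
#' @param compartment `"SAT"` or `"VAT"`.
#' @export
truth_slice_areas <- function(label_mask, compartment = c("SAT", "VAT")) {
  compartment <- match.arg(compartment)
  code <- label_codes()[[compartment]]
  apply(label_mask$labels == code, 3L, sum) * label_mask$pixel_spacing^2
}
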
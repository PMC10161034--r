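#' Specification of a synthetic abdominal phantom
#'
#' The phantom is an extruded elliptical abdomen: an outer subcutaneous fat
#' (SAT) ring of constant thickness, a muscle wall inside it, and an organ
#' interior carrying scattered circular visceral fat (VAT) deposits.  The SAT
#' region is bounded by the outer body ellipse (semi-axes `lat/2`, `ap/2`) and
#' an inner ellipse with both semi-axes reduced by `sat_thickness`, so its
#' analytic per-slice area is exactly
#' `pi * (a*b - (a - t)*(b - t))`.  VAT deposits are equal-radius disks whose
#' total area is `vat_fill_fraction` of the interior-cavity area.
#'
#' @param body_ap,body_lat Outer body AP and LAT diameters in mm.
#' @param sat_thickness,muscle_thickness Ring thicknesses in mm.
#' @param n_vat_deposits Number of circular VAT deposits.
#' @param vat_fill_fraction Fraction of the interior cavity area occupied by
#'   VAT, in `[0, 1)` (practically <= 0.4 so deposits can be placed without
#'   overlap).
#' @param organ_seeds RNG seed controlling deposit placement and HU texture.
#' @param hu_means Named HU means per tissue class
#'   (`fat`, `muscle`, `organ`, `air`, `bone`).
#' @param hu_jitter Within-tissue HU texture standard deviation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_ap = 250, body_lat = 400,
                         sat_thickness = 20, muscle_thickness = 10,
                         n_vat_deposits = 10, vat_fill_fraction = 0.25,
                         organ_seeds = 1L,
                         hu_means = c(fat = -100, muscle = 50, organ = 30,
                                      air = -1000, bone = 700),
                         hu_jitter = 3) {
  check_scalar_number(body_ap, "body_ap", positive = TRUE)
  check_scalar_number(body_lat, "body_lat", positive = TRUE)
  check_scalar_number(sat_thickness, "sat_thickness", positive = TRUE)
  check_scalar_number(muscle_thickness, "muscle_thickness", positive = TRUE)
  check_scalar_number(hu_jitter, "hu_jitter", nonneg = TRUE)
  if (n_vat_deposits < 0 || n_vat_deposits != round(n_vat_deposits))
    stop_adipo("`n_vat_deposits` must be a non-negative integer")
  if (vat_fill_fraction < 0 || vat_fill_fraction >= 1)
    stop_adipo("`vat_fill_fraction` must be in [0, 1)")
  wall <- 2 * (sat_thickness + muscle_thickness)
  if (body_ap <= wall || body_lat <= wall)
    stop_adipo("body diameters must exceed 2*(sat_thickness + muscle_thickness) = %g mm",
               wall)
  need <- c("fat", "muscle", "organ", "air")
  if (!all(need %in% names(hu_means)))
    stop_adipo("`hu_means` must name at least %s", paste(need, collapse = ", "))
  structure(
    list(body_ap = body_ap, body_lat = body_lat,
         sat_thickness = sat_thickness, muscle_thickness = muscle_thickness,
         n_vat_deposits = as.integer(n_vat_deposits),
         vat_fill_fraction = vat_fill_fraction,
         organ_seeds = as.integer(organ_seeds),
         hu_means = hu_means, hu_jitter = hu_jitter),
    class = "phantom_spec")
}

#' Volume geometry for phantom rasterisation
#'
#' @param n_pixels In-plane matrix size (square).
#' @param pixel_spacing Pixel size in mm.
#' @param n_slices Number of axial slices.
#' @param slice_thickness,slice_interval Reconstruction geometry in mm.
#' @param fov_diameter FOV diameter in mm (defaults to the array extent).
#' @return A plain list used by [build_phantom()].
#' @export
volume_geometry <- function(n_pixels = 512, pixel_spacing = 500 / 512,
                            n_slices = 3, slice_thickness = 5.25,
                            slice_interval = 5, fov_diameter = NULL) {
  list(n_pixels = as.integer(n_pixels), pixel_spacing = pixel_spacing,
       n_slices = as.integer(n_slices), slice_thickness = slice_thickness,
       slice_interval = slice_interval,
       fov_diameter = fov_diameter %||% (n_pixels * pixel_spacing))
}

#' Rasterise a noiseless phantom volume with ground-truth labels
#'
#' @param spec A [phantom_spec()].
#' @param geometry A [volume_geometry()].
#' @return A list with elements `volume` (a `ct_volume`, noiseless apart from
#'   the deterministic within-tissue texture), `mask` (a `label_mask`) and
#'   `analytic` (exact per-slice SAT/VAT areas in mm^2 and the deposit table),
#'   for verification against pixel counts.
#' @export
build_phantom <- function(spec, geometry = volume_geometry()) {
  stopifnot(inherits(spec, "phantom_spec"))
  a <- spec$body_lat / 2; b <- spec$body_ap / 2
  ts <- spec$sat_thickness; tm <- spec$muscle_thickness
  np <- geometry$n_pixels
  if (2 * a > np * geometry$pixel_spacing || 2 * b > np * geometry$pixel_spacing)
    stop_adipo("geometry too small: body %g x %g mm exceeds the %g mm image extent",
               2 * a, 2 * b, np * geometry$pixel_spacing)
  xs <- plane_coords(np, geometry$pixel_spacing)
  X <- matrix(xs, np, np)                    # LAT coordinate
  Y <- matrix(xs, np, np, byrow = TRUE)      # AP coordinate (negative anterior)
  inside <- function(ax, by) (X / ax)^2 + (Y / by)^2 <= 1

  body <- inside(a, b)
  sat_inner <- inside(a - ts, b - ts)
  wall_inner <- inside(a - ts - tm, b - ts - tm)

  ai <- a - ts - tm; bi <- b - ts - tm       # interior cavity semi-axes
  interior_area <- pi * ai * bi
  codes <- label_codes()
  lab <- matrix(codes[["background"]], np, np)
  lab[body & !sat_inner] <- codes[["SAT"]]
  lab[sat_inner & !wall_inner] <- codes[["lean"]]
  lab[wall_inner] <- codes[["lean"]]

  deposits <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  if (spec$n_vat_deposits > 0L && spec$vat_fill_fraction > 0) {
    r <- sqrt(spec$vat_fill_fraction * interior_area / (spec$n_vat_deposits * pi))
    margin <- 6                                # mm clearance from the wall
    if (ai - r - margin <= 0 || bi - r - margin <= 0)
      stop_adipo("geometry too small to place VAT deposits of radius %.1f mm", r)
    deposits <- with_seed(substream_seed(spec$organ_seeds, "vat_deposits"),
                          place_deposits(spec$n_vat_deposits, r,
                                         ai - r - margin, bi - r - margin))
    for (i in seq_len(nrow(deposits)))
      lab[(X - deposits$x[i])^2 + (Y - deposits$y[i])^2 <= deposits$r[i]^2] <-
        codes[["VAT"]]
  }

  hu <- matrix(spec$hu_means[["air"]], np, np)
  hu[lab == codes[["SAT"]] | lab == codes[["VAT"]]] <- spec$hu_means[["fat"]]
  hu[sat_inner & !wall_inner & lab != codes[["VAT"]]] <- spec$hu_means[["muscle"]]
  hu[wall_inner & lab != codes[["VAT"]]] <- spec$hu_means[["organ"]]

  vox <- array(hu, dim = c(np, np, geometry$n_slices))
  labs <- array(lab, dim = c(np, np, geometry$n_slices))
  if (spec$hu_jitter > 0) {
    bodyv <- array(body, dim = dim(vox))
    nb <- sum(bodyv)
    jit <- with_seed(substream_seed(spec$organ_seeds, "hu_texture"),
                     rnorm(nb, 0, spec$hu_jitter))
    vox[bodyv] <- vox[bodyv] + jit
  }
  vox <- clamp(vox, -1024, 3071)

  vol <- ct_volume(vox, geometry$pixel_spacing, geometry$slice_thickness,
                   geometry$slice_interval, geometry$fov_diameter)
  msk <- label_mask(labs, vol)
  analytic <- list(
    sat_area_mm2 = pi * (a * b - (a - ts) * (b - ts)),
    vat_area_mm2 = if (nrow(deposits)) sum(pi * deposits$r^2) else 0,
    deposits = deposits)
  list(volume = vol, mask = msk, analytic = analytic)
}

# Place n non-overlapping disk centres inside the ellipse with semi-axes
# (ax, by) (caller already subtracted radius + margin): candidates on a
# square grid with spacing 2r + 4 mm are subsampled and jittered within the
# slack, guaranteeing non-overlap by construction.
place_deposits <- function(n, r, ax, by) {
  if (ax <= 0 || by <= 0)
    stop_adipo("could not place %d VAT deposits (fill fraction too high)", n)
  spacing <- 2 * r + 3
  gx <- seq(0, ax, by = spacing); gx <- c(-rev(gx[-1]), gx)
  gy <- seq(0, by, by = spacing); gy <- c(-rev(gy[-1]), gy)
  cand <- expand.grid(x = gx, y = gy)
  cand <- cand[(cand$x / ax)^2 + (cand$y / by)^2 <= 1, , drop = FALSE]
  if (nrow(cand) < n)
    stop_adipo("could not place %d VAT deposits (fill fraction too high)", n)
  pick <- cand[sample.int(nrow(cand), n), , drop = FALSE]
  jit <- 1.4   # mm, below half the 3-mm grid slack: overlap impossible
  data.frame(x = pick$x + runif(n, -jit, jit),
             y = pick$y + runif(n, -jit, jit), r = r)
}

#' Noise calibration anchor
#'
#' Pins the additive-noise model `sigma = sigma_ref *
#' sqrt((ssde_ref * thickness_ref) / (ssde * thickness))` to a measured
#' reference point.  The default anchor is 33.8 HU at SSDE 1.9 mGy and 5.25 mm
#' slice thickness (a measured fat-region noise level on a low-dose scan).
#'
#' @param sigma_ref Reference noise standard deviation in HU.
#' @param ssde_ref Reference SSDE in mGy.
#' @param thickness_ref Reference slice thickness in mm.
#' @return An object of class `noise_calibration`.
#' @export
noise_calibration <- function(sigma_ref = 33.8, ssde_ref = 1.9,
                              thickness_ref = 5.25) {
  check_scalar_number(sigma_ref, "sigma_ref", nonneg = TRUE)
  check_scalar_number(ssde_ref, "ssde_ref", positive = TRUE)
  check_scalar_number(thickness_ref, "thickness_ref", positive = TRUE)
  structure(list(sigma_ref = sigma_ref, ssde_ref = ssde_ref,
                 thickness_ref = thickness_ref),
            class = "noise_calibration")
}

#' Predicted noise level at a dose/thickness
#'
#' @param cal A [noise_calibration()].
#' @param ssde SSDE in mGy.
#' @param thickness Slice thickness in mm.
#' @return Noise standard deviation in HU.
#' @export
noise_sigma <- function(cal, ssde, thickness) {
  check_scalar_number(ssde, "ssde", positive = TRUE)
  check_scalar_number(thickness, "thickness", positive = TRUE)
  cal$sigma_ref * sqrt((cal$ssde_ref * cal$thickness_ref) / (ssde * thickness))
}

#' Inject dose-dependent image noise
#'
#' Adds zero-mean white Gaussian noise in HU whose standard deviation follows
#' the inverse-square-root law in dose and slice thickness (see
#' [noise_calibration()]).  Output HU are clipped to the valid range, so air
#' voxels near -1000 HU have slightly truncated noise; homogeneous soft-tissue
#' regions are unaffected by the clip.
#'
#' @param volume A `ct_volume`.
#' @param dose A [dose_record()] with `ssde > 0`.
#' @param noise_cal A [noise_calibration()].
#' @param seed RNG seed for the noise field.
#' @return A new `ct_volume` with noise added.
#' @export
inject_noise <- function(volume, dose, noise_cal = noise_calibration(),
                         seed = 1L) {
  stopifnot(inherits(volume, "ct_volume"))
  sigma <- noise_sigma(noise_cal, dose$ssde, volume$slice_thickness)
  vox <- volume$voxels +
    with_seed(seed, array(rnorm(length(volume$voxels), 0, sigma),
                          dim = dim(volume$voxels)))
  out <- volume
  out$voxels <- clamp(vox, -1024, 3071)
  out
}

#' Positioning parameters for a scan event
#'
#' @param rotation_deg In-plane rotation about the image centre (degrees).
#' @param translation_mm Length-2 in-plane translation (LAT, AP) in mm.
#' @param compression Anterior compression fraction in `[0, 0.15]`: the
#'   anterior half (negative AP coordinates) is scaled towards the table by
#'   `1 - compression`.
#' @param max_rotation_deg Validity bound on `|rotation_deg|`.
#' @return An object of class `positioning`.
#' @export
positioning <- function(rotation_deg = 0, translation_mm = c(0, 0),
                        compression = 0, max_rotation_deg = 15) {
  check_scalar_number(rotation_deg, "rotation_deg")
  if (abs(rotation_deg) > max_rotation_deg)
    stop_adipo("|rotation| exceeds the configured maximum %g deg", max_rotation_deg)
  if (length(translation_mm) != 2L || !all(is.finite(translation_mm)))
    stop_adipo("`translation_mm` must be two finite numbers")
  check_scalar_number(compression, "compression", nonneg = TRUE)
  if (compression > 0.15)
    stop_adipo("compression fraction must be in [0, 0.15]")
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = as.numeric(translation_mm),
                 compression = compression),
            class = "positioning")
}

#' Apply a positioning transform to a volume and its mask
#'
#' Forward model: anterior compression, then in-plane rotation about the image
#' centre, then translation, applied identically to every slice.  Resampling
#' is by inverse mapping with bilinear interpolation for HU and
#' nearest-neighbour for labels; samples mapped from outside the original grid
#' become air / background.  An exact identity transform returns the inputs
#' unchanged.
#'
#' @param volume A `ct_volume`.
#' @param mask The paired `label_mask`.
#' @param pos A [positioning()].
#' @param background_hu HU assigned where the source lies outside the grid.
#' @return A list with transformed `volume` and `mask`.
#' @export
apply_positioning <- function(volume, mask, pos, background_hu = -1000) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "label_mask"))
  if (!identical(dim(volume$voxels), dim(mask$labels)))
    stop_adipo("volume and mask shapes differ")
  if (pos$rotation_deg == 0 && all(pos$translation_mm == 0) &&
      pos$compression == 0)
    return(list(volume = volume, mask = mask))

  np <- dim(volume$voxels)[1L]
  sp <- volume$pixel_spacing
  xs <- plane_coords(np, sp)
  Xo <- matrix(xs, np, np); Yo <- matrix(xs, np, np, byrow = TRUE)
  # inverse transform: untranslate -> unrotate -> uncompress
  th <- -pos$rotation_deg * pi / 180
  Xt <- Xo - pos$translation_mm[1]; Yt <- Yo - pos$translation_mm[2]
  Xs <- cos(th) * Xt - sin(th) * Yt
  Ys <- sin(th) * Xt + cos(th) * Yt
  if (pos$compression > 0) {
    ant <- Ys < 0
    Ys[ant] <- Ys[ant] / (1 - pos$compression)
  }
  # fractional source pixel indices
  fi <- (Xs / sp) + (np + 1) / 2
  fj <- (Ys / sp) + (np + 1) / 2

  i0 <- floor(fi); j0 <- floor(fj)
  wi <- fi - i0; wj <- fj - j0
  inb <- i0 >= 1 & i0 < np & j0 >= 1 & j0 < np
  ir <- round(fi); jr <- round(fj)
  inb_n <- ir >= 1 & ir <= np & jr >= 1 & jr <= np

  nz <- dim(volume$voxels)[3L]
  vox <- array(background_hu, dim = dim(volume$voxels))
  labs <- array(label_codes()[["background"]], dim = dim(mask$labels))
  idx00 <- cbind(i0[inb], j0[inb])
  idx10 <- cbind(i0[inb] + 1L, j0[inb])
  idx01 <- cbind(i0[inb], j0[inb] + 1L)
  idx11 <- cbind(i0[inb] + 1L, j0[inb] + 1L)
  w00 <- (1 - wi[inb]) * (1 - wj[inb]); w10 <- wi[inb] * (1 - wj[inb])
  w01 <- (1 - wi[inb]) * wj[inb];       w11 <- wi[inb] * wj[inb]
  idxn <- cbind(ir[inb_n], jr[inb_n])
  for (k in seq_len(nz)) {
    src <- volume$voxels[, , k]
    out <- matrix(background_hu, np, np)
    out[inb] <- src[idx00] * w00 + src[idx10] * w10 +
      src[idx01] * w01 + src[idx11] * w11
    vox[, , k] <- out
    lsrc <- mask$labels[, , k]
    lout <- matrix(label_codes()[["background"]], np, np)
    lout[inb_n] <- lsrc[idxn]
    labs[, , k] <- lout
  }
  if (!any(labs != label_codes()[["background"]]))
    stop_adipo("positioning transform moved the whole body outside the FOV")
  out_vol <- volume; out_vol$voxels <- clamp(vox, -1024, 3071)
  out_msk <- mask; out_msk$labels <- labs
  list(volume = out_vol, mask = out_msk)
}

#' Truncate a volume to a reconstruction FOV
#'
#' Voxels outside the centred FOV circle are set to background (air HU, label
#' background).  The `truncated` flag is `TRUE` iff at least one non-background
#' label voxel was removed.
#'
#' @inheritParams apply_positioning
#' @param fov_diameter New FOV diameter in mm (> 0).
#' @return A list with `volume`, `mask` and logical `truncated`.
#' @export
apply_truncation <- function(volume, mask, fov_diameter,
                             background_hu = -1000) {
  stopifnot(inherits(volume, "ct_volume"), inherits(mask, "label_mask"))
  check_scalar_number(fov_diameter, "fov_diameter", positive = TRUE)
  np <- dim(volume$voxels)[1L]
  xs <- plane_coords(np, volume$pixel_spacing)
  X <- matrix(xs, np, np); Y <- matrix(xs, np, np, byrow = TRUE)
  outside <- X^2 + Y^2 > (fov_diameter / 2)^2
  out3 <- array(outside, dim = dim(volume$voxels))
  truncated <- any(mask$labels[out3] != label_codes()[["background"]])
  vol <- volume; msk <- mask
  vol$voxels[out3] <- background_hu
  msk$labels[out3] <- label_codes()[["background"]]
  vol$fov_diameter <- fov_diameter
  msk$fov_diameter <- fov_diameter
  list(volume = vol, mask = msk, truncated = truncated)
}
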
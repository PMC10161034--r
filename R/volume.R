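#' CT volume and label-mask containers
#'
#' `ct_volume()` wraps a 3-D array of Hounsfield units (HU) together with its
#' geometry metadata; `label_mask()` wraps the paired per-voxel tissue labels.
#' Conventions used throughout the package: the first array axis is the
#' lateral (LAT, x) direction, the second the anterior-posterior (AP, y)
#' direction with negative y anterior, the third the slice axis with slice 1
#' the most superior; the in-plane origin is the image centre; lengths are mm,
#' intensities HU, doses mGy.
#'
#' @param voxels 3-D numeric array of HU values, finite, in `[-1024, 3071]`.
#' @param pixel_spacing In-plane pixel size in mm (isotropic).
#' @param slice_thickness Reconstructed slice thickness in mm.
#' @param slice_interval Distance between slice centres in mm.
#' @param fov_diameter Reconstruction field-of-view diameter in mm; defaults
#'   to the in-plane extent of the array.
#' @return An object of class `ct_volume`.
#' @seealso [label_mask()], [write_ct_container()]
#' @export
ct_volume <- function(voxels, pixel_spacing, slice_thickness, slice_interval,
                      fov_diameter = NULL) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop_adipo("`voxels` must be a 3-D array")
  if (!all(is.finite(voxels)))
    stop_adipo("`voxels` must be finite HU values")
  if (min(voxels) < -1024 || max(voxels) > 3071)
    stop_adipo("HU values must lie in [-1024, 3071]")
  check_scalar_number(pixel_spacing, "pixel_spacing", positive = TRUE)
  check_scalar_number(slice_thickness, "slice_thickness", positive = TRUE)
  check_scalar_number(slice_interval, "slice_interval", positive = TRUE)
  fov_diameter <- fov_diameter %||% (max(dim(voxels)[1:2]) * pixel_spacing)
  check_scalar_number(fov_diameter, "fov_diameter", positive = TRUE)
  structure(
    list(voxels = voxels, pixel_spacing = pixel_spacing,
         slice_thickness = slice_thickness, slice_interval = slice_interval,
         fov_diameter = fov_diameter, n_slices = dim(voxels)[3L]),
    class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<ct_volume> %d x %d px, %d slice(s); %.3g mm px, T=%.3g mm, I=%.3g mm, FOV=%.3g mm\n",
    d[1], d[2], d[3], x$pixel_spacing, x$slice_thickness, x$slice_interval,
    x$fov_diameter))
  invisible(x)
}

#' Tissue label codes used in ground-truth masks
#'
#' Integer codes: background 0, SAT 1, VAT 2, lean (muscle/organ) 3, other 4.
#' @return Named integer vector.
#' @export
label_codes <- function() {
  c(background = 0L, SAT = 1L, VAT = 2L, lean = 3L, other = 4L)
}

#' @rdname ct_volume
#' @param labels 3-D integer array over the codes of [label_codes()].
#' @param geometry A `ct_volume` (or compatible list) whose geometry metadata
#'   the mask shares.
#' @return `label_mask()` returns an object of class `label_mask`.
#' @export
label_mask <- function(labels, geometry) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop_adipo("`labels` must be a 3-D array")
  if (!all(labels %in% label_codes()))
    stop_adipo("labels must be codes from label_codes()")
  structure(
    list(labels = labels, pixel_spacing = geometry$pixel_spacing,
         slice_thickness = geometry$slice_thickness,
         slice_interval = geometry$slice_interval,
         fov_diameter = geometry$fov_diameter, n_slices = dim(labels)[3L]),
    class = "label_mask")
}

#' @export
print.label_mask <- function(x, ...) {
  tb <- table(factor(x$labels, levels = label_codes(),
                     labels = names(label_codes())))
  cat("<label_mask>", paste(names(tb), as.integer(tb), sep = "=",
                            collapse = " "), "\n")
  invisible(x)
}

# Physical in-plane coordinates (mm) of pixel centres, origin at image centre.
plane_coords <- function(n, spacing) (seq_len(n) - (n + 1) / 2) * spacing

#' Write/read a CT volume or label mask as a raw array container
#'
#' The container is a gzip-compressed little-endian binary array (`.bin.gz`,
#' 4-byte floats for HU, 1-byte integers for labels) accompanied by a JSON
#' sidecar (`.json`) carrying the array dimensions, value kind and geometry
#' metadata (pixel spacing, slice thickness/interval, FOV; all mm).  This is
#' the package's on-disk interchange format for image data.
#'
#' @param x A `ct_volume` or `label_mask`.
#' @param path_prefix Output path without extension; `<prefix>.bin.gz` and
#'   `<prefix>.json` are written.
#' @return `write_ct_container()` returns `path_prefix` invisibly;
#'   `read_ct_container()` returns the reconstructed object.
#' @export
write_ct_container <- function(x, path_prefix) {
  is_mask <- inherits(x, "label_mask")
  if (!is_mask && !inherits(x, "ct_volume"))
    stop_adipo("`x` must be a ct_volume or label_mask")
  arr <- if (is_mask) x$labels else x$voxels
  meta <- list(
    kind = if (is_mask) "label_mask" else "ct_volume",
    dim = dim(arr),
    dtype = if (is_mask) "uint8" else "float32",
    pixel_spacing_mm = x$pixel_spacing,
    slice_thickness_mm = x$slice_thickness,
    slice_interval_mm = x$slice_interval,
    fov_diameter_mm = x$fov_diameter)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  con <- gzfile(paste0(path_prefix, ".bin.gz"), "wb")
  on.exit(close(con))
  if (is_mask) writeBin(as.integer(arr), con, size = 1L)
  else writeBin(as.numeric(arr), con, size = 4L, endian = "little")
  invisible(path_prefix)
}

#' @rdname write_ct_container
#' @export
read_ct_container <- function(path_prefix) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- gzfile(paste0(path_prefix, ".bin.gz"), "rb")
  on.exit(close(con))
  geom <- list(pixel_spacing = as.numeric(meta$pixel_spacing_mm),
               slice_thickness = as.numeric(meta$slice_thickness_mm),
               slice_interval = as.numeric(meta$slice_interval_mm),
               fov_diameter = as.numeric(meta$fov_diameter_mm))
  if (identical(meta$kind, "label_mask")) {
    arr <- array(readBin(con, "integer", n, size = 1L, signed = FALSE),
                 dim = meta$dim)
    label_mask(arr, geom)
  } else {
    arr <- array(readBin(con, "numeric", n, size = 4L, endian = "little"),
                 dim = meta$dim)
    ct_volume(arr, geom$pixel_spacing, geom$slice_thickness,
              geom$slice_interval, geom$fov_diameter)
  }
}
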
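#' Activity-concentration map
#'
#' A 3-D grid of activity concentration in Bq/mL at a fixed time post
#' injection, with isotropic-or-not voxel geometry.  This is the basic
#' volumetric container of the package; quantitative SPECT exports in
#' kBq/mL are rescaled to Bq/mL on load (see [read_activity_series()]).
#'
#' @param values Numeric 3-D array, Bq/mL.  Must be non-negative; negative
#'   voxels are rejected unless `clamp_negative = TRUE`, in which case they
#'   are set to zero with a warning (small negatives are common in
#'   reconstructed data).
#' @param voxel_size_mm Voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param time_h Acquisition time in hours post injection (>= 0).
#' @param cycle_id Label of the therapy cycle the map belongs to.
#' @param clamp_negative Clamp negative voxels to zero instead of erroring.
#'
#' @return An object of class `activity_map`.
#' @seealso [region_mask()], [read_activity_series()], [apply_psf()]
#' @examples
#' m <- activity_map(array(1000, c(8, 8, 8)), voxel_size_mm = 1.95, time_h = 4)
#' voxel_volume_ml(m) * prod(dim(m$values))  # total grid volume in mL
#' @export
activity_map <- function(values, voxel_size_mm, time_h, cycle_id = "cycle1",
                         clamp_negative = FALSE) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array", call. = FALSE)
  if (!is.numeric(voxel_size_mm) || !length(voxel_size_mm) %in% c(1L, 3L) ||
      any(voxel_size_mm <= 0))
    stop("'voxel_size_mm' must be 1 or 3 positive numbers", call. = FALSE)
  stopifnot_scalar(time_h, "time_h", nonneg = TRUE)
  if (any(values < 0)) {
    if (clamp_negative) {
      nneg <- sum(values < 0)
      values[values < 0] <- 0
      warning(sprintf("clamped %d negative voxel(s) to zero", nneg),
              call. = FALSE)
    } else {
      stop("activity values must be >= 0 (use clamp_negative = TRUE)",
           call. = FALSE)
    }
  }
  structure(list(values = values,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 time_h = as.numeric(time_h),
                 cycle_id = as.character(cycle_id)),
            class = "activity_map")
}

#' @export
print.activity_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("activity_map: %dx%dx%d voxels, %.4g x %.4g x %.4g mm, t = %g h (%s)\n",
              d[1], d[2], d[3], x$voxel_size_mm[1], x$voxel_size_mm[2],
              x$voxel_size_mm[3], x$time_h, x$cycle_id))
  cat(sprintf("  range %.4g .. %.4g Bq/mL, total %.4g Bq\n",
              min(x$values), max(x$values), total_activity_Bq(x)))
  invisible(x)
}

#' Voxel volume in millilitres
#'
#' @param x An `activity_map`, `dose_map`, `region_mask`, or a numeric
#'   vector of voxel edge lengths in mm.
#' @return Voxel volume in mL (1 mL = 1000 mm^3).
#' @export
voxel_volume_ml <- function(x) {
  v <- if (is.numeric(x)) rep_len(x, 3L) else x$voxel_size_mm
  prod(v) / 1000
}

#' Total activity on the grid in Bq
#'
#' Sum of concentration times voxel volume; conserved by [apply_psf()]
#' whenever the blurred distribution stays inside the grid.
#' @param map An `activity_map`.
#' @return Total activity (Bq).
#' @export
total_activity_Bq <- function(map) {
  stopifnot(inherits(map, "activity_map"))
  sum(map$values) * voxel_volume_ml(map)
}

#' Region mask aligned to an activity map
#'
#' @param mask Logical 3-D array (or coercible), same grid as the maps it
#'   will be used with.
#' @param label Region name.
#' @param kind `"organ"` or `"lesion"`.
#' @param voxel_size_mm Voxel edge lengths in mm (for volume computations).
#' @param ct_volume_ml Optional independently measured anatomical volume
#'   (mL) from CT; used by the partial-volume compensation
#'   [eq1_pve_correct()].
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask, label, kind = c("organ", "lesion"),
                        voxel_size_mm, ct_volume_ml = NULL) {
  kind <- match.arg(kind)
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a 3-D array", call. = FALSE)
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  if (!is.null(ct_volume_ml))
    stopifnot_scalar(ct_volume_ml, "ct_volume_ml", positive = TRUE)
  structure(list(mask = mask, label = as.character(label), kind = kind,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 ct_volume_ml = ct_volume_ml),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask '%s' (%s): %d voxels, %.4g mL%s\n",
              x$label, x$kind, sum(x$mask), mask_volume_ml(x),
              if (is.null(x$ct_volume_ml)) ""
              else sprintf(", CT volume %.4g mL", x$ct_volume_ml)))
  invisible(x)
}

#' Voxelised volume of a region mask (mL)
#' @param x A `region_mask`.
#' @return Voxel count times voxel volume, in mL.
#' @export
mask_volume_ml <- function(x) {
  stopifnot(inherits(x, "region_mask"))
  sum(x$mask) * voxel_volume_ml(x)
}

#' Per-cycle administration metadata
#'
#' @param cycle_id Cycle label.
#' @param injected_activity_MBq Administered activity (MBq), > 0.
#' @param injection_time Free-form timestamp of injection (optional).
#' @param patient_weight_kg Body weight (kg), > 0; required for SUV.
#' @return An object of class `cycle_metadata`.
#' @export
cycle_metadata <- function(cycle_id, injected_activity_MBq,
                           injection_time = NA_character_,
                           patient_weight_kg = NULL) {
  stopifnot_scalar(injected_activity_MBq, "injected_activity_MBq",
                   positive = TRUE)
  if (!is.null(patient_weight_kg))
    stopifnot_scalar(patient_weight_kg, "patient_weight_kg", positive = TRUE)
  structure(list(cycle_id = as.character(cycle_id),
                 injected_activity_MBq = injected_activity_MBq,
                 injection_time = injection_time,
                 patient_weight_kg = patient_weight_kg),
            class = "cycle_metadata")
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(if (inherits(a, "region_mask")) a$mask else a$values),
            dim(if (inherits(b, "region_mask")) b$mask else b$values)) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol)
}
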
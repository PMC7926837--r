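#' Standardized uptake value map
#'
#' Body-weight SUV: `SUV = C[kBq/mL] / (A_inj[MBq] / W[kg])`, with the
#' usual 1 mL = 1 g tissue convention making it dimensionless.  The map's
#' concentrations are held in Bq/mL internally and divided by 1000 here.
#'
#' @param map An [activity_map()] (Bq/mL).
#' @param meta A [cycle_metadata()]; `patient_weight_kg` must be present
#'   (SUV is undefined without it).
#' @return An object of class `suv_map`: dimensionless 3-D `values`, plus
#'   geometry, time and the normalisation inputs.
#' @examples
#' m <- activity_map(array(2500, c(4, 4, 4)), 2, time_h = 1)
#' s <- suv_map(m, cycle_metadata("c1", 200, patient_weight_kg = 80))
#' s$values[1]    # 2.5 kBq/mL / (200 MBq / 80 kg) = 1
#' @export
suv_map <- function(map, meta) {
  stopifnot(inherits(map, "activity_map"), inherits(meta, "cycle_metadata"))
  if (is.null(meta$patient_weight_kg))
    stop("patient weight is required: SUV is undefined without it",
         call. = FALSE)
  suv <- (map$values / 1000) /
    (meta$injected_activity_MBq / meta$patient_weight_kg)
  structure(list(values = suv, voxel_size_mm = map$voxel_size_mm,
                 time_h = map$time_h, cycle_id = meta$cycle_id,
                 injected_activity_MBq = meta$injected_activity_MBq,
                 patient_weight_kg = meta$patient_weight_kg),
            class = "suv_map")
}

#' @export
print.suv_map <- function(x, ...) {
  cat(sprintf("suv_map: t = %g h (%s), SUV range %.4g .. %.4g\n",
              x$time_h, x$cycle_id, min(x$values), max(x$values)))
  invisible(x)
}

#' SUVmax with adaptive isocontour VOI
#'
#' Finds the maximum SUV inside a seed region and grows the measurement
#' VOI automatically: the VOI is the connected component, among all voxels
#' of the map at or above `isocontour_fraction * SUVmax`, that contains
#' the maximum voxel (the standard "40% isocontour" adaptive VOI).
#'
#' @param suv An `suv_map`.
#' @param seed_region A [region_mask()]; the maximum is taken over it.
#' @param isocontour_fraction Fraction of SUVmax in (0, 1); default 0.40.
#' @param connectivity 26 (default) or 6.
#' @return List with `suvmax`, `voi` (a `region_mask` of the adapted VOI)
#'   and `voi_volume_ml`.
#' @export
suvmax_in_voi <- function(suv, seed_region, isocontour_fraction = 0.40,
                          connectivity = 26L) {
  stopifnot(inherits(suv, "suv_map"), inherits(seed_region, "region_mask"))
  if (!any(seed_region$mask)) stop("empty seed region", call. = FALSE)
  if (isocontour_fraction <= 0 || isocontour_fraction >= 1)
    stop("isocontour_fraction must be in (0, 1)", call. = FALSE)
  vals <- suv$values
  inmask <- which(seed_region$mask)
  imax <- inmask[which.max(vals[inmask])]
  suvmax <- vals[imax]
  thr_mask <- vals >= isocontour_fraction * suvmax
  lab <- label_components(thr_mask, connectivity)
  voi <- lab == lab[imax]
  voi_mask <- region_mask(voi, label = paste0(seed_region$label, "_voi"),
                          kind = seed_region$kind,
                          voxel_size_mm = suv$voxel_size_mm)
  list(suvmax = suvmax, voi = voi_mask,
       voi_volume_ml = mask_volume_ml(voi_mask))
}

#' Metabolic tumor volume
#'
#' Total volume of voxels with SUV strictly above a threshold (3.5 by
#' default, the usual whole-body tumor-burden setting), grouped into
#' connected components.  Regions of physiological uptake (kidneys,
#' bladder, salivary glands, gut) can be removed with an exclusion mask
#' before thresholding.
#'
#' @param suv An `suv_map`.
#' @param threshold SUV threshold, > 0; voxels must exceed it strictly
#'   (ties are excluded).
#' @param connectivity 26 (default) or 6.
#' @param exclude Optional logical array or `region_mask` of voxels to
#'   exclude (physiological uptake).
#' @return An object of class `mtv_result`: `threshold`,
#'   `total_volume_ml`, `n_components`, `component_volumes_ml`.
#' @export
mtv <- function(suv, threshold = 3.5, connectivity = 26L, exclude = NULL) {
  stopifnot(inherits(suv, "suv_map"))
  stopifnot_scalar(threshold, "threshold", positive = TRUE)
  fg <- suv$values > threshold
  if (!is.null(exclude)) {
    ex <- if (inherits(exclude, "region_mask")) exclude$mask else exclude
    fg <- fg & !ex
  }
  lab <- label_components(fg, connectivity)
  vox_ml <- voxel_volume_ml(suv$voxel_size_mm)
  comp <- if (max(lab) == 0L) numeric(0) else
    as.numeric(tabulate(lab[lab > 0L])) * vox_ml
  structure(list(threshold = threshold,
                 total_volume_ml = sum(comp),
                 n_components = length(comp),
                 component_volumes_ml = comp),
            class = "mtv_result")
}

#' @export
print.mtv_result <- function(x, ...) {
  cat(sprintf("MTV (SUV > %g): %.4g mL in %d component(s)\n",
              x$threshold, x$total_volume_ml, x$n_components))
  invisible(x)
}
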
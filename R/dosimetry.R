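# Voxel and organ absorbed dose from time-integrated activity.
# Tissue density is fixed at 1 g/mL throughout (no CT density map is in
# scope), so a voxel of volume v mL has mass v grams.

# Gy per (Bq.h/mL) under local energy deposition; independent of voxel
# size: 1 Bq.h = 3600 decays, energy/mL = 3600 * delta_J, mass/mL = 1e-3 kg.
tia_to_dose_Gy <- function(tia_Bqh_per_ml, constants = lu177_constants()) {
  tia_Bqh_per_ml * 3600 * constants$delta_np_J / 1e-3
}

new_dose_map <- function(values, voxel_size_mm, cycle_id = "cycle1",
                         method = "local_deposition") {
  structure(list(values = values,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L),
                 cycle_id = cycle_id, method = method),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("dose_map (%s): %dx%dx%d voxels, %.4g mm, max %.4g Gy\n",
              x$method, d[1], d[2], d[3], x$voxel_size_mm[1], max(x$values)))
  invisible(x)
}

#' Voxel-wise time-integrated activity map
#'
#' Integrates every voxel's own time-activity curve across the series
#' ("voxel-based" dosimetry proper).  The per-voxel mono-exponential fit
#' and the piecewise scheme are evaluated in closed form, vectorised over
#' the grid.  Voxels with any non-positive sample (background, noise
#' zeros) get TIA 0.  A faster per-region alternative — fit the
#' region-mean TAC once and assign it uniformly — is provided by
#' [tia_map_regional()].
#'
#' @param series List of [activity_map()] (or a `lu_phantom`).
#' @param scheme,constants,uptake,clamp_to_physical As in
#'   [time_integrated_activity()]; `single_time_point` requires a
#'   one-element series.
#' @return An object of class `tia_map`: `values` in Bq.h/mL on the same
#'   grid, with `voxel_size_mm`, `scheme`, and `cycle_id`.
#' @export
tia_map_voxelwise <- function(series,
                              scheme = c("monoexp_global", "piecewise_exp",
                                         "single_time_point"),
                              constants = lu177_constants(),
                              uptake = c("linear", "plateau"),
                              clamp_to_physical = TRUE) {
  scheme <- match.arg(scheme)
  uptake <- match.arg(uptake)
  if (inherits(series, "lu_phantom")) series <- series$maps
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  t <- vapply(series, `[[`, 0, "time_h")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing",
                              call. = FALSE)
  vs <- series[[1]]$voxel_size_mm
  d <- dim(series[[1]]$values)
  lam_phys <- constants$lambda_phys_per_h

  if (scheme == "single_time_point") {
    if (length(series) != 1L)
      stop("single_time_point scheme needs exactly one map", call. = FALSE)
    tia <- series[[1]]$values * 2 * t[1] / log(2)
    return(new_dose_like(tia, vs, series[[1]]$cycle_id, scheme))
  }

  if (length(series) < 2L) stop("need >= 2 time points", call. = FALSE)
  Y <- vapply(series, function(m) as.vector(m$values), numeric(prod(d)))
  ok <- rowSums(Y <= 0) == 0L
  tia <- numeric(prod(d))

  if (scheme == "monoexp_global") {
    if (any(ok)) {
      LY <- log(Y[ok, , drop = FALSE])
      tm <- mean(t); sxx <- sum((t - tm)^2)
      slope <- (LY %*% (t - tm)) / sxx
      a0 <- exp(rowMeans(LY) - slope * tm)
      lambda <- -slope
      if (clamp_to_physical) lambda <- pmax(lambda, lam_phys)
      v <- as.vector(a0 / lambda)
      v[as.vector(lambda) <= 0] <- 0   # divergent fits without clamp
      tia[ok] <- v
    }
  } else {  # piecewise_exp, vectorised
    if (any(ok)) {
      Yk <- Y[ok, , drop = FALSE]
      acc <- if (uptake == "linear") 0.5 * t[1] * Yk[, 1] else t[1] * Yk[, 1]
      n <- length(t)
      for (i in seq_len(n - 1L)) {
        dt <- t[i + 1L] - t[i]
        lam <- log(Yk[, i] / Yk[, i + 1L]) / dt
        seg <- ifelse(abs(lam) < 1e-12, Yk[, i] * dt,
                      (Yk[, i] - Yk[, i + 1L]) / lam)
        acc <- acc + seg
      }
      lam_tail <- log(Yk[, n - 1L] / Yk[, n]) / (t[n] - t[n - 1L])
      if (clamp_to_physical) lam_tail <- pmax(lam_tail, lam_phys)
      tail <- ifelse(lam_tail > 0, Yk[, n] / lam_tail, NA_real_)
      if (anyNA(tail))
        stop("non-positive tail decay constant with clamping disabled",
             call. = FALSE)
      acc <- acc + tail
      tia[ok] <- acc
    }
  }
  new_dose_like(array(tia, dim = d), vs, series[[1]]$cycle_id, scheme)
}

new_dose_like <- function(values, vs, cycle_id, scheme) {
  structure(list(values = values, voxel_size_mm = rep_len(vs, 3L),
                 cycle_id = cycle_id, scheme = scheme),
            class = "tia_map")
}

#' Per-region (uniform) time-integrated activity map
#'
#' Fits the region-mean TAC of each mask once and assigns the resulting
#' TIA concentration uniformly inside the mask — the fast mode used when
#' voxel-level heterogeneity is not needed.
#'
#' @inheritParams tia_map_voxelwise
#' @param masks Named list of [region_mask()] objects (non-overlapping).
#' @param scheme Passed to [time_integrated_activity()].
#' @return A `tia_map` (zero outside all masks).
#' @export
tia_map_regional <- function(series, masks,
                             scheme = "monoexp_global",
                             constants = lu177_constants(),
                             uptake = "linear",
                             clamp_to_physical = TRUE) {
  if (inherits(series, "lu_phantom")) series <- series$maps
  d <- dim(series[[1]]$values)
  out <- array(0, dim = d)
  for (m in masks) {
    tac <- extract_tac(series, m, statistic = "mean")
    tia <- time_integrated_activity(tac, scheme = scheme,
                                    constants = constants, uptake = uptake,
                                    clamp_to_physical = clamp_to_physical)
    out[m$mask] <- tia
  }
  new_dose_like(out, series[[1]]$voxel_size_mm, series[[1]]$cycle_id,
                paste0("regional_", scheme))
}

#' Voxel dose by local energy deposition
#'
#' Converts a TIA concentration map to absorbed dose assuming every
#' decay's non-penetrating energy is absorbed in the voxel where it
#' occurs: `D = TIA * 3600 * delta_np / (1e-3 kg/mL)` Gy, independent of
#' voxel size.  This is the appropriate engine for Lu-177, whose beta
#' range is below the 1.95 mm voxel scale.
#'
#' @param tia_map A `tia_map` (Bq.h/mL), or a plain array with
#'   `voxel_size_mm` given.
#' @param constants [lu177_constants()].
#' @param voxel_size_mm Needed for plain arrays.
#' @return A `dose_map` (Gy).
#' @export
dose_local_deposition <- function(tia_map, constants = lu177_constants(),
                                  voxel_size_mm = NULL) {
  if (inherits(tia_map, "tia_map")) {
    vals <- tia_map$values; vs <- tia_map$voxel_size_mm
    cyc <- tia_map$cycle_id
  } else {
    vals <- tia_map
    if (is.null(voxel_size_mm)) stop("voxel_size_mm required", call. = FALSE)
    vs <- voxel_size_mm; cyc <- "cycle1"
  }
  if (any(vals < 0)) stop("negative TIA", call. = FALSE)
  new_dose_map(tia_to_dose_Gy(vals, constants), vs, cyc, "local_deposition")
}

#' Voxel dose kernel
#'
#' An odd-sized 3-D table of absorbed dose (Gy) delivered to a voxel at
#' each offset per decay occurring in the source voxel — the voxel
#' S-value formalism.  [delta_kernel()] builds the single-voxel kernel
#' that reproduces local deposition exactly; [normalized_kernel()] scales
#' an arbitrary non-negative shape so that its total energy per decay
#' equals the nuclide's non-penetrating energy.
#'
#' @param values Odd-sized, non-negative 3-D array with positive centre,
#'   Gy per decay.
#' @param voxel_size_mm Voxel size the kernel was tabulated for.
#' @return An object of class `dose_kernel`.
#' @export
dose_kernel <- function(values, voxel_size_mm) {
  d <- dim(values)
  if (is.null(d) || length(d) != 3L)
    stop("kernel must be a 3-D array", call. = FALSE)
  if (any(d %% 2L == 0L))
    stop("kernel extents must be odd", call. = FALSE)
  if (any(values < 0)) stop("kernel values must be >= 0", call. = FALSE)
  ctr <- (d + 1L) %/% 2L
  if (values[ctr[1], ctr[2], ctr[3]] <= 0)
    stop("kernel centre must be > 0", call. = FALSE)
  structure(list(values = values,
                 voxel_size_mm = rep_len(as.numeric(voxel_size_mm), 3L)),
            class = "dose_kernel")
}

#' @rdname dose_kernel
#' @param constants [lu177_constants()].
#' @export
delta_kernel <- function(voxel_size_mm, constants = lu177_constants()) {
  mass_kg <- voxel_volume_ml(voxel_size_mm) * 1e-3
  k <- array(0, dim = c(1, 1, 1))
  k[1, 1, 1] <- constants$delta_np_J / mass_kg
  dose_kernel(k, voxel_size_mm)
}

#' @rdname dose_kernel
#' @param shape Non-negative 3-D array giving the relative spatial
#'   deposition pattern (odd extents, positive centre).
#' @export
normalized_kernel <- function(shape, voxel_size_mm,
                              constants = lu177_constants()) {
  mass_kg <- voxel_volume_ml(voxel_size_mm) * 1e-3
  dose_kernel(shape / sum(shape) * constants$delta_np_J / mass_kg,
              voxel_size_mm)
}

#' Read and write dose kernels as plain-text CSV
#'
#' The format is a commented header (`# dim:`, `# voxel_size_mm:`,
#' `# units: Gy_per_decay`) followed by `i,j,k,value` rows of the nonzero
#' elements, 1-based centre-origin-free indices.
#'
#' @param kernel A `dose_kernel`.
#' @param path File path.
#' @return `read_dose_kernel` returns a `dose_kernel`;
#'   `write_dose_kernel` returns `path` invisibly.
#' @export
write_dose_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "dose_kernel"))
  d <- dim(kernel$values)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# dim: %d %d %d", d[1], d[2], d[3]),
               sprintf("# voxel_size_mm: %g %g %g", kernel$voxel_size_mm[1],
                       kernel$voxel_size_mm[2], kernel$voxel_size_mm[3]),
               "# units: Gy_per_decay", "i,j,k,value"), con)
  nz <- which(kernel$values != 0)
  ind <- arrayInd(nz, d)
  utils::write.table(
    data.frame(i = ind[, 1], j = ind[, 2], k = ind[, 3],
               value = format(kernel$values[nz], digits = 17)),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dose_kernel
#' @export
read_dose_kernel <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  gethdr <- function(key) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (length(m) != 1L) stop("kernel file missing header '", key, "'",
                              call. = FALSE)
    scan(text = sub(paste0("^# ", key, ":"), "", m), quiet = TRUE)
  }
  d <- as.integer(gethdr("dim"))
  vs <- gethdr("voxel_size_mm")
  body <- utils::read.csv(text = lines[!grepl("^#", lines)])
  vals <- array(0, dim = d)
  vals[cbind(body$i, body$j, body$k)] <- body$value
  dose_kernel(vals, vs)
}

#' Voxel dose by kernel convolution
#'
#' Converts the TIA map to decays per voxel and convolves with the dose
#' kernel.  With [delta_kernel()] this reproduces [dose_local_deposition()]
#' exactly; with an extended kernel built by [normalized_kernel()] the
#' deposited energy spreads spatially while total energy is conserved
#' (exactly under periodic padding, and for sources whose kernel support
#' stays inside the grid under zero padding).
#'
#' @param tia_map A `tia_map` (Bq.h/mL).
#' @param kernel A `dose_kernel` tabulated for the map's voxel size.
#' @param periodic Use periodic padding (infinite-medium equilibrium).
#' @return A `dose_map` (Gy).
#' @export
dose_kernel_convolution <- function(tia_map, kernel, periodic = FALSE) {
  stopifnot(inherits(kernel, "dose_kernel"))
  if (inherits(tia_map, "tia_map")) {
    vals <- tia_map$values; vs <- tia_map$voxel_size_mm
    cyc <- tia_map$cycle_id
  } else stop("tia_map must be a 'tia_map'", call. = FALSE)
  if (any(abs(kernel$voxel_size_mm - vs) > 1e-6))
    stop("kernel voxel size does not match the map", call. = FALSE)
  if (any(vals < 0)) stop("negative TIA", call. = FALSE)
  decays <- vals * 3600 * voxel_volume_ml(vs)   # decays per voxel
  new_dose_map(convolve3d(decays, kernel$values, periodic = periodic),
               vs, cyc, "kernel")
}

#' Partial-volume compensation by the VOI-to-anatomical volume ratio
#'
#' Small structures lose apparent dose to the point-spread function; the
#' spill-out can be recovered by measuring the mean dose over a VOI large
#' enough to contain the smeared signal and rescaling by the ratio of VOI
#' volume to the anatomical (CT) volume of the structure:
#' `D = mean * voi_volume / ct_volume`.  Large organs are essentially
#' unaffected by this correction because their measurement VOI matches
#' the anatomical volume.
#'
#' @param mean_dose_Gy Mean dose over the measurement VOI (Gy), > 0.
#' @param voi_volume_ml Volume of the measurement VOI (mL), > 0.
#' @param ct_volume_ml Anatomical volume from CT (mL), > 0.
#' @return Compensated dose D (Gy).  A VOI smaller than the CT volume is
#'   allowed (the correction then reduces the dose) but triggers a
#'   warning, since it usually indicates a mis-segmented VOI.
#' @examples
#' eq1_pve_correct(2, voi_volume_ml = 4, ct_volume_ml = 2)  # 4 Gy
#' @export
eq1_pve_correct <- function(mean_dose_Gy, voi_volume_ml, ct_volume_ml) {
  stopifnot_scalar(mean_dose_Gy, "mean_dose_Gy", nonneg = TRUE)
  stopifnot_scalar(voi_volume_ml, "voi_volume_ml", positive = TRUE)
  stopifnot_scalar(ct_volume_ml, "ct_volume_ml", positive = TRUE)
  if (voi_volume_ml < ct_volume_ml)
    warning("VOI volume is smaller than the CT volume; ",
            "the compensation reduces the dose", call. = FALSE)
  mean_dose_Gy * voi_volume_ml / ct_volume_ml
}

#' MIRD-style organ self-dose
#'
#' Organ-level dose from cumulated activity, for the non-penetrating
#' emissions of Lu-177 with absorbed fraction 1:
#' `D = decays * delta_np / organ_mass`.
#'
#' @param total_decays Cumulated activity in the organ (decays), > 0.
#' @param organ_mass_kg Organ mass (kg), > 0.
#' @param constants [lu177_constants()].
#' @return Absorbed dose (Gy).
#' @export
mird_self_dose <- function(total_decays, organ_mass_kg,
                           constants = lu177_constants()) {
  stopifnot_scalar(total_decays, "total_decays", positive = TRUE)
  stopifnot_scalar(organ_mass_kg, "organ_mass_kg", positive = TRUE)
  total_decays * constants$delta_np_J / organ_mass_kg
}

#' Dose normalised by injected activity
#'
#' @param dose_Gy Absorbed dose (Gy).
#' @param injected_activity_MBq Administered activity (MBq), > 0.
#' @return Dose per injected activity (Gy/GBq).
#' @export
dose_per_injected <- function(dose_Gy, injected_activity_MBq) {
  stopifnot_scalar(injected_activity_MBq, "injected_activity_MBq",
                   positive = TRUE)
  dose_Gy / (injected_activity_MBq / 1000)
}

#' Per-region dose report
#'
#' Summarises a dose/TIA map pair over a set of measurement VOIs: mean
#' voxel dose, partial-volume-compensated dose (applied when the CT
#' volume is known and below `eq1_threshold_ml`, the regime where the
#' compensation is needed), MIRD self-dose from the cumulated activity in
#' the VOI attributed to the anatomical mass, and everything normalised
#' to Gy/GBq.
#'
#' @param tia_map A `tia_map` (Bq.h/mL).
#' @param regions Named list of [region_mask()] measurement VOIs (with
#'   `ct_volume_ml` set where available).
#' @param injected_activity_MBq Administered activity for the Gy/GBq
#'   normalisation.
#' @param constants [lu177_constants()].
#' @param eq1_threshold_ml Apply the volume-ratio compensation only when
#'   the CT volume is below this (default 25 mL: small organs and
#'   lesions; large organs do not need it).
#' @param dose_map Optional precomputed `dose_map`; defaults to local
#'   deposition from `tia_map`.
#' @return A data frame of class `organ_dose_report` with one row per
#'   region: `mean_dose_Gy`, `corrected_dose_Gy` (NA when not applied),
#'   `mird_dose_Gy`, `dose_Gy` (corrected where applied, mean otherwise),
#'   `dose_Gy_per_GBq`, `voi_volume_ml`, `ct_volume_ml`.
#' @export
organ_dose_report <- function(tia_map, regions, injected_activity_MBq,
                              constants = lu177_constants(),
                              eq1_threshold_ml = 25, dose_map = NULL) {
  if (is.null(dose_map)) dose_map <- dose_local_deposition(tia_map, constants)
  vs <- tia_map$voxel_size_mm
  vox_ml <- voxel_volume_ml(vs)
  rows <- lapply(regions, function(rg) {
    stopifnot(inherits(rg, "region_mask"))
    mean_dose <- mean(dose_map$values[rg$mask])
    voi_ml <- mask_volume_ml(rg)
    ct_ml <- rg$ct_volume_ml
    decays <- sum(tia_map$values[rg$mask]) * 3600 * vox_ml
    mass_kg <- (if (!is.null(ct_ml)) ct_ml else voi_ml) * 1e-3
    mird <- if (decays > 0) mird_self_dose(decays, mass_kg, constants) else 0
    corrected <- NA_real_
    if (!is.null(ct_ml) && ct_ml < eq1_threshold_ml)
      corrected <- eq1_pve_correct(mean_dose, voi_ml, ct_ml)
    dose <- if (is.na(corrected)) mean_dose else corrected
    data.frame(region = rg$label, kind = rg$kind,
               mean_dose_Gy = mean_dose, corrected_dose_Gy = corrected,
               mird_dose_Gy = mird, dose_Gy = dose,
               dose_Gy_per_GBq = dose_per_injected(dose,
                                                   injected_activity_MBq),
               voi_volume_ml = voi_ml,
               ct_volume_ml = if (is.null(ct_ml)) NA_real_ else ct_ml,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("organ_dose_report", "data.frame")
  out
}
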
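# NIfTI volume I/O and tabular report writing.  Masks and maps must share
# the exact grid: no resampling or registration is performed here (spatial
# registration error between time points is a known, unsolved error source
# in serial post-therapy SPECT, and silently resampling would hide it).

#' Write an activity map or mask as NIfTI
#'
#' Values are stored as float32 with the voxel size in the NIfTI pixdim.
#' Acquisition time and cycle are not representable in the NIfTI header
#' and are supplied externally on read (see [read_activity_series()]).
#'
#' @param x An `activity_map` or `region_mask`.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  vals <- if (inherits(x, "region_mask")) x$mask + 0 else x$values
  img <- RNifti::asNifti(vals)
  RNifti::pixdim(img) <- x$voxel_size_mm
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  list(values = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = as.numeric(RNifti::pixdim(img))[1:3])
}

#' Read a multi-time-point activity series
#'
#' Loads one NIfTI volume per acquisition time, validates that all share
#' the same grid shape and voxel size, and returns an ordered list of
#' [activity_map()] objects.  Concentrations stored in kBq/mL (the usual
#' quantitative SPECT export unit) are rescaled to Bq/mL.
#'
#' @param paths Character vector of NIfTI files, one per time point.
#' @param times_h Acquisition times in hours post injection, strictly
#'   increasing, same length as `paths`.
#' @param units Unit of the stored voxel values: `"Bq/mL"` or `"kBq/mL"`.
#' @param cycle_id Cycle label attached to every map.
#' @param clamp_negative Passed to [activity_map()].
#' @return List of `activity_map`, ordered by time.
#' @export
read_activity_series <- function(paths, times_h, units = c("Bq/mL", "kBq/mL"),
                                 cycle_id = "cycle1", clamp_negative = FALSE) {
  units <- match.arg(units)
  if (length(paths) != length(times_h) || length(paths) == 0L)
    stop("'paths' and 'times_h' must have equal, nonzero length",
         call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("acquisition times must be strictly increasing", call. = FALSE)
  scale <- if (units == "kBq/mL") 1000 else 1
  vols <- lapply(paths, read_volume)
  for (i in seq_along(vols)[-1]) {
    if (!identical(dim(vols[[i]]$values), dim(vols[[1]]$values)))
      stop(sprintf("grid shape of '%s' differs from '%s'",
                   paths[i], paths[1]), call. = FALSE)
    if (any(abs(vols[[i]]$voxel_size_mm - vols[[1]]$voxel_size_mm) > 1e-4))
      stop(sprintf("voxel size of '%s' differs from '%s'",
                   paths[i], paths[1]), call. = FALSE)
  }
  Map(function(v, t) activity_map(v$values * scale, v$voxel_size_mm, t,
                                  cycle_id = cycle_id,
                                  clamp_negative = clamp_negative),
      vols, as.list(as.numeric(times_h)))
}

#' Read a region mask from NIfTI
#'
#' Voxels with value > 0.5 are foreground.
#'
#' @inheritParams region_mask
#' @param path NIfTI file.
#' @return A `region_mask`.
#' @export
read_region_mask <- function(path, label, kind = c("organ", "lesion"),
                             ct_volume_ml = NULL) {
  v <- read_volume(path)
  region_mask(v$values > 0.5, label = label, kind = kind,
              voxel_size_mm = v$voxel_size_mm, ct_volume_ml = ct_volume_ml)
}

#' Write result tables and a run manifest
#'
#' Writes each table in `tables` as `<name>.csv` under `outdir` plus a
#' `manifest.json` recording the seed, package version and an MD5 hash of
#' the configuration, so a run can be identified and reproduced.
#' Missing values are written as the literal marker `"N/A"`, matching the
#' convention of the clinical trajectory tables this package models.
#'
#' @param tables Named list of data frames.
#' @param outdir Output directory (created if needed).
#' @param config Optional configuration list stored (hashed) in the manifest.
#' @param seed Optional integer seed recorded in the manifest.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, outdir, config = NULL, seed = NULL) {
  if (!is.list(tables) || (length(tables) > 0 && is.null(names(tables))))
    stop("'tables' must be a named list of data frames", call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE, na = "N/A")
    files <- c(files, f)
  }
  manifest <- list(
    package = "lutracer",
    version = as.character(utils::packageVersion("lutracer")),
    seed = seed,
    config_md5 = if (is.null(config)) NA_character_ else config_hash(config),
    tables = as.list(names(tables))
  )
  mf <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(c(files, mf))
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
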
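#' Physical constants for Lu-177 dosimetry
#'
#' Bundles the two nuclide-level quantities the dose and kinetics code
#' needs: the physical decay constant of \eqn{^{177}}Lu and the mean
#' non-penetrating (beta + conversion/Auger electron) energy emitted per
#' decay.  Both are configurable; the defaults are a physical half-life of
#' 6.647 days and 147.9 keV per decay.
#'
#' Electron ranges of the Lu-177 beta spectrum are below ~2 mm in soft
#' tissue, i.e. below the 1.95 mm voxel size used throughout, which is why
#' local energy deposition is a defensible voxel dose engine for this
#' nuclide (see [dose_local_deposition()]).
#'
#' @param half_life_days Physical half-life in days.
#' @param delta_np_keV Mean non-penetrating energy per decay (keV).
#'
#' @return An object of class `lu_constants`: a list with elements
#'   `lambda_phys_per_h` (1/h), `half_life_h`, `delta_np_keV` and
#'   `delta_np_J` (Joule per decay).
#'
#' @examples
#' k <- lu177_constants()
#' k$half_life_h             # 159.528
#' log(2) / k$lambda_phys_per_h
#' @export
lu177_constants <- function(half_life_days = 6.647, delta_np_keV = 147.9) {
  stopifnot_scalar(half_life_days, "half_life_days", positive = TRUE)
  stopifnot_scalar(delta_np_keV, "delta_np_keV", positive = TRUE)
  half_life_h <- half_life_days * 24
  structure(list(
    half_life_h = half_life_h,
    lambda_phys_per_h = log(2) / half_life_h,
    delta_np_keV = delta_np_keV,
    delta_np_J = delta_np_keV * 1e3 * 1.602176634e-19
  ), class = "lu_constants")
}

#' @export
print.lu_constants <- function(x, ...) {
  cat("Lu-177 constants\n")
  cat(sprintf("  physical half-life : %.3f h (%.3f d)\n",
              x$half_life_h, x$half_life_h / 24))
  cat(sprintf("  lambda_phys        : %.6g 1/h\n", x$lambda_phys_per_h))
  cat(sprintf("  mean non-penetrating energy: %.1f keV/decay (%.4g J)\n",
              x$delta_np_keV, x$delta_np_J))
  invisible(x)
}
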
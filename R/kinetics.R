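#' Extract a region time-activity curve
#'
#' Reduces each activity map of a series to one statistic over the voxels
#' of a region mask: the mean (used for dose VOIs) or the maximum (the
#' SPECT SUVmax-style statistic used for lesion trajectories).
#'
#' @param series List of [activity_map()] (or a `lu_phantom`, whose maps
#'   are used).
#' @param mask A [region_mask()] on the same grid.
#' @param statistic `"mean"` or `"max"`.
#' @return An object of class `tac`: a data frame with columns `time_h`
#'   and `conc_Bq_per_ml`, with the region label and statistic as
#'   attributes.
#' @export
extract_tac <- function(series, mask, statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  if (inherits(series, "lu_phantom")) series <- series$maps
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  stopifnot(inherits(mask, "region_mask"))
  if (!any(mask$mask)) stop("empty region mask", call. = FALSE)
  fun <- if (statistic == "mean") mean else max
  samples <- vapply(series, function(m) {
    if (!same_grid(m, mask))
      stop("mask and activity map are not on the same grid", call. = FALSE)
    fun(m$values[mask$mask])
  }, 0)
  times <- vapply(series, `[[`, 0, "time_h")
  if (any(diff(times) <= 0))
    stop("series times must be strictly increasing", call. = FALSE)
  new_tac(times, samples, region = mask$label, statistic = statistic)
}

#' Construct a time-activity curve from raw samples
#'
#' @param time_h Sample times (hours), strictly increasing.
#' @param conc_Bq_per_ml Concentrations (Bq/mL), >= 0.
#' @param region Region label.
#' @param statistic Which voxel statistic the samples represent.
#' @return A `tac` object.
#' @export
new_tac <- function(time_h, conc_Bq_per_ml, region = "region",
                    statistic = "mean") {
  if (length(time_h) != length(conc_Bq_per_ml) || length(time_h) < 1L)
    stop("need equal-length, nonempty time and concentration vectors",
         call. = FALSE)
  if (any(diff(time_h) <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(conc_Bq_per_ml < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  structure(data.frame(time_h = as.numeric(time_h),
                       conc_Bq_per_ml = as.numeric(conc_Bq_per_ml)),
            region = region, statistic = statistic,
            class = c("tac", "data.frame"))
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("time-activity curve, region '%s' (%s of voxels), %d sample(s)\n",
              attr(x, "region"), attr(x, "statistic"), nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tac <- function(x, log = "y", ...) {
  graphics::plot(x$time_h, x$conc_Bq_per_ml, log = log,
                 xlab = "time post injection (h)",
                 ylab = "activity concentration (Bq/mL)",
                 main = attr(x, "region"), type = "b", ...)
  invisible(x)
}

#' Fit a mono-exponential washout model to a TAC
#'
#' Least-squares straight-line fit of `log(concentration)` against time:
#' `A0 = exp(intercept)`, `lambda_eff = -slope`.  With two to three
#' samples per curve (the practical reality of post-therapy imaging) the
#' log-domain linear fit is the only model the data can support; it is
#' exact for two samples.  All concentrations must be strictly positive
#' (callers dealing with resolved lesions must pre-filter or use the
#' piecewise integration scheme).
#'
#' A perfectly flat curve fits with `lambda_eff = 0`; such a fit is
#' flagged `degenerate` and its half-life reported as infinite.
#'
#' @param tac A [new_tac()]/[extract_tac()] object, or a data frame with
#'   columns `time_h` and `conc_Bq_per_ml`; >= 2 samples.
#' @return An object of class `monoexp_fit` with components
#'   `A0_Bq_per_ml`, `lambda_per_h`, `half_life_h`, `r_squared` (on the
#'   log scale), `degenerate`, and the fitted samples.
#' @examples
#' fit <- fit_monoexp(new_tac(c(4, 24), c(8, 4)))
#' fit$half_life_h   # exactly 20
#' coef(fit)
#' @export
fit_monoexp <- function(tac) {
  t <- tac$time_h; y <- tac$conc_Bq_per_ml
  if (length(t) < 2L) stop("need >= 2 samples to fit", call. = FALSE)
  if (any(y <= 0))
    stop("mono-exponential fit requires strictly positive concentrations",
         call. = FALSE)
  ly <- log(y)
  tm <- mean(t); lym <- mean(ly)
  sxx <- sum((t - tm)^2)
  slope <- sum((t - tm) * (ly - lym)) / sxx
  intercept <- lym - slope * tm
  fitted <- intercept + slope * t
  ss_res <- sum((ly - fitted)^2)
  ss_tot <- sum((ly - lym)^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  lambda <- -slope
  structure(list(
    A0_Bq_per_ml = exp(intercept),
    lambda_per_h = lambda,
    half_life_h = if (lambda > 0) log(2) / lambda else Inf,
    r_squared = r2,
    degenerate = lambda <= 0,
    samples = data.frame(time_h = t, conc_Bq_per_ml = y),
    region = attr(tac, "region") %||% "region"
  ), class = "monoexp_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.monoexp_fit <- function(x, ...) {
  cat(sprintf("mono-exponential fit, region '%s' (%d samples)\n",
              x$region, nrow(x$samples)))
  cat(sprintf("  A0        = %.6g Bq/mL\n", x$A0_Bq_per_ml))
  cat(sprintf("  lambda_eff= %.6g 1/h%s\n", x$lambda_per_h,
              if (x$degenerate) "  [degenerate: no net clearance]" else ""))
  cat(sprintf("  T1/2_eff  = %.6g h\n", x$half_life_h))
  cat(sprintf("  R^2 (log) = %.4f\n", x$r_squared))
  invisible(x)
}

#' @export
coef.monoexp_fit <- function(object, ...) {
  c(A0_Bq_per_ml = object$A0_Bq_per_ml,
    lambda_per_h = object$lambda_per_h)
}

#' @export
predict.monoexp_fit <- function(object, time_h = object$samples$time_h, ...) {
  object$A0_Bq_per_ml * exp(-object$lambda_per_h * time_h)
}

#' @export
summary.monoexp_fit <- function(object, ...) {
  out <- c(coef(object),
           half_life_h = object$half_life_h,
           r_squared = object$r_squared,
           tia_Bqh_per_ml = if (object$lambda_per_h > 0)
             object$A0_Bq_per_ml / object$lambda_per_h else Inf)
  class(out) <- "summary.monoexp_fit"
  out
}

#' @export
print.summary.monoexp_fit <- function(x, ...) {
  print(unclass(x)); invisible(x)
}

#' @export
plot.monoexp_fit <- function(x, ...) {
  graphics::plot(x$samples$time_h, x$samples$conc_Bq_per_ml, log = "y",
                 xlab = "time post injection (h)",
                 ylab = "activity concentration (Bq/mL)",
                 main = sprintf("%s: T1/2_eff = %.3g h", x$region,
                                x$half_life_h), ...)
  tt <- seq(min(x$samples$time_h), max(x$samples$time_h), length.out = 100)
  graphics::lines(tt, predict(x, tt))
  invisible(x)
}

#' Effective half-life from a fit or decay constant
#'
#' @param fit A `monoexp_fit`, or a positive decay constant in 1/h.
#' @return `log(2) / lambda_eff`, in hours.
#' @export
effective_half_life <- function(fit) {
  lambda <- if (inherits(fit, "monoexp_fit")) fit$lambda_per_h else fit
  stopifnot_scalar(lambda, "lambda")
  if (lambda <= 0) stop("lambda_eff must be > 0", call. = FALSE)
  log(2) / lambda
}

#' Time-integrated activity concentration of a TAC
#'
#' Integrates a region (or voxel) time-activity curve from injection to
#' infinity, returning the TIA concentration in Bq.h/mL.  Three schemes:
#'
#' \describe{
#'   \item{`piecewise_exp`}{Linear rise from zero at t = 0 to the first
#'     sample (no data exist before the first scan; a linear rise is the
#'     conservative standard assumption, switchable to a plateau via
#'     `uptake`), exact exponential interpolation between consecutive
#'     samples, and a mono-exponential tail beyond the last sample with
#'     the decay constant of the last segment.  An exact-zero final sample
#'     truncates the integral at that time.}
#'   \item{`monoexp_global`}{`A0 / lambda` from a single [fit_monoexp()]
#'     over all samples.}
#'   \item{`single_time_point`}{From one sample `(T, A)`:
#'     `TIA = A * 2T / log(2)`, the simplified one-scan estimator; it is
#'     exact when `T` equals the effective half-life, which motivates
#'     scanning near 4 days for Lu-177.}
#' }
#'
#' Clearance cannot be slower than physical decay, so extrapolated decay
#' constants (tail or global) are clamped below by the Lu-177 physical
#' decay constant when `clamp_to_physical = TRUE` (the default).  With the
#' clamp disabled a non-positive extrapolation constant is an error: the
#' integral would diverge.
#'
#' @param tac A `tac` object (see [new_tac()]).
#' @param scheme Integration scheme, see Details.
#' @param constants [lu177_constants()] supplying the physical decay
#'   constant used by the clamp.
#' @param uptake Shape of the unobserved 0 -> first-sample segment for the
#'   piecewise scheme: `"linear"` rise from zero (default) or
#'   `"plateau"` at the first sample's value (instantaneous uptake).
#' @param clamp_to_physical Clamp extrapolated decay constants to be >=
#'   the physical decay constant.
#' @return TIA concentration (Bq.h/mL), a single number.
#' @examples
#' tac <- new_tac(c(4, 24, 48), 1000 * exp(-log(2) / 24 * c(4, 24, 48)))
#' time_integrated_activity(tac, "monoexp_global")   # 1000 * 24 / log(2)
#' @export
time_integrated_activity <- function(tac,
                                     scheme = c("piecewise_exp",
                                                "monoexp_global",
                                                "single_time_point"),
                                     constants = lu177_constants(),
                                     uptake = c("linear", "plateau"),
                                     clamp_to_physical = TRUE) {
  scheme <- match.arg(scheme)
  uptake <- match.arg(uptake)
  t <- tac$time_h; y <- tac$conc_Bq_per_ml
  lam_phys <- constants$lambda_phys_per_h

  clamp <- function(lambda, what) {
    if (clamp_to_physical) return(max(lambda, lam_phys))
    if (lambda <= 0)
      stop(sprintf("%s decay constant is <= 0 and clamping is disabled: ",
                   what), "integral diverges", call. = FALSE)
    lambda
  }

  if (scheme == "monoexp_global") {
    fit <- fit_monoexp(tac)
    lambda <- clamp(fit$lambda_per_h, "global")
    return(fit$A0_Bq_per_ml / lambda)
  }

  if (scheme == "single_time_point") {
    if (length(t) != 1L)
      stop("single_time_point scheme needs exactly one sample", call. = FALSE)
    return(y * 2 * t / log(2))
  }

  # piecewise_exp
  if (length(t) < 2L)
    stop("piecewise_exp scheme needs >= 2 samples", call. = FALSE)
  if (any(y[-length(y)] <= 0) || y[length(y)] < 0)
    stop("piecewise_exp requires positive samples (a zero is allowed only ",
         "as the final sample)", call. = FALSE)
  tia <- if (uptake == "linear") 0.5 * t[1] * y[1] else t[1] * y[1]
  for (i in seq_len(length(t) - 1L)) {
    dt <- t[i + 1L] - t[i]
    if (y[i + 1L] == 0) {            # truncation: lesion gone by t[i+1]
      # integrate the last positive segment as linear down to zero
      tia <- tia + 0.5 * dt * y[i]
      return(tia)
    }
    lam <- log(y[i] / y[i + 1L]) / dt
    tia <- tia + if (abs(lam) < 1e-12) y[i] * dt else (y[i] - y[i + 1L]) / lam
  }
  n <- length(t)
  lam_tail <- log(y[n - 1L] / y[n]) / (t[n] - t[n - 1L])
  lam_tail <- clamp(lam_tail, "tail")
  tia + y[n] / lam_tail
}
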
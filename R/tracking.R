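# Multi-cycle per-lesion trajectories: dose per injected activity,
# SUVmax at each imaging time point, lesion volume and status, plus the
# cross-cycle summaries (group means, fold changes, washout-slope
# comparison).
#
# The package ships a transcription of a published single-patient
# Lu-177 PSMA I&T case series (four therapy cycles, six target lesions:
# one local lymph node LLN, two distant lymph nodes DLN1-2, three bone
# lesions B1-3) under inst/extdata/case_*.csv; see read_case_tables().
# Per-cycle administered activities were not published for that series,
# only the mean (7395 MBq), so all Gy conversions use the mean and every
# report says so.

#' Mean administered activity of the bundled case series (GBq)
#' @return 7.395 (GBq); the published per-cycle range is 6.934-7.722 GBq.
#' @export
case_mean_injected_GBq <- function() 7.395

#' A per-lesion multi-cycle record
#'
#' @param id Lesion label (unique within a record set).
#' @param type `"local_LN"`, `"distant_LN"` or `"bone"`.
#' @param cycles Data frame with columns `cycle` (integer), `status`
#'   (`"active"`, `"resolved"`, `"not_measurable"`), `volume_ml`,
#'   `dose_Gy_per_GBq` (NA where not measurable).
#' @param suv Data frame with columns `cycle`, `time_h`, `suvmax` (NA
#'   allowed).  A cycle whose status is `resolved` must have no SUVmax
#'   measurements (the lesion is gone; its automated dose-VOI read-out
#'   may still exist and is kept as transcribed).
#' @return An object of class `lesion_record`.
#' @export
lesion_record <- function(id, type = c("local_LN", "distant_LN", "bone"),
                          cycles, suv) {
  type <- match.arg(type)
  need_c <- c("cycle", "status", "volume_ml", "dose_Gy_per_GBq")
  if (!all(need_c %in% names(cycles)))
    stop("'cycles' needs columns: ", paste(need_c, collapse = ", "),
         call. = FALSE)
  need_s <- c("cycle", "time_h", "suvmax")
  if (!all(need_s %in% names(suv)))
    stop("'suv' needs columns: ", paste(need_s, collapse = ", "),
         call. = FALSE)
  if (!all(cycles$status %in% c("active", "resolved", "not_measurable")))
    stop("unknown lesion status", call. = FALSE)
  if (any(cycles$volume_ml < 0, na.rm = TRUE))
    stop("volumes must be >= 0", call. = FALSE)
  resolved <- cycles$cycle[cycles$status == "resolved"]
  if (any(!is.na(suv$suvmax[suv$cycle %in% resolved])))
    stop(sprintf("lesion '%s': SUVmax present in a resolved cycle", id),
         call. = FALSE)
  structure(list(id = as.character(id), type = type,
                 cycles = cycles[order(cycles$cycle), , drop = FALSE],
                 suv = suv[order(suv$cycle, suv$time_h), , drop = FALSE]),
            class = "lesion_record")
}

#' @export
print.lesion_record <- function(x, ...) {
  cat(sprintf("lesion_record '%s' (%s), %d cycle(s)\n", x$id, x$type,
              nrow(x$cycles)))
  print(x$cycles, row.names = FALSE)
  invisible(x)
}

#' Long trajectory table from lesion records
#'
#' One row per defined measurement: columns `lesion`, `type`, `cycle`,
#' `time_h` (NA for cycle-level measures), `measure` (`volume_ml`,
#' `dose_Gy_per_GBq`, `suvmax`), `value` (NA carries the explicit
#' not-available marker when written to CSV) and `status`.
#'
#' @param records List of [lesion_record()] with unique ids.
#' @return Data frame of class `trajectory_table`.
#' @export
build_trajectories <- function(records) {
  if (length(records) == 0L) {
    out <- data.frame(lesion = character(0), type = character(0),
                      cycle = integer(0), time_h = numeric(0),
                      measure = character(0), value = numeric(0),
                      status = character(0), stringsAsFactors = FALSE)
    class(out) <- c("trajectory_table", "data.frame")
    return(out)
  }
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("lesion ids must be unique", call. = FALSE)
  rows <- lapply(records, function(r) {
    st <- function(cy) r$cycles$status[match(cy, r$cycles$cycle)]
    cyc <- r$cycles
    base <- rbind(
      data.frame(lesion = r$id, type = r$type, cycle = cyc$cycle,
                 time_h = NA_real_, measure = "volume_ml",
                 value = cyc$volume_ml, status = cyc$status,
                 stringsAsFactors = FALSE),
      data.frame(lesion = r$id, type = r$type, cycle = cyc$cycle,
                 time_h = NA_real_, measure = "dose_Gy_per_GBq",
                 value = cyc$dose_Gy_per_GBq, status = cyc$status,
                 stringsAsFactors = FALSE))
    suv <- data.frame(lesion = r$id, type = r$type, cycle = r$suv$cycle,
                      time_h = r$suv$time_h, measure = "suvmax",
                      value = r$suv$suvmax, status = st(r$suv$cycle),
                      stringsAsFactors = FALSE)
    rbind(base, suv)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  key <- paste(out$lesion, out$cycle, out$measure, out$time_h)
  if (anyDuplicated(key))
    stop("duplicate (lesion, cycle, time point, measure) entry",
         call. = FALSE)
  class(out) <- c("trajectory_table", "data.frame")
  out
}

#' Rebuild lesion records from a trajectory table
#'
#' Inverse of [build_trajectories()]; `build_trajectories(
#' trajectories_to_records(tab))` reproduces `tab` up to row order.
#'
#' @param tab A `trajectory_table`.
#' @return List of [lesion_record()].
#' @export
trajectories_to_records <- function(tab) {
  lapply(unique(tab$lesion), function(id) {
    sub <- tab[tab$lesion == id, , drop = FALSE]
    vol <- sub[sub$measure == "volume_ml", ]
    dose <- sub[sub$measure == "dose_Gy_per_GBq", ]
    suv <- sub[sub$measure == "suvmax", ]
    cycles <- data.frame(cycle = vol$cycle, status = vol$status,
                         volume_ml = vol$value,
                         dose_Gy_per_GBq = dose$value[match(vol$cycle,
                                                            dose$cycle)],
                         stringsAsFactors = FALSE)
    lesion_record(id, sub$type[1], cycles,
                  data.frame(cycle = suv$cycle, time_h = suv$time_h,
                             suvmax = suv$value, stringsAsFactors = FALSE))
  })
}

#' Read the bundled case-series tables
#'
#' Transcriptions of the published four-cycle, six-lesion case series:
#' per-lesion absorbed dose (Gy/GBq), per-lesion volume and SPECT SUVmax
#' at 4/24/48 h, per-organ doses (voxel-based and MIRD, Gy/GBq) and the
#' PSA / tumor-burden biomarker series.  Missing measurements are the
#' literal marker `N/A` in the files and become `NA` here.
#'
#' @return List of data frames: `lesion_doses` (wide: cycle x lesion),
#'   `lesion_suv` (long), `organ_doses`, `biomarkers`.
#' @export
read_case_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "lutracer",
                               mustWork = TRUE)
  rd <- function(f) utils::read.csv(p(f), na.strings = "N/A",
                                    stringsAsFactors = FALSE)
  list(lesion_doses = rd("case_lesion_doses_gy_per_gbq.csv"),
       lesion_suv = rd("case_lesion_suv_volumes.csv"),
       organ_doses = rd("case_organ_doses_gy_per_gbq.csv"),
       biomarkers = rd("case_biomarkers.csv"))
}

#' Lesion records of the bundled case series
#'
#' Assembles [lesion_record()] objects from [read_case_tables()].
#' Statuses: the local lymph node disappeared after two cycles and is
#' `resolved` from cycle 3; the bone lesions fell below detectability on
#' SPECT in later cycles and are `not_measurable` at cycle 4 (B2/B3
#' additionally have no SUVmax at cycle 3 while their dose VOIs were
#' still read out); everything else is `active`.
#'
#' @return Named list of six `lesion_record` objects
#'   (LLN, DLN1, DLN2, B1, B2, B3).
#' @export
case_lesion_records <- function() {
  tb <- read_case_tables()
  types <- c(LLN = "local_LN", DLN1 = "distant_LN", DLN2 = "distant_LN",
             B1 = "bone", B2 = "bone", B3 = "bone")
  status_of <- function(lesion, cycle) {
    if (lesion == "LLN" && cycle >= 3) return("resolved")
    if (lesion %in% c("B1", "B2", "B3") && cycle >= 4)
      return("not_measurable")
    "active"
  }
  recs <- lapply(names(types), function(id) {
    sv <- tb$lesion_suv[tb$lesion_suv$lesion == id, ]
    cycles <- data.frame(
      cycle = sv$cycle,
      status = vapply(sv$cycle, function(cy) status_of(id, cy), ""),
      volume_ml = sv$volume_ml,
      dose_Gy_per_GBq = tb$lesion_doses[[id]][match(sv$cycle,
                                                    tb$lesion_doses$cycle)],
      stringsAsFactors = FALSE)
    suv <- data.frame(
      cycle = rep(sv$cycle, 3L),
      time_h = rep(c(4, 24, 48), each = nrow(sv)),
      suvmax = c(sv$suvmax_4h, sv$suvmax_24h, sv$suvmax_48h),
      stringsAsFactors = FALSE)
    lesion_record(id, types[[id]], cycles, suv)
  })
  names(recs) <- names(types)
  recs
}

#' Mean absorbed dose of a lesion group at one cycle
#'
#' Mean of the per-lesion Gy/GBq values of all *active* lesions of the
#' given type at the given cycle, converted to Gy with the injected
#' activity.  Resolved or not-measurable lesions are excluded and the
#' exclusion reported via `message()`.
#'
#' @param records List of [lesion_record()].
#' @param lesion_type `"local_LN"`, `"distant_LN"` or `"bone"`.
#' @param cycle Cycle number.
#' @param injected_GBq Administered activity (GBq).
#' @return Mean absorbed dose (Gy).
#' @examples
#' \dontrun{
#' group_mean_dose(case_lesion_records(), "bone", 1,
#'                 case_mean_injected_GBq())   # ~38.3 Gy
#' }
#' @export
group_mean_dose <- function(records, lesion_type, cycle, injected_GBq) {
  stopifnot_scalar(injected_GBq, "injected_GBq", positive = TRUE)
  doses <- c(); excluded <- character(0)
  for (r in records) {
    if (r$type != lesion_type) next
    i <- match(cycle, r$cycles$cycle)
    if (is.na(i)) next
    d <- r$cycles$dose_Gy_per_GBq[i]
    if (r$cycles$status[i] != "active" || is.na(d)) {
      excluded <- c(excluded,
                    sprintf("%s (%s)", r$id, r$cycles$status[i]))
      next
    }
    doses <- c(doses, d)
  }
  if (length(excluded) > 0L)
    message("group_mean_dose: excluded ", paste(excluded, collapse = ", "),
            " at cycle ", cycle)
  if (length(doses) == 0L)
    stop(sprintf("no active '%s' lesion with a dose at cycle %s",
                 lesion_type, cycle), call. = FALSE)
  mean(doses) * injected_GBq
}

#' Fold change of a lesion measure between two cycles
#'
#' `value(cycle_a) / value(cycle_b)`.  A missing value at either cycle is
#' an explicit error naming the lesion, cycle and measure — never a
#' silent NaN.
#'
#' @param records List of [lesion_record()].
#' @param lesion Lesion id.
#' @param measure `"dose_Gy_per_GBq"`, `"volume_ml"` or `"suvmax"`.
#' @param cycle_a,cycle_b Cycle numbers (numerator, denominator).
#' @param time_h Imaging time point for `measure = "suvmax"` (default 24).
#' @return The ratio.
#' @export
fold_change <- function(records, lesion,
                        measure = c("dose_Gy_per_GBq", "volume_ml",
                                    "suvmax"),
                        cycle_a, cycle_b, time_h = 24) {
  measure <- match.arg(measure)
  ids <- vapply(records, `[[`, "", "id")
  ri <- match(lesion, ids)
  if (is.na(ri)) stop("unknown lesion '", lesion, "'", call. = FALSE)
  r <- records[[ri]]
  getval <- function(cy) {
    if (measure == "suvmax") {
      i <- which(r$suv$cycle == cy & r$suv$time_h == time_h)
      v <- if (length(i) == 1L) r$suv$suvmax[i] else NA_real_
    } else {
      i <- match(cy, r$cycles$cycle)
      v <- if (!is.na(i)) r$cycles[[measure]][i] else NA_real_
    }
    if (is.na(v)) {
      st <- r$cycles$status[match(cy, r$cycles$cycle)]
      stop(sprintf(
        "lesion '%s': %s not available at cycle %s (status: %s)",
        lesion, measure, cy, if (is.na(st)) "absent" else st),
        call. = FALSE)
    }
    v
  }
  getval(cycle_a) / getval(cycle_b)
}

#' Compare lesion washout slopes at one cycle
#'
#' Per-lesion log-linear slope of SUVmax against time (1/h) at the given
#' cycle, using whichever time points are measured; lesions with fewer
#' than two positive measurements are skipped with a `message()`.
#' Manually drawn VOIs make absolute TAC levels incomparable between
#' lesions, but the slopes are comparable — which is exactly what this
#' returns, sorted increasing (fastest washout first), ties broken by
#' lesion id.
#'
#' @param records List of [lesion_record()].
#' @param lesions Lesion ids to include.
#' @param cycle Cycle number.
#' @return Named numeric vector of slopes (1/h), sorted.
#' @export
tac_slope_compare <- function(records, lesions, cycle) {
  ids <- vapply(records, `[[`, "", "id")
  slopes <- c()
  for (les in lesions) {
    ri <- match(les, ids)
    if (is.na(ri)) stop("unknown lesion '", les, "'", call. = FALSE)
    r <- records[[ri]]
    sub <- r$suv[r$suv$cycle == cycle & !is.na(r$suv$suvmax) &
                   r$suv$suvmax > 0, ]
    if (nrow(sub) < 2L) {
      message("tac_slope_compare: skipping '", les,
              "' (fewer than 2 valid SUVmax points at cycle ", cycle, ")")
      next
    }
    fit <- fit_monoexp(new_tac(sub$time_h, sub$suvmax, region = les,
                               statistic = "max"))
    slopes[les] <- -fit$lambda_per_h
  }
  # sort increasing; ties broken by lesion id
  slopes[order(slopes, names(slopes))]
}
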
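# Biochemical (PSA) and molecular (SUVmax, MTV) response metrics and
# categorical classification under EORTC / PERCIST conventions.

#' Percent decrease between baseline and follow-up
#'
#' `100 * (baseline - followup) / baseline`; positive values are a
#' decrease, negative an increase.
#'
#' @param baseline Baseline value, > 0.
#' @param followup Follow-up value, >= 0.
#' @return Percent decrease.
#' @examples
#' percent_change(154.2, 24.6)   # 84.05 — PSA drop after one cycle
#' percent_change(160.3, 4.1)    # 97.44 — tumor-burden drop after four
#' @export
percent_change <- function(baseline, followup) {
  if (any(!is.finite(baseline)) || any(baseline <= 0))
    stop("baseline must be > 0", call. = FALSE)
  100 * (baseline - followup) / baseline
}

#' Classify an SUV-based response
#'
#' EORTC: partial response (PR) at a decrease > 25%, progressive disease
#' (PD) at an increase > 25% or a new lesion; PERCIST 1.0: PR at a
#' decrease >= 30%, PD at an increase >= 30% or a new lesion.  Complete
#' response (CR) if the lesion disappeared.  Everything else is stable
#' disease (SD).  Applied here to SUVmax (the criteria's SULpeak is not
#' available from quantitative SPECT; this deviation is deliberate and
#' documented).
#'
#' @param percent_decrease Percent decrease (positive = decrease), e.g.
#'   from [percent_change()].
#' @param criteria `"EORTC"` or `"PERCIST"`.
#' @param disappeared Lesion no longer detectable: CR regardless of
#'   percent.
#' @param new_lesion A new lesion appeared: PD regardless of percent.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @examples
#' classify_suv_response(80.7, "EORTC")     # "PR"
#' classify_suv_response(80.7, "PERCIST")   # "PR"
#' @export
classify_suv_response <- function(percent_decrease,
                                  criteria = c("EORTC", "PERCIST"),
                                  disappeared = FALSE, new_lesion = FALSE) {
  criteria <- match.arg(criteria)
  if (disappeared) return("CR")
  if (new_lesion) return("PD")
  if (criteria == "EORTC") {
    if (percent_decrease > 25) return("PR")
    if (percent_decrease < -25) return("PD")
  } else {
    if (percent_decrease >= 30) return("PR")
    if (percent_decrease <= -30) return("PD")
  }
  "SD"
}

#' Classify a PSA response
#'
#' PR at a decrease of at least `threshold` percent (default 50, the
#' PCWG convention), PD at an increase of 25% or more, otherwise SD.
#'
#' @param percent_decrease Percent decrease (positive = decrease).
#' @param threshold PR threshold in percent, in (0, 100).
#' @return List with `category` (`"PR"`/`"SD"`/`"PD"`) and `responder`
#'   (logical).
#' @examples
#' classify_psa_response(84.05)$category    # "PR"
#' @export
classify_psa_response <- function(percent_decrease, threshold = 50) {
  if (threshold <= 0 || threshold >= 100)
    stop("threshold must be in (0, 100)", call. = FALSE)
  category <- if (percent_decrease >= threshold) "PR"
  else if (percent_decrease <= -25) "PD"
  else "SD"
  list(category = category, responder = category == "PR")
}

#' Assemble a response assessment row
#'
#' Computes the percent change and the category for one metric and
#' returns a one-row data frame suitable for binding into a response
#' summary table.
#'
#' @param metric One of `"PSA"`, `"SUVmax"`, `"MTV"`.
#' @param baseline,followup Values of the metric, baseline > 0.
#' @param criteria For SUV-type metrics, `"EORTC"` or `"PERCIST"`; PSA
#'   uses the PCWG-style threshold rule.
#' @param disappeared,new_lesion Flags forwarded to
#'   [classify_suv_response()].
#' @param psa_threshold PR threshold for PSA (percent).
#' @return One-row data frame: metric, baseline, followup,
#'   `percent_decrease`, `category`, `criteria`.
#' @export
response_assessment <- function(metric = c("PSA", "SUVmax", "MTV"),
                                baseline, followup,
                                criteria = c("EORTC", "PERCIST"),
                                disappeared = FALSE, new_lesion = FALSE,
                                psa_threshold = 50) {
  metric <- match.arg(metric)
  pc <- percent_change(baseline, followup)
  if (metric == "PSA") {
    category <- classify_psa_response(pc, psa_threshold)$category
    criteria_used <- sprintf("PSA>=%g%%", psa_threshold)
  } else {
    criteria <- match.arg(criteria)
    category <- classify_suv_response(pc, criteria, disappeared, new_lesion)
    criteria_used <- criteria
  }
  data.frame(metric = metric, baseline = baseline, followup = followup,
             percent_decrease = pc, category = category,
             criteria = criteria_used, stringsAsFactors = FALSE)
}

#' Read a biomarker series from CSV
#'
#' Expected columns: `cycle`, `label`, `marker`, `value`, `units`.
#' Values must be >= 0 and rows are kept in file (chronological) order.
#'
#' @param path CSV file.
#' @return Data frame of class `biomarker_series`.
#' @export
read_biomarkers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cycle", "label", "marker", "value", "units")
  if (!all(need %in% names(df)))
    stop("biomarker CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(df$value < 0, na.rm = TRUE))
    stop("biomarker values must be >= 0", call. = FALSE)
  class(df) <- c("biomarker_series", "data.frame")
  df
}
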
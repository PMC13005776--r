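#' Classify glucose tolerance from an OGTT glucose series
#'
#' Assigns one of four glucose-tolerance categories from the 2 h (120 min)
#' diagnostic glucose and the mid-OGTT samples (10, 30 and 60 min):
#' \itemize{
#'   \item \strong{CFRD}: 2 h glucose >= 11.1 mmol/l.
#'   \item \strong{IGT}: 2 h glucose in \[7.8, 11.1) mmol/l.
#'   \item \strong{INDET}: 2 h glucose < 7.8 mmol/l but any mid-OGTT glucose
#'     >= 11.1 mmol/l.
#'   \item \strong{NGT}: otherwise.
#' }
#' The rules are evaluated in exactly this precedence, so every valid input
#' maps to exactly one label. The 2 h upper bound of IGT is implemented as
#' `< 11.1` so the scale is gap-free. The 180 min sample is not a mid-OGTT
#' sample and does not trigger INDET.
#'
#' @param glucose_by_timepoint named numeric vector of OGTT glucose values
#'   (mmol/l); names are timepoint minutes drawn from -1, 10, 30, 60, 180.
#' @param glucose_120 the 2 h diagnostic glucose (mmol/l). Required: the
#'   sampling grid does not contain 120 min, so this value cannot be derived
#'   and is never interpolated.
#' @param thresholds threshold list, see [default_thresholds()].
#' @return one of `"NGT"`, `"INDET"`, `"IGT"`, `"CFRD"`.
#' @examples
#' classify_glucose_tolerance(c(`10` = 6, `30` = 6, `60` = 6), 11.1) # "CFRD"
#' classify_glucose_tolerance(c(`30` = 11.5, `60` = 6), 7.0)        # "INDET"
#' @export
classify_glucose_tolerance <- function(glucose_by_timepoint, glucose_120,
                                       thresholds = default_thresholds()) {
  if (missing(glucose_120) || is.null(glucose_120) || length(glucose_120) != 1 ||
      is.na(glucose_120)) {
    abort_mirogtt("2 h (120 min) glucose is required; participant is unclassifiable without it",
                  "mirogtt_unclassifiable")
  }
  g <- glucose_by_timepoint
  if (length(g)) {
    if (is.null(names(g)) || any(!names(g) %in% as.character(OGTT_TIMEPOINTS))) {
      abort_mirogtt(
        sprintf("timepoint labels must be among {%s} minutes",
                paste(OGTT_TIMEPOINTS, collapse = ", ")),
        "mirogtt_validation")
    }
  }
  vals <- c(g[!is.na(g)], glucose_120)
  if (any(vals <= 0)) {
    abort_mirogtt("glucose values must be positive", "mirogtt_validation")
  }
  mid <- g[names(g) %in% as.character(MID_OGTT_TIMEPOINTS)]
  mid <- mid[!is.na(mid)]
  if (length(mid) == 0) {
    abort_mirogtt("at least one mid-OGTT glucose (10, 30 or 60 min) is required",
                  "mirogtt_unclassifiable")
  }
  if (glucose_120 >= thresholds$glucose_cfrd) return("CFRD")
  if (glucose_120 >= thresholds$glucose_igt_lower) return("IGT")
  if (any(mid >= thresholds$glucose_cfrd)) return("INDET")
  "NGT"
}

#' Classify every participant in a long-format sample sheet
#'
#' @param sample_sheet data frame with columns `participant_id`,
#'   `timepoint_min`, `glucose_mmol_l` (one row per participant x timepoint)
#'   and optionally `insulin_pmol_l`.
#' @param glucose_120 named numeric vector of 2 h glucose values keyed by
#'   participant id, or a data frame with columns `participant_id` and
#'   `glucose_120_mmol_l`.
#' @inheritParams classify_glucose_tolerance
#' @return data frame `participant_id`, `group` (factor with levels
#'   NGT, INDET, IGT, CFRD).
#' @export
classify_participants <- function(sample_sheet, glucose_120,
                                  thresholds = default_thresholds()) {
  req <- c("participant_id", "timepoint_min", "glucose_mmol_l")
  if (!all(req %in% names(sample_sheet))) {
    abort_mirogtt(sprintf("sample sheet is missing column(s): %s",
                          paste(setdiff(req, names(sample_sheet)), collapse = ", ")),
                  "mirogtt_schema")
  }
  if (is.data.frame(glucose_120)) {
    glucose_120 <- stats::setNames(glucose_120$glucose_120_mmol_l,
                                   glucose_120$participant_id)
  }
  ids <- unique(sample_sheet$participant_id)
  grp <- vapply(ids, function(id) {
    rows <- sample_sheet[sample_sheet$participant_id == id, ]
    g <- stats::setNames(rows$glucose_mmol_l, rows$timepoint_min)
    classify_glucose_tolerance(g, unname(glucose_120[as.character(id)]),
                               thresholds = thresholds)
  }, character(1))
  data.frame(participant_id = ids,
             group = factor(grp, levels = GROUP_LEVELS),
             stringsAsFactors = FALSE)
}

#' Glucose tolerance group labels, in order of worsening tolerance
#' @export
GROUP_LEVELS <- c("NGT", "INDET", "IGT", "CFRD")
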
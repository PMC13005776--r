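#' Interplate calibration against the UniSp3 spike-in
#'
#' Each plate carries the UniSp3 interplate calibrator. Calibration subtracts,
#' from every Ct on a plate, the difference between that plate's mean UniSp3
#' Ct and the global mean UniSp3 Ct across all plates. After calibration the
#' per-plate UniSp3 means are all equal, and the transform is idempotent.
#'
#' @param ct_records long-format Ct data frame with columns `participant_id`,
#'   `timepoint_min`, `plate_id`, `assay_id`, `ct` (NA = undetected).
#' @return the same data frame with calibrated `ct` values.
#' @export
interplate_calibrate <- function(ct_records) {
  validate_ct_records(ct_records)
  sp3 <- ct_records$assay_id == "UniSp3" & !is.na(ct_records$ct)
  plates <- unique(ct_records$plate_id)
  have <- unique(ct_records$plate_id[sp3])
  missing_plates <- setdiff(plates, have)
  if (length(missing_plates)) {
    abort_mirogtt(
      sprintf("plate(s) without a numeric UniSp3 record: %s",
              paste(missing_plates, collapse = ", ")),
      "mirogtt_calibration")
  }
  plate_means <- tapply(ct_records$ct[sp3], ct_records$plate_id[sp3], mean)
  global_mean <- mean(ct_records$ct[sp3])
  offset <- plate_means[as.character(ct_records$plate_id)] - global_mean
  ct_records$ct <- as.vector(ct_records$ct - offset)
  ct_records
}

#' Reverse-transcription inhibition gate (UniSp6)
#'
#' UniSp6 is spiked into the reverse-transcription reaction; a late or absent
#' signal indicates RT/PCR inhibition. A sample fails when its UniSp6 Ct is
#' strictly above the threshold (default 23 cycles) or undetected.
#'
#' @param sample_records Ct records for one sample (one participant at one
#'   timepoint).
#' @inheritParams classify_glucose_tolerance
#' @return logical: `TRUE` = pass.
#' @export
rt_inhibition_gate <- function(sample_records,
                               thresholds = default_thresholds()) {
  ct <- sample_records$ct[sample_records$assay_id == "UniSp6"]
  if (length(ct) == 0) {
    abort_mirogtt("sample has no UniSp6 record; RT-inhibition gate cannot run",
                  "mirogtt_gate")
  }
  if (all(is.na(ct))) return(FALSE)
  mean(ct, na.rm = TRUE) <= thresholds$unisp6_max
}

#' Haemolysis gate (miR-23a-3p / miR-451a index)
#'
#' Erythrocytes are rich in miR-451a, so haemolysis drives its Ct down
#' relative to miR-23a-3p. The index is
#' `Ct(miR-23a-3p) - Ct(miR-451a)`; a sample passes when the index is
#' strictly below the threshold (default 7 cycles).
#'
#' @inheritParams rt_inhibition_gate
#' @return list with `index` (cycles, NA when unevaluable) and `pass`.
#' @export
haemolysis_gate <- function(sample_records,
                            thresholds = default_thresholds()) {
  ct23 <- sample_records$ct[sample_records$assay_id == HAEMOLYSIS_NUMERATOR]
  ct451 <- sample_records$ct[sample_records$assay_id == HAEMOLYSIS_DENOMINATOR]
  if (length(ct23) == 0 || length(ct451) == 0) {
    abort_mirogtt("sample lacks miR-23a-3p and/or miR-451a; haemolysis gate cannot run",
                  "mirogtt_gate")
  }
  if (all(is.na(ct23)) || all(is.na(ct451))) {
    return(list(index = NA_real_, pass = FALSE,
                reason = "haemolysis_unevaluable"))
  }
  idx <- mean(ct23, na.rm = TRUE) - mean(ct451, na.rm = TRUE)
  list(index = idx, pass = idx < thresholds$haemolysis_max, reason = NULL)
}

#' Extraction-consistency gate (UniSp2/4/5)
#'
#' The extraction spike-ins UniSp2, UniSp4 and UniSp5 are added to every
#' serum aliquot before RNA extraction, so within one participant their Ct
#' should be stable across all OGTT samples. For each spike-in separately the
#' gate fails when the Ct range (max - min) across the participant's samples
#' is strictly greater than the threshold (default 3 cycles).
#'
#' @param participant_records all Ct records of one participant.
#' @inheritParams rt_inhibition_gate
#' @return named logical vector over UniSp2, UniSp4, UniSp5 (`TRUE` = pass),
#'   with attribute `"range"` holding the observed Ct ranges.
#' @export
extraction_consistency_gate <- function(participant_records,
                                        thresholds = default_thresholds()) {
  spikes <- c("UniSp2", "UniSp4", "UniSp5")
  rng <- vapply(spikes, function(sp) {
    ct <- participant_records$ct[participant_records$assay_id == sp]
    ct <- ct[!is.na(ct)]
    if (length(ct) == 0) {
      abort_mirogtt(sprintf("spike-in %s absent from all of the participant's samples", sp),
                    "mirogtt_gate")
    }
    diff(range(ct))
  }, numeric(1))
  pass <- rng <= thresholds$extraction_max_range
  attr(pass, "range") <- rng
  pass
}

#' Run all sample QC gates and the participant inclusion rule
#'
#' Applies, in order: interplate calibration (optional), the RT-inhibition
#' and haemolysis gates per sample, the extraction-consistency gate per
#' participant, and the inclusion rule: a participant is included when the
#' baseline (-1 min) sample passes all gates and at least two further OGTT
#' samples pass all gates; an extraction-consistency failure excludes the
#' participant entirely. The gates are independent per sample, so the
#' included set does not depend on evaluation order.
#'
#' @inheritParams interplate_calibrate
#' @param calibrate apply [interplate_calibrate()] first (default TRUE).
#' @inheritParams rt_inhibition_gate
#' @return object of class `mirogtt_qc_report`: a list with
#'   \describe{
#'     \item{samples}{per-sample gate outcomes: `participant_id`,
#'       `timepoint_min`, `rt_inhibition_pass`, `haemolysis_index`,
#'       `haemolysis_pass`, `sample_pass`, `reasons`.}
#'     \item{participants}{per-participant: extraction gate outcomes and
#'       ranges, `included`, `reasons`.}
#'     \item{filtered}{calibrated Ct records restricted to passing samples of
#'       included participants.}
#'     \item{thresholds}{the thresholds actually applied.}
#'   }
#' @export
qc_report <- function(ct_records, calibrate = TRUE,
                      thresholds = default_thresholds()) {
  validate_ct_records(ct_records)
  if (calibrate) ct_records <- interplate_calibrate(ct_records)

  key <- interaction(ct_records$participant_id, ct_records$timepoint_min,
                     drop = TRUE)
  samp_idx <- split(seq_len(nrow(ct_records)), key)
  samples <- do.call(rbind, lapply(samp_idx, function(ii) {
    rec <- ct_records[ii, ]
    rt <- rt_inhibition_gate(rec, thresholds)
    hg <- haemolysis_gate(rec, thresholds)
    reasons <- c(if (!rt) "rt_inhibition",
                 if (!hg$pass) if (is.null(hg$reason)) "haemolysis" else hg$reason)
    data.frame(participant_id = rec$participant_id[1],
               timepoint_min = rec$timepoint_min[1],
               rt_inhibition_pass = rt,
               haemolysis_index = hg$index,
               haemolysis_pass = hg$pass,
               sample_pass = rt && hg$pass,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(samples) <- NULL

  ids <- unique(ct_records$participant_id)
  participants <- do.call(rbind, lapply(ids, function(id) {
    prec <- ct_records[ct_records$participant_id == id, ]
    ext <- extraction_consistency_gate(prec, thresholds)
    rng <- attr(ext, "range")
    ss <- samples[samples$participant_id == id, ]
    baseline <- ss[ss$timepoint_min == -1, ]
    n_follow <- sum(ss$sample_pass[ss$timepoint_min != -1])
    reasons <- character(0)
    if (nrow(baseline) == 0) {
      reasons <- c(reasons, "no_baseline")
      baseline_ok <- FALSE
    } else {
      baseline_ok <- all(baseline$sample_pass)
      if (!baseline_ok) reasons <- c(reasons, "baseline_fail")
    }
    if (n_follow < 2) reasons <- c(reasons, "insufficient_followup")
    if (!all(ext)) {
      reasons <- c(reasons, paste0("extraction_", names(ext)[!ext]))
    }
    data.frame(participant_id = id,
               unisp2_range = rng[["UniSp2"]],
               unisp4_range = rng[["UniSp4"]],
               unisp5_range = rng[["UniSp5"]],
               extraction_pass = all(ext),
               baseline_pass = baseline_ok,
               n_followup_pass = n_follow,
               included = all(ext) && baseline_ok && n_follow >= 2,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(participants) <- NULL

  ok_participants <- participants$participant_id[participants$included]
  ok_samples <- samples[samples$sample_pass &
                          samples$participant_id %in% ok_participants,
                        c("participant_id", "timepoint_min")]
  keep <- paste(ct_records$participant_id, ct_records$timepoint_min) %in%
    paste(ok_samples$participant_id, ok_samples$timepoint_min)
  structure(list(samples = samples,
                 participants = participants,
                 filtered = ct_records[keep, ],
                 thresholds = thresholds),
            class = "mirogtt_qc_report")
}

#' @export
print.mirogtt_qc_report <- function(x, ...) {
  cat("mirogtt QC report\n")
  cat(sprintf("  samples:      %d assessed, %d passed all gates\n",
              nrow(x$samples), sum(x$samples$sample_pass)))
  cat(sprintf("  participants: %d assessed, %d included\n",
              nrow(x$participants), sum(x$participants$included)))
  invisible(x)
}

# Internal: schema check shared by QC entry points.
validate_ct_records <- function(ct_records) {
  req <- c("participant_id", "timepoint_min", "plate_id", "assay_id", "ct")
  miss <- setdiff(req, names(ct_records))
  if (length(miss)) {
    abort_mirogtt(sprintf("Ct table is missing column(s): %s",
                          paste(miss, collapse = ", ")),
                  "mirogtt_schema")
  }
  bad <- !is.na(ct_records$ct) &
    (ct_records$ct <= 0 | ct_records$ct > 45)
  if (any(bad)) {
    abort_mirogtt("numeric Ct values must lie in (0, 45]", "mirogtt_schema")
  }
  invisible(TRUE)
}
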
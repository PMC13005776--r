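#' Read a long-format Ct table
#'
#' TSV/CSV with columns `participant_id`, `timepoint_min`, `plate_id`,
#' `assay_id`, `ct`. An empty `ct` field means "undetected" and is read as
#' NA; no sentinel Ct values are used.
#'
#' @param path file path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab).
#' @return validated Ct data frame.
#' @export
read_ct_table <- function(path) {
  d <- read_table_auto(path)
  validate_ct_records(d)
  dup <- duplicated(d[, c("participant_id", "timepoint_min", "plate_id",
                          "assay_id")])
  if (any(dup)) {
    abort_mirogtt("duplicate (participant, timepoint, plate, assay) rows",
                  "mirogtt_schema")
  }
  d
}

#' Read an OGTT sample sheet
#'
#' One row per participant x timepoint with `participant_id`,
#' `timepoint_min`, `glucose_mmol_l` and optionally `insulin_pmol_l`.
#'
#' @inheritParams read_ct_table
#' @return validated data frame.
#' @export
read_sample_sheet <- function(path) {
  d <- read_table_auto(path)
  req <- c("participant_id", "timepoint_min", "glucose_mmol_l")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    abort_mirogtt(sprintf("sample sheet missing column(s): %s",
                          paste(miss, collapse = ", ")), "mirogtt_schema")
  }
  if (any(!is.na(d$glucose_mmol_l) & d$glucose_mmol_l <= 0)) {
    abort_mirogtt("glucose values must be positive", "mirogtt_schema")
  }
  d
}

read_table_auto <- function(path) {
  if (!file.exists(path)) {
    abort_mirogtt(sprintf("cannot read %s", path), "mirogtt_io")
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("", "NA"))
}

#' Validate pipeline input files
#'
#' Per-file column, type and duplicate-key checks, returned as a
#' machine-readable report rather than a hard stop.
#'
#' @param ct_path path to the Ct table (optional).
#' @param sample_sheet_path path to the OGTT sample sheet (optional).
#' @return data frame: `file`, `check`, `ok`, `detail`.
#' @export
validate_inputs <- function(ct_path = NULL, sample_sheet_path = NULL) {
  rows <- list()
  add <- function(file, check, ok, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, check = check, ok = ok, detail = detail,
      stringsAsFactors = FALSE)
  }
  try_check <- function(file, check, fn) {
    res <- tryCatch({ fn(); list(TRUE, "") },
                    error = function(e) list(FALSE, conditionMessage(e)))
    add(file, check, res[[1]], res[[2]])
  }
  if (!is.null(ct_path)) {
    try_check(ct_path, "ct_table_schema", function() read_ct_table(ct_path))
  }
  if (!is.null(sample_sheet_path)) {
    try_check(sample_sheet_path, "sample_sheet_schema",
              function() read_sample_sheet(sample_sheet_path))
  }
  do.call(rbind, rows)
}

#' Run the qPCR analysis pipeline end to end
#'
#' Classify participants, calibrate and QC the Ct table, normalize with both
#' schemes, compute per-timepoint volcano comparisons for every non-reference
#' group, and (for the requested miRNAs) the across-group baseline ANOVA and
#' OGTT mixed-effects time course. Writes tidy CSV outputs, a JSON QC report,
#' a run manifest (thresholds actually applied, seed, input digests) and a
#' plain-text summary. Identical inputs and config give identical outputs.
#'
#' @param ct_records Ct data frame (or path to one).
#' @param sample_sheet OGTT sample sheet data frame (or path).
#' @param glucose_120 named vector or data frame of 2 h glucose values.
#' @param out_dir output directory (created if needed).
#' @param focus_mirnas miRNAs given the ANOVA / time-course treatment.
#' @param timepoints,volcano_groups volcano grid; defaults to all non-baseline
#'   timepoints and all non-NGT groups present.
#' @inheritParams classify_glucose_tolerance
#' @return (invisibly) list of the in-memory results:
#'   `groups`, `qc`, `expr_dct`, `expr_ddct`, `volcano`, `anova`,
#'   `timecourse`, `out_dir`.
#' @export
run_pipeline <- function(ct_records, sample_sheet, glucose_120, out_dir,
                         focus_mirnas = c("miR-34a-5p", "miR-122-5p",
                                          "miR-223-3p"),
                         timepoints = NULL, volcano_groups = NULL,
                         thresholds = default_thresholds()) {
  if (is.character(ct_records)) ct_records <- read_ct_table(ct_records)
  if (is.character(sample_sheet)) sample_sheet <- read_sample_sheet(sample_sheet)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(sprintf(...))

  groups <- classify_participants(sample_sheet, glucose_120, thresholds)
  log_stage("classify: %d participants (%s)", nrow(groups),
            paste(sprintf("%s=%d", names(table(groups$group)),
                          table(groups$group)), collapse = ", "))

  qc <- qc_report(ct_records, calibrate = TRUE, thresholds = thresholds)
  log_stage("qc: %d/%d samples pass, %d/%d participants included",
            sum(qc$samples$sample_pass), nrow(qc$samples),
            sum(qc$participants$included), nrow(qc$participants))

  expr_dct <- normalize_control_mean(qc$filtered, groups)
  expr_ddct <- normalize_ddct(qc$filtered, groups)
  log_stage("normalize: %d expression records", nrow(expr_dct))

  present_groups <- intersect(GROUP_LEVELS, unique(expr_dct$group))
  if (is.null(volcano_groups)) volcano_groups <- setdiff(present_groups, "NGT")
  if (is.null(timepoints)) timepoints <- sort(unique(expr_dct$timepoint_min))
  volcano <- do.call(rbind, lapply(volcano_groups, function(g) {
    do.call(rbind, lapply(timepoints, function(tp) {
      volcano_per_timepoint(expr_dct, g, "NGT", tp, thresholds = thresholds)
    }))
  }))
  log_stage("volcano: %d comparisons", nrow(volcano))

  anova_res <- list(); tc_res <- list()
  for (m in intersect(focus_mirnas, unique(expr_ddct$mirna))) {
    anova_res[[m]] <- tryCatch(baseline_group_anova(expr_ddct, m),
                               error = function(e) conditionMessage(e))
    tc_res[[m]] <- tryCatch(dynamic_mixed_effects(expr_ddct, m),
                            error = function(e) conditionMessage(e))
  }

  # outputs
  utils::write.csv(groups, file.path(out_dir, "groups.csv"), row.names = FALSE)
  utils::write.csv(expr_dct, file.path(out_dir, "expression_dct.csv"),
                   row.names = FALSE)
  utils::write.csv(expr_ddct, file.path(out_dir, "expression_ddct.csv"),
                   row.names = FALSE)
  utils::write.csv(volcano, file.path(out_dir, "volcano.csv"),
                   row.names = FALSE)
  tukey_tab <- do.call(rbind, lapply(names(anova_res), function(m) {
    a <- anova_res[[m]]
    if (is.character(a)) return(NULL)
    cbind(mirna = m, omnibus_p = a$omnibus_p, a$tukey)
  }))
  if (!is.null(tukey_tab)) {
    utils::write.csv(tukey_tab, file.path(out_dir, "baseline_anova.csv"),
                     row.names = FALSE)
  }
  tc_tab <- do.call(rbind, lapply(names(tc_res), function(m) {
    a <- tc_res[[m]]
    if (is.character(a)) return(NULL)
    cbind(mirna = m, a$contrasts)
  }))
  if (!is.null(tc_tab)) {
    utils::write.csv(tc_tab, file.path(out_dir, "timecourse_contrasts.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(samples = qc$samples, participants = qc$participants),
    file.path(out_dir, "qc_report.json"), dataframe = "rows", na = "null",
    auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(thresholds = thresholds,
         n_participants = nrow(groups),
         n_samples_in = nrow(qc$samples),
         n_samples_pass = sum(qc$samples$sample_pass),
         n_participants_included = sum(qc$participants$included)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  summary_lines <- c(
    sprintf("participants: %d, included after QC: %d", nrow(groups),
            sum(qc$participants$included)),
    sprintf("samples: %d, passing all gates: %d", nrow(qc$samples),
            sum(qc$samples$sample_pass)),
    sprintf("volcano comparisons: %d (up: %d, down: %d)",
            nrow(volcano), sum(volcano$volcano_class == "up", na.rm = TRUE),
            sum(volcano$volcano_class == "down", na.rm = TRUE)))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))

  invisible(list(groups = groups, qc = qc, expr_dct = expr_dct,
                 expr_ddct = expr_ddct, volcano = volcano,
                 anova = anova_res, timecourse = tc_res, out_dir = out_dir))
}
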
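#' Control-mean delta-Ct normalization
#'
#' Per sample, subtracts the arithmetic mean of the three endogenous serum
#' control Cts (miR-16-5p, miR-23a-3p, miR-486-5p) from each target miRNA Ct.
#' This in-sample normalization yields one delta-Ct value per miRNA x sample
#' and feeds the per-timepoint volcano comparisons. Samples with any control
#' undetected are dropped with a logged reason.
#'
#' @param ct_records filtered, calibrated long Ct table (see [qc_report()]).
#' @param groups data frame `participant_id`, `group` (e.g. from
#'   [classify_participants()]).
#' @param controls endogenous control assay names.
#' @return data frame of expression records: `participant_id`,
#'   `timepoint_min`, `group`, `mirna`, `delta_ct`, `rel_expr` = 2^(-delta_ct),
#'   `scheme = "group_timepoint_mean"`. Dropped samples are reported in the
#'   `"dropped"` attribute.
#' @export
normalize_control_mean <- function(ct_records, groups,
                                   controls = ENDOGENOUS_CONTROLS) {
  norm_delta_ct(ct_records, groups, controls, mean, "group_timepoint_mean")
}

#' Delta-delta-Ct normalization against the NGT baseline
#'
#' Two-step scheme used for the across-group comparisons. In-sample step: the
#' geometric mean of the three endogenous-control Ct values (taken on the Ct
#' scale) is subtracted from each miRNA Ct, giving delta-Ct. Between-group
#' step: the NGT-baseline reference — the log2 of the geometric mean of the
#' NGT baseline relative-expression values, i.e. the arithmetic mean of the
#' NGT baseline delta-Ct values — is subtracted, giving delta-delta-Ct and
#' `fold = 2^(-ddct)`. By construction the geometric mean of `fold` over NGT
#' baseline samples is exactly 1.
#'
#' @inheritParams normalize_control_mean
#' @return data frame: `participant_id`, `timepoint_min`, `group`, `mirna`,
#'   `delta_ct`, `ddct`, `fold`, `scheme = "geometric_ngt_baseline"`.
#' @export
normalize_ddct <- function(ct_records, groups,
                           controls = ENDOGENOUS_CONTROLS) {
  expr <- norm_delta_ct(ct_records, groups, controls, geometric_mean,
                        "geometric_ngt_baseline")
  out <- lapply(split(expr, expr$mirna), function(d) {
    ref_rows <- d$group == "NGT" & d$timepoint_min == -1
    if (!any(ref_rows)) {
      abort_mirogtt(sprintf(
        "no NGT baseline sample available as delta-delta-Ct reference for %s",
        d$mirna[1]), "mirogtt_reference")
    }
    ref <- mean(d$delta_ct[ref_rows])
    d$ddct <- d$delta_ct - ref
    d$fold <- 2^(-d$ddct)
    d
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "dropped") <- attr(expr, "dropped")
  res
}

# Shared in-sample normalization step: `center_fun` is how the three control
# Cts are combined (arithmetic mean or geometric mean on the Ct scale).
norm_delta_ct <- function(ct_records, groups, controls, center_fun, scheme) {
  validate_ct_records(ct_records)
  gmap <- stats::setNames(as.character(groups$group), groups$participant_id)
  key <- interaction(ct_records$participant_id, ct_records$timepoint_min,
                     drop = TRUE)
  dropped <- list(); out <- list()
  for (ii in split(seq_len(nrow(ct_records)), key)) {
    rec <- ct_records[ii, ]
    ctrl <- rec$ct[match(controls, rec$assay_id)]
    pid <- rec$participant_id[1]; tp <- rec$timepoint_min[1]
    if (any(is.na(ctrl))) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        participant_id = pid, timepoint_min = tp,
        reason = "control_undetected", stringsAsFactors = FALSE)
      next
    }
    center <- center_fun(ctrl)
    tgt <- rec[!rec$assay_id %in% c(controls, names(SPIKE_INS)) &
                 !is.na(rec$ct), ]
    if (nrow(tgt) == 0) next
    out[[length(out) + 1L]] <- data.frame(
      participant_id = pid, timepoint_min = tp,
      group = gmap[[as.character(pid)]],
      mirna = tgt$assay_id, delta_ct = tgt$ct - center,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$rel_expr <- 2^(-res$delta_ct)
  res$scheme <- scheme
  attr(res, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else NULL
  res
}

#' Per-timepoint volcano differential expression
#'
#' For every miRNA at one OGTT timepoint, compares a test group against a
#' reference group: Student's t test on the delta-Ct values (equal variances
#' by default, matching common qPCR practice; Welch available via
#' `var_equal = FALSE`) and a group fold change taken as the ratio of group
#' arithmetic means of the relative expression `2^(-delta_ct)`. Volcano
#' class: `up` when fold >= `volcano_fold` and p < `alpha`; `down` when
#' fold <= 1/`volcano_fold` and p < `alpha`; else `ns`. The fold cut-off is
#' inclusive.
#'
#' @param expr expression records from [normalize_control_mean()] (or
#'   [normalize_ddct()]).
#' @param group_test,group_ref group labels to compare (fold is test / ref).
#' @param timepoint OGTT timepoint in minutes.
#' @param var_equal use the pooled-variance t test (default TRUE).
#' @inheritParams classify_glucose_tolerance
#' @return data frame: `mirna`, `comparison`, `timepoint_min`, `log2fc`,
#'   `fold`, `p`, `volcano_class`; skipped miRNAs carry NA statistics and a
#'   `skip_reason`.
#' @export
volcano_per_timepoint <- function(expr, group_test, group_ref = "NGT",
                                  timepoint, var_equal = TRUE,
                                  thresholds = default_thresholds()) {
  d <- expr[expr$timepoint_min == timepoint &
              expr$group %in% c(group_test, group_ref), ]
  comparison <- sprintf("%s_vs_%s_t%d", group_test, group_ref,
                        as.integer(timepoint))
  out <- lapply(split(d, d$mirna), function(m) {
    a <- m$delta_ct[m$group == group_ref]
    b <- m$delta_ct[m$group == group_test]
    base <- data.frame(mirna = m$mirna[1], comparison = comparison,
                       timepoint_min = as.integer(timepoint),
                       stringsAsFactors = FALSE)
    if (length(a) < 2 || length(b) < 2) {
      return(cbind(base, log2fc = NA_real_, fold = NA_real_, p = NA_real_,
                   volcano_class = NA_character_,
                   skip_reason = "fewer_than_2_samples_per_group"))
    }
    fold <- mean(2^(-b)) / mean(2^(-a))
    p <- stats::t.test(b, a, var.equal = var_equal)$p.value
    cls <- volcano_class(fold, p, thresholds$volcano_fold, thresholds$alpha)
    cbind(base, log2fc = log2(fold), fold = fold, p = p,
          volcano_class = cls, skip_reason = NA_character_)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Volcano classification shared by the qPCR and count arms.
volcano_class <- function(fold, p, fold_cut, alpha) {
  if (is.na(fold) || is.na(p)) return(NA_character_)
  if (fold >= fold_cut && p < alpha) return("up")
  if (fold <= 1 / fold_cut && p < alpha) return("down")
  "ns"
}

#' Across-group baseline comparison: one-way ANOVA with Tukey post hoc
#'
#' One-way ANOVA on the baseline fold values (2^(-ddct)) of one miRNA across
#' the four glucose-tolerance groups, followed by Tukey's honestly
#' significant difference pairwise comparisons (studentized range).
#'
#' @param expr delta-delta-Ct records from [normalize_ddct()].
#' @param mirna miRNA assay name.
#' @param timepoint timepoint analysed (default -1, baseline).
#' @param value column analysed (default `"fold"`).
#' @return list: `omnibus_p`, `anova` (the fitted `aov`), `tukey` (data frame
#'   `contrast`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
baseline_group_anova <- function(expr, mirna, timepoint = -1, value = "fold") {
  d <- expr[expr$mirna == mirna & expr$timepoint_min == timepoint, ]
  d <- d[!is.na(d[[value]]), ]
  tab <- table(d$group)
  if (sum(tab >= 2) < 2) {
    abort_mirogtt("need at least two groups with >= 2 samples", "mirogtt_validation")
  }
  d$group <- factor(d$group, levels = intersect(GROUP_LEVELS, unique(d$group)))
  y <- d[[value]]
  if (all(tapply(y, d$group, stats::var) < .Machine$double.eps)) {
    abort_mirogtt("zero within-group variance everywhere: ANOVA is degenerate",
                  "mirogtt_degenerate")
  }
  fit <- stats::aov(y ~ group, data = data.frame(y = y, group = d$group))
  om <- summary(fit)[[1]][["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(omnibus_p = om, anova = fit, tukey = tukey)
}

#' OGTT time-course mixed-effects analysis
#'
#' Fits, for one miRNA, a linear mixed model on log2 expression (-ddct by
#' default) with fixed effects for group, timepoint and their interaction and
#' a per-participant random intercept, by REML. Per-timepoint pairwise group
#' contrasts are then tested with no multiplicity correction (the
#' uncorrected-Fisher / Fisher's LSD convention), using Satterthwaite
#' degrees of freedom.
#'
#' @inheritParams baseline_group_anova
#' @param value column analysed; the default `"neg_ddct"` uses -ddct (log2
#'   expression relative to NGT baseline). Any numeric column of `expr` can
#'   be named instead.
#' @return list: `fit` (the `lmerModLmerTest`), `contrasts` (data frame
#'   `timepoint_min`, `contrast`, `estimate`, `se`, `df`, `p`),
#'   `converged` (logical), `messages` (character, convergence diagnostics).
#' @export
dynamic_mixed_effects <- function(expr, mirna, value = "neg_ddct") {
  d <- expr[expr$mirna == mirna, ]
  if (value == "neg_ddct") {
    if (!"ddct" %in% names(d)) {
      abort_mirogtt("expr lacks a ddct column; use normalize_ddct() output",
                    "mirogtt_validation")
    }
    d$neg_ddct <- -d$ddct
  }
  d <- d[!is.na(d[[value]]), ]
  d$group <- factor(d$group, levels = intersect(GROUP_LEVELS, unique(d$group)))
  d$timepoint <- factor(d$timepoint_min,
                        levels = sort(unique(d$timepoint_min)))
  d$y <- d[[value]]
  fit <- lmerTest::lmer(y ~ group * timepoint + (1 | participant_id), data = d)
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  em <- emmeans::emmeans(fit, ~ group | timepoint,
                         lmer.df = "satterthwaite")
  pr <- summary(emmeans::contrast(em, method = "pairwise", adjust = "none"))
  contrasts <- data.frame(
    timepoint_min = as.integer(as.character(pr$timepoint)),
    contrast = as.character(pr$contrast),
    estimate = pr$estimate, se = pr$SE, df = pr$df, p = pr$p.value,
    stringsAsFactors = FALSE)
  list(fit = fit, contrasts = contrasts,
       converged = is.null(msgs), messages = msgs %||% character(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
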
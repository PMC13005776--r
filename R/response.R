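#' Median-of-ratios size factors
#'
#' Per-sample size factor computed as the median, over reference miRNAs (those
#' with strictly positive counts in every sample), of the ratio of the
#' sample's count to the miRNA's geometric mean across samples. Normalized
#' counts are `count / size_factor`.
#'
#' @param counts non-negative integer matrix, miRNAs x samples.
#' @param pseudo_reference when no miRNA is positive in all samples, setting
#'   `pseudo_reference = TRUE` computes geometric means over positive entries
#'   only (documented fallback); the default is to stop.
#' @return numeric vector of positive size factors, one per sample.
#' @export
size_factors_median_of_ratios <- function(counts, pseudo_reference = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    abort_mirogtt("counts must be non-negative", "mirogtt_validation")
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos)) {
    if (!pseudo_reference) {
      abort_mirogtt(paste(
        "no miRNA has positive counts in every sample;",
        "re-run with pseudo_reference = TRUE to use positive entries only"),
        "mirogtt_size_factors")
    }
    loggeo <- apply(counts, 1, function(x) mean(log(x[x > 0])))
    ratios <- log(counts) - loggeo
    sf <- apply(ratios, 2, function(r) exp(stats::median(r[is.finite(r)])))
  } else {
    ref <- counts[all_pos, , drop = FALSE]
    loggeo <- rowMeans(log(ref))
    sf <- apply(log(ref) - loggeo, 2, function(r) exp(stats::median(r)))
  }
  unname(sf)
}

#' Expressed-miRNA filter
#'
#' Retains a miRNA when its normalized count is strictly greater than
#' `expressed_min_count` (default 5) in at least `expressed_min_fraction`
#' (default 50%, inclusive) of the samples.
#'
#' @param norm_counts normalized count matrix (counts / size factors).
#' @inheritParams classify_glucose_tolerance
#' @return character vector of retained miRNA names.
#' @export
filter_expressed <- function(norm_counts, thresholds = default_thresholds()) {
  frac <- rowMeans(norm_counts > thresholds$expressed_min_count)
  rownames(norm_counts)[frac >= thresholds$expressed_min_fraction]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in p rank, capped at 1), with input
#' validation. Thin, validated wrapper around `p.adjust(method = "BH")`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort_mirogtt("p-values must lie in [0, 1] with no missing values",
                  "mirogtt_validation")
  }
  stats::p.adjust(p, method = "BH")
}

#' Differential glucose response (group x timepoint interaction)
#'
#' Paired log-ratio Wald test for whether a miRNA's baseline-to-60-min change
#' differs between a glucose-tolerance group and the reference group. Per
#' participant, the response is
#' `r_i = log2((n60 + pc) / (n0 + pc))` on normalized counts (pseudocount
#' `pc` = 0.5 by default); the interaction effect is
#' `mean r (test group) - mean r (reference group)`; a Wald-type z uses the
#' pooled standard error, with a two-sided normal p-value, BH FDR across
#' miRNAs, and a volcano class at |effect| >= 1 (2-fold) and q < 0.05.
#' Pairing within participant is the correction for participant variability.
#' This is a deliberately simplified statistic targeting the same estimand as
#' a negative-binomial GLM interaction Wald test on the log scale.
#'
#' @param counts miRNA x sample count matrix.
#' @param meta sample data frame: `sample_id` (matching `colnames(counts)`),
#'   `participant_id`, `timepoint_min` (-1 or 60), `group`.
#' @param group_test group compared against the reference.
#' @param group_ref reference group (default `"NGT"`).
#' @param filter apply [filter_expressed()] before testing (default TRUE).
#' @inheritParams classify_glucose_tolerance
#' @return data frame: `mirna`, `comparison`, `response_ref`, `response_test`
#'   (mean per-group log2 responses), `effect` (log2 interaction), `se`, `z`,
#'   `p`, `q`, `volcano_class`.
#' @export
differential_response <- function(counts, meta, group_test, group_ref = "NGT",
                                  filter = TRUE,
                                  thresholds = default_thresholds()) {
  m <- align_counts_meta(counts, meta)
  counts <- m$counts; meta <- m$meta
  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (filter) {
    keep <- filter_expressed(norm, thresholds)
    norm <- norm[keep, , drop = FALSE]
  }
  pc <- thresholds$pseudocount

  resp_group <- function(grp) {
    pid <- unique(meta$participant_id[meta$group == grp])
    if (length(pid) < 2) {
      abort_mirogtt(sprintf("group %s has fewer than 2 paired participants", grp),
                    "mirogtt_validation")
    }
    r <- vapply(pid, function(id) {
      j0 <- which(meta$participant_id == id & meta$timepoint_min == -1)
      j1 <- which(meta$participant_id == id & meta$timepoint_min == 60)
      if (length(j0) != 1 || length(j1) != 1) {
        abort_mirogtt(sprintf(
          "participant %s lacks the paired -1/60 min samples", id),
          "mirogtt_validation")
      }
      log2((norm[, j1] + pc) / (norm[, j0] + pc))
    }, numeric(nrow(norm)))
    matrix(r, nrow = nrow(norm), dimnames = list(rownames(norm), pid))
  }
  r_ref <- resp_group(group_ref)
  r_test <- resp_group(group_test)
  na <- ncol(r_ref); nb <- ncol(r_test)
  mean_ref <- rowMeans(r_ref); mean_test <- rowMeans(r_test)
  effect <- mean_test - mean_ref
  va <- apply(r_ref, 1, stats::var); vb <- apply(r_test, 1, stats::var)
  s2p <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(s2p * (1 / na + 1 / nb))
  z <- ifelse(se > 0, effect / se, 0)
  p <- 2 * stats::pnorm(-abs(z))
  q <- bh_fdr(p)
  cls <- mapply(volcano_class, 2^effect, q,
                MoreArgs = list(fold_cut = thresholds$response_fold,
                                alpha = thresholds$alpha))
  data.frame(mirna = rownames(norm),
             comparison = sprintf("%s_vs_%s_response", group_test, group_ref),
             response_ref = mean_ref, response_test = mean_test,
             effect = effect, se = se, z = z, p = p, q = q,
             volcano_class = cls, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Baseline differential expression on counts
#'
#' Welch t test on `log2(normalized count + pseudocount)` between two groups
#' at the baseline timepoint, with BH FDR, ranked by p.
#'
#' @inheritParams differential_response
#' @return data frame: `mirna`, `comparison`, `log2fc` (test - ref), `p`,
#'   `q`, sorted by p.
#' @export
baseline_de <- function(counts, meta, group_test, group_ref = "NGT",
                        filter = TRUE, thresholds = default_thresholds()) {
  m <- align_counts_meta(counts, meta)
  counts <- m$counts; meta <- m$meta
  sf <- size_factors_median_of_ratios(counts)
  norm <- sweep(counts, 2, sf, "/")
  if (filter) {
    keep <- filter_expressed(norm, thresholds)
    norm <- norm[keep, , drop = FALSE]
  }
  base <- meta$timepoint_min == -1
  ja <- which(base & meta$group == group_ref)
  jb <- which(base & meta$group == group_test)
  if (length(ja) < 2 || length(jb) < 2) {
    abort_mirogtt("each group needs >= 2 baseline samples", "mirogtt_validation")
  }
  lg <- log2(norm + thresholds$pseudocount)
  log2fc <- rowMeans(lg[, jb, drop = FALSE]) - rowMeans(lg[, ja, drop = FALSE])
  p <- apply(lg, 1, function(x) {
    if (stats::sd(x[ja]) == 0 && stats::sd(x[jb]) == 0) return(1)
    stats::t.test(x[jb], x[ja])$p.value
  })
  res <- data.frame(mirna = rownames(norm),
                    comparison = sprintf("%s_vs_%s_baseline",
                                         group_test, group_ref),
                    log2fc = log2fc, p = p, q = bh_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$p), ]
}

# Internal: align meta rows to count columns by sample_id.
align_counts_meta <- function(counts, meta) {
  req <- c("sample_id", "participant_id", "timepoint_min", "group")
  miss <- setdiff(req, names(meta))
  if (length(miss)) {
    abort_mirogtt(sprintf("sample metadata missing column(s): %s",
                          paste(miss, collapse = ", ")), "mirogtt_schema")
  }
  if (!all(colnames(counts) %in% meta$sample_id)) {
    abort_mirogtt("count matrix has samples absent from the metadata",
                  "mirogtt_schema")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  list(counts = as.matrix(counts), meta = meta)
}
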
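#' Spearman correlation with exact small-sample p-values
#'
#' Spearman's rank correlation using average ranks (midranks under ties).
#' For n <= `exact_n` (default 10) the two-sided p-value is computed by full
#' enumeration of all n! rank permutations (exact, ties handled through the
#' midranks); for larger n the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 df is used. Missing pairs
#' are dropped pairwise. With a constant vector rho is undefined and is
#' reported as NA, not 0.
#'
#' @param x,y numeric vectors of equal length.
#' @param exact_n largest n at which the exact permutation p is used.
#' @return list: `rho`, `p`, `n`, `method` (`"exact_permutation"` or
#'   `"t_approximation"`, or `"undefined"`).
#' @export
spearman_test <- function(x, y, exact_n = 10) {
  if (length(x) != length(y)) {
    abort_mirogtt("x and y must have equal length", "mirogtt_validation")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) {
    abort_mirogtt("need at least 3 complete pairs", "mirogtt_validation")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    p <- .spearman_perm_p(rx, ry)
    method <- "exact_permutation"
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t_approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Correlate miRNA expression with clinical analytes, per stratum
#'
#' Runs [spearman_test()] for every requested (miRNA, analyte) pair within
#' each (group, timepoint) stratum, joining expression and participant
#' profiles on participant id. Strata with fewer than 3 complete pairs are
#' skipped with a logged reason; no multiplicity correction is applied (the
#' panel is exploratory).
#'
#' @param expr expression records ([normalize_ddct()] output by default
#'   feeds the `value` column choice).
#' @param profiles participant table with `participant_id` and one column per
#'   analyte (e.g. `cohort$participants` or a clinical analyte sheet).
#' @param mirnas,analytes character vectors naming the panel.
#' @param value expression column correlated (default `"fold"`).
#' @param groups,timepoints strata to evaluate; defaults to all present.
#' @return data frame: `mirna`, `analyte`, `group`, `timepoint_min`, `rho`,
#'   `p`, `n`, `method`; skipped strata appear with NA statistics and a
#'   `skip_reason`.
#' @export
correlate_panel <- function(expr, profiles, mirnas, analytes,
                            value = "fold",
                            groups = NULL, timepoints = NULL) {
  if (is.null(groups)) groups <- unique(expr$group)
  if (is.null(timepoints)) timepoints <- unique(expr$timepoint_min)
  keep_cols <- c("participant_id",
                 setdiff(names(profiles), names(expr)))
  merged <- merge(expr, profiles[, keep_cols, drop = FALSE],
                  by = "participant_id")
  if (nrow(merged) == 0) {
    warning("expression/profile join produced zero rows")
    return(data.frame())
  }
  out <- list()
  for (grp in groups) for (tp in timepoints) for (m in mirnas) {
    d <- merged[merged$group == grp & merged$timepoint_min == tp &
                  merged$mirna == m, ]
    for (an in analytes) {
      base <- data.frame(mirna = m, analyte = an, group = grp,
                         timepoint_min = tp, stringsAsFactors = FALSE)
      xv <- d[[value]]; yv <- d[[an]]
      n_ok <- if (is.null(yv) || is.null(xv)) 0 else
        sum(is.finite(xv) & is.finite(yv))
      if (n_ok < 3) {
        out[[length(out) + 1L]] <- cbind(
          base, rho = NA_real_, p = NA_real_, n = n_ok,
          method = NA_character_, skip_reason = "fewer_than_3_pairs")
        next
      }
      st <- spearman_test(xv, yv)
      out[[length(out) + 1L]] <- cbind(
        base, rho = st$rho, p = st$p, n = st$n, method = st$method,
        skip_reason = NA_character_)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
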
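#' Geometric mean
#'
#' Plain geometric mean of a positive numeric vector. Used for the in-sample
#' step of the delta-delta-Ct scheme, which takes the geometric mean of the
#' endogenous-control Ct values on the Ct scale.
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values first.
#' @return scalar geometric mean.
#' @export
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(is.na(x))) return(NA_real_)
  if (any(x <= 0)) stop("geometric_mean() requires strictly positive values")
  exp(mean(log(x)))
}

# Internal: stop with a classed condition so callers/tests can distinguish
# validation failures from other errors.
abort_mirogtt <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "mirogtt_error")))
}

# Internal: canonical OGTT sampling grid (minutes). Baseline is -1 min.
OGTT_TIMEPOINTS <- c(-1L, 10L, 30L, 60L, 180L)

# Internal: timepoints strictly between baseline and the 2 h diagnostic draw.
MID_OGTT_TIMEPOINTS <- c(10L, 30L, 60L)

# Names of the spike-in controls and their roles.
SPIKE_INS <- c(
  UniSp2 = "extraction", UniSp4 = "extraction", UniSp5 = "extraction",
  UniSp3 = "interplate_calibration", UniSp6 = "rt_control"
)

# Endogenous serum controls used by both normalization schemes.
ENDOGENOUS_CONTROLS <- c("miR-16-5p", "miR-23a-3p", "miR-486-5p")

# Haemolysis index pair: index = Ct(miR-23a-3p) - Ct(miR-451a).
HAEMOLYSIS_NUMERATOR <- "miR-23a-3p"
HAEMOLYSIS_DENOMINATOR <- "miR-451a"

#' Default analysis thresholds
#'
#' All decision thresholds used by the pipeline, collected in one place so
#' they are defaults rather than constants buried at call sites.
#'
#' @return named list:
#' \describe{
#'   \item{glucose_cfrd}{2 h glucose at or above which CFRD is called (mmol/l).}
#'   \item{glucose_igt_lower}{2 h glucose at or above which IGT is called (mmol/l).}
#'   \item{haemolysis_max}{haemolysis index must be strictly below this (Ct cycles).}
#'   \item{unisp6_max}{UniSp6 Ct strictly above this fails RT inhibition (cycles).}
#'   \item{extraction_max_range}{per-spike-in Ct range strictly above this fails
#'     extraction consistency (cycles).}
#'   \item{volcano_fold}{fold-change cut-off for qPCR volcano class (inclusive).}
#'   \item{response_fold}{fold-change cut-off for the count-based response volcano.}
#'   \item{alpha}{significance level for volcano classes.}
#'   \item{expressed_min_count}{normalized count must be strictly above this.}
#'   \item{expressed_min_fraction}{in at least this fraction of samples (inclusive).}
#'   \item{pseudocount}{added to normalized counts before log-ratios.}
#' }
#' @export
default_thresholds <- function() {
  list(
    glucose_cfrd = 11.1,
    glucose_igt_lower = 7.8,
    haemolysis_max = 7,
    unisp6_max = 23,
    extraction_max_range = 3,
    volcano_fold = 1.5,
    response_fold = 2.0,
    alpha = 0.05,
    expressed_min_count = 5,
    expressed_min_fraction = 0.5,
    pseudocount = 0.5
  )
}
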
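#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. The defaults emulate
#' the study conditions the analysis assumes: four glucose-tolerance groups
#' with the qPCR-cohort sizes (NGT 18, INDET 6, IGT 12, CFRD 14), OGTT
#' sampling at -1, 10, 30, 60 and 180 min plus a separate 120 min diagnostic
#' glucose, a 16-miRNA qPCR panel with three endogenous controls and the five
#' UniSp spike-ins laid out on plates, and negative-binomial counts for the
#' sequencing arm (twelve participants, three per group, baseline and 60 min).
#'
#' @param n_per_group named integer vector over NGT, INDET, IGT, CFRD.
#' @param timepoints OGTT sampling grid in minutes.
#' @param plate_size samples per qPCR plate.
#' @param plate_offset_sd SD of the per-plate Ct offset (cycles).
#' @param ct_noise_sd SD of per-well Ct noise (cycles). Noise is truncated at
#'   3 SD so that injected QC artifacts sit unambiguously across their gates.
#' @param baseline_log2fc data frame (`mirna`, `group`, `log2fc`): log2 fold
#'   change vs the NGT baseline level, applied at every timepoint.
#' @param response_log2fc data frame (`mirna`, `group`, `log2fc`): additional
#'   log2 change from baseline to the 60 min sample.
#' @param haemolysis_fraction,inhibition_fraction proportion of samples given
#'   a haemolysis / RT-inhibition artifact.
#' @param nb_dispersion negative-binomial dispersion of the count arm
#'   (variance = mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param library_size_range range of per-sample library sizes (reads).
#' @param n_null_mirna number of null (no-effect) miRNAs in the count arm.
#' @param candidate_abundance counts-per-million abundance given to miRNAs
#'   named in an effect map. Candidate biomarker miRNAs in serum are among
#'   the most abundant species, so they sit near the top of the abundance
#'   distribution rather than being drawn from it.
#' @param analyte_coupling data frame (`mirna`, `analyte`, `rho`): target
#'   Spearman correlation, realized through a Gaussian copula between a
#'   per-participant miRNA level offset and the analyte.
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return object of class `mirogtt_sim_config`.
#' @export
sim_config <- function(n_per_group = c(NGT = 18, INDET = 6, IGT = 12, CFRD = 14),
                       timepoints = c(-1, 10, 30, 60, 180),
                       plate_size = 15,
                       plate_offset_sd = 0.25,
                       ct_noise_sd = 0.2,
                       baseline_log2fc = NULL,
                       response_log2fc = NULL,
                       haemolysis_fraction = 0.1,
                       inhibition_fraction = 0.05,
                       nb_dispersion = 0.1,
                       library_size_range = c(8e5, 1.2e6),
                       n_null_mirna = 200,
                       candidate_abundance = 2000,
                       analyte_coupling = NULL,
                       seed = 1L) {
  stopifnot(all(GROUP_LEVELS %in% names(n_per_group)), all(n_per_group >= 0))
  if (!any(n_per_group > 0)) {
    abort_mirogtt("empty cohort: all group sizes are zero", "mirogtt_validation")
  }
  if (haemolysis_fraction < 0 || haemolysis_fraction > 1 ||
      inhibition_fraction < 0 || inhibition_fraction > 1) {
    abort_mirogtt("artifact fractions must lie in [0, 1]", "mirogtt_validation")
  }
  if (plate_offset_sd < 0 || ct_noise_sd < 0 || nb_dispersion < 0) {
    abort_mirogtt("standard deviations and dispersion must be >= 0",
                  "mirogtt_validation")
  }
  check_effect_map <- function(m, what) {
    if (is.null(m)) return(invisible(NULL))
    if (!all(c("mirna", "group", "log2fc") %in% names(m))) {
      abort_mirogtt(sprintf("%s needs columns mirna, group, log2fc", what),
                    "mirogtt_validation")
    }
  }
  check_effect_map(baseline_log2fc, "baseline_log2fc")
  check_effect_map(response_log2fc, "response_log2fc")
  if (!is.null(analyte_coupling)) {
    if (!all(c("mirna", "analyte", "rho") %in% names(analyte_coupling)) ||
        any(abs(analyte_coupling$rho) > 1)) {
      abort_mirogtt("analyte_coupling needs columns mirna, analyte, rho with |rho| <= 1",
                    "mirogtt_validation")
    }
  }
  structure(list(
    n_per_group = n_per_group[GROUP_LEVELS],
    timepoints = timepoints,
    plate_size = plate_size,
    plate_offset_sd = plate_offset_sd,
    ct_noise_sd = ct_noise_sd,
    baseline_log2fc = baseline_log2fc,
    response_log2fc = response_log2fc,
    haemolysis_fraction = haemolysis_fraction,
    inhibition_fraction = inhibition_fraction,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    n_null_mirna = n_null_mirna,
    candidate_abundance = candidate_abundance,
    analyte_coupling = analyte_coupling,
    seed = as.integer(seed)
  ), class = "mirogtt_sim_config")
}

# qPCR panel: candidate miRNAs assayed across the OGTT. miR-451a doubles as
# the haemolysis indicator.
QPCR_PANEL <- c("miR-28-3p", "miR-34a-5p", "miR-122-5p", "miR-127-3p",
                "miR-134-5p", "miR-223-3p", "miR-223-5p", "miR-224-5p",
                "miR-363-3p", "miR-382-5p", "miR-409-3p", "miR-432-5p",
                "miR-451a", "miR-885-3p", "miR-885-5p", "miR-1301-3p")

# Baseline Ct anchors (cycles) for controls, panel targets and spike-ins.
# Chosen so the haemolysis index sits at 5 cycles (2 below the gate) and
# UniSp6 at 20 cycles (3 below the gate) in clean samples.
CT_ANCHORS <- list(
  controls = c("miR-16-5p" = 20, "miR-23a-3p" = 23, "miR-486-5p" = 21),
  mir451a = 18,
  target_dct_range = c(1, 7),       # target Ct minus control mean, clean NGT
  spikeins = c(UniSp2 = 19, UniSp3 = 21, UniSp4 = 17.5, UniSp5 = 21.5,
               UniSp6 = 20),
  haemolysis_shift = -4,            # applied to miR-451a: index 5 -> 9
  inhibition_shift = 4.5            # applied to UniSp6: 20 -> 24.5
)

# Clinical analyte distributions per group: mean and [min, max] at baseline.
ANALYTE_TABLE <- local({
  tab <- list(
    GGT  = list(NGT = c(21.8, 10, 100),  INDET = c(97.2, 10, 238),
                IGT = c(37.0, 7, 190),   CFRD = c(105.7, 9, 767)),
    ALP  = list(NGT = c(94.5, 62, 157),  INDET = c(167.0, 55, 336),
                IGT = c(112.3, 61, 335), CFRD = c(161.6, 49, 391)),
    ALAT = list(NGT = c(31.8, 14, 72),   INDET = c(31.5, 15, 54),
                IGT = c(28.5, 12, 57),   CFRD = c(68.7, 16, 278)),
    ASAT = list(NGT = c(27.7, 17, 47),   INDET = c(38.2, 16, 60),
                IGT = c(30.9, 19, 75),   CFRD = c(39.3, 18, 118)),
    CRP  = list(NGT = c(2.9, 1, 12),     INDET = c(2.0, 1, 7),
                IGT = c(3.8, 1, 19),     CFRD = c(5.4, 1, 36)),
    LPK  = list(NGT = c(6.9, 4.3, 10.2), INDET = c(5.6, 3.9, 7.6),
                IGT = c(7.0, 3.7, 10.1), CFRD = c(7.7, 2.5, 14.9))
  )
  tab
})

# Group-level OGTT glucose trajectory means (mmol/l) at -1/10/30/60/180 min,
# plus the safe sampling band for the 2 h diagnostic glucose. Bands keep a
# 0.3 mmol/l margin to every classification threshold so that jittered
# trajectories always reclassify to the intended group.
GLUCOSE_PROFILES <- list(
  NGT   = list(traj = c(5.3, 6.5, 8.3, 8.8, 5.5),  g120 = c(5.0, 7.4)),
  INDET = list(traj = c(5.4, 7.0, 10.0, 10.5, 6.0), g120 = c(5.0, 7.4),
               peak = c(11.5, 14.0)),
  IGT   = list(traj = c(5.5, 7.0, 9.3, 10.0, 7.3),  g120 = c(8.2, 10.7)),
  CFRD  = list(traj = c(7.7, 9.5, 12.5, 14.0, 11.0), g120 = c(11.5, 16.0))
)

# Baseline fasting insulin means (pmol/l) and OGTT fold-trajectory per group.
INSULIN_PROFILES <- list(
  NGT   = list(base = 47.4, mult = c(1, 2.2, 4.5, 5.0, 1.4)),
  INDET = list(base = 47.4, mult = c(1, 1.8, 3.5, 4.0, 1.5)),
  IGT   = list(base = 31.9, mult = c(1, 1.6, 3.0, 3.6, 1.8)),
  CFRD  = list(base = 37.8, mult = c(1, 1.2, 2.0, 2.6, 1.8))
)

# Truncated-normal draw (vectorized), truncation at +/- k SD.
rtnorm <- function(n, mean = 0, sd = 1, k = 3) {
  if (sd == 0) return(rep(mean, n))
  u <- stats::runif(n, stats::pnorm(-k), stats::pnorm(k))
  mean + sd * stats::qnorm(u)
}

#' Simulate a cohort of participants
#'
#' Draws, per glucose-tolerance group: OGTT glucose trajectories whose
#' classification by [classify_glucose_tolerance()] reproduces the intended
#' group by construction; insulin series; clinical analytes within their
#' per-group observed ranges; and per-participant miRNA level offsets coupled
#' to designated analytes through a Gaussian copula at the configured
#' Spearman strength.
#'
#' @param config a [sim_config()].
#' @return object of class `mirogtt_cohort`: list with `participants` (wide
#'   per-participant table incl. analytes and `glucose_120_mmol_l`),
#'   `samples` (long participant x timepoint glucose/insulin sheet) and
#'   `mirna_offsets` (participants x coupled-miRNA matrix of log2 offsets).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mirogtt_sim_config"))
  if (sum(config$n_per_group) == 0) {
    abort_mirogtt("empty cohort: all group sizes are zero", "mirogtt_validation")
  }
  set.seed(config$seed)
  tps <- config$timepoints
  rows <- list(); prof_rows <- list()
  for (grp in GROUP_LEVELS) {
    n <- config$n_per_group[[grp]]
    if (n == 0) next
    gp <- GLUCOSE_PROFILES[[grp]]
    ids <- sprintf("%s%03d", grp, seq_len(n))
    for (i in seq_len(n)) {
      gl <- gp$traj + rtnorm(length(tps), 0, 0.4)
      names(gl) <- tps
      # keep every sampled value clear of the 11.1 mmol/l mid-OGTT trigger
      # except where the group definition requires it
      if (grp %in% c("NGT", "IGT", "INDET")) gl <- pmin(gl, 10.8)
      gl <- pmax(gl, 3.5)
      if (grp == "INDET") {
        peak_tp <- sample(c("30", "60"), 1)
        gl[peak_tp] <- stats::runif(1, gp$peak[1], gp$peak[2])
      }
      if (grp == "CFRD") {
        gl[c("30", "60")] <- pmax(gl[c("30", "60")], 9)
      }
      g120 <- stats::runif(1, gp$g120[1], gp$g120[2])
      ip <- INSULIN_PROFILES[[grp]]
      ins <- ip$base * ip$mult * exp(rtnorm(length(tps), 0, 0.25))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = ids[i], timepoint_min = as.integer(tps),
        glucose_mmol_l = round(unname(gl), 2),
        insulin_pmol_l = round(unname(ins), 1),
        stringsAsFactors = FALSE)
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        participant_id = ids[i], group = grp,
        sex = sample(c("male", "female"), 1),
        age = round(stats::runif(1, 18, 53)),
        glucose_120_mmol_l = round(g120, 2),
        stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  participants <- do.call(rbind, prof_rows)

  # analytes + copula-coupled per-participant miRNA offsets
  coup <- config$analyte_coupling
  coup_mirnas <- if (is.null(coup)) character(0) else unique(coup$mirna)
  offsets <- matrix(0, nrow(participants), length(coup_mirnas),
                    dimnames = list(participants$participant_id, coup_mirnas))
  z_mir <- matrix(stats::rnorm(nrow(participants) * length(coup_mirnas)),
                  nrow(participants),
                  dimnames = list(NULL, coup_mirnas))
  if (length(coup_mirnas)) {
    # miRNA offset: log2-scale level shift, SD 0.5 cycles
    offsets[] <- 0.5 * z_mir
  }
  for (an in names(ANALYTE_TABLE)) {
    z <- stats::rnorm(nrow(participants))
    if (!is.null(coup) && an %in% coup$analyte) {
      row <- coup[coup$analyte == an, ][1, ]
      r <- 2 * sin(pi * row$rho / 6)  # Spearman -> Pearson under the copula
      z <- r * z_mir[, row$mirna] + sqrt(1 - r^2) * z
    }
    u <- stats::pnorm(z)
    vals <- numeric(nrow(participants))
    for (grp in GROUP_LEVELS) {
      sel <- participants$group == grp
      if (!any(sel)) next
      par <- ANALYTE_TABLE[[an]][[grp]]
      m <- (par[1] - par[2]) / (par[3] - par[2])
      m <- min(max(m, 0.05), 0.95)
      a <- 2 * m; b <- 2 * (1 - m)
      vals[sel] <- par[2] + (par[3] - par[2]) * stats::qbeta(u[sel], a, b)
    }
    participants[[an]] <- round(vals, 1)
  }
  structure(list(participants = participants, samples = samples,
                 mirna_offsets = offsets, config = config),
            class = "mirogtt_cohort")
}

#' Simulate RT-qPCR plates for a cohort
#'
#' Generates long-format Ct records for the 16-miRNA panel, the three
#' endogenous controls and the five spike-ins, one sample per participant x
#' timepoint, laid out on plates of `plate_size` samples. Endogenous controls
#' carry no group or timepoint effect. Target Cts are anchored to the control
#' mean as delta-Ct offsets minus the injected log2 effects (baseline effects
#' at every timepoint, response effects at 60 min) minus any per-participant
#' copula offset, plus the plate offset and truncated Gaussian well noise.
#' Haemolysis artifacts lower miR-451a so the haemolysis index lands above
#' the gate; RT-inhibition artifacts raise UniSp6 above its gate.
#'
#' @param cohort a `mirogtt_cohort` from [simulate_cohort()].
#' @param config the same [sim_config()].
#' @return list: `ct_records` (long Ct data frame) and `truth` (data frame of
#'   per-sample artifact labels `haemolysed`, `inhibited`).
#' @export
simulate_ct_plates <- function(cohort, config = cohort$config) {
  stopifnot(inherits(cohort, "mirogtt_cohort"))
  if (nrow(cohort$participants) == 0) {
    abort_mirogtt("cohort has no participants", "mirogtt_validation")
  }
  set.seed(config$seed + 1L)
  meta <- merge(cohort$samples[, c("participant_id", "timepoint_min")],
                cohort$participants[, c("participant_id", "group")],
                by = "participant_id", sort = FALSE)
  meta <- meta[order(match(meta$participant_id,
                           cohort$participants$participant_id),
                     meta$timepoint_min), ]
  n_samp <- nrow(meta)
  meta$plate_id <- sprintf("plate%02d",
                           ceiling(seq_len(n_samp) / config$plate_size))
  plates <- unique(meta$plate_id)
  plate_off <- stats::setNames(rtnorm(length(plates), 0, config$plate_offset_sd),
                               plates)
  meta$haemolysed <- stats::runif(n_samp) < config$haemolysis_fraction
  meta$inhibited <- stats::runif(n_samp) < config$inhibition_fraction

  assays <- c(names(CT_ANCHORS$controls),
              setdiff(QPCR_PANEL, HAEMOLYSIS_DENOMINATOR),
              HAEMOLYSIS_DENOMINATOR, names(CT_ANCHORS$spikeins))
  targets <- setdiff(QPCR_PANEL, HAEMOLYSIS_DENOMINATOR)
  ctrl_mean <- mean(CT_ANCHORS$controls)
  dct <- stats::setNames(
    seq(CT_ANCHORS$target_dct_range[1], CT_ANCHORS$target_dct_range[2],
        length.out = length(targets)),
    targets)

  effect_lookup <- function(map, mirna, group) {
    if (is.null(map)) return(0)
    hit <- map$mirna == mirna & map$group == group
    if (any(hit)) sum(map$log2fc[hit]) else 0
  }
  off_mat <- cohort$mirna_offsets

  rec <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    grp <- meta$group[s]; tp <- meta$timepoint_min[s]
    pid <- meta$participant_id[s]
    base <- numeric(length(assays)); names(base) <- assays
    base[names(CT_ANCHORS$controls)] <- CT_ANCHORS$controls
    base[HAEMOLYSIS_DENOMINATOR] <- CT_ANCHORS$mir451a
    base[names(CT_ANCHORS$spikeins)] <- CT_ANCHORS$spikeins
    for (m in targets) {
      eff <- effect_lookup(config$baseline_log2fc, m, grp)
      if (tp == 60) eff <- eff + effect_lookup(config$response_log2fc, m, grp)
      if (m %in% colnames(off_mat)) eff <- eff + off_mat[pid, m]
      base[m] <- ctrl_mean + dct[m] - eff
    }
    # artifacts occupy the gate's failing side with margin > 3 noise SDs
    if (meta$haemolysed[s]) {
      base[HAEMOLYSIS_DENOMINATOR] <- base[HAEMOLYSIS_DENOMINATOR] +
        CT_ANCHORS$haemolysis_shift
    }
    if (meta$inhibited[s]) {
      base["UniSp6"] <- base["UniSp6"] + CT_ANCHORS$inhibition_shift
    }
    ct <- base + plate_off[meta$plate_id[s]] +
      rtnorm(length(base), 0, config$ct_noise_sd)
    rec[[s]] <- data.frame(participant_id = pid, timepoint_min = tp,
                           plate_id = meta$plate_id[s], assay_id = assays,
                           ct = unname(ct),
                           stringsAsFactors = FALSE)
  }
  list(ct_records = do.call(rbind, rec),
       truth = meta[, c("participant_id", "timepoint_min",
                        "haemolysed", "inhibited")])
}

#' Simulate a paired small-RNA count matrix
#'
#' Builds a miRNA x sample count matrix for a subset of participants at the
#' baseline (-1 min) and 60 min timepoints, mirroring a paired sequencing
#' design. Counts are negative binomial with mean
#' `library_size x abundance x participant factor x 2^(injected effects)`;
#' the per-participant lognormal factor encodes the pairing.
#'
#' @inheritParams simulate_ct_plates
#' @param n_per_group participants taken from each group (default 3, the
#'   three-per-category sequencing design).
#' @return list: `counts` (integer matrix, miRNAs x samples), `meta` (sample
#'   data frame: `sample_id`, `participant_id`, `timepoint_min`, `group`).
#' @export
simulate_counts <- function(cohort, config = cohort$config, n_per_group = 3) {
  stopifnot(inherits(cohort, "mirogtt_cohort"))
  set.seed(config$seed + 2L)
  sel <- do.call(rbind, lapply(GROUP_LEVELS, function(grp) {
    p <- cohort$participants[cohort$participants$group == grp, ]
    utils::head(p, n_per_group)
  }))
  meta <- expand.grid(timepoint_min = c(-1L, 60L),
                      participant_id = sel$participant_id,
                      stringsAsFactors = FALSE)[, 2:1]
  meta$group <- sel$group[match(meta$participant_id, sel$participant_id)]
  meta$sample_id <- paste0(meta$participant_id, "_t", meta$timepoint_min)

  effect_names <- unique(c(
    if (!is.null(config$baseline_log2fc)) config$baseline_log2fc$mirna,
    if (!is.null(config$response_log2fc)) config$response_log2fc$mirna))
  mirnas <- c(effect_names,
              sprintf("null-mir-%03d", seq_len(config$n_null_mirna)))
  abundance <- exp(stats::rnorm(length(mirnas), log(100), 1.2))
  names(abundance) <- mirnas
  abundance[effect_names] <- config$candidate_abundance
  part_factor <- exp(stats::rnorm(nrow(sel), 0, 0.3))
  names(part_factor) <- sel$participant_id
  libsize <- stats::runif(nrow(meta), config$library_size_range[1],
                          config$library_size_range[2])

  effect_lookup <- function(map, mirna, group) {
    if (is.null(map)) return(0)
    hit <- map$mirna == mirna & map$group == group
    if (any(hit)) sum(map$log2fc[hit]) else 0
  }
  counts <- matrix(0L, length(mirnas), nrow(meta),
                   dimnames = list(mirnas, meta$sample_id))
  for (j in seq_len(nrow(meta))) {
    grp <- meta$group[j]; tp <- meta$timepoint_min[j]
    l2 <- vapply(mirnas, function(m) {
      e <- effect_lookup(config$baseline_log2fc, m, grp)
      if (tp == 60) e <- e + effect_lookup(config$response_log2fc, m, grp)
      e
    }, numeric(1))
    mu <- (libsize[j] / 1e6) * abundance *
      part_factor[meta$participant_id[j]] * 2^l2
    counts[, j] <- if (config$nb_dispersion == 0) {
      stats::rpois(length(mu), mu)
    } else {
      stats::rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion)
    }
  }
  list(counts = counts, meta = meta)
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: cohort, qPCR plates and count arm in one call, with
#' the injected truth collected alongside.
#'
#' @inheritParams simulate_cohort
#' @return list with `cohort`, `ct_records`, `counts`, `meta` and `truth`
#'   (artifact labels, effect maps and per-participant miRNA offsets).
#' @export
simulate_dataset <- function(config) {
  cohort <- simulate_cohort(config)
  plates <- simulate_ct_plates(cohort, config)
  cnt <- simulate_counts(cohort, config)
  list(cohort = cohort,
       ct_records = plates$ct_records,
       counts = cnt$counts,
       meta = cnt$meta,
       truth = list(artifacts = plates$truth,
                    baseline_log2fc = config$baseline_log2fc,
                    response_log2fc = config$response_log2fc,
                    mirna_offsets = cohort$mirna_offsets))
}
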
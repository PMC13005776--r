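groups2 <- data.frame(participant_id = c("P1", "P2", "P3", "P4"),
                      group = c("NGT", "NGT", "CFRD", "CFRD"))

test_that("control-mean delta-Ct is the target Ct minus the control mean", {
  rec <- make_sample_records(targets = c("miR-122-5p" = 25),
                             ctrl16 = 20, ctrl23a = 21, ctrl486 = 22)
  expr <- normalize_control_mean(rec, data.frame(participant_id = "P1",
                                                 group = "NGT"))
  expect_equal(expr$delta_ct[expr$mirna == "miR-122-5p"], 4.0)
  # target at the control mean has delta-Ct 0 and relative expression 1
  rec2 <- make_sample_records(targets = c("miR-122-5p" = 21),
                              ctrl16 = 20, ctrl23a = 21, ctrl486 = 22)
  expr2 <- normalize_control_mean(rec2, data.frame(participant_id = "P1",
                                                   group = "NGT"))
  expect_equal(expr2$delta_ct[expr2$mirna == "miR-122-5p"], 0)
  expect_equal(expr2$rel_expr[expr2$mirna == "miR-122-5p"], 1)
})

test_that("delta-Ct is invariant to adding one cycle to every assay of a sample", {
  rec <- make_sample_records(targets = c("miR-122-5p" = 25))
  shifted <- rec; shifted$ct <- shifted$ct + 1
  g <- data.frame(participant_id = "P1", group = "NGT")
  expect_equal(normalize_control_mean(shifted, g)$delta_ct,
               normalize_control_mean(rec, g)$delta_ct)
})

test_that("samples with an undetected control are dropped with a reason", {
  rec <- rbind(make_sample_records("P1", ctrl16 = NA),
               make_sample_records("P2"))
  g <- data.frame(participant_id = c("P1", "P2"), group = c("NGT", "NGT"))
  expr <- normalize_control_mean(rec, g)
  expect_false("P1" %in% expr$participant_id)
  dropped <- attr(expr, "dropped")
  expect_equal(dropped$participant_id, "P1")
  expect_equal(dropped$reason, "control_undetected")
})

test_that("delta-delta-Ct anchors the NGT baseline at fold 1 and inverts injected effects", {
  # geometric mean of fold over NGT baseline samples is exactly 1
  rec <- rbind(
    make_sample_records("P1", targets = c("miR-122-5p" = 25.0)),
    make_sample_records("P2", targets = c("miR-122-5p" = 26.0)),
    make_sample_records("P3", targets = c("miR-122-5p" = 24.0)),
    make_sample_records("P4", targets = c("miR-122-5p" = 24.5)))
  expr <- normalize_ddct(rec, groups2)
  ngt_base <- expr$group == "NGT" & expr$timepoint_min == -1
  expect_equal(exp(mean(log(expr$fold[ngt_base]))), 1)
  expect_equal(expr$fold, 2^(-expr$ddct))

  # the reference subtraction: P3's target sits 1.5 cycles below the NGT
  # baseline mean, so ddct = -1.5 and fold = 2^1.5
  one <- expr[expr$participant_id == "P3" & expr$mirna == "miR-122-5p", ]
  expect_equal(one$ddct, 24 - mean(c(25, 26)), tolerance = 1e-12)
  expect_equal(one$fold, 2^1.5, tolerance = 1e-12)
})

test_that("injected baseline effects are recovered exactly with zero noise", {
  cfg <- sim_config(seed = 31, ct_noise_sd = 0, plate_offset_sd = 0,
                    haemolysis_fraction = 0, inhibition_fraction = 0,
                    n_per_group = c(NGT = 4, INDET = 4, IGT = 4, CFRD = 4),
                    baseline_log2fc = data.frame(mirna = "miR-122-5p",
                                                 group = "CFRD", log2fc = 1))
  co <- simulate_cohort(cfg)
  pl <- simulate_ct_plates(co, cfg)
  grp <- co$participants[, c("participant_id", "group")]
  expr <- normalize_ddct(pl$ct_records, grp)
  cfrd <- expr$mirna == "miR-122-5p" & expr$group == "CFRD" &
    expr$timepoint_min == -1
  expect_equal(mean(expr$fold[cfrd]), 2.0, tolerance = 1e-9)
})

test_that("volcano classifies at the 1.5-fold (inclusive) and p < 0.05 cut-offs", {
  set.seed(42)
  # group shifted by exactly -log2(1.5) cycles: fold is exactly 1.5
  a <- rnorm(6, 5, 0.01)
  b <- a - log2(1.5000001)  # nudged above the cut-off: fold 1.5 to 7 digits
  expr <- data.frame(
    participant_id = paste0("P", 1:12),
    timepoint_min = 30,
    group = rep(c("NGT", "CFRD"), each = 6),
    mirna = "miR-223-3p",
    delta_ct = c(a, b))
  expr$rel_expr <- 2^(-expr$delta_ct)
  res <- volcano_per_timepoint(expr, "CFRD", "NGT", 30)
  expect_equal(res$fold, 1.5, tolerance = 1e-6)
  expect_lt(res$p, 0.05)
  expect_equal(res$volcano_class, "up")

  # just inside the cut-off flips to ns even at small p
  expr_ns <- expr
  expr_ns$delta_ct[expr_ns$group == "CFRD"] <- a - log2(1.49)
  expr_ns$rel_expr <- 2^(-expr_ns$delta_ct)
  res_ns <- volcano_per_timepoint(expr_ns, "CFRD", "NGT", 30)
  expect_lt(res_ns$p, 0.05)
  expect_equal(res_ns$volcano_class, "ns")

  # identical groups: fold 1, ns
  expr_id <- expr
  expr_id$delta_ct <- rep(a, 2)
  expr_id$rel_expr <- 2^(-expr_id$delta_ct)
  res_id <- volcano_per_timepoint(expr_id, "CFRD", "NGT", 30)
  expect_equal(res_id$fold, 1)
  expect_equal(res_id$volcano_class, "ns")

  # swapping the group labels maps up to down with the same p
  res_swap <- volcano_per_timepoint(expr, "NGT", "CFRD", 30)
  expect_equal(res_swap$p, res$p)
  expect_equal(res_swap$volcano_class, "down")
  expect_equal(res_swap$fold, 1 / res$fold, tolerance = 1e-9)
})

test_that("a group with fewer than two samples is skipped with a reason", {
  expr <- data.frame(participant_id = c("P1", "P2", "P3"),
                     timepoint_min = 30, group = c("NGT", "NGT", "CFRD"),
                     mirna = "miR-122-5p", delta_ct = c(4, 5, 3))
  expr$rel_expr <- 2^(-expr$delta_ct)
  res <- volcano_per_timepoint(expr, "CFRD", "NGT", 30)
  expect_true(is.na(res$p))
  expect_equal(res$skip_reason, "fewer_than_2_samples_per_group")
})

test_that("baseline ANOVA detects separation and respects exchangeability under the null", {
  set.seed(7)
  mk_expr <- function(shift_cfrd = 0, n = 10) {
    data.frame(participant_id = paste0("P", 1:(4 * n)), timepoint_min = -1,
               group = rep(GROUP_LEVELS, each = n), mirna = "m",
               fold = 2^(rnorm(4 * n, 0, 0.3) +
                           rep(c(0, 0, 0, shift_cfrd), each = n)))
  }
  # two groups separated by ~5 pooled SD -> overwhelming evidence
  strong <- baseline_group_anova(mk_expr(shift_cfrd = 1.5), "m")
  expect_lt(strong$omnibus_p, 0.001)
  expect_equal(nrow(strong$tukey), 6)
  cfrd_ngt <- strong$tukey[strong$tukey$contrast == "CFRD-NGT", ]
  expect_lt(cfrd_ngt$p_adj, 0.01)

  # null simulation: one-way ANOVA p < 0.05 in about 5% of replicates
  hits <- vapply(1:200, function(i) {
    baseline_group_anova(mk_expr(0, n = 5), "m")$omnibus_p < 0.05
  }, logical(1))
  se <- sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(mean(hits) - 0.05), 2.58 * se + 1e-9)

  expect_error(
    baseline_group_anova(data.frame(participant_id = paste0("P", 1:8),
                                    timepoint_min = -1,
                                    group = rep(c("NGT", "CFRD"), each = 4),
                                    mirna = "m", fold = rep(c(1, 2), each = 4)),
                         "m"),
    class = "mirogtt_degenerate")
})

test_that("mixed-model fixed effects match OLS on balanced complete data", {
  set.seed(11)
  d <- expand.grid(participant_id = paste0("P", 1:16),
                   timepoint_min = c(-1, 10, 30, 60, 180))
  d$group <- rep(rep(GROUP_LEVELS, each = 4), 5)
  u <- rnorm(16, 0, 0.5)
  d$ddct <- -(rnorm(nrow(d), 0, 0.4) + u[as.integer(factor(d$participant_id))])
  d$mirna <- "m"
  res <- dynamic_mixed_effects(d, "m")
  lm_fit <- lm(y ~ group * timepoint,
               data = transform(d, y = -ddct,
                                group = factor(group, levels = unique(GROUP_LEVELS)),
                                timepoint = factor(timepoint_min,
                                                   levels = sort(unique(timepoint_min)))))
  expect_equal(unname(lme4::fixef(res$fit)), unname(coef(lm_fit)),
               tolerance = 1e-6)
  expect_equal(nrow(res$contrasts), 6 * 5)  # 6 pairs x 5 timepoints
})

test_that("a timepoint-specific group shift is found by the matching contrast", {
  # IGT shifted at 30 min only: the 30-min IGT contrasts carry the signal
  hits <- vapply(1:25, function(s) {
    set.seed(400 + s)
    d <- expand.grid(participant_id = paste0("P", 1:48),
                     timepoint_min = c(-1, 10, 30, 60, 180))
    d$group <- rep(rep(GROUP_LEVELS, each = 12), 5)
    u <- rnorm(48, 0, 0.3)
    d$ddct <- -(rnorm(nrow(d), 0, 0.4) + u[as.integer(factor(d$participant_id))] +
                  1 * (d$group == "IGT" & d$timepoint_min == 30))
    d$mirna <- "m"
    ct <- dynamic_mixed_effects(d, "m")$contrasts
    best <- ct[which.min(ct$p), ]
    best$timepoint_min == 30 && grepl("IGT", best$contrast)
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
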
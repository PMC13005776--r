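test_that("median-of-ratios size factors satisfy the scaling identities", {
  set.seed(1)
  m <- matrix(rnbinom(200 * 6, mu = 100, size = 5), 200, 6,
              dimnames = list(sprintf("mir%03d", 1:200), paste0("s", 1:6)))
  m[m == 0] <- 1
  # sample 2 = exactly 2 x sample 1
  m2 <- cbind(m[, 1, drop = FALSE], 2L * m[, 1, drop = FALSE], m[, 3:6])
  colnames(m2) <- paste0("s", 1:6)
  sf <- size_factors_median_of_ratios(m2)
  expect_equal(sf[2] / sf[1], 2)

  # identical samples: all factors equal
  m3 <- m[, c(1, 1, 1, 1)]
  sf3 <- size_factors_median_of_ratios(m3)
  expect_equal(sf3, rep(sf3[1], 4))

  # size factors are defined up to a common scale (the per-feature geometric
  # mean moves too): scaling one sample by 10 multiplies its factor by 10
  # relative to every other sample's
  sf_base <- size_factors_median_of_ratios(m)
  m10 <- m; m10[, 3] <- m[, 3] * 10
  sf10 <- size_factors_median_of_ratios(m10)
  expect_equal(sf10[3] / sf10[-3], 10 * sf_base[3] / sf_base[-3],
               tolerance = 1e-10)
})

test_that("size factors agree with the established NB-normalization implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(2)
  m <- matrix(rnbinom(300 * 8, mu = 80, size = 3) + 1L, 300, 8)
  expect_equal(size_factors_median_of_ratios(m),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("all-zero-somewhere matrices need the documented pseudo-reference switch", {
  m <- matrix(c(0, 5, 5, 5, 5, 0, 5, 5), 2, 4, byrow = TRUE)
  expect_error(size_factors_median_of_ratios(m), class = "mirogtt_size_factors")
  expect_length(size_factors_median_of_ratios(m, pseudo_reference = TRUE), 4)
})

test_that("the expressed filter requires > 5 normalized counts in >= 50% of samples", {
  m <- rbind(retained = c(6, 6, 1, 1),
             dropped_low = c(6, 1, 1, 1),
             dropped_at5 = c(5, 5, 5, 5))
  expect_equal(filter_expressed(m), "retained")
})

test_that("BH adjustment matches brute-force step-up and its trivial identities", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (i in 1:25) {
    p <- round(runif(sample(2:6, 1)), 3)
    expect_equal(bh_fdr(p), bh_bruteforce(p))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mirogtt_validation")
  expect_error(bh_fdr(c(0.5, NA)), class = "mirogtt_validation")
})

make_paired_counts <- function(tab, groups) {
  # tab: list per participant of c(n0, n60); stable filler miRNAs keep size
  # factors at 1
  pids <- names(tab)
  meta <- data.frame(
    sample_id = c(rbind(paste0(pids, "_t-1"), paste0(pids, "_t60"))),
    participant_id = rep(pids, each = 2),
    timepoint_min = rep(c(-1L, 60L), length(pids)),
    group = rep(groups, each = 2))
  filler <- matrix(rep(c(100, 200, 400, 800, 1600, 3200, 6400, 12800, 25600, 51200),
                       nrow(meta)), 10, nrow(meta),
                   dimnames = list(sprintf("stable%02d", 1:10), meta$sample_id))
  target <- matrix(unlist(tab), 1, nrow(meta),
                   dimnames = list("target", meta$sample_id))
  list(counts = rbind(filler, target), meta = meta)
}

test_that("the paired response statistic equals the difference-of-differences oracle", {
  # 2 participants per group, equal size factors by construction
  x <- make_paired_counts(list(N1 = c(100, 100), N2 = c(50, 100),
                               C1 = c(100, 400), C2 = c(200, 400)),
                          c("NGT", "NGT", "CFRD", "CFRD"))
  res <- differential_response(x$counts, x$meta, "CFRD", filter = FALSE)
  # exhaustive arithmetic with pseudocount 0.5
  r <- function(n0, n60) log2((n60 + 0.5) / (n0 + 0.5))
  oracle <- mean(c(r(100, 400), r(200, 400))) - mean(c(r(100, 100), r(50, 100)))
  expect_equal(res$effect[res$mirna == "target"], oracle, tolerance = 1e-10)
})

test_that("identical responses across groups give a zero effect and z", {
  # both groups see the same pair of per-participant count trajectories
  x <- make_paired_counts(list(N1 = c(100, 200), N2 = c(50, 100),
                               C1 = c(100, 200), C2 = c(50, 100)),
                          c("NGT", "NGT", "CFRD", "CFRD"))
  res <- differential_response(x$counts, x$meta, "CFRD", filter = FALSE)
  tgt <- res[res$mirna == "target", ]
  expect_equal(tgt$effect, 0, tolerance = 1e-10)
  expect_equal(tgt$z, 0, tolerance = 1e-8)
})

test_that("exchanging the timepoint labels negates every effect with p unchanged", {
  cfg <- sim_config(seed = 19, n_per_group = c(NGT = 3, INDET = 3, IGT = 3, CFRD = 3),
                    nb_dispersion = 0.05, n_null_mirna = 60,
                    response_log2fc = data.frame(mirna = "miR-223-3p",
                                                 group = "CFRD", log2fc = 1))
  co <- simulate_cohort(cfg)
  cn <- simulate_counts(co, cfg)
  res <- differential_response(cn$counts, cn$meta, "CFRD")
  meta_sw <- cn$meta
  meta_sw$timepoint_min <- ifelse(meta_sw$timepoint_min == -1, 60L, -1L)
  res_sw <- differential_response(cn$counts, meta_sw, "CFRD")
  expect_equal(res_sw$effect, -res$effect)
  expect_equal(res_sw$p, res$p)
})

test_that("groups with fewer than two participants are refused", {
  x <- make_paired_counts(list(N1 = c(100, 100), C1 = c(100, 100)),
                          c("NGT", "CFRD"))
  expect_error(differential_response(x$counts, x$meta, "CFRD"),
               class = "mirogtt_validation")
})

test_that("baseline DE ranks an injected shift first and ignores library scaling", {
  cfg <- sim_config(seed = 23, n_per_group = c(NGT = 3, INDET = 3, IGT = 3, CFRD = 3),
                    nb_dispersion = 0.005, n_null_mirna = 100,
                    baseline_log2fc = data.frame(mirna = "miR-122-5p",
                                                 group = "CFRD", log2fc = 1))
  co <- simulate_cohort(cfg)
  cn <- simulate_counts(co, cfg)
  res <- baseline_de(cn$counts, cn$meta, "CFRD")
  expect_equal(res$mirna[1], "miR-122-5p")
  expect_equal(res$log2fc[1], 1, tolerance = 0.35)

  # doubling every library of one group is removed by normalization up to
  # the pseudocount's interaction with the arbitrary size-factor scale
  cnt2 <- cn$counts
  cfrd_cols <- cn$meta$sample_id[cn$meta$group == "CFRD"]
  cnt2[, cfrd_cols] <- cnt2[, cfrd_cols] * 2L
  res2 <- baseline_de(cnt2, cn$meta, "CFRD")
  m <- match(res$mirna, res2$mirna)
  expect_equal(res2$log2fc[m], res$log2fc, tolerance = 0.01)
  expect_equal(res2$p[m], res$p, tolerance = 0.01)
  expect_equal(res2$mirna[1], res$mirna[1])
})

test_that("shuffling the participant pairing inflates the response null variance", {
  cfg <- sim_config(seed = 29, n_per_group = c(NGT = 6, INDET = 2, IGT = 2, CFRD = 6),
                    nb_dispersion = 0.02, n_null_mirna = 150)
  co <- simulate_cohort(cfg)
  cn <- simulate_counts(co, cfg, n_per_group = 6)
  sf <- size_factors_median_of_ratios(cn$counts)
  norm <- sweep(cn$counts, 2, sf, "/")
  paired_var <- function(meta) {
    grp_r <- function(grp) {
      pid <- unique(meta$participant_id[meta$group == grp])
      sapply(pid, function(id) {
        j0 <- meta$sample_id[meta$participant_id == id & meta$timepoint_min == -1]
        j1 <- meta$sample_id[meta$participant_id == id & meta$timepoint_min == 60]
        log2((norm[, j1] + 0.5) / (norm[, j0] + 0.5))
      })
    }
    e <- rowMeans(grp_r("CFRD")) - rowMeans(grp_r("NGT"))
    var(e)
  }
  v_paired <- paired_var(cn$meta)
  # break the pairing: permute which baseline goes with which 60-min sample
  set.seed(1)
  meta_shuf <- cn$meta
  for (grp in c("NGT", "CFRD")) {
    rows <- which(meta_shuf$group == grp & meta_shuf$timepoint_min == -1)
    meta_shuf$participant_id[rows] <- sample(meta_shuf$participant_id[rows])
  }
  v_shuffled <- paired_var(meta_shuf)
  expect_gt(v_shuffled, v_paired)
})
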
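# Builders for small hand-made Ct tables used across the QC and
# quantification tests.

# One sample's worth of Ct records. `targets` is a named vector of target
# miRNA Cts; controls and spike-ins get sensible clean defaults unless
# overridden.
make_sample_records <- function(participant = "P1", timepoint = -1,
                                plate = "plateA",
                                targets = c("miR-122-5p" = 26),
                                ctrl16 = 20, ctrl23a = 23, ctrl486 = 21,
                                mir451a = 18,
                                unisp2 = 19, unisp3 = 21, unisp4 = 17.5,
                                unisp5 = 21.5, unisp6 = 20) {
  assays <- c("miR-16-5p", "miR-23a-3p", "miR-486-5p", "miR-451a",
              "UniSp2", "UniSp3", "UniSp4", "UniSp5", "UniSp6",
              names(targets))
  ct <- c(ctrl16, ctrl23a, ctrl486, mir451a,
          unisp2, unisp3, unisp4, unisp5, unisp6, unname(targets))
  data.frame(participant_id = participant, timepoint_min = timepoint,
             plate_id = plate, assay_id = assays, ct = ct,
             stringsAsFactors = FALSE)
}

# A full participant: one sample per timepoint, all clean by default.
make_participant_records <- function(participant = "P1",
                                     timepoints = c(-1, 10, 30, 60, 180),
                                     ...) {
  do.call(rbind, lapply(timepoints, function(tp) {
    make_sample_records(participant = participant, timepoint = tp, ...)
  }))
}

# All permutations of 1..n (matrix, one permutation per row). Only used as a
# brute-force oracle at n <= 6.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Independent brute-force BH step-up: q_(i) = min_{j >= i} m * p_(j) / j,
# capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}
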
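# Printed summary counts from the published Korean cohort analysis that
# motivated the default generator parameters. Used only for arithmetic
# consistency checks (percentages and group-size bookkeeping); the
# underlying individual-level data are controlled-access.

ref_quartile_n <- c(Q1 = 2069L, Q2 = 1169L, Q3 = 2195L, Q4 = 910L)

# per-quartile counts with the percentages printed beside them
ref_quartile_counts <- list(
  mets = list(count = c(547, 314, 510, 186), pct = c(26, 27, 23, 20)),
  abdominal_obesity = list(count = c(686, 416, 753, 305),
                           pct = c(30, 36, 34, 34)),
  high_triglycerides = list(count = c(748, 382, 631, 235),
                            pct = c(36, 33, 29, 26)),
  low_hdl = list(count = c(1087, 667, 1294, 539), pct = c(53, 57, 59, 59)),
  high_blood_pressure = list(count = c(486, 287, 432, 161),
                             pct = c(24, 25, 20, 18)),
  high_fasting_glucose = list(count = c(465, 244, 392, 131),
                              pct = c(23, 21, 18, 14)),
  male = list(count = c(1432, 569, 817, 199), pct = c(69, 49, 37, 22)),
  female = list(count = c(637, 600, 1378, 711), pct = c(31, 51, 63, 78)),
  rural = list(count = c(1194, 618, 989, 419), pct = c(58, 53, 45, 46)),
  urban = list(count = c(875, 551, 1206, 491), pct = c(42, 47, 55, 54)))

# published cells whose printed percentage is NOT consistent with the
# printed count/denominator (typesetting slips in the source tables);
# they are asserted to be the only inconsistencies
ref_known_pct_slips <- "abdominal_obesity.Q1"

ref_total_n <- 6414L
ref_non_mets_n <- 4838L
ref_mets_n <- 1576L

# equal-weight quartile association counts: cases (controls)
ref_assoc_cases <- c(547L, 314L, 510L, 186L)
ref_assoc_controls <- c(1522L, 855L, 1685L, 724L)

expand_counts_to_individuals <- function(cases, controls) {
  q <- factor(rep(paste0("Q", 1:4), times = cases + controls),
              levels = paste0("Q", 1:4))
  y <- unlist(lapply(1:4, function(i)
    rep(c(1L, 0L), c(cases[i], controls[i]))))
  data.frame(quartile = q, status = y)
}
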
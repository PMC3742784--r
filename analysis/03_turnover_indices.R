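#!/usr/bin/env Rscript

# BrdU pulse-chase labelling indices and turnover.
#
# Simulates acute-pulse cohorts for a slow-exit (wild-type-like) and a
# fast-exit group over the standard chase times (4 h, 1, 3, 7, 14 d),
# computes BLI / SLI / ASLI per region and whole eye, the day-1 percentage of
# labelled cells that are suprabasal (both unadjusted and adjusted), and the
# turnover-time bound.

suppressMessages(library(corneamosaic))
dir.create("results", showWarnings = FALSE)

chase <- c(1 / 6, 1, 3, 7, 14)
groups <- list(slow_exit = cohort_params(),
               fast_exit = cohort_params(transfer_rate = 0.6))
n_eyes <- 10

indices <- list()
day1 <- list()
for (g in names(groups)) {
  for (eye in seq_len(n_eyes)) {
    tc <- generate_cohort_timecourse(groups[[g]], times = chase,
                                     seed = 5000L + 100L * match(g, names(groups)) + eye,
                                     eye_id = sprintf("%s_%02d", g, eye),
                                     genotype = g)
    for (i in seq_along(chase)) {
      li <- labelling_indices(tc[[i]])
      li$group <- g
      li$eye <- eye
      li$time_days <- chase[i]
      indices[[length(indices) + 1L]] <- li
    }
    w1 <- labelling_indices(tc[[2]])
    w1 <- w1[w1$region == "whole", ]
    day1[[length(day1) + 1L]] <- data.frame(
      group = g, eye = eye,
      frac_suprabasal = suprabasal_fraction(w1$SLI, w1$BLI),
      frac_suprabasal_adj = suprabasal_fraction(w1$ASLI, w1$BLI))
  }
}
indices <- do.call(rbind, indices)
day1 <- do.call(rbind, day1)
write_tsv(indices, "results/labelling_indices.tsv")
write_tsv(day1, "results/day1_suprabasal_fraction.tsv")

cat("Whole-eye indices over the chase (group means):\n")
whole <- indices[indices$region == "whole", ]
print(aggregate(cbind(BLI, SLI, ASLI) ~ group + time_days, whole, mean),
      row.names = FALSE, digits = 3)

cat("\nDay-1 percentage of labelled cells that are suprabasal:\n")
print(aggregate(cbind(frac_suprabasal, frac_suprabasal_adj) ~ group, day1,
                function(x) c(mean = mean(x), sem = sd(x) / sqrt(length(x)))),
      row.names = FALSE, digits = 3)
tt <- t.test(frac_suprabasal ~ group, day1)
cat(sprintf("Welch t-test on the unadjusted fraction: p = %.3g\n", tt$p.value))

tc_ref <- generate_cohort_timecourse(groups$slow_exit, times = chase,
                                     seed = 6001)
print(estimate_turnover_time(tc_ref))
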
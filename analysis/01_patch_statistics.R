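#!/usr/bin/env Rscript

# Developmental mosaic patch analysis.
#
# Simulates beta-gal mosaic basal-cell sequences across the corneal diameter
# at the "patches, not yet stripes" stage for two groups: a reference group
# and a finer-mixed group (smaller coherent clones, as seen in the mutant at
# 3 weeks). For each section we record the patch summary, the corrected mean
# patch length (the coherent-clone-length estimate) and the median minority
# patch length, then compare groups with standard tests.

suppressMessages(library(corneamosaic))

dir.create("results", showWarnings = FALSE)
set.seed(101)

n_eyes <- 12
groups <- list(
  reference = list(n_cells = 420, clone_len_mean = 4.0),
  fine_mixed = list(n_cells = 300, clone_len_mean = 2.5)
)

rows <- list()
for (g in names(groups)) {
  cfg <- groups[[g]]
  for (eye in seq_len(n_eyes)) {
    p_eye <- stats::rbeta(1, 10, 10)  # X-inactivation proportion varies by eye
    ms <- generate_mosaic(cfg$n_cells, p = p_eye,
                          clone_len_mean = cfg$clone_len_mean,
                          seed = 1000L + 100L * match(g, names(groups)) + eye)
    s <- extract_patches(ms)
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(group = g, eye = eye,
                 corrected_mean_patch_len = corrected_mean_patch_length(s),
                 median_minority_len = as.numeric(median_minority_patch_length(s)),
                 true_clone_len = mean(tabulate(ms$clone_id))),
      as.data.frame(s))
  }
}
tab <- do.call(rbind, rows)
write_tsv(tab, "results/patch_statistics.tsv")

cat("Per-group corrected mean patch length (estimates the coherent clone length):\n")
print(aggregate(cbind(corrected_mean_patch_len, true_clone_len, mean_len_pos)
                ~ group, tab, mean), row.names = FALSE)

tt <- t.test(corrected_mean_patch_len ~ group, tab)
wt <- wilcox.test(median_minority_len ~ group, tab, exact = FALSE)
cat(sprintf("\nWelch t-test, corrected mean patch length: p = %.3g\n", tt$p.value))
cat(sprintf("Mann-Whitney, median minority patch length: p = %.3g\n", wt$p.value))
cat("\nThe corrected statistic tracks the generating clone length and is the\n")
cat("one that separates the groups; the uncorrected mean patch length also\n")
cat("moves with each eye's labelled proportion and is noisier.\n")
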
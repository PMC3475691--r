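#!/usr/bin/env Rscript
# Longitudinal plasma statistics: per-age genotype t-tests, within-genotype
# contrasts against the 3-month baseline, and a genotype x age two-way
# ANOVA per analyte.

suppressPackageStartupMessages(library(hypoproteo))

panel <- read_panel("results/inputs/panel.tsv")
res <- run_longitudinal_panel(panel)
write_stats_tables(res, "results/stats_t_tests.tsv", "results/stats_anova.tsv")

sig <- res$t_tests[res$t_tests$significant, ]
cat(sprintf("%d of %d t-tests significant at p < 0.05:\n",
            nrow(sig), nrow(res$t_tests)))
for (i in seq_len(nrow(sig)))
  cat(sprintf("  %-8s %-18s p = %.4f\n", sig$analyte[i], sig$comparison[i],
              sig$p[i]))

truth <- read_tsv("results/inputs/truth_panel.tsv")
merged <- merge(res$t_tests, truth)
agree <- mean(merged$significant == (abs(merged$effect) >= 0.8))
cat(sprintf("agreement with planted effects (|d| >= 0.8 vs calls): %.2f\n",
            agree))

for (an in names(res$anova)) {
  tab <- res$anova[[an]]
  cat(sprintf("ANOVA %-8s genotype p = %.4g, age p = %.4g, interaction p = %.4g\n",
              an, tab$p[tab$effect == "genotype"], tab$p[tab$effect == "age"],
              tab$p[tab$effect == "genotype:age"]))
}
cat("Wrote results/stats_t_tests.tsv and results/stats_anova.tsv\n")
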
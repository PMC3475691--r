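#!/usr/bin/env Rscript
# Literature latent semantic indexing: correlate each differential protein's
# abstract pseudo-document against the interrogation terms Huntingtin,
# Chorea, Diabetes and Insulin; genes scoring > 0.1 are reported with their
# regulation direction.

suppressPackageStartupMessages(library(hypoproteo))

quant <- read_quant_table("results/quant.tsv")
corp <- read_corpus("results/inputs/corpus.jsonl")
diff <- quant[quant$call != "unchanged", ]
genes <- data.frame(gene = diff$protein_accession, direction = diff$call,
                    stringsAsFactors = FALSE)

corr <- lsi_correlate(genes, corp, k = 10L, threshold = 0.1)
write_lsi_table(corr, "results/lsi.tsv")
sig <- classify_report(corr, threshold = 0.1)
write_lsi_table(sig, "results/lsi_significant.tsv")

for (tm in unique(corr$term)) {
  s <- sig[sig$term == tm, ]
  cat(sprintf("%-11s %2d significant genes; top: %s\n", tm, nrow(s),
              if (nrow(s)) sprintf("%s (%.2f, %s)", s$gene[1], s$score[1],
                                   s$direction[1]) else "-"))
}

truth <- read_tsv("results/inputs/truth_corpus.tsv")
for (tm in intersect(tolower(unique(corr$term)), unique(truth$term))) {
  sub <- corr[tolower(corr$term) == tm, ]
  auc <- rank_auc(sub$score, sub$gene %in% truth$gene[truth$term == tm])
  cat(sprintf("planted-association AUC for '%s': %.3f\n", tm, auc))
}
cat("Wrote results/lsi.tsv and results/lsi_significant.tsv\n")
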
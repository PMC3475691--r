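#!/usr/bin/env Rscript
# Hypergeometric gene-set enrichment of the up- and down-regulated protein
# sets, ranked by the hybrid score R * (-log10 p) with the 2-protein and
# p < 0.05 inclusion gates.

suppressPackageStartupMessages(library(hypoproteo))

quant <- read_quant_table("results/quant.tsv")
universe <- read_gmt("results/inputs/sets.gmt", "results/inputs/background.txt")
planted <- readLines("results/inputs/planted_set_id.txt")

for (dir in c("up", "down")) {
  query <- quant$protein_accession[quant$call == dir]
  res <- enrich_all(query, universe)
  write_enrichment_table(res, sprintf("results/enrichment_%s.tsv", dir))
  top <- res[1, ]
  cat(sprintf(paste0(
    "%s set (%d proteins): %d/%d sets pass the gates; top set %s ",
    "(O=%d, E=%.2f, R=%.2f, p=%.2e, hybrid=%.2f)%s\n"),
    dir, length(query), sum(res$significant), nrow(res), top$set_id,
    top$O, top$E, top$R, top$p, top$hybrid_score,
    if (top$set_id == planted) " <- planted set" else ""))
}
cat("Wrote results/enrichment_up.tsv and results/enrichment_down.tsv\n")
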
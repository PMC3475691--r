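#!/usr/bin/env Rscript
# Generate the synthetic study inputs with known ground truth.
#
# Emulated design: 4-plex isobaric labelling with three pooled transgenic
# samples (channels 114/115/116) against one pooled wild-type sample
# (channel 117); 200 proteins with 10% planted 1.5-fold up and 10%
# 0.67-fold down; a gene-set annotation with one set re-planted from the
# differential proteins; a 300-abstract gene-tagged corpus with planted
# gene-term associations; and a 2-genotype x 3-age plasma panel with n = 5
# animals per cell.

suppressPackageStartupMessages(library(hypoproteo))

seed <- 1L
dir.create("results", showWarnings = FALSE)
bundle <- simulate_input_bundle("results/inputs", seed = seed)

# persist the ground truth so the later scripts can score their stages
write_tsv(bundle$truth$psm$proteins, "results/inputs/truth_proteins.tsv")
write_tsv(bundle$truth$corpus, "results/inputs/truth_corpus.tsv")
write_tsv(bundle$truth$panel, "results/inputs/truth_panel.tsv")
writeLines(bundle$truth$annotations$planted_set_id,
           "results/inputs/planted_set_id.txt")

tp <- bundle$truth$psm$proteins
cat(sprintf(paste0(
  "Wrote synthetic inputs (seed %d) to results/inputs/:\n",
  "  %d proteins (%d planted up, %d planted down)\n",
  "  %d gene sets, planted: %s\n",
  "  %d abstracts, %d planted gene-term pairs\n",
  "  plasma panel: %d rows\n"),
  seed, nrow(tp), sum(tp$direction == "up"), sum(tp$direction == "down"),
  length(bundle$truth$annotations$universe$sets),
  bundle$truth$annotations$planted_set_id,
  nrow(read_corpus(bundle$paths$corpus)$documents),
  nrow(bundle$truth$corpus),
  nrow(read_panel(bundle$paths$panel))))
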
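# Independent oracles used across tests.

# Exhaustive hypergeometric upper tail: enumerate every size-n draw from a
# background of N in which the first K elements are the set members, and
# count draws overlapping the set in at least O elements.
enum_hypergeom_tail <- function(O, n, K, N) {
  if (O == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= O)
}

# Tiny PSM data.frame builder with the default channel layout.
make_psm <- function(ints, accession = "P1", confidence = 99,
                     peptide = NULL, id = NULL) {
  ints <- matrix(unlist(ints), ncol = 4, byrow = TRUE)
  n <- nrow(ints)
  data.frame(spectrum_id = id %||% sprintf("sp%02d", seq_len(n)),
             peptide = peptide %||% sprintf("PEP%02d", seq_len(n)),
             protein_accession = rep_len(accession, n),
             confidence_pct = rep_len(confidence, n),
             i114 = ints[, 1], i115 = ints[, 2], i116 = ints[, 3],
             i117 = ints[, 4], stringsAsFactors = FALSE)
}

make_scores <- function(accessions, unused = 5) {
  data.frame(protein_accession = accessions,
             unused_protscore = rep_len(unused, length(accessions)),
             total_protscore = rep_len(unused, length(accessions)) + 1,
             stringsAsFactors = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
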
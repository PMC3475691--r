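#' Four-channel isobaric reporter design
#'
#' Describes the 4-plex labelling layout: which reporter channel carries which
#' biological condition and which channel is the reference (denominator of all
#' ratios). The default is the study design this package emulates: three
#' pooled transgenic samples on channels 114/115/116 against one pooled
#' wild-type sample on channel 117.
#'
#' @param channels character vector of exactly four reporter mass labels.
#' @param conditions named character vector mapping each channel to a
#'   condition label.
#' @param reference the reference channel label; must be one of `channels`.
#' @return object of class `channel_design` with elements `channels`,
#'   `conditions`, `reference` and `test_channels` (the non-reference
#'   channels, in channel order).
#' @export
channel_design <- function(channels = c("114", "115", "116", "117"),
                           conditions = c("114" = "tgHD", "115" = "tgHD",
                                          "116" = "tgHD", "117" = "WT"),
                           reference = "117") {
  channels <- as.character(channels)
  if (length(channels) != 4L || anyDuplicated(channels))
    stop("a channel design needs exactly 4 distinct channels")
  if (!all(channels %in% names(conditions)))
    stop("every channel needs a condition label")
  if (!reference %in% channels)
    stop("reference channel '", reference, "' is not among the channels")
  test <- setdiff(channels, reference)
  if (length(test) < 1L) stop("need at least one non-reference channel")
  structure(list(channels = channels,
                 conditions = conditions[channels],
                 reference = reference,
                 test_channels = test),
            class = "channel_design")
}

intensity_cols <- function(design) paste0("i", design$channels)
ratio_cols <- function(design) paste0("r", design$test_channels)

#' Quantification rules for reporter-ion protein quantification
#'
#' Bundles the thresholds of the quantification scheme: the detector
#' saturation cutoff (spectra with any channel at or above it are discarded),
#' the fold-change cutoffs for calling a protein up- (mean ratio >= 1.2) or
#' down-regulated (<= 0.8), the identification gates (unused ProtScore >= 2.0
#' and at least two peptides at >= 95% confidence), and the channel
#' consistency gate requiring all three test:reference channel means on the
#' same side of unity before a differential call is made.
#'
#' @param saturation_threshold counts; spectra with any channel `>=` this are
#'   dropped (the boundary itself saturates). Default 1500.
#' @param up_cutoff,down_cutoff mean-ratio cutoffs for up/down calls
#'   (inclusive). Defaults 1.2 and 0.8.
#' @param min_peptides minimum qualifying peptides per protein. Default 2.
#' @param min_peptide_confidence_pct minimum peptide identification
#'   confidence, percent. Default 95.
#' @param min_unused_protscore minimum unused ProtScore. Default 2.0.
#' @param require_channel_consistency if `TRUE` (default), an up/down call
#'   additionally requires every per-channel mean ratio on the same side of 1.
#' @param ratio_mean `"arithmetic"` (default) or `"geometric"`: how peptide
#'   ratios are averaged within a channel and across channels.
#' @return list of class `quant_config`.
#' @export
quant_config <- function(saturation_threshold = 1500,
                         up_cutoff = 1.2,
                         down_cutoff = 0.8,
                         min_peptides = 2L,
                         min_peptide_confidence_pct = 95,
                         min_unused_protscore = 2.0,
                         require_channel_consistency = TRUE,
                         ratio_mean = c("arithmetic", "geometric")) {
  ratio_mean <- match.arg(ratio_mean)
  if (!(down_cutoff > 0 && down_cutoff < 1 && up_cutoff > 1))
    stop("cutoffs must satisfy 0 < down_cutoff < 1 < up_cutoff")
  if (min_peptides < 1L) stop("min_peptides must be >= 1")
  structure(list(saturation_threshold = saturation_threshold,
                 up_cutoff = up_cutoff, down_cutoff = down_cutoff,
                 min_peptides = as.integer(min_peptides),
                 min_peptide_confidence_pct = min_peptide_confidence_pct,
                 min_unused_protscore = min_unused_protscore,
                 require_channel_consistency = require_channel_consistency,
                 ratio_mean = ratio_mean),
            class = "quant_config")
}

psm_required_cols <- function(design) {
  c("spectrum_id", "peptide", "protein_accession", "confidence_pct",
    intensity_cols(design))
}

#' Read a peptide-spectrum-match table
#'
#' One row per PSM with four reporter-channel intensity columns
#' (`i114`..`i117` under the default design). Row order is preserved.
#'
#' @param path TSV file with header columns `spectrum_id`, `peptide`,
#'   `protein_accession`, `confidence_pct` and one `i<channel>` column per
#'   design channel.
#' @param design a [channel_design()].
#' @return data.frame of PSMs.
#' @export
read_psm_table <- function(path, design = channel_design()) {
  psm <- read_tsv(path)
  validate_psm_table(psm, design)
}

validate_psm_table <- function(psm, design = channel_design()) {
  need <- psm_required_cols(design)
  missing <- setdiff(need, names(psm))
  if (length(missing))
    stop("PSM table is missing column(s): ", paste(missing, collapse = ", "))
  for (col in intensity_cols(design)) {
    v <- psm[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop("negative or non-numeric intensity in column '", col,
           "' at row ", bad[1])
    psm[[col]] <- v
  }
  bad_conf <- which(!is.finite(psm$confidence_pct) |
                    psm$confidence_pct < 0 | psm$confidence_pct > 100)
  if (length(bad_conf))
    stop("confidence_pct outside [0,100] at row ", bad_conf[1])
  psm[, need]
}

#' Write a PSM table
#' @param psm data.frame of PSMs.
#' @param path output TSV path.
#' @export
write_psm_table <- function(psm, path) write_tsv(psm, path)

#' Default isotope impurity mixing matrix
#'
#' Reporter labels carry isotope impurities, so a fraction of each channel's
#' true signal is observed in neighbouring channels. Vendor certificates give
#' per-lot values; this default puts 94% of a channel's signal on-diagonal,
#' leaks 2% to each +/-1 mass neighbour and 1% to the -2 neighbour, truncated
#' at the matrix edge. Entry (i, j) is the fraction of channel j's true
#' signal observed in channel i.
#'
#' @param design a [channel_design()].
#' @param diagonal on-diagonal fraction.
#' @param adjacent leakage to each +/-1 neighbour.
#' @param minus2 leakage to the -2 neighbour.
#' @return 4x4 matrix with channel dimnames.
#' @export
default_impurity_matrix <- function(design = channel_design(),
                                    diagonal = 0.94, adjacent = 0.02,
                                    minus2 = 0.01) {
  n <- length(design$channels)
  m <- matrix(0, n, n, dimnames = list(design$channels, design$channels))
  for (j in seq_len(n)) {
    m[j, j] <- diagonal
    if (j > 1L) m[j - 1L, j] <- adjacent
    if (j < n)  m[j + 1L, j] <- adjacent
    if (j > 2L) m[j - 2L, j] <- minus2
  }
  m
}

#' Correct reporter intensities for isotopic overlap
#'
#' Solves `mixing %*% x = observed` for the true per-channel signal `x`,
#' clamping any negative component to zero. An identity matrix returns the
#' input unchanged.
#'
#' @param intensities numeric vector of 4 observed counts, or a matrix with
#'   one spectrum per row and one channel per column.
#' @param mixing invertible 4x4 impurity matrix; entry (i, j) is the fraction
#'   of channel j's true signal observed in channel i.
#' @return corrected intensities, same shape as the input.
#' @export
correct_isotope_overlap <- function(intensities, mixing) {
  if (!is.matrix(mixing) || nrow(mixing) != ncol(mixing))
    stop("mixing must be a square matrix")
  if (rcond(mixing) < 1e-12)
    stop("impurity mixing matrix is singular or near-singular")
  if (is.matrix(intensities)) {
    out <- t(solve(mixing, t(intensities)))
    out[out < 0] <- 0
    dimnames(out) <- dimnames(intensities)
    return(out)
  }
  x <- solve(mixing, as.numeric(intensities))
  x[x < 0] <- 0
  names(x) <- names(intensities)
  x
}

#' Drop spectra with a saturated detector channel
#'
#' A reporter peak at or above the saturation threshold no longer measures
#' abundance linearly, and a ratio needs both its channels, so the whole
#' spectrum is discarded if any channel saturates.
#'
#' @param psm PSM data.frame.
#' @param config a [quant_config()]; `saturation_threshold` is used.
#' @param design a [channel_design()].
#' @return the retained rows, with attributes `n_retained` and `n_dropped`.
#' @export
filter_saturated <- function(psm, config = quant_config(),
                             design = channel_design()) {
  ints <- as.matrix(psm[, intensity_cols(design), drop = FALSE])
  keep <- apply(ints < config$saturation_threshold, 1L, all)
  out <- psm[keep, , drop = FALSE]
  attr(out, "n_retained") <- sum(keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Per-spectrum test:reference channel ratios
#'
#' Computes, for each qualifying PSM, the intensity ratio of every test
#' channel to the reference channel. Spectra below the peptide confidence
#' cutoff, and spectra whose reference intensity is zero (a ratio would be
#' undefined), are excluded with a recorded reason rather than an error.
#'
#' @param psm PSM data.frame (normally already saturation-filtered).
#' @param design a [channel_design()].
#' @param config a [quant_config()]; the confidence gate is applied here.
#' @return list with `ratios` (data.frame: `protein_accession`, `peptide`,
#'   `spectrum_id`, one `r<channel>` column per test channel) and `excluded`
#'   (data.frame: `spectrum_id`, `reason`).
#' @export
peptide_ratios <- function(psm, design = channel_design(),
                           config = quant_config()) {
  conf_ok <- psm$confidence_pct >= config$min_peptide_confidence_pct
  ref <- psm[[paste0("i", design$reference)]]
  ref_ok <- ref > 0
  low_conf_ids <- psm$spectrum_id[!conf_ok]
  zero_ref_ids <- psm$spectrum_id[conf_ok & !ref_ok]
  excluded <- data.frame(
    spectrum_id = c(low_conf_ids, zero_ref_ids),
    reason = c(rep("low confidence", length(low_conf_ids)),
               rep("zero reference", length(zero_ref_ids))),
    stringsAsFactors = FALSE)
  keep <- conf_ok & ref_ok
  kept <- psm[keep, , drop = FALSE]
  ratios <- data.frame(protein_accession = kept$protein_accession,
                       peptide = kept$peptide,
                       spectrum_id = kept$spectrum_id,
                       stringsAsFactors = FALSE)
  for (ch in design$test_channels)
    ratios[[paste0("r", ch)]] <-
      kept[[paste0("i", ch)]] / kept[[paste0("i", design$reference)]]
  list(ratios = ratios, excluded = excluded)
}

#' Roll peptide ratios up to protein-level mean ratios
#'
#' Applies the protein identification gates (unused ProtScore and minimum
#' qualifying peptide count), then averages peptide ratios per channel and
#' across the three test channels.
#'
#' @param ratios the `ratios` data.frame from [peptide_ratios()].
#' @param scores data.frame with `protein_accession`, `unused_protscore`,
#'   `total_protscore`; every quantified protein must have a row.
#' @param design a [channel_design()].
#' @param config a [quant_config()].
#' @return data.frame with one row per retained protein
#'   (`protein_accession`, `n_peptides`, per-channel mean ratio columns,
#'   `mean_ratio`), with attributes `excluded_by_score` and
#'   `excluded_by_peptides` (character vectors of accessions).
#' @export
rollup_protein <- function(ratios, scores, design = channel_design(),
                           config = quant_config()) {
  accs <- unique(ratios$protein_accession)
  missing <- setdiff(accs, scores$protein_accession)
  if (length(missing))
    stop("no ProtScore row for protein(s): ", paste(missing, collapse = ", "))
  unused <- stats::setNames(scores$unused_protscore, scores$protein_accession)

  score_fail <- accs[unused[accs] < config$min_unused_protscore]
  pep_counts <- table(ratios$protein_accession)
  kept_after_score <- setdiff(accs, score_fail)
  pep_fail <- kept_after_score[pep_counts[kept_after_score] < config$min_peptides]
  kept <- setdiff(kept_after_score, pep_fail)

  rc <- ratio_cols(design)
  avg <- if (config$ratio_mean == "geometric")
    function(x) exp(mean(log(x))) else mean
  rows <- lapply(kept, function(acc) {
    sub <- ratios[ratios$protein_accession == acc, rc, drop = FALSE]
    ch_means <- vapply(sub, avg, numeric(1))
    out <- data.frame(protein_accession = acc, n_peptides = nrow(sub),
                      stringsAsFactors = FALSE)
    for (nm in rc) out[[nm]] <- ch_means[[nm]]
    out$mean_ratio <- avg(ch_means)
    out
  })
  quant <- if (length(rows)) do.call(rbind, rows) else
    empty_quant_frame(design)[, c("protein_accession", "n_peptides", rc, "mean_ratio")]
  attr(quant, "excluded_by_score") <- score_fail
  attr(quant, "excluded_by_peptides") <- pep_fail
  quant
}

#' Call proteins up-, down- or unchanged from their mean ratio
#'
#' A protein is called up when its mean test:reference ratio is at or above
#' `up_cutoff` (default 1.2) and down at or below `down_cutoff` (default
#' 0.8). With the channel consistency gate on, an up/down call additionally
#' requires all per-channel means on the same side of unity. The signed
#' relative expression equals the mean ratio, negated for down-regulated
#' proteins to indicate direction.
#'
#' @param quant data.frame from [rollup_protein()].
#' @param design a [channel_design()].
#' @param config a [quant_config()].
#' @return `quant` with columns `call` (up/down/unchanged) and
#'   `signed_expression` appended.
#' @export
call_differential <- function(quant, design = channel_design(),
                              config = quant_config()) {
  rc <- ratio_cols(design)
  ch <- as.matrix(quant[, rc, drop = FALSE])
  all_above <- apply(ch > 1, 1L, all)
  all_below <- apply(ch < 1, 1L, all)
  up <- quant$mean_ratio >= config$up_cutoff
  down <- quant$mean_ratio <= config$down_cutoff
  if (config$require_channel_consistency) {
    up <- up & all_above
    down <- down & all_below
  }
  call <- rep("unchanged", nrow(quant))
  call[up] <- "up"
  call[down] <- "down"
  quant$call <- call
  quant$signed_expression <- ifelse(call == "down",
                                    -quant$mean_ratio, quant$mean_ratio)
  quant
}

empty_quant_frame <- function(design = channel_design()) {
  out <- data.frame(protein_accession = character(0),
                    n_peptides = integer(0), stringsAsFactors = FALSE)
  for (nm in ratio_cols(design)) out[[nm]] <- numeric(0)
  out$mean_ratio <- numeric(0)
  out$call <- character(0)
  out$signed_expression <- numeric(0)
  out
}

#' Full reporter-ion quantification of a PSM table
#'
#' Runs the whole quantification chain: isotope-overlap correction,
#' saturation filtering, peptide confidence gating, test:reference ratios,
#' protein roll-up with identification gates, and differential calling.
#'
#' @param psm PSM data.frame (see [read_psm_table()]).
#' @param scores ProtScore data.frame.
#' @param design a [channel_design()].
#' @param config a [quant_config()].
#' @param impurity_matrix impurity mixing matrix, or `NULL` to skip the
#'   correction step.
#' @return list with `quant` (called protein table sorted by
#'   `|signed_expression|` descending, ties by accession) and `report`, a
#'   named list of counts satisfying
#'   `n_input_proteins == n_excluded_by_score + n_excluded_by_peptides +
#'   n_called_up + n_called_down + n_unchanged`.
#' @export
quantify_proteins <- function(psm, scores, design = channel_design(),
                              config = quant_config(),
                              impurity_matrix = default_impurity_matrix(design)) {
  psm <- validate_psm_table(psm, design)
  input_proteins <- unique(psm$protein_accession)
  ic <- intensity_cols(design)
  if (!is.null(impurity_matrix)) {
    corrected <- correct_isotope_overlap(as.matrix(psm[, ic, drop = FALSE]),
                                         impurity_matrix)
    psm[, ic] <- corrected
  }
  filt <- filter_saturated(psm, config, design)
  pr <- peptide_ratios(filt, design, config)
  quant <- rollup_protein(pr$ratios, scores, design, config)
  quant <- call_differential(quant, design, config)
  ord <- order(-abs(quant$signed_expression), quant$protein_accession)
  quant <- quant[ord, , drop = FALSE]
  rownames(quant) <- NULL

  score_fail <- attr(quant, "excluded_by_score") %||% character(0)
  pep_fail <- attr(quant, "excluded_by_peptides") %||% character(0)
  # proteins whose spectra were all lost to saturation / confidence / zero
  # reference never reach the roll-up; they count as peptide-gate exclusions
  vanished <- setdiff(input_proteins,
                      c(quant$protein_accession, score_fail, pep_fail))
  report <- list(
    n_spectra_in = nrow(psm),
    n_spectra_saturated = attr(filt, "n_dropped"),
    n_spectra_excluded = nrow(pr$excluded),
    n_input_proteins = length(input_proteins),
    n_excluded_by_score = length(score_fail),
    n_excluded_by_peptides = length(pep_fail) + length(vanished),
    n_called_up = sum(quant$call == "up"),
    n_called_down = sum(quant$call == "down"),
    n_unchanged = sum(quant$call == "unchanged"))
  list(quant = quant, report = report)
}

#' Write the protein quantification table
#'
#' TSV with one row per protein: accession, qualifying peptide count,
#' per-channel mean ratios, mean ratio, call, and signed expression (the
#' mean ratio, negative for down-regulated proteins). Rows are sorted by
#' `|signed_expression|` descending, ties broken by accession.
#'
#' @param quant called quantification data.frame.
#' @param path output TSV path.
#' @export
write_quant_table <- function(quant, path) {
  ord <- order(-abs(quant$signed_expression), quant$protein_accession)
  write_tsv(quant[ord, , drop = FALSE], path)
}

#' Read a protein quantification table
#' @param path TSV written by [write_quant_table()].
#' @return data.frame.
#' @export
read_quant_table <- function(path) read_tsv(path)

#' Tally differential calls from a signed mean-ratio listing
#'
#' Supplementary-style listings report one signed mean ratio per protein:
#' positive ratios `>= up_cutoff` mark increased proteins, and negative
#' entries whose magnitude is `<= down_cutoff` mark reduced proteins. This
#' tallies such a listing.
#'
#' @param signed numeric vector of signed mean ratios, or a data.frame with a
#'   `signed_expression` column.
#' @param up_cutoff,down_cutoff the call cutoffs (defaults 1.2 and 0.8).
#' @return list with `total`, `up` and `down` counts.
#' @export
tally_differential_calls <- function(signed, up_cutoff = 1.2,
                                     down_cutoff = 0.8) {
  if (is.data.frame(signed)) signed <- signed$signed_expression
  up <- sum(signed > 0 & signed >= up_cutoff)
  down <- sum(signed < 0 & -signed <= down_cutoff)
  list(total = up + down, up = up, down = down)
}
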
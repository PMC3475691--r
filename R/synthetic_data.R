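#' Configuration for the synthetic reporter-ion experiment
#'
#' Defaults reproduce the study conditions emulated throughout the package:
#' 200 proteins of which 10% are planted 1.5-fold up and 10% 0.67-fold down
#' (three transgenic channels vs the wild-type reference), a mean of 4
#' peptides per protein, 10% multiplicative lognormal intensity noise,
#' isotope impurity leakage via the default mixing matrix, a 5% share of
#' saturated spectra, and 10% of proteins drawn below the identification
#' score gate.
#'
#' @param n_proteins number of proteins.
#' @param frac_up,frac_down planted fractions (sum <= 1).
#' @param fold_up,fold_down planted fold changes, `fold_up > 1 > fold_down`.
#' @param peptides_per_protein_mean mean qualifying peptides per protein
#'   (count ~ 1 + Poisson(mean - 1)).
#' @param intensity_scale median reference-channel intensity, counts.
#' @param intensity_spread sdlog of the lognormal reference intensity.
#' @param noise_cv coefficient of variation of the multiplicative
#'   channel noise.
#' @param saturation_frac share of spectra rescaled to exceed the detector
#'   saturation threshold.
#' @param saturation_threshold counts (default 1500).
#' @param impurity_matrix mixing matrix applied to true intensities, or
#'   `NULL` for none.
#' @param frac_low_score share of proteins drawn below the unused-ProtScore
#'   gate.
#' @param low_confidence_frac share of spectra emitted below the 95%
#'   peptide confidence gate.
#' @param seed integer RNG seed.
#' @return list of class `psm_sim_config`.
#' @export
psm_sim_config <- function(n_proteins = 200L, frac_up = 0.1, frac_down = 0.1,
                           fold_up = 1.5, fold_down = 0.67,
                           peptides_per_protein_mean = 4,
                           intensity_scale = 300, intensity_spread = 0.5,
                           noise_cv = 0.1, saturation_frac = 0.05,
                           saturation_threshold = 1500,
                           impurity_matrix = default_impurity_matrix(),
                           frac_low_score = 0.1,
                           low_confidence_frac = 0.05, seed = 1L) {
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  if (!(fold_up > 1 && fold_down > 0 && fold_down < 1))
    stop("need fold_up > 1 > fold_down > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (peptides_per_protein_mean < 1) stop("peptides_per_protein_mean >= 1")
  structure(as.list(environment()), class = "psm_sim_config")
}

#' Simulate a 4-plex reporter-ion experiment with known ground truth
#'
#' Per protein: a peptide count drawn as `1 + Poisson(mean - 1)`; per
#' peptide spectrum, a lognormal reference intensity, test-channel
#' intensities equal to reference times the protein's true fold times
#' multiplicative lognormal noise at the configured CV, impurity mixing,
#' and for a configured share of spectra a rescaling that pushes the
#' maximum channel past the saturation threshold. ProtScores are fabricated
#' so a configured share of proteins fails the score gate. Fully
#' reproducible from the seed; per-protein random sub-streams mean adding
#' proteins does not perturb existing ones.
#'
#' @param config a [psm_sim_config()].
#' @param design a [channel_design()].
#' @return list with `psm` (PSM data.frame), `scores` (ProtScore
#'   data.frame) and `truth` (list: `proteins` data.frame with
#'   `protein_accession`, `direction`, `fold`, `low_score`; `spectra`
#'   data.frame of pre-mixing intensities per spectrum).
#' @export
simulate_psm_experiment <- function(config = psm_sim_config(),
                                    design = channel_design()) {
  n <- config$n_proteins
  accs <- sprintf("P%04d", seq_len(n))
  n_up <- round(config$frac_up * n)
  n_down <- round(config$frac_down * n)
  direction <- rep("unchanged", n)
  direction[seq_len(n_up)] <- "up"
  if (n_down > 0) direction[n_up + seq_len(n_down)] <- "down"
  fold <- ifelse(direction == "up", config$fold_up,
                 ifelse(direction == "down", config$fold_down, 1))
  set.seed(sub_seed(config$seed, 0L))
  low_score <- seq_len(n) %in%
    sample.int(n, round(config$frac_low_score * n))

  sdlog_noise <- sqrt(log(1 + config$noise_cv^2))
  test_ch <- design$test_channels
  psm_rows <- list(); spectra_rows <- list()
  for (i in seq_len(n)) {
    set.seed(sub_seed(config$seed, i))
    n_pep <- 1L + stats::rpois(1, config$peptides_per_protein_mean - 1)
    for (p in seq_len(n_pep)) {
      ref <- stats::rlnorm(1, meanlog = log(config$intensity_scale),
                           sdlog = config$intensity_spread)
      noise <- if (sdlog_noise > 0)
        stats::rlnorm(length(test_ch), meanlog = -sdlog_noise^2 / 2,
                      sdlog = sdlog_noise) else rep(1, length(test_ch))
      true <- stats::setNames(numeric(4), design$channels)
      true[design$reference] <- ref
      true[test_ch] <- ref * fold[i] * noise
      saturate <- stats::runif(1) < config$saturation_frac
      if (saturate) true <- true * (config$saturation_threshold * 1.1 / max(true))
      observed <- if (is.null(config$impurity_matrix)) true else
        as.numeric(config$impurity_matrix %*% true)
      low_conf <- stats::runif(1) < config$low_confidence_frac
      conf <- if (low_conf) stats::runif(1, 50, 94.9) else
        stats::runif(1, 95, 99.9)
      sid <- sprintf("%s_sp%02d", accs[i], p)
      row <- data.frame(spectrum_id = sid,
                        peptide = sprintf("PEP%s%02d", i, p),
                        protein_accession = accs[i],
                        confidence_pct = round(conf, 1),
                        stringsAsFactors = FALSE)
      for (ch in design$channels)
        row[[paste0("i", ch)]] <- observed[match(ch, design$channels)]
      psm_rows[[length(psm_rows) + 1L]] <- row
      srow <- data.frame(spectrum_id = sid, stringsAsFactors = FALSE)
      for (ch in design$channels)
        srow[[paste0("true_i", ch)]] <- true[[ch]]
      spectra_rows[[length(spectra_rows) + 1L]] <- srow
    }
  }
  psm <- do.call(rbind, psm_rows)
  set.seed(sub_seed(config$seed, n + 1L))
  unused <- ifelse(low_score, stats::runif(n, 0.3, 1.9),
                   stats::runif(n, 2.2, 12))
  scores <- data.frame(protein_accession = accs,
                       unused_protscore = round(unused, 2),
                       total_protscore = round(unused + stats::runif(n, 0, 4), 2),
                       stringsAsFactors = FALSE)
  truth_proteins <- data.frame(protein_accession = accs,
                               direction = direction, fold = fold,
                               low_score = low_score,
                               stringsAsFactors = FALSE)
  list(psm = psm, scores = scores,
       truth = list(proteins = truth_proteins,
                    spectra = do.call(rbind, spectra_rows)))
}

#' Score recovered differential calls against simulation truth
#'
#' @param quant called quantification table.
#' @param truth the `truth` element of [simulate_psm_experiment()].
#' @return list with `sensitivity` (recall of planted up/down proteins among
#'   score-qualifying ones, with the correct direction) and `fdp` (share of
#'   called proteins whose planted direction disagrees).
#' @export
score_quant_recovery <- function(quant, truth) {
  tp_frame <- merge(quant, truth$proteins, by = "protein_accession")
  called <- tp_frame[tp_frame$call %in% c("up", "down"), , drop = FALSE]
  planted <- tp_frame[tp_frame$direction %in% c("up", "down"), , drop = FALSE]
  sensitivity <- if (nrow(planted) == 0) NA_real_ else
    mean(planted$call == planted$direction)
  fdp <- if (nrow(called) == 0) 0 else
    mean(called$call != called$direction)
  list(sensitivity = sensitivity, fdp = fdp,
       n_called = nrow(called), n_planted = nrow(planted))
}

#' Simulate a gene-set annotation universe with one planted enriched set
#'
#' Draws `n_sets` member lists uniformly from a symbol background; designates
#' the first as the planted set and composes a query that takes a
#' `strength` share of its symbols from the planted set (the rest drawn
#' uniformly from the remaining background). `strength = 0` makes the
#' planted set indistinguishable.
#'
#' @param n_sets number of gene sets.
#' @param set_size_range integer range of set sizes.
#' @param background_size number of background symbols.
#' @param strength share of the query drawn from the planted set, in \[0,1\].
#' @param query_size number of query symbols.
#' @param background_symbols optional explicit symbol vector (length
#'   `background_size` inferred from it).
#' @param seed RNG seed.
#' @return list with `universe` (an `annotation_universe`), `query`
#'   (character vector) and `planted_set_id`.
#' @export
simulate_annotations <- function(n_sets = 20L, set_size_range = c(10L, 30L),
                                 background_size = 200L, strength = 0.8,
                                 query_size = 30L,
                                 background_symbols = NULL, seed = 1L) {
  if (max(set_size_range) > background_size)
    stop("set sizes cannot exceed the background size")
  if (query_size > background_size)
    stop("query cannot exceed the background")
  if (is.null(background_symbols))
    background_symbols <- sprintf("G%04d", seq_len(background_size))
  background_size <- length(background_symbols)
  set.seed(sub_seed(seed, 0L))
  sizes <- sample(seq(set_size_range[1], set_size_range[2]), n_sets,
                  replace = TRUE)
  sets <- lapply(seq_len(n_sets), function(i) {
    set.seed(sub_seed(seed, i))
    sample(background_symbols, sizes[i])
  })
  names(sets) <- sprintf("SET%03d", seq_len(n_sets))
  planted_id <- names(sets)[1]
  set.seed(sub_seed(seed, n_sets + 1L))
  n_from_planted <- min(round(strength * query_size), length(sets[[1]]))
  q_planted <- sample(sets[[1]], n_from_planted)
  q_rest <- sample(setdiff(background_symbols, q_planted),
                   query_size - n_from_planted)
  universe <- annotation_universe(
    sets, stats::setNames(sprintf("synthetic set %d", seq_len(n_sets)),
                          names(sets)),
    background = background_symbols)
  list(universe = universe, query = c(q_planted, q_rest),
       planted_set_id = planted_id)
}

#' Configuration for the synthetic literature corpus
#'
#' Desk-scale stand-in for a large gene-tagged abstract database: topical
#' documents carry their topic's token, and planted genes are linked to
#' topic documents with high probability against a low background linkage
#' rate.
#'
#' @param n_docs number of abstracts (default 300).
#' @param n_genes number of genes (default 40).
#' @param topics interrogation-term topics; defaults to the study's four.
#' @param planted data.frame `gene, term, prob` of planted associations, or
#'   `NULL` for the default: two genes planted per topic at probability 0.8.
#' @param background_prob linkage probability outside planted pairs
#'   (default 0.05).
#' @param vocab_size number of filler vocabulary words (default 150).
#' @param words_per_doc mean document length in tokens (default 40).
#' @param topic_doc_frac share of documents that carry a topic
#'   (default 0.6).
#' @param gene_symbols optional explicit gene symbols.
#' @param seed RNG seed.
#' @return list of class `corpus_sim_config`.
#' @export
corpus_sim_config <- function(n_docs = 300L, n_genes = 40L,
                              topics = c("huntingtin", "chorea",
                                         "diabetes", "insulin"),
                              planted = NULL, background_prob = 0.05,
                              vocab_size = 150L, words_per_doc = 40,
                              topic_doc_frac = 0.6,
                              gene_symbols = NULL, seed = 1L) {
  if (length(topics) == 0L) stop("need at least one topic")
  if (!(background_prob >= 0 && background_prob <= 1))
    stop("background_prob must be in [0, 1]")
  if (is.null(gene_symbols)) gene_symbols <- sprintf("GENE%03d", seq_len(n_genes))
  n_genes <- length(gene_symbols)
  if (is.null(planted)) {
    per <- 2L
    planted <- do.call(rbind, lapply(seq_along(topics), function(ti) {
      idx <- ((ti - 1L) * per + seq_len(per) - 1L) %% n_genes + 1L
      data.frame(gene = gene_symbols[idx], term = topics[ti], prob = 0.8,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!all(planted$gene %in% gene_symbols))
    stop("planted genes must be among the gene symbols")
  if (!all(planted$prob >= 0 & planted$prob <= 1))
    stop("planted probabilities must be in [0, 1]")
  structure(list(n_docs = n_docs, gene_symbols = gene_symbols,
                 topics = topics, planted = planted,
                 background_prob = background_prob, vocab_size = vocab_size,
                 words_per_doc = words_per_doc,
                 topic_doc_frac = topic_doc_frac, seed = seed),
            class = "corpus_sim_config")
}

#' Simulate a gene-tagged abstract corpus with planted associations
#'
#' Documents are bags of filler words; a topical document additionally
#' repeats its topic token. Gene links are drawn per (gene, document): with
#' the planted probability when the document carries a term planted for the
#' gene, otherwise with the background probability.
#'
#' @param config a [corpus_sim_config()].
#' @return list with `corpus` (a `corpus`) and `truth` (the planted
#'   data.frame of (gene, term, prob)).
#' @export
simulate_corpus <- function(config = corpus_sim_config()) {
  vocab <- sprintf("word%03d", seq_len(config$vocab_size))
  # Zipf-ish filler frequencies so the matrix is not uniform
  vprob <- 1 / seq_len(config$vocab_size)
  docs <- vector("list", config$n_docs)
  doc_topic <- character(config$n_docs)
  for (j in seq_len(config$n_docs)) {
    set.seed(sub_seed(config$seed, j))
    topical <- stats::runif(1) < config$topic_doc_frac
    topic <- if (topical) sample(config$topics, 1) else NA_character_
    n_words <- max(10L, stats::rpois(1, config$words_per_doc))
    words <- sample(vocab, n_words, replace = TRUE, prob = vprob)
    if (topical) words <- c(words, rep(topic, 1L + stats::rpois(1, 2)))
    doc_topic[j] <- topic
    docs[[j]] <- paste(sample(words), collapse = " ")
  }
  documents <- data.frame(doc_id = sprintf("DOC%04d", seq_len(config$n_docs)),
                          text = unlist(docs), stringsAsFactors = FALSE)
  planted_terms <- split(config$planted$term, config$planted$gene)
  planted_prob <- stats::setNames(config$planted$prob,
                                  paste(config$planted$gene,
                                        config$planted$term))
  links <- list()
  for (gi in seq_along(config$gene_symbols)) {
    g <- config$gene_symbols[gi]
    set.seed(sub_seed(config$seed, config$n_docs + gi))
    pr <- vapply(seq_len(config$n_docs), function(j) {
      t <- doc_topic[j]
      if (!is.na(t) && t %in% (planted_terms[[g]] %||% character(0)))
        planted_prob[[paste(g, t)]] else config$background_prob
    }, numeric(1))
    linked <- stats::runif(config$n_docs) < pr
    if (any(linked)) links[[g]] <- documents$doc_id[linked]
  }
  list(corpus = corpus(documents, links),
       truth = config$planted, doc_topic = doc_topic)
}

#' Configuration for the synthetic plasma analyte panel
#'
#' Cell means emulate the hormone patterns of the modelled study: reduced
#' insulin and leptin in young transgenic animals, an age-dependent decline
#' in insulin in both genotypes, and a no-effect analyte (glucose) for
#' calibration. Group size defaults to 5 animals per genotype-by-age cell.
#'
#' @param analytes named list; each element a list with `means` (matrix
#'   genotypes x ages), `sd` (scalar) and `units`. `NULL` for the default
#'   three-analyte panel.
#' @param genotypes,ages design labels (defaults `c("tgHD", "WT")`,
#'   `c(3, 9, 12)`).
#' @param n_per_group animals per cell (default 5).
#' @param seed RNG seed.
#' @return list of class `panel_sim_config`.
#' @export
panel_sim_config <- function(analytes = NULL, genotypes = c("tgHD", "WT"),
                             ages = c(3, 9, 12), n_per_group = 5L,
                             seed = 1L) {
  if (n_per_group < 2L) stop("n_per_group must be >= 2")
  if (is.null(analytes)) {
    mk <- function(tg, wt) matrix(c(tg, wt), nrow = 2, byrow = TRUE,
                                  dimnames = list(genotypes, ages))
    analytes <- list(
      insulin = list(means = mk(c(1.2, 1.0, 0.6), c(2.0, 1.4, 1.1)),
                     sd = 0.3, units = "ng/ml"),
      leptin  = list(means = mk(c(2.0, 3.5, 2.2), c(3.2, 3.4, 3.3)),
                     sd = 0.5, units = "ng/ml"),
      glucose = list(means = mk(c(6.0, 6.0, 6.0), c(6.0, 6.0, 6.0)),
                     sd = 0.6, units = "mmol/l"))
  }
  for (an in names(analytes)) {
    a <- analytes[[an]]
    if (any(a$sd < 0)) stop("SDs must be >= 0")
    if (!all(dim(a$means) == c(length(genotypes), length(ages))))
      stop("means matrix for '", an, "' must be genotypes x ages")
  }
  structure(list(analytes = analytes, genotypes = genotypes, ages = ages,
                 n_per_group = as.integer(n_per_group), seed = seed),
            class = "panel_sim_config")
}

#' Simulate a longitudinal plasma analyte panel with known effects
#'
#' Gaussian values per (genotype, age, analyte) cell around the configured
#' means. The truth table lists, for every comparison of the longitudinal
#' scheme, whether the configured cell means actually differ (a planted
#' effect).
#'
#' @param config a [panel_sim_config()].
#' @return list with `panel` (long-format data.frame) and `truth`
#'   (data.frame `analyte, comparison, effect` with the planted mean
#'   difference).
#' @export
simulate_plasma_panel <- function(config = panel_sim_config()) {
  rows <- list(); truth <- list()
  gts <- config$genotypes; ages <- config$ages
  for (ai in seq_along(config$analytes)) {
    an <- names(config$analytes)[ai]
    a <- config$analytes[[an]]
    for (gi in seq_along(gts)) for (agi in seq_along(ages)) {
      set.seed(sub_seed(config$seed, ai * 10000L + gi * 100L + agi))
      v <- stats::rnorm(config$n_per_group, a$means[gi, agi], a$sd)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%s", gts[gi],
                             seq_len(config$n_per_group)),
        genotype = gts[gi], age_months = ages[agi], analyte = an,
        value = round(v, 4), units = a$units, stringsAsFactors = FALSE)
    }
    for (agi in seq_along(ages))
      truth[[length(truth) + 1L]] <- data.frame(
        analyte = an,
        comparison = sprintf("%s vs %s at %sm", gts[1], gts[2], ages[agi]),
        effect = a$means[1, agi] - a$means[2, agi],
        stringsAsFactors = FALSE)
    for (gi in seq_along(gts)) for (agi in seq_along(ages)[-1])
      truth[[length(truth) + 1L]] <- data.frame(
        analyte = an,
        comparison = sprintf("%s %sm vs %sm", gts[gi], ages[agi], ages[1]),
        effect = a$means[gi, agi] - a$means[gi, 1],
        stringsAsFactors = FALSE)
  }
  list(panel = do.call(rbind, rows), truth = do.call(rbind, truth))
}
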
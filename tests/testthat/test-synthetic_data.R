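test_that("generators are pure functions of config and seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  b1 <- simulate_input_bundle(d1, seed = 5L, n_proteins = 40L)
  b2 <- simulate_input_bundle(d2, seed = 5L, n_proteins = 40L)
  for (f in basename(unlist(b1$paths)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  b3 <- simulate_input_bundle(withr::local_tempdir(), seed = 6L,
                              n_proteins = 40L)
  expect_false(identical(readLines(b1$paths$psm), readLines(b3$paths$psm)))
})

test_that("adding proteins does not perturb existing sub-streams", {
  # no planted effects, so the per-protein truth cannot shift with n
  small <- simulate_psm_experiment(psm_sim_config(n_proteins = 10L,
                                                  frac_up = 0, frac_down = 0,
                                                  seed = 2L))
  large <- simulate_psm_experiment(psm_sim_config(n_proteins = 20L,
                                                  frac_up = 0, frac_down = 0,
                                                  seed = 2L))
  shared <- small$psm$spectrum_id
  expect_equal(small$psm,
               large$psm[match(shared, large$psm$spectrum_id), ],
               ignore_attr = TRUE)
})

test_that("generated files parse through their readers without warnings", {
  dir <- withr::local_tempdir()
  b <- simulate_input_bundle(dir, seed = 1L, n_proteins = 30L)
  expect_no_warning(read_psm_table(b$paths$psm))
  expect_no_warning(read_gmt(b$paths$gmt, b$paths$background))
  expect_no_warning(read_corpus(b$paths$corpus))
  expect_no_warning(read_panel(b$paths$panel))
})

test_that("the noiseless limit recovers planted folds exactly", {
  cfg <- psm_sim_config(n_proteins = 20L, noise_cv = 0, saturation_frac = 0,
                        impurity_matrix = NULL, frac_low_score = 0,
                        low_confidence_frac = 0, seed = 2L)
  sim <- simulate_psm_experiment(cfg)
  res <- quantify_proteins(sim$psm, sim$scores, impurity_matrix = NULL)
  m <- merge(res$quant, sim$truth$proteins)
  # only single-peptide proteins can drop out of the roll-up here
  expect_gte(nrow(m), 18L)
  expect_equal(m$mean_ratio, m$fold, tolerance = 1e-9)
  expect_true(all(m$call[m$direction == "up"] == "up"))
  expect_true(all(m$call[m$direction == "down"] == "down"))
})

test_that("truth objects score recovery without re-reading configs", {
  sim <- simulate_psm_experiment(psm_sim_config(seed = 1L))
  res <- quantify_proteins(sim$psm, sim$scores)
  sc <- score_quant_recovery(res$quant, sim$truth)
  expect_gte(sc$sensitivity, 0.9)
  expect_lte(sc$fdp, 0.1)
  # pre-mixing intensities cover every emitted spectrum
  expect_setequal(sim$truth$spectra$spectrum_id, sim$psm$spectrum_id)
})

test_that("an unenriched planted set is indistinguishable from the rest", {
  ranks <- vapply(1:100, function(s) {
    ann <- simulate_annotations(n_sets = 15L, strength = 0, seed = s)
    res <- suppressWarnings(enrich_all(ann$query, ann$universe))
    match(ann$planted_set_id, res$set_id)
  }, numeric(1))
  expect_gt(stats::median(ranks), 1)
})

test_that("null corpus associations give chance-level AUC", {
  aucs <- vapply(1:5, function(s) {
    cc <- corpus_sim_config(n_docs = 150L, n_genes = 20L, seed = s,
                            planted = data.frame(gene = "GENE001",
                                                 term = "diabetes",
                                                 prob = 0.05))
    sim <- simulate_corpus(cc)
    corr <- lsi_correlate(cc$gene_symbols, sim$corpus, terms = "diabetes",
                          k = 10L)
    # score the non-planted genes against an arbitrary half split
    rank_auc(corr$score, seq_along(corr$gene) <= 10)
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("plasma panel generator respects its configured design", {
  cfg <- panel_sim_config(seed = 4L)
  sim <- simulate_plasma_panel(cfg)
  counts <- table(sim$panel$genotype, sim$panel$age_months, sim$panel$analyte)
  expect_true(all(counts == cfg$n_per_group))
  expect_equal(sort(unique(sim$panel$age_months)), c(3, 9, 12))
  # truth covers the full comparison scheme per analyte: 3 + 4 contrasts
  expect_equal(nrow(sim$truth), 7L * length(cfg$analytes))
  expect_error(panel_sim_config(n_per_group = 1L), ">= 2")
})

test_that("invalid simulation configs fail before any output", {
  expect_error(psm_sim_config(frac_up = 0.7, frac_down = 0.4), "<= 1")
  expect_error(psm_sim_config(fold_down = 1.2), "fold_up > 1 > fold_down")
  expect_error(corpus_sim_config(topics = character(0)), "topic")
  expect_error(simulate_annotations(set_size_range = c(5, 500),
                                    background_size = 100), "exceed")
})
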
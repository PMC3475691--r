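design <- channel_design()
cfg <- quant_config()

test_that("PSM tables round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".tsv")

  writeLines(paste(c("spectrum_id", "peptide", "protein_accession",
                     "confidence_pct", "i114", "i115", "i116", "i117"),
                   collapse = "\t"), path)
  expect_equal(nrow(read_psm_table(path, design)), 0L)

  sim <- simulate_psm_experiment(psm_sim_config(n_proteins = 3L, seed = 4L))
  write_psm_table(sim$psm, path)
  back <- read_psm_table(path, design)
  expect_equal(back$spectrum_id, sim$psm$spectrum_id)
  expect_equal(back$i117, sim$psm$i117, tolerance = 1e-10)

  bad <- make_psm(list(c(10, 20, 30, -5)))
  write_psm_table(bad, path)
  expect_error(read_psm_table(path, design), "row 1")

  write_tsv(bad[, setdiff(names(bad), "i116")], path)
  expect_error(read_psm_table(path, design), "i116")
})

test_that("isotope overlap correction inverts the mixing model", {
  id4 <- diag(4)
  expect_equal(correct_isotope_overlap(c(100, 200, 300, 400), id4),
               c(100, 200, 300, 400))
  expect_equal(correct_isotope_overlap(c(0, 0, 0, 0),
                                       default_impurity_matrix()),
               c(0, 0, 0, 0), ignore_attr = TRUE)

  # 6% of channel-114 signal leaks into 115: hand-inverted two-channel case
  m <- diag(4); m[1, 1] <- 0.94; m[2, 1] <- 0.06
  expect_equal(correct_isotope_overlap(c(940, 560, 0, 0), m),
               c(1000, 500, 0, 0))

  expect_error(correct_isotope_overlap(1:4, matrix(1, 4, 4)), "singular")
})

test_that("correction round-trips mixing %*% x for random non-negative x", {
  m <- default_impurity_matrix()
  set.seed(42)
  for (i in 1:50) {
    x <- runif(4, 0, 2000)
    expect_equal(unname(correct_isotope_overlap(as.numeric(m %*% x), m)),
                 x, tolerance = 1e-9)
  }
  # matrix form corrects each spectrum row at once
  xs <- matrix(runif(40, 0, 1500), ncol = 4)
  obs <- t(m %*% t(xs))
  expect_equal(unname(correct_isotope_overlap(obs, m)), xs, tolerance = 1e-9)
})

test_that("saturation filter drops whole spectra at the exclusive boundary", {
  psm <- make_psm(list(c(100, 200, 300, 400),
                       c(1600, 200, 300, 400),
                       c(1500, 200, 300, 400)))
  kept <- filter_saturated(psm, cfg, design)
  expect_equal(kept$spectrum_id, "sp01")
  expect_equal(attr(kept, "n_dropped"), 2L)
})

test_that("peptide ratios divide test channels by the reference", {
  psm <- make_psm(list(c(200, 100, 50, 100),
                       c(100, 100, 100, 100),
                       c(100, 100, 100, 0)))
  pr <- peptide_ratios(psm, design, cfg)
  expect_equal(unlist(pr$ratios[1, c("r114", "r115", "r116")]),
               c(r114 = 2, r115 = 1, r116 = 0.5))
  expect_equal(unlist(pr$ratios[2, c("r114", "r115", "r116")]),
               c(r114 = 1, r115 = 1, r116 = 1))
  expect_equal(pr$excluded$spectrum_id, "sp03")
  expect_equal(pr$excluded$reason, "zero reference")

  low <- make_psm(list(c(1, 1, 1, 1)), confidence = 80)
  pr2 <- peptide_ratios(low, design, cfg)
  expect_equal(nrow(pr2$ratios), 0L)
  expect_equal(pr2$excluded$reason, "low confidence")
})

test_that("protein roll-up applies identification gates and averages ratios", {
  ratios <- data.frame(
    protein_accession = c("P1", "P1", "P2"),
    peptide = c("a", "b", "c"), spectrum_id = c("s1", "s2", "s3"),
    r114 = c(1.3, 1.1, 1.0), r115 = c(1.4, 1.2, 1.0),
    r116 = c(1.2, 1.0, 1.0), stringsAsFactors = FALSE)
  scores <- make_scores(c("P1", "P2"))

  quant <- rollup_protein(ratios, scores, design, cfg)
  expect_equal(quant$protein_accession, "P1")  # P2 has 1 peptide
  expect_equal(attr(quant, "excluded_by_peptides"), "P2")
  expect_equal(unlist(quant[1, c("r114", "r115", "r116")]),
               c(r114 = 1.2, r115 = 1.3, r116 = 1.1))
  expect_equal(quant$mean_ratio, 1.2)

  scores_low <- make_scores(c("P1", "P2"), unused = 1.9)
  quant2 <- rollup_protein(ratios, scores_low, design, cfg)
  expect_equal(nrow(quant2), 0L)
  expect_setequal(attr(quant2, "excluded_by_score"), c("P1", "P2"))

  expect_error(rollup_protein(ratios, make_scores("P1"), design, cfg), "P2")
})

test_that("differential calls follow the 1.2/0.8 cutoffs with signed output", {
  quant <- data.frame(protein_accession = c("A", "B", "C"),
                      n_peptides = 2L,
                      r114 = c(1.25, 0.70, 1.00), r115 = c(1.20, 0.80, 1.00),
                      r116 = c(1.15, 0.75, 1.00),
                      mean_ratio = c(1.2, 0.75, 1.0),
                      stringsAsFactors = FALSE)
  called <- call_differential(quant, design, cfg)
  expect_equal(called$call, c("up", "down", "unchanged"))
  expect_equal(called$signed_expression, c(1.2, -0.75, 1.0))

  # consistency gate: mean passes the cutoff but one channel sits below unity
  mixed <- data.frame(protein_accession = "D", n_peptides = 2L,
                      r114 = 2.0, r115 = 1.9, r116 = 0.9, mean_ratio = 1.6,
                      stringsAsFactors = FALSE)
  expect_equal(call_differential(mixed, design, cfg)$call, "unchanged")
  lax <- quant_config(require_channel_consistency = FALSE)
  expect_equal(call_differential(mixed, design, lax)$call, "up")
})

test_that("quant table writer sorts by |signed expression| with accession ties", {
  quant <- call_differential(data.frame(
    protein_accession = c("PB", "PA", "PC"), n_peptides = 2L,
    r114 = c(1.5, 1.5, 0.7), r115 = c(1.5, 1.5, 0.7),
    r116 = c(1.5, 1.5, 0.7), mean_ratio = c(1.5, 1.5, 0.7),
    stringsAsFactors = FALSE), design, cfg)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_quant_table(quant, path)
  back <- read_quant_table(path)
  expect_equal(back$protein_accession, c("PA", "PB", "PC"))
  expect_equal(back$signed_expression, c(1.5, 1.5, -0.7))

  write_quant_table(quant[0, ], path)
  expect_equal(nrow(read_quant_table(path)), 0L)
})

test_that("ratios, calls and signed expressions are scale invariant", {
  # no saturated spectra, so rescaling cannot change which spectra qualify
  sim <- simulate_psm_experiment(psm_sim_config(n_proteins = 20L,
                                                saturation_frac = 0,
                                                seed = 9L))
  r1 <- quantify_proteins(sim$psm, sim$scores, design, cfg)
  scaled <- sim$psm
  ic <- paste0("i", design$channels)
  set.seed(9)
  const <- runif(nrow(scaled), 0.2, 0.9)
  scaled[, ic] <- scaled[, ic] * const
  r2 <- quantify_proteins(scaled, sim$scores, design, cfg)
  shared <- intersect(r1$quant$protein_accession, r2$quant$protein_accession)
  q1 <- r1$quant[match(shared, r1$quant$protein_accession), ]
  q2 <- r2$quant[match(shared, r2$quant$protein_accession), ]
  expect_equal(q1$mean_ratio, q2$mean_ratio, tolerance = 1e-9)
  expect_equal(q1$call, q2$call)
  expect_equal(q1$signed_expression, q2$signed_expression, tolerance = 1e-9)
})

test_that("a null experiment at low noise rarely triggers the cutoffs", {
  frac_called <- vapply(1:20, function(s) {
    sim <- simulate_psm_experiment(psm_sim_config(
      n_proteins = 60L, frac_up = 0, frac_down = 0, noise_cv = 0.05,
      saturation_frac = 0, frac_low_score = 0, seed = s))
    res <- quantify_proteins(sim$psm, sim$scores, design, cfg)
    with(res$report, (n_called_up + n_called_down) /
           (n_called_up + n_called_down + n_unchanged))
  }, numeric(1))
  expect_lte(mean(frac_called), 0.05)
})

test_that("exclusion accounting sums to the input protein count", {
  sim <- simulate_psm_experiment(psm_sim_config(seed = 3L))
  rep <- quantify_proteins(sim$psm, sim$scores, design, cfg)$report
  expect_equal(rep$n_input_proteins,
               rep$n_excluded_by_score + rep$n_excluded_by_peptides +
                 rep$n_called_up + rep$n_called_down + rep$n_unchanged)
})

test_that("signed-ratio listings tally into up/down/total counts", {
  signed <- c(1.5, 1.21, 1.2, -0.8, -0.75, -0.3, 1.0, -1.1)
  # entries inside the (0.8, 1.2) band or negated ratios above 0.8 don't count
  tally <- tally_differential_calls(signed)
  expect_equal(tally$up, 3L)
  expect_equal(tally$down, 3L)
  expect_equal(tally$total, 6L)
})
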
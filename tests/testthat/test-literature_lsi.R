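two_doc_corpus <- function() {
  corpus(data.frame(doc_id = c("d1", "d2"),
                    text = c("insulin signaling", "insulin receptor"),
                    stringsAsFactors = FALSE),
         list(GENE1 = "d1"))
}

test_that("tokenization and term-document counts match hand counts", {
  m <- build_term_document_matrix(two_doc_corpus())
  expect_equal(rownames(m), c("insulin", "receptor", "signaling"))
  expect_equal(unname(m[, "d1"]), c(1L, 0L, 1L))
  expect_equal(unname(m[, "d2"]), c(1L, 1L, 0L))

  expect_warning(
    corpus(data.frame(doc_id = c("d1", "d2"), text = c("a a a", "insulin"),
                      stringsAsFactors = FALSE)),
    "dropped")
})

test_that("corpus files round-trip through JSON-lines", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  corp <- two_doc_corpus()
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(back$documents, corp$documents)
  expect_equal(back$gene_links, corp$gene_links)

  sim <- simulate_corpus(corpus_sim_config(n_docs = 30L, n_genes = 5L,
                                           seed = 3L))
  write_corpus(sim$corpus, path)
  back <- read_corpus(path)
  expect_equal(back$documents$text, sim$corpus$documents$text)
  expect_equal(back$gene_links[order(names(back$gene_links))],
               sim$corpus$gene_links[order(names(sim$corpus$gene_links))])
})

test_that("log-entropy weighting matches the hand-derived global weights", {
  # term in exactly one of several documents: maximal information, g = 1
  counts <- rbind(solo = c(3, 0, 0), uniform = c(2, 2, 2),
                  mixed = c(2, 1, 1))
  colnames(counts) <- paste0("d", 1:3)
  w <- apply_log_entropy(counts)
  expect_equal(unname(w$global_weights["solo"]), 1)
  expect_equal(unname(w$global_weights["uniform"]), 0, tolerance = 1e-12)
  expect_equal(unname(w$values["uniform", ]), c(0, 0, 0),
               ignore_attr = TRUE)
  # tf (2,1,1): g = 1 + [0.5 log2 0.5 + 2 * 0.25 log2 0.25] / log2 3
  expect_equal(unname(w$global_weights["mixed"]), 1 - 1.5 / log2(3),
               tolerance = 1e-9)
  expect_equal(unname(w$values["mixed", "d1"]),
               log2(3) * (1 - 1.5 / log2(3)), tolerance = 1e-9)

  expect_error(apply_log_entropy(counts[, 1, drop = FALSE]), "2 documents")
})

test_that("truncated decomposition reconstructs and fixes signs", {
  set.seed(5)
  counts <- matrix(rpois(20 * 15, 2), 20, 15,
                   dimnames = list(sprintf("t%02d", 1:20),
                                   sprintf("d%02d", 1:15)))
  w <- apply_log_entropy(counts)
  full <- lsi_decompose(w, min(dim(w$values)))
  expect_equal(full$term_vectors %*% t(full$doc_vectors), w$values,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_true(all(diff(full$singular_values) <= 1e-12))
  # sign convention: the largest-magnitude term component is positive
  for (j in seq_len(full$k)) {
    col <- full$term_vectors[, j]
    expect_gt(col[which.max(abs(col))], 0)
  }

  # rank-1 input: one informative direction, exact reconstruction at k = 1
  r1 <- outer(runif(8), runif(6))
  w1 <- list(values = r1, vocabulary = paste0("t", 1:8),
             doc_index = paste0("d", 1:6),
             global_weights = rep(1, 8), scheme = "log-entropy")
  sp1 <- lsi_decompose(structure(w1, class = "weighted_matrix"), 1L)
  expect_equal(sp1$term_vectors %*% t(sp1$doc_vectors), r1,
               tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(lsi_decompose(w, 0L), "k must lie")
  expect_error(lsi_decompose(w, 99L), "k must lie")
})

test_that("truncated doc-doc cosines match an independent full decomposition", {
  set.seed(6)
  m <- matrix(rexp(20 * 15), 20, 15,
              dimnames = list(sprintf("t%02d", 1:20), sprintf("d%02d", 1:15)))
  w <- apply_log_entropy(m)
  sp <- lsi_decompose(w, 5L)
  # independent oracle: plain svd truncated to 5, docs as V Sigma rows
  s <- svd(w$values)
  oracle_docs <- s$v[, 1:5] %*% diag(s$d[1:5])
  cos_mat <- function(X) {
    X <- X / sqrt(rowSums(X^2))
    X %*% t(X)
  }
  expect_equal(cos_mat(sp$doc_vectors), cos_mat(oracle_docs),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("full-rank latent cosines reproduce weighted-space cosines", {
  set.seed(7)
  m <- matrix(rpois(30 * 12, 3), 30, 12,
              dimnames = list(sprintf("t%02d", 1:30), sprintf("d%02d", 1:12)))
  w <- apply_log_entropy(m)
  sp <- lsi_decompose(w, min(dim(w$values)))
  for (pair in list(c(1, 2), c(3, 10), c(5, 12))) {
    x1 <- w$values[, pair[1]]; x2 <- w$values[, pair[2]]
    orig <- sum(x1 * x2) / sqrt(sum(x1^2) * sum(x2^2))
    expect_equal(hypoproteo:::latent_cosine(hypoproteo:::fold_in(x1, sp),
                                            hypoproteo:::fold_in(x2, sp), sp),
                 orig, tolerance = 1e-8)
  }
})

test_that("gene vectors behave as pseudo-documents", {
  corp <- two_doc_corpus()
  counts <- build_term_document_matrix(corp)
  sp <- lsi_decompose(apply_log_entropy(counts), 2L)
  gv <- gene_vector("GENE1", corp, sp)
  d1 <- hypoproteo:::fold_in(sp$values[, "d1"], sp)
  expect_equal(hypoproteo:::latent_cosine(gv, d1, sp), 1, tolerance = 1e-9)
  # positive rescaling of the pseudo-document leaves its direction unchanged
  expect_equal(hypoproteo:::latent_cosine(gv * 7, d1, sp), 1,
               tolerance = 1e-9)
  expect_warning(missing <- gene_vector("NOPE", corp, sp), "no linked")
  expect_null(missing)
})

test_that("term correlation is a cosine in [-1, 1] with defined edge cases", {
  corp <- two_doc_corpus()
  sp <- lsi_decompose(apply_log_entropy(build_term_document_matrix(corp)), 2L)
  # "insulin" occurs uniformly in both documents, so log-entropy rightly
  # zeroes it out; "receptor" is the informative query here
  q <- query_vector("receptor", sp)
  expect_equal(hypoproteo:::latent_cosine(q, q, sp), 1, tolerance = 1e-12)
  expect_equal(hypoproteo:::latent_cosine(q, -q, sp), -1, tolerance = 1e-12)
  expect_equal(hypoproteo:::latent_cosine(q, q * 0, sp), 0)
  expect_warning(oov <- query_vector("xyzzy", sp), "no in-vocabulary")
  expect_null(oov)
  expect_true(is.na(correlate_term(NULL, "insulin", sp)))
})

test_that("scores are invariant to document order", {
  sim <- simulate_corpus(corpus_sim_config(n_docs = 40L, n_genes = 6L,
                                           seed = 8L))
  genes <- names(sim$corpus$gene_links)
  s1 <- lsi_correlate(genes, sim$corpus, terms = "diabetes", k = 5L)
  set.seed(1)
  perm <- sample(nrow(sim$corpus$documents))
  shuffled <- corpus(sim$corpus$documents[perm, ], sim$corpus$gene_links)
  s2 <- lsi_correlate(genes, shuffled, terms = "diabetes", k = 5L)
  expect_equal(s1$score, s2$score, tolerance = 1e-6)
})

test_that("planted gene-term associations are recovered with high AUC", {
  cc <- corpus_sim_config(seed = 3L)
  sim <- simulate_corpus(cc)
  corr <- lsi_correlate(cc$gene_symbols, sim$corpus, terms = "diabetes",
                        k = 10L)
  planted <- sim$truth$gene[sim$truth$term == "diabetes"]
  expect_gte(rank_auc(corr$score, corr$gene %in% planted), 0.9)
})

test_that("the report applies a strict threshold and keeps missing scores", {
  corr <- data.frame(gene = c("G1", "G2", "G3", "G4"),
                     term = "diabetes",
                     score = c(0.10, 0.25, NA, 0.11),
                     significant = c(FALSE, TRUE, FALSE, TRUE),
                     direction = c("up", "up", "down", "down"),
                     stringsAsFactors = FALSE)
  rep <- classify_report(corr, threshold = 0.1)
  expect_equal(rep$gene, c("G2", "G4"))     # 0.10 exactly is not significant
  expect_equal(rep$direction, c("up", "down"))
  expect_equal(nrow(classify_report(corr[0, ], 0.1)), 0L)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_lsi_table(corr, path)
  back <- read_tsv(path)
  expect_true(is.na(back$score[3]))          # missing is preserved, not zero
  expect_true(all(back$score >= -1 & back$score <= 1, na.rm = TRUE))
})
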
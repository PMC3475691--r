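#' Packaged stop-word list
#'
#' The short English stop-word list applied during tokenization. Frozen with
#' the package because latent-semantic scores depend on the exact
#' tokenization rules.
#'
#' @return character vector of lower-case stop words.
#' @export
lsi_stopwords <- function() {
  c("a", "an", "and", "are", "as", "at", "be", "been", "but", "by", "can",
    "did", "do", "for", "from", "had", "has", "have", "in", "into", "is",
    "it", "its", "may", "more", "most", "not", "of", "on", "or", "our",
    "such", "than", "that", "the", "their", "there", "these", "this",
    "those", "to", "was", "we", "were", "which", "while", "with", "within")
}

#' Tokenize free text for the term-document matrix
#'
#' Lower-cases, splits on non-alphanumeric characters, drops tokens shorter
#' than two characters and stop words from [lsi_stopwords()].
#'
#' @param text character vector.
#' @return list of token vectors, one per input string.
#' @export
lsi_tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) {
    t <- t[nchar(t) >= 2L]
    t[!t %in% lsi_stopwords()]
  })
}

#' Read a gene-tagged abstract corpus from JSON-lines
#'
#' One JSON object per line with fields `doc_id`, `text` and `genes` (the
#' gene symbols tagged to that abstract). Documents that are empty after
#' tokenization are dropped with a warning.
#'
#' @param path JSON-lines file.
#' @return list of class `corpus` with `documents` (data.frame `doc_id`,
#'   `text`) and `gene_links` (named list: gene symbol -> doc_id vector).
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  objs <- lapply(lines, jsonlite::fromJSON)
  docs <- data.frame(
    doc_id = vapply(objs, function(o) as.character(o$doc_id), character(1)),
    text = vapply(objs, function(o) as.character(o$text), character(1)),
    stringsAsFactors = FALSE)
  links <- list()
  for (o in objs) {
    for (g in unlist(o$genes))
      links[[g]] <- c(links[[g]], as.character(o$doc_id))
  }
  corpus(docs, links)
}

#' Construct a corpus object
#'
#' @param documents data.frame with `doc_id` and `text`.
#' @param gene_links named list mapping gene symbols to linked doc_ids.
#' @return list of class `corpus`.
#' @export
corpus <- function(documents, gene_links = list()) {
  if (anyDuplicated(documents$doc_id)) stop("doc_ids must be unique")
  empty <- lengths(lsi_tokenize(documents$text)) == 0L
  if (any(empty)) {
    warning(sum(empty), " document(s) empty after tokenization were dropped")
    documents <- documents[!empty, , drop = FALSE]
  }
  gene_links <- lapply(gene_links, function(d) {
    d <- unique(as.character(d))
    bad <- setdiff(d, documents$doc_id)
    if (length(bad)) stop("gene link to unknown doc_id: ", bad[1])
    d
  })
  structure(list(documents = documents, gene_links = gene_links),
            class = "corpus")
}

#' Write a corpus to JSON-lines
#' @param x a `corpus`.
#' @param path output path.
#' @export
write_corpus <- function(x, path) {
  gene_of_doc <- list()
  for (g in names(x$gene_links))
    for (d in x$gene_links[[g]])
      gene_of_doc[[d]] <- c(gene_of_doc[[d]], g)
  lines <- vapply(seq_len(nrow(x$documents)), function(i) {
    d <- x$documents$doc_id[i]
    jsonlite::toJSON(list(doc_id = d, text = x$documents$text[i],
                          genes = as.list(gene_of_doc[[d]] %||% character(0))),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Raw term-document count matrix
#'
#' @param corpus a `corpus`.
#' @param min_term_docs drop terms occurring in fewer than this many
#'   documents (default 1 keeps everything).
#' @return integer matrix, terms in rows (sorted), documents in columns
#'   (corpus order).
#' @export
build_term_document_matrix <- function(corpus, min_term_docs = 1L) {
  toks <- lsi_tokenize(corpus$documents$text)
  if (all(lengths(toks) == 0L)) stop("all documents empty after tokenization")
  vocab <- sort(unique(unlist(toks)))
  m <- matrix(0L, length(vocab), length(toks),
              dimnames = list(vocab, corpus$documents$doc_id))
  for (j in seq_along(toks)) {
    tab <- table(toks[[j]])
    m[names(tab), j] <- as.integer(tab)
  }
  if (min_term_docs > 1L) {
    df <- rowSums(m > 0)
    m <- m[df >= min_term_docs, , drop = FALSE]
  }
  m
}

#' Log-entropy weighting of a count matrix
#'
#' The weighting standard in literature latent-semantic systems: local weight
#' `log2(1 + tf)`, global weight
#' `g_i = 1 + sum_j p_ij log2(p_ij) / log2(n_docs)` with
#' `p_ij = tf_ij / gf_i`. A term confined to one document gets `g = 1`; a
#' term spread uniformly over all documents gets `g = 0`.
#'
#' @param counts non-negative term-document count matrix with >= 2 columns.
#' @return list of class `weighted_matrix` with `values`, `vocabulary`,
#'   `doc_index`, `global_weights` and `scheme`.
#' @export
apply_log_entropy <- function(counts) {
  if (ncol(counts) < 2L) stop("entropy weighting needs at least 2 documents")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- ncol(counts)
  gf <- rowSums(counts)
  p <- counts / ifelse(gf == 0, 1, gf)
  plogp <- ifelse(p > 0, p * log2(p), 0)
  g <- 1 + rowSums(plogp) / log2(n)
  values <- log2(1 + counts) * g
  structure(list(values = values, vocabulary = rownames(counts),
                 doc_index = colnames(counts), global_weights = g,
                 scheme = "log-entropy"),
            class = "weighted_matrix")
}

#' TF-IDF weighting (alternative scheme)
#'
#' Local raw term frequency times `log2(n_docs / df)`.
#'
#' @inheritParams apply_log_entropy
#' @return a `weighted_matrix`.
#' @export
apply_tfidf <- function(counts) {
  if (ncol(counts) < 2L) stop("idf weighting needs at least 2 documents")
  n <- ncol(counts)
  df <- rowSums(counts > 0)
  g <- log2(n / pmax(df, 1)) / log2(n)   # scaled to [0,1]
  structure(list(values = counts * log2(n / pmax(df, 1)),
                 vocabulary = rownames(counts), doc_index = colnames(counts),
                 global_weights = g, scheme = "tfidf"),
            class = "weighted_matrix")
}

#' Truncated singular decomposition of a weighted term-document matrix
#'
#' Rank-`k` latent semantic space. Signs are fixed deterministically: each
#' left singular vector is flipped, together with its right partner, so that
#' its largest-magnitude component is positive.
#'
#' @param weighted a `weighted_matrix`.
#' @param k truncation rank, `1 <= k <= min(terms, docs)`.
#' @return list of class `lsi_space` with `k`, `term_vectors` (terms x k),
#'   `doc_vectors` (docs x k, rows comparable via [correlate_term()]'s
#'   cosine), `singular_values`, `vocabulary`, `doc_index`,
#'   `global_weights`, and the weighted `values` used (needed for fold-in).
#' @export
lsi_decompose <- function(weighted, k) {
  v <- weighted$values
  if (k < 1L || k > min(dim(v)))
    stop("k must lie in [1, ", min(dim(v)), "]")
  s <- svd(v, nu = k, nv = k)
  d <- s$d[seq_len(k)]
  U <- s$u; V <- s$v
  for (j in seq_len(k)) {
    i_max <- which.max(abs(U[, j]))
    if (U[i_max, j] < 0) { U[, j] <- -U[, j]; V[, j] <- -V[, j] }
  }
  rownames(U) <- weighted$vocabulary
  rownames(V) <- weighted$doc_index
  structure(list(k = k, term_vectors = U,
                 doc_vectors = sweep(V, 2L, d, `*`),
                 singular_values = d,
                 vocabulary = weighted$vocabulary,
                 doc_index = weighted$doc_index,
                 global_weights = weighted$global_weights,
                 values = v),
            class = "lsi_space")
}

# Fold a weighted term-space column into the latent space; returns the
# classic pseudo-document coordinates v = Sigma^-1 U' x (rows-of-V scale).
fold_in <- function(x, space) {
  as.numeric(crossprod(space$term_vectors, x)) / space$singular_values
}

#' Latent-space vector of a gene's literature pseudo-document
#'
#' A gene is represented by the sum of its linked abstracts' weighted term
#' columns, folded into the space by projection onto the term vectors scaled
#' by the inverse singular values. The alternative centroid representation
#' averages the linked documents' latent vectors instead.
#'
#' @param gene gene symbol.
#' @param corpus the `corpus` the space was built from.
#' @param space an `lsi_space`.
#' @param method `"pseudo-document"` (default) or `"centroid"`.
#' @return numeric k-vector, or `NULL` (with a warning) for a gene with no
#'   linked document — a missing score, distinct from zero.
#' @export
gene_vector <- function(gene, corpus, space,
                        method = c("pseudo-document", "centroid")) {
  method <- match.arg(method)
  docs <- intersect(corpus$gene_links[[gene]] %||% character(0),
                    space$doc_index)
  if (length(docs) == 0L) {
    warning("gene '", gene, "' has no linked document; score is missing")
    return(NULL)
  }
  cols <- space$values[, docs, drop = FALSE]
  if (method == "pseudo-document") {
    fold_in(rowSums(cols), space)
  } else {
    vs <- vapply(docs, function(d) fold_in(space$values[, d], space),
                 numeric(space$k))
    rowMeans(matrix(vs, nrow = space$k))
  }
}

# cosine between two pseudo-document vectors, weighted by the singular
# values so that at full rank it reproduces cosines of the original weighted
# columns (x = U S v  =>  S v = U' x, and U is orthonormal).
latent_cosine <- function(a, b, space) {
  cosine_similarity(a * space$singular_values, b * space$singular_values)
}

#' Correlate a gene vector with an interrogation term
#'
#' The term is tokenized, weighted (local log, packaged global weights) and
#' folded into the space as a query pseudo-document; the score is the cosine
#' similarity with the gene vector in the latent space, in \[-1, 1\].
#' Positive scores indicate association strength; 0 is neutral; negative
#' scores indicate a strengthening lack of association.
#'
#' @param gene_vec k-vector from [gene_vector()] (or `NULL` for missing).
#' @param term interrogation term, e.g. `"diabetes"`.
#' @param space an `lsi_space`.
#' @return cosine score, 0 for zero-norm vectors, or `NA` (with a warning)
#'   when the term has no in-vocabulary token or the gene vector is missing.
#' @export
correlate_term <- function(gene_vec, term, space) {
  q <- query_vector(term, space)
  if (is.null(q) || is.null(gene_vec)) return(NA_real_)
  latent_cosine(gene_vec, q, space)
}

#' Latent-space vector of an interrogation term
#'
#' @param term query text; may tokenize to several terms.
#' @param space an `lsi_space`.
#' @return k-vector, or `NULL` with a warning when no token is in vocabulary.
#' @export
query_vector <- function(term, space) {
  toks <- lsi_tokenize(term)[[1]]
  toks <- toks[toks %in% space$vocabulary]
  if (length(toks) == 0L) {
    warning("term '", term, "' has no in-vocabulary token; score is missing")
    return(NULL)
  }
  tf <- table(toks)
  x <- numeric(length(space$vocabulary))
  names(x) <- space$vocabulary
  x[names(tf)] <- log2(1 + as.numeric(tf)) * space$global_weights[names(tf)]
  fold_in(x, space)
}

#' Score genes against interrogation terms through a literature LSI space
#'
#' End-to-end driver: builds the term-document matrix, weights it, truncates
#' the decomposition at rank `k`, and scores every gene against every term.
#'
#' @param genes character vector of gene symbols, or a data.frame with
#'   columns `gene` and `direction` (up/down labels carried from the
#'   quantification stage).
#' @param corpus a `corpus`.
#' @param terms interrogation terms; defaults to the study's four:
#'   Huntingtin, Chorea, Diabetes, Insulin.
#' @param k latent rank (default 10, suited to a desk-scale corpus).
#' @param threshold significance threshold on the score, strict `>`
#'   (default 0.1).
#' @param weighting `"log-entropy"` (default) or `"tfidf"`.
#' @param min_term_docs passed to [build_term_document_matrix()].
#' @param gene_method passed to [gene_vector()].
#' @return data.frame `gene, term, score, significant, direction`; missing
#'   scores are `NA` and never significant.
#' @export
lsi_correlate <- function(genes, corpus,
                          terms = c("Huntingtin", "Chorea", "Diabetes", "Insulin"),
                          k = 10L, threshold = 0.1,
                          weighting = c("log-entropy", "tfidf"),
                          min_term_docs = 1L,
                          gene_method = "pseudo-document") {
  weighting <- match.arg(weighting)
  if (is.data.frame(genes)) {
    direction <- stats::setNames(as.character(genes$direction), genes$gene)
    genes <- genes$gene
  } else direction <- stats::setNames(rep(NA_character_, length(genes)), genes)
  counts <- build_term_document_matrix(corpus, min_term_docs)
  weighted <- switch(weighting,
                     "log-entropy" = apply_log_entropy(counts),
                     "tfidf" = apply_tfidf(counts))
  k <- min(k, dim(weighted$values))
  space <- lsi_decompose(weighted, k)
  gvecs <- lapply(genes, function(g)
    withCallingHandlers(gene_vector(g, corpus, space, gene_method),
                        warning = function(w) invokeRestart("muffleWarning")))
  names(gvecs) <- genes
  rows <- list()
  for (tm in terms) {
    q <- withCallingHandlers(query_vector(tm, space),
                             warning = function(w) invokeRestart("muffleWarning"))
    for (g in genes) {
      score <- if (is.null(q) || is.null(gvecs[[g]])) NA_real_ else
        latent_cosine(gvecs[[g]], q, space)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, term = tm, score = score,
        significant = !is.na(score) && score > threshold,
        direction = direction[[g]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-term report of significantly correlated genes
#'
#' Keeps, for each interrogation term, the genes whose score strictly
#' exceeds the threshold, sorted by score descending, carrying their
#' regulation direction labels (up is conventionally rendered red,
#' down green).
#'
#' @param correlations data.frame from [lsi_correlate()].
#' @param threshold strict significance threshold (default 0.1); a score of
#'   exactly the threshold is not significant.
#' @return filtered, sorted data.frame with the same columns.
#' @export
classify_report <- function(correlations, threshold = 0.1) {
  if (nrow(correlations) == 0L) return(correlations)
  sig <- !is.na(correlations$score) & correlations$score > threshold
  out <- correlations[sig, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  out <- out[order(out$term, -out$score, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a gene-term correlation table
#' @param correlations data.frame from [lsi_correlate()] or
#'   [classify_report()]; `NA` scores are preserved as `NA`.
#' @param path output TSV path.
#' @export
write_lsi_table <- function(correlations, path) write_tsv(correlations, path)
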
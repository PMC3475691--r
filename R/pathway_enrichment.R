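#' Gene-set inclusion gates for enrichment reporting
#'
#' A set is reported as significantly enriched only when it overlaps the
#' query in at least `min_overlap` members, its enrichment p-value is below
#' `alpha`, and its enrichment ratio exceeds 1. No multiplicity correction is
#' applied by default; see the `adjust` argument of [enrich_all()].
#'
#' @param min_overlap minimum observed overlap (default 2).
#' @param alpha raw p-value cutoff, strict `<` (default 0.05).
#' @return list of class `enrich_gates`.
#' @export
enrich_gates <- function(min_overlap = 2L, alpha = 0.05) {
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(min_overlap = as.integer(min_overlap), alpha = alpha),
            class = "enrich_gates")
}

normalize_symbols <- function(x) unique(toupper(trimws(x)))

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `set_id`, `description`, then member symbols. Members are trimmed,
#' upper-cased and de-duplicated within a set. Unless an explicit background
#' is supplied, the annotation background is the union of all set members.
#'
#' @param path GMT file.
#' @param background optional character vector of background symbols, or a
#'   path to a plain-text file with one symbol per line; overrides the
#'   union-of-members default.
#' @return list of class `annotation_universe` with `sets` (named list of
#'   member vectors), `set_names` (named descriptions) and `background`.
#' @export
read_gmt <- function(path, background = NULL) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); set_names <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    id <- fields[1]
    if (id %in% names(sets)) stop("duplicate set id '", id, "' at line ", i)
    sets[[id]] <- normalize_symbols(fields[-(1:2)])
    set_names[id] <- fields[2]
  }
  annotation_universe(sets, set_names, background)
}

#' Construct an annotation universe from sets and a background
#'
#' @param sets named list of member-symbol vectors.
#' @param set_names named character vector of set descriptions (optional).
#' @param background background symbols, a file path, or `NULL` to use the
#'   union of all members.
#' @return list of class `annotation_universe`.
#' @export
annotation_universe <- function(sets, set_names = NULL, background = NULL) {
  sets <- lapply(sets, normalize_symbols)
  if (any(lengths(sets) < 1L)) stop("every set must have at least 1 member")
  if (is.null(set_names)) set_names <- stats::setNames(names(sets), names(sets))
  if (is.character(background) && length(background) == 1L &&
      file.exists(background))
    background <- readLines(background, warn = FALSE)
  if (is.null(background)) background <- unlist(sets, use.names = FALSE)
  background <- normalize_symbols(background)
  stray <- setdiff(unlist(sets, use.names = FALSE), background)
  if (length(stray))
    stop("set member(s) outside the background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  structure(list(sets = sets, set_names = set_names, background = background),
            class = "annotation_universe")
}

#' Write gene sets to a GMT file
#' @param universe an `annotation_universe`.
#' @param path output path.
#' @export
write_gmt <- function(universe, path) {
  lines <- vapply(names(universe$sets), function(id) {
    paste(c(id, universe$set_names[[id]], universe$sets[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric enrichment probability
#'
#' Probability of observing `O` or more members of a size-`K` set in a draw
#' of `n` from a background of `N`, i.e. `P(X >= O)` for
#' `X ~ Hypergeometric(N, K, n)`. Returns 1 when `O = 0`.
#'
#' @param O observed overlap, `0 <= O <= min(n, K)`.
#' @param n query size after background intersection.
#' @param K set size within the background.
#' @param N background size.
#' @return probability in (0, 1\].
#' @export
hypergeom_pvalue <- function(O, n, K, N) {
  if (any(c(O, n, K, N) < 0) || O > min(n, K) || n > N || K > N)
    stop("hypergeometric bounds violated: need 0 <= O <= min(n, K), n, K <= N")
  if (O == 0) return(1)
  stats::phyper(O - 1, K, N - K, n, lower.tail = FALSE)
}

#' Expected overlap and enrichment ratio
#'
#' Under random sampling from the background, the expected overlap of an
#' `n`-gene query with a size-`K` set is `E = n * K / N`; the enrichment
#' ratio is `R = O / E` (0 when the overlap is empty).
#'
#' @inheritParams hypergeom_pvalue
#' @return list with `E` and `R`.
#' @export
enrichment_stats <- function(O, n, K, N) {
  if (N <= 0 || n <= 0 || K <= 0) stop("n, K and N must be positive")
  E <- n * K / N
  R <- if (O == 0) 0 else O / E
  list(E = E, R = R)
}

#' Hybrid enrichment score
#'
#' The ranking statistic combining enrichment strength and significance:
#' `R * (-log10(p))`. Zero when `p = 1`.
#'
#' @param R enrichment ratio, `>= 0`.
#' @param p enrichment probability in (0, 1\].
#' @return non-negative when `R >= 1`.
#' @export
hybrid_score <- function(R, p) {
  if (any(p <= 0) || any(p > 1)) stop("p must lie in (0, 1]")
  if (any(R < 0)) stop("R must be >= 0")
  R * (-log10(p))
}

#' Score every annotated set against a query gene list
#'
#' Intersects the query with the background (dropping and counting symbols
#' outside it), computes the overlap, expectation, enrichment ratio,
#' hypergeometric p-value and hybrid score for every set, applies the
#' inclusion gates, and ranks by hybrid score (descending, ties by set id).
#'
#' @param query character vector of query symbols (case-insensitive).
#' @param universe an `annotation_universe` from [read_gmt()].
#' @param gates an [enrich_gates()].
#' @param adjust `"none"` (default, the raw-p gate) or `"BH"` to gate on
#'   Benjamini-Hochberg adjusted p-values instead.
#' @return data.frame `set_id, set_name, O, E, R, p, hybrid_score,
#'   significant`, one row per set; attribute `n_query_dropped` counts query
#'   symbols outside the background.
#' @export
enrich_all <- function(query, universe, gates = enrich_gates(),
                       adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query <- normalize_symbols(query)
  in_bg <- query %in% universe$background
  n_dropped <- sum(!in_bg)
  if (n_dropped)
    warning(n_dropped, " query symbol(s) outside the background were dropped")
  query <- query[in_bg]
  empty <- data.frame(set_id = character(0), set_name = character(0),
                      O = integer(0), E = numeric(0), R = numeric(0),
                      p = numeric(0), hybrid_score = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
  if (length(query) == 0L) {
    warning("empty query after background intersection; no enrichment computed")
    attr(empty, "n_query_dropped") <- n_dropped
    return(empty)
  }
  n <- length(query); N <- length(universe$background)
  rows <- lapply(names(universe$sets), function(id) {
    members <- universe$sets[[id]]
    K <- length(members)
    O <- length(intersect(query, members))
    st <- enrichment_stats(O, n, K, N)
    p <- hypergeom_pvalue(O, n, K, N)
    data.frame(set_id = id, set_name = universe$set_names[[id]],
               O = O, E = st$E, R = st$R, p = p,
               hybrid_score = hybrid_score(st$R, p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  p_gate <- if (adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
  res$significant <- res$O >= gates$min_overlap & p_gate < gates$alpha &
    res$R > 1
  res <- res[order(-res$hybrid_score, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_query_dropped") <- n_dropped
  res
}

#' Write an enrichment result table
#' @param res data.frame from [enrich_all()].
#' @param path output TSV path.
#' @export
write_enrichment_table <- function(res, path) write_tsv(res, path)
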
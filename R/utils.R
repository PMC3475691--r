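#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a tab-separated table with a header
#'
#' Thin wrapper around [utils::write.table()] fixing the dialect used by all
#' package outputs: tab separator, no quoting, no row names, `\n` line ends,
#' `.` decimal separator, `NA` written literally.
#'
#' @param x data.frame to write.
#' @param path output file path.
#' @export
write_tsv <- function(x, path) {
  ok <- tryCatch({
    utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n", na = "NA")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path input file path.
#' @return data.frame with character columns left unfactored.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'")
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Ranking AUC by the Mann-Whitney statistic
#'
#' Probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, with ties counted 1/2. Used to summarise how well a score
#' separates planted from background items.
#'
#' @param scores numeric scores (higher = more positive-like). `NA` dropped.
#' @param labels logical, `TRUE` for positives, same length as `scores`.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  keep <- !is.na(scores)
  scores <- scores[keep]; labels <- as.logical(labels[keep])
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("need at least one positive and one negative")
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Deterministic sub-stream seed for entity i of a simulation seeded with
# `seed`; keeps derived seeds inside 32-bit integer range so adding entities
# never reshuffles existing ones.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 100003 + as.numeric(i) * 7919) %% 2147483629)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  s <- sum(a * b) / (na * nb)
  max(-1, min(1, s))
}
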
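#' Read a longitudinal plasma analyte panel
#'
#' Long-format TSV: `subject_id  genotype  age_months  analyte  value  units`,
#' one row per measurement. Genotypes are tgHD/WT and ages 3/9/12 months in
#' the emulated study, but any two-genotype, multi-age panel validates.
#'
#' @param path TSV file.
#' @return validated data.frame.
#' @export
read_panel <- function(path) validate_panel(read_tsv(path))

validate_panel <- function(panel) {
  need <- c("subject_id", "genotype", "age_months", "analyte", "value")
  missing <- setdiff(need, names(panel))
  if (length(missing))
    stop("panel is missing column(s): ", paste(missing, collapse = ", "))
  if (!all(is.finite(panel$value))) stop("panel values must be finite")
  key <- paste(panel$subject_id, panel$age_months, panel$analyte, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (subject_id, age_months, analyte) measurement")
  panel
}

#' Write a plasma analyte panel
#' @param panel data.frame.
#' @param path output TSV path.
#' @export
write_panel <- function(panel, path) write_tsv(panel, path)

#' Two-sample Student's t-test
#'
#' Classical pooled-variance two-sided t-test (`df = nA + nB - 2`); Welch's
#' unequal-variance form is available as an option. Two degenerate inputs are
#' defined rather than errors: identical constant groups give `t = 0, p = 1`;
#' constant groups with different means have no valid t-statistic and raise
#' an error.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param comparison label carried into the result row.
#' @param var_equal pooled variance if `TRUE` (default, the Student form).
#' @param alpha significance level, strict `<` (default 0.05).
#' @return one-row data.frame `comparison, statistic, df, p, significant`.
#' @export
students_t <- function(a, b, comparison = "A vs B", var_equal = TRUE,
                       alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b))
      return(data.frame(comparison = comparison, statistic = 0,
                        df = length(a) + length(b) - 2, p = 1,
                        significant = FALSE, stringsAsFactors = FALSE))
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  p <- unname(tt$p.value)
  data.frame(comparison = comparison, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p = p, significant = p < alpha,
             stringsAsFactors = FALSE)
}

#' Two-way ANOVA with genotype and age as crossed factors
#'
#' Fits `value ~ genotype * age` by sequential (type I) sums of squares;
#' with the balanced cells of the emulated design (n = 5 per
#' genotype-by-age cell) this coincides with the other SS types. All effects
#' are tested against the residual mean square.
#'
#' @param rows panel rows for a single analyte.
#' @param alpha significance level (default 0.05).
#' @return data.frame `effect, ss, df, F, p` with rows genotype, age,
#'   genotype:age and residual.
#' @export
two_way_anova <- function(rows, alpha = 0.05) {
  g <- factor(rows$genotype); a <- factor(rows$age_months)
  if (nlevels(g) < 2L || nlevels(a) < 2L)
    stop("need at least 2 genotype and 2 age levels")
  cells <- table(g, a)
  if (any(cells < 2L)) {
    bad <- which(cells < 2L, arr.ind = TRUE)[1, ]
    stop("cell (", levels(g)[bad[1]], ", ", levels(a)[bad[2]],
         " months) has fewer than 2 replicates")
  }
  fit <- stats::aov(value ~ g * a, data = data.frame(value = rows$value,
                                                     g = g, a = a))
  tab <- summary(fit)[[1]]
  eff <- trimws(rownames(tab))
  eff <- c("genotype", "age", "genotype:age", "residual")[
    match(eff, c("g", "a", "g:a", "Residuals"))]
  out <- data.frame(effect = eff, ss = tab[["Sum Sq"]], df = tab[["Df"]],
                    F = tab[["F value"]], p = tab[["Pr(>F)"]],
                    stringsAsFactors = FALSE)
  # a literally zero effect sum of squares carries no signal even when the
  # residual is also zero (all values identical): report F = 0, p = 1
  null_eff <- out$effect != "residual" & out$ss < 1e-12
  out$F[null_eff] <- 0
  out$p[null_eff] <- 1
  out
}

# group values for one analyte / genotype / age, NULL when absent
panel_cell <- function(rows, genotype, age) {
  v <- rows$value[rows$genotype == genotype & rows$age_months == age]
  if (length(v) < 2L) NULL else v
}

#' Run the two-track longitudinal statistics scheme on a panel
#'
#' For every analyte: (i) genotype contrasts (tgHD vs WT) at each age;
#' (ii) within-genotype longitudinal contrasts against the youngest age as
#' baseline (9 vs 3 and 12 vs 3 months under the default ages); and (iii)
#' one genotype-by-age two-way ANOVA. Comparisons with a missing group are
#' skipped with a warning; the rest proceed.
#'
#' @param panel validated analyte panel.
#' @param genotypes two genotype labels, test first (default
#'   `c("tgHD", "WT")`).
#' @param ages ordered age groups in months; the first is the longitudinal
#'   baseline (default `c(3, 9, 12)`).
#' @param alpha significance level (default 0.05).
#' @return list with `t_tests` (data.frame with an `analyte` column plus the
#'   [students_t()] columns, in fixed scheme order) and `anova` (named list
#'   of per-analyte ANOVA tables).
#' @export
run_longitudinal_panel <- function(panel, genotypes = c("tgHD", "WT"),
                                   ages = c(3, 9, 12), alpha = 0.05) {
  panel <- validate_panel(panel)
  baseline <- ages[1]
  t_rows <- list(); anova_tabs <- list()
  for (an in unique(panel$analyte)) {
    rows <- panel[panel$analyte == an, , drop = FALSE]
    add <- function(a, b, label) {
      if (is.null(a) || is.null(b)) {
        warning("skipping '", label, "' for ", an, ": missing group")
        return(invisible())
      }
      res <- students_t(a, b, comparison = label, alpha = alpha)
      res <- cbind(analyte = an, res, stringsAsFactors = FALSE)
      t_rows[[length(t_rows) + 1L]] <<- res
    }
    for (age in ages)
      add(panel_cell(rows, genotypes[1], age),
          panel_cell(rows, genotypes[2], age),
          sprintf("%s vs %s at %sm", genotypes[1], genotypes[2], age))
    for (gt in genotypes)
      for (age in ages[-1])
        add(panel_cell(rows, gt, age), panel_cell(rows, gt, baseline),
            sprintf("%s %sm vs %sm", gt, age, baseline))
    anova_tabs[[an]] <- tryCatch(two_way_anova(rows, alpha),
                                 error = function(e) {
                                   warning("ANOVA skipped for ", an, ": ",
                                           conditionMessage(e))
                                   NULL
                                 })
  }
  t_tests <- if (length(t_rows)) do.call(rbind, t_rows) else
    data.frame(analyte = character(0), comparison = character(0),
               statistic = numeric(0), df = numeric(0), p = numeric(0),
               significant = logical(0), stringsAsFactors = FALSE)
  rownames(t_tests) <- NULL
  list(t_tests = t_tests, anova = anova_tabs)
}

#' Write the longitudinal statistics results
#'
#' Emits one TSV of t-test rows and one TSV of stacked ANOVA blocks
#' (analyte column plus the per-effect rows).
#'
#' @param results list from [run_longitudinal_panel()].
#' @param t_path,anova_path output TSV paths.
#' @export
write_stats_tables <- function(results, t_path, anova_path) {
  write_tsv(results$t_tests, t_path)
  blocks <- lapply(names(results$anova), function(an) {
    tab <- results$anova[[an]]
    if (is.null(tab)) return(NULL)
    cbind(analyte = an, tab, stringsAsFactors = FALSE)
  })
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  anova_df <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(analyte = character(0), effect = character(0),
               ss = numeric(0), df = numeric(0), F = numeric(0),
               p = numeric(0), stringsAsFactors = FALSE)
  write_tsv(anova_df, anova_path)
  invisible(list(t_path, anova_path))
}
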
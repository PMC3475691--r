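#' Default pipeline configuration
#'
#' Assembles the per-stage settings with the scheme defaults: 1.2/0.8
#' fold-change cutoffs, 1500-count saturation, 2-peptide/95%-confidence/2.0
#' ProtScore identification gates, 2-protein and p < 0.05 enrichment gates,
#' rank-10 LSI with the 0.1 score threshold and the four standard
#' interrogation terms.
#'
#' @param inputs named list of input paths: `psm`, `scores`, `gmt`,
#'   optionally `background`, `corpus`, `panel`.
#' @param out_dir output directory.
#' @param quant,enrich,lsi,stats per-stage option lists overriding
#'   defaults.
#' @param seed seed echoed into the report (inputs are files; the pipeline
#'   itself draws no random numbers).
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(inputs = list(), out_dir = ".",
                            quant = list(), enrich = list(), lsi = list(),
                            stats = list(), seed = 1L, log_level = "info") {
  lsi_defaults <- list(k = 10L, threshold = 0.1,
                       terms = c("Huntingtin", "Chorea", "Diabetes", "Insulin"))
  stats_defaults <- list(alpha = 0.05)
  check_keys <- function(given, allowed, section) {
    unknown <- setdiff(names(given), allowed)
    if (length(unknown))
      stop("unknown ", section, " key(s): ", paste(unknown, collapse = ", "))
  }
  check_keys(inputs, c("psm", "scores", "gmt", "background", "corpus",
                       "panel"), "inputs")
  check_keys(quant, names(formals(quant_config)), "quant")
  check_keys(enrich, c(names(formals(enrich_gates)), "adjust"), "enrich")
  check_keys(lsi, c(names(lsi_defaults), "weighting"), "lsi")
  check_keys(stats, names(stats_defaults), "stats")
  num_keys <- c("saturation_threshold", "up_cutoff", "down_cutoff",
                "min_peptides", "min_peptide_confidence_pct",
                "min_unused_protscore", "min_overlap", "alpha", "k",
                "threshold")
  for (section in list(quant, enrich, lsi, stats))
    for (key in intersect(names(section), num_keys))
      if (!is.numeric(section[[key]]))
        stop("config key '", key, "' must be numeric, got '",
             section[[key]], "'")
  structure(list(inputs = inputs, out_dir = out_dir,
                 quant = quant, enrich = enrich,
                 lsi = utils::modifyList(lsi_defaults, lsi),
                 stats = utils::modifyList(stats_defaults, stats),
                 seed = seed, log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys take their defaults; unknown keys are rejected by name; a
#' saved configuration reloads identically.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- c("inputs", "out_dir", "quant", "enrich", "lsi", "stats",
               "seed", "log_level")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, raw)
}

#' Save a pipeline configuration to YAML
#' @param config a `pipeline_config`.
#' @param path output path.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

log_stage <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message("[hypoproteo] ", ...)
}

run_stage <- function(name, config, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Quantification feeds enrichment twice — once with the up-regulated and
#' once with the down-regulated protein set, which partition the
#' differential list — and feeds the literature LSI stage with direction
#' labels; the longitudinal statistics scheme runs independently on the
#' analyte panel. Stages whose inputs are not configured are skipped. All
#' primary outputs are deterministic given identical inputs.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) list with stage results (`quant`, `enrichment_up`,
#'   `enrichment_down`, `lsi`, `stats`), the `report` data.frame of
#'   per-stage counts, and `outputs` (written file paths).
#' @export
run_all <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  outputs <- character(0)
  report <- list()
  note <- function(stage, metric, value)
    report[[length(report) + 1L]] <<- data.frame(
      stage = stage, metric = metric, value = value,
      stringsAsFactors = FALSE)

  qc <- do.call(quant_config, config$quant)
  design <- channel_design()

  # --- quantification ------------------------------------------------------
  log_stage(config, "quant: reading PSM and score tables")
  res <- run_stage("quant", config, {
    psm <- read_psm_table(config$inputs$psm, design)
    scores <- read_tsv(config$inputs$scores)
    quantify_proteins(psm, scores, design, qc)
  })
  quant <- res$quant
  for (m in names(res$report)) note("quant", m, res$report[[m]])
  write_quant_table(quant, out("quant.tsv"))
  outputs <- c(outputs, out("quant.tsv"))

  up_set <- quant$protein_accession[quant$call == "up"]
  down_set <- quant$protein_accession[quant$call == "down"]
  if (length(up_set) + length(down_set) == 0L)
    warning("quantification produced no differential proteins; ",
            "enrichment and LSI outputs will be empty")

  # --- enrichment (up and down sets separately) ----------------------------
  enr <- list(up = NULL, down = NULL)
  if (!is.null(config$inputs$gmt)) {
    gates <- do.call(enrich_gates,
                     config$enrich[setdiff(names(config$enrich), "adjust")])
    adjust <- config$enrich$adjust %||% "none"
    universe <- run_stage("enrichment", config,
                          read_gmt(config$inputs$gmt,
                                   config$inputs$background))
    for (dir in c("up", "down")) {
      set <- if (dir == "up") up_set else down_set
      log_stage(config, "enrichment: ", dir, " set of ", length(set))
      enr[[dir]] <- run_stage("enrichment", config,
        suppressWarnings(enrich_all(set, universe, gates, adjust)))
      note("enrichment", paste0("n_", dir, "_query"), length(set))
      note("enrichment", paste0("n_", dir, "_significant"),
           sum(enr[[dir]]$significant))
      write_enrichment_table(enr[[dir]], out(paste0("enrichment_", dir, ".tsv")))
      outputs <- c(outputs, out(paste0("enrichment_", dir, ".tsv")))
    }
  }

  # --- literature LSI ------------------------------------------------------
  lsi <- NULL
  if (!is.null(config$inputs$corpus)) {
    log_stage(config, "lsi: correlating ", length(up_set) + length(down_set),
              " differential proteins")
    lsi <- run_stage("lsi", config, {
      corp <- read_corpus(config$inputs$corpus)
      genes <- data.frame(
        gene = c(up_set, down_set),
        direction = c(rep("up", length(up_set)),
                      rep("down", length(down_set))),
        stringsAsFactors = FALSE)
      if (nrow(genes) == 0L) {
        warning("no differential proteins; LSI report is empty")
        data.frame(gene = character(0), term = character(0),
                   score = numeric(0), significant = logical(0),
                   direction = character(0), stringsAsFactors = FALSE)
      } else {
        lsi_correlate(genes, corp, terms = config$lsi$terms,
                      k = config$lsi$k, threshold = config$lsi$threshold,
                      weighting = config$lsi$weighting %||% "log-entropy")
      }
    })
    note("lsi", "n_scores", nrow(lsi))
    note("lsi", "n_significant", sum(lsi$significant))
    write_lsi_table(lsi, out("lsi.tsv"))
    write_lsi_table(classify_report(lsi, config$lsi$threshold),
                    out("lsi_significant.tsv"))
    outputs <- c(outputs, out("lsi.tsv"), out("lsi_significant.tsv"))
  }

  # --- longitudinal plasma statistics --------------------------------------
  stats_res <- NULL
  if (!is.null(config$inputs$panel)) {
    log_stage(config, "stats: longitudinal panel scheme")
    stats_res <- run_stage("stats", config, {
      panel <- read_panel(config$inputs$panel)
      run_longitudinal_panel(panel, alpha = config$stats$alpha)
    })
    note("stats", "n_t_tests", nrow(stats_res$t_tests))
    note("stats", "n_significant_t", sum(stats_res$t_tests$significant))
    note("stats", "n_anova", length(stats_res$anova))
    write_stats_tables(stats_res, out("stats_t_tests.tsv"),
                       out("stats_anova.tsv"))
    outputs <- c(outputs, out("stats_t_tests.tsv"), out("stats_anova.tsv"))
  }

  report_df <- do.call(rbind, report)
  write_tsv(report_df, out("report.tsv"))
  txt <- c("hypoproteo pipeline report",
           sprintf("  %-12s %-28s %s", report_df$stage, report_df$metric,
                   report_df$value))
  writeLines(txt, out("report.txt"))
  outputs <- c(outputs, out("report.tsv"), out("report.txt"))
  invisible(list(quant = quant, enrichment_up = enr$up,
                 enrichment_down = enr$down, lsi = lsi, stats = stats_res,
                 report = report_df, outputs = outputs))
}

#' Generate a coherent synthetic input bundle
#'
#' Writes, under `dir`, a PSM table, ProtScore table, GMT annotation with
#' background, gene-tagged corpus and plasma panel whose symbol spaces agree
#' (corpus genes and gene-set members are the simulated protein accessions),
#' so [run_all()] can be exercised end-to-end with known ground truth.
#'
#' @param dir directory for the input files (created if absent).
#' @param seed master seed; stage generators derive their own sub-streams.
#' @param n_proteins passed to [psm_sim_config()].
#' @return list with the written `paths` (usable as the `inputs` entry of
#'   [pipeline_config()]) and the per-stage `truth` objects.
#' @export
simulate_input_bundle <- function(dir, seed = 1L, n_proteins = 200L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  sim <- simulate_psm_experiment(psm_sim_config(n_proteins = n_proteins,
                                                seed = seed))
  write_psm_table(sim$psm, p("psm.tsv"))
  write_tsv(sim$scores, p("scores.tsv"))
  accs <- sim$truth$proteins$protein_accession
  diff_accs <- accs[sim$truth$proteins$direction != "unchanged"]
  ann <- simulate_annotations(background_symbols = accs,
                              strength = 0.8, seed = seed + 1L)
  # re-plant the designated set from the truly differential proteins so the
  # pipeline's enrichment stage has a recoverable signal
  sets <- ann$universe$sets
  k_planted <- length(sets[[ann$planted_set_id]])
  n_diff <- min(round(0.8 * k_planted), length(diff_accs))
  set.seed(sub_seed(seed + 1L, 999L))
  sets[[ann$planted_set_id]] <- c(
    sample(diff_accs, n_diff),
    sample(setdiff(accs, diff_accs), k_planted - n_diff))
  ann$universe <- annotation_universe(sets, ann$universe$set_names,
                                      background = accs)
  write_gmt(ann$universe, p("sets.gmt"))
  writeLines(ann$universe$background, p("background.txt"))
  corp <- simulate_corpus(corpus_sim_config(
    gene_symbols = c(diff_accs, utils::head(setdiff(accs, diff_accs), 10)),
    seed = seed + 2L))
  write_corpus(corp$corpus, p("corpus.jsonl"))
  panel <- simulate_plasma_panel(panel_sim_config(seed = seed + 3L))
  write_panel(panel$panel, p("panel.tsv"))
  list(paths = list(psm = p("psm.tsv"), scores = p("scores.tsv"),
                    gmt = p("sets.gmt"), background = p("background.txt"),
                    corpus = p("corpus.jsonl"), panel = p("panel.tsv")),
       truth = list(psm = sim$truth, annotations = ann,
                    corpus = corp$truth, panel = panel$truth))
}
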
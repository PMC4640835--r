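#' Run the full matched-cohort differential-regulation pipeline
#'
#' Executes the stages end to end from on-disk inputs: read and pair the
#' expression matrix, apply the detectable-change filter, run the f_up
#' screen, compute proliferation scores and the detrended f_up screen,
#' gene-set enrichment on both statistics, and (when methylation inputs are
#' supplied) probe-level f_up, gene regulation calls and the TSS/gene-body
#' odds ratios; optionally a co-differential-expression profile for a
#' target gene. All result tables are written as TSVs plus a JSON run
#' summary recording the configuration in effect.
#'
#' @param config Named list. Required paths: `expression`, `manifest`,
#'   `signature` (one gene id per line). Optional paths: `gene_sets` (GMT),
#'   `methylation`, `probe_annotation`. Options (with defaults):
#'   `min_detectable_fraction` (0.5), `level` (0.95), `bonferroni_ci`
#'   (FALSE), `prior` ("uniform"), `alpha` (0.05), `min_set_size` (5),
#'   `detrend` (TRUE), `codiff_target` (NULL), `log2_transform` (FALSE).
#' @param out_dir Output directory; must not already contain a run summary
#'   (outputs are write-once per run directory).
#' @return Invisibly, a list of the in-memory results (`fup`, `detrended`,
#'   `enrichment_fup`, `enrichment_detrended`, `calls`, `odds_ratios`,
#'   `codiff`, `summary`).
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "run_summary.json")
  if (file.exists(summary_path))
    stop("output directory already holds a completed run: ", out_dir)
  stages <- character(0)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    message(sprintf("[%s] starting", name))
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    stages <<- c(stages, name)
    res
  }
  out <- list()

  mat <- stage("read_expression",
               read_marker_matrix(cfg$expression, "mrna",
                                  log2_transform = cfg$log2_transform))
  manifest <- stage("read_manifest", read_manifest(cfg$manifest))
  cohort <- stage("match", build_matched_cohort(mat, manifest))
  cohort <- stage("filter_detectable",
                  filter_detectable(cohort, cfg$min_detectable_fraction))

  out$fup <- stage("fup_screen",
                   fup_screen(cohort, level = cfg$level,
                              bonferroni_ci = cfg$bonferroni_ci,
                              prior = cfg$prior))
  write_marker_table(out$fup, file.path(out_dir, "fup_screen.tsv"))

  signature <- readLines(cfg$signature, warn = FALSE)
  scores <- stage("proliferation_scores",
                  cohort_proliferation_scores(cohort, signature))
  utils::write.table(
    data.frame(patient_id = cohort$patients,
               score_tumor = unname(scores$tumor[cohort$patients]),
               score_normal = unname(scores$normal[cohort$patients])),
    file.path(out_dir, "proliferation_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  if (cfg$detrend) {
    out$detrended <- stage("detrended_fup_screen",
                           detrended_fup_screen(cohort, scores,
                                                level = cfg$level,
                                                bonferroni_ci = cfg$bonferroni_ci,
                                                prior = cfg$prior))
    write_marker_table(out$detrended,
                       file.path(out_dir, "detrended_fup_screen.tsv"))
  }

  if (!is.null(cfg$gene_sets)) {
    collection <- read_gmt(cfg$gene_sets)
    fup_stat <- stats::setNames(out$fup$f_up, out$fup$marker_id)
    out$enrichment_fup <- stage("enrichment_fup",
                                enrichment_screen(fup_stat, collection,
                                                  cfg$min_set_size))
    utils::write.table(out$enrichment_fup,
                       file.path(out_dir, "enrichment_fup.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (cfg$detrend) {
      dt_stat <- stats::setNames(out$detrended$f_up, out$detrended$marker_id)
      out$enrichment_detrended <- stage("enrichment_detrended",
                                        enrichment_screen(dt_stat, collection,
                                                          cfg$min_set_size))
      utils::write.table(out$enrichment_detrended,
                         file.path(out_dir, "enrichment_detrended.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(cfg$codiff_target)) {
      prof <- stage("codiff",
                    codiff_profile(cfg$codiff_target, cohort))
      out$codiff <- pathway_codiff_enrichment(prof, collection)
      utils::write.table(out$codiff, file.path(out_dir, "codiff.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if (!is.null(cfg$methylation) && !is.null(cfg$probe_annotation) &&
      cfg$detrend) {
    meth_mat <- stage("read_methylation",
                      read_marker_matrix(cfg$methylation, "methylation"))
    annotation <- read_probe_annotation(cfg$probe_annotation)
    meth_cohort <- stage("match_methylation",
                         build_matched_cohort(meth_mat, manifest))
    meth_cohort <- filter_detectable(meth_cohort,
                                     cfg$min_detectable_fraction)
    meth_tab <- stage("fup_screen_methylation", fup_screen(meth_cohort))
    write_marker_table(meth_tab, file.path(out_dir, "fup_methylation.tsv"))
    out$calls <- stage("classify_genes",
                       classify_genes(out$detrended, alpha = cfg$alpha))
    probe_stats <- stats::setNames(meth_tab$f_up, meth_tab$marker_id)
    out$odds_ratios <- stage("methylation_odds_ratios", {
      lapply(c(tss = "tss", gene_body = "gene_body"), function(rg)
        methylation_odds_ratio(probe_stats, annotation, out$calls, rg))
    })
    or_df <- do.call(rbind, lapply(out$odds_ratios, function(o)
      data.frame(region = o$region, a = o$a, b = o$b, c = o$c, d = o$d,
                 odds_ratio = o$odds_ratio, ci_low = o$ci_low,
                 ci_high = o$ci_high, p_value = o$p_value,
                 stringsAsFactors = FALSE)))
    utils::write.table(or_df, file.path(out_dir, "methylation_odds_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  out$summary <- list(
    package_version = as.character(utils::packageVersion("fupscreen")),
    stages = stages,
    config = cfg[!vapply(cfg, is.null, logical(1L))],
    n_patients = length(cohort$patients),
    n_markers = nrow(cohort$tumor),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(out$summary, summary_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  message(sprintf("pipeline complete: %d stage(s), outputs in %s",
                  length(stages), out_dir))
  invisible(out)
}

validate_run_config <- function(config) {
  defaults <- list(min_detectable_fraction = 0.5, level = 0.95,
                   bonferroni_ci = FALSE, prior = "uniform", alpha = 0.05,
                   min_set_size = 5, detrend = TRUE, codiff_target = NULL,
                   log2_transform = FALSE, gene_sets = NULL,
                   methylation = NULL, probe_annotation = NULL)
  cfg <- utils::modifyList(defaults, config)
  for (key in c("expression", "manifest", "signature")) {
    if (is.null(cfg[[key]]))
      stop("config error: required path '", key, "' missing")
    if (!file.exists(cfg[[key]]))
      stop("config error: ", key, " file not found: ", cfg[[key]])
  }
  for (key in c("gene_sets", "methylation", "probe_annotation")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("config error: ", key, " file not found: ", cfg[[key]])
  }
  if (cfg$level <= 0 || cfg$level >= 1) stop("config error: level in (0,1)")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("config error: alpha in (0,1)")
  cfg
}
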
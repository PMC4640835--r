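#' Classify genes as up-, down-regulated or neutral
#'
#' Calls a gene `up` when its Bonferroni-adjusted detrended f_up p-value is
#' below `alpha` with `f_up > 0.5`, `down` with `f_up < 0.5`; everything
#' else (including `f_up` exactly 0.5 and untestable markers) is `neutral`.
#'
#' @param detrended_table A `marker_table` (typically from
#'   [detrended_fup_screen()]) with columns `marker_id`, `f_up`, `p_bonf`.
#' @param alpha Significance threshold on the Bonferroni-adjusted p.
#'   Default 0.05.
#' @return data.frame: `gene`, `call` (`up`/`down`/`neutral`), `p_bonf`.
#' @export
classify_genes <- function(detrended_table, alpha = 0.05) {
  need <- c("marker_id", "f_up", "p_bonf")
  miss <- setdiff(need, names(detrended_table))
  if (length(miss)) stop("table missing column(s): ",
                         paste(miss, collapse = ", "))
  sig <- !is.na(detrended_table$p_bonf) & detrended_table$p_bonf < alpha
  call <- ifelse(sig & detrended_table$f_up > 0.5, "up",
                 ifelse(sig & detrended_table$f_up < 0.5, "down", "neutral"))
  data.frame(gene = detrended_table$marker_id, call = call,
             p_bonf = detrended_table$p_bonf,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Median-split methylation odds ratio for one probe region
#'
#' Quantifies methylation asymmetry at probes of one region class: the
#' median of the probe statistic (methylation f_up, the fraction of
#' patients hypermethylated in tumor) is taken over ALL probes of the
#' chosen region, and a 2x2 table counts probes above vs not-above that
#' global split point against whether the probe maps to a downregulated
#' gene. The odds ratio is the cross-product ratio `(a d)/(b c)` with cell
#' `a` = above-median probes of down-genes; a Haldane-Anscombe +0.5
#' continuity correction is applied when any cell is zero. The p-value is
#' Fisher's exact test; the CI is the Woolf logit interval.
#'
#' @param probe_stats Named numeric vector, methylation f_up per probe.
#' @param annotation Probe annotation data.frame (`probe_id`, `gene`,
#'   `region`).
#' @param calls Gene regulation calls from [classify_genes()].
#' @param region `"tss"` or `"gene_body"`.
#' @param conf_level Confidence level of the Woolf CI. Default 0.95.
#' @return An `odds_ratio_result` list: `region`, `table` (2x2), `a`, `b`,
#'   `c`, `d`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `median_split`.
#' @export
methylation_odds_ratio <- function(probe_stats, annotation, calls,
                                   region = c("tss", "gene_body"),
                                   conf_level = 0.95) {
  region <- match.arg(region)
  annotation <- validate_probe_annotation(annotation)
  ann <- annotation[annotation$region == region &
                      annotation$probe_id %in% names(probe_stats), ]
  if (!nrow(ann)) stop("no scored probes annotated to region '", region, "'")
  x <- probe_stats[ann$probe_id]
  ok <- !is.na(x)
  ann <- ann[ok, ]
  x <- x[ok]
  med <- stats::median(x)
  above <- x > med
  down_genes <- calls$gene[calls$call == "down"]
  is_down <- ann$gene %in% down_genes
  a <- sum(above & is_down)
  b <- sum(above & !is_down)
  c_ <- sum(!above & is_down)
  d <- sum(!above & !is_down)
  if ((a + c_) == 0L) stop("empty stratum: no probes map to downregulated genes")
  if ((b + d) == 0L) stop("empty stratum: no probes map to other genes")
  if ((a + b) == 0L || (c_ + d) == 0L)
    stop("empty stratum: degenerate above/below-median margin")
  tab <- matrix(c(a, b, c_, d), 2L, byrow = TRUE,
                dimnames = list(split = c("above_median", "at_or_below"),
                                gene = c("down", "other")))
  cc <- if (any(tab == 0L)) 0.5 else 0
  or <- ((a + cc) * (d + cc)) / ((b + cc) * (c_ + cc))
  se <- sqrt(1 / (a + cc) + 1 / (b + cc) + 1 / (c_ + cc) + 1 / (d + cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- stats::fisher.test(tab)$p.value
  structure(list(region = region, table = tab,
                 a = a, b = b, c = c_, d = d,
                 odds_ratio = or,
                 ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se),
                 p_value = p, median_split = med,
                 conf_level = conf_level),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("%s probes: OR = %.3f [%.3f, %.3f], Fisher p = %.3g\n",
              x$region, x$odds_ratio, x$ci_low, x$ci_high, x$p_value))
  print(x$table)
  invisible(x)
}

#' Per-probe paired summary for one gene
#'
#' The machinery behind manual inspection of candidate silenced genes: for
#' every probe annotated to the gene, the paired methylation f_up counts and
#' region, computed with the same sign-test machinery as the genome-wide
#' screen.
#'
#' @param gene Gene id.
#' @param probe_cohort A `matched_cohort` of methylation probes.
#' @param annotation Probe annotation data.frame.
#' @return data.frame: `probe_id`, `region`, `k`, `n_eff`, `f_up`,
#'   `p_value`, one row per probe.
#' @export
gene_probe_view <- function(gene, probe_cohort, annotation) {
  annotation <- validate_probe_annotation(annotation)
  probes <- annotation$probe_id[annotation$gene == gene]
  probes <- intersect(probes, rownames(probe_cohort$tumor))
  if (!length(probes)) stop("gene '", gene, "' has no annotated probes in the cohort")
  sub <- subset_cohort_markers(probe_cohort,
                               match(probes, rownames(probe_cohort$tumor)))
  tab <- fup_screen(sub)
  data.frame(probe_id = tab$marker_id,
             region = annotation$region[match(tab$marker_id,
                                              annotation$probe_id)],
             k = tab$k, n_eff = tab$n_eff, f_up = tab$f_up,
             p_value = tab$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}
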
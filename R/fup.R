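#' Fraction of upregulated patients for one marker
#'
#' Counts the matched pairs in which the tumor value strictly exceeds the
#' normal value. Pairs that tie, or that are missing on either side, are
#' uninformative under the sign test and are excluded from both the count
#' and the denominator.
#'
#' @param tumor_values,normal_values Equal-length numeric vectors of paired
#'   values (one entry per patient).
#' @return List with `k` (pairs with tumor > normal), `n_eff` (informative
#'   pairs), `f_up` (`k / n_eff`; `NA` when untestable) and `testable`
#'   (`FALSE` when `n_eff == 0`).
#' @export
fraction_upregulated <- function(tumor_values, normal_values) {
  if (length(tumor_values) != length(normal_values))
    stop("tumor and normal vectors must have equal length")
  d <- tumor_values - normal_values
  informative <- !is.na(d) & d != 0
  k <- sum(d[informative] > 0)
  n_eff <- sum(informative)
  list(k = k, n_eff = n_eff,
       f_up = if (n_eff > 0L) k / n_eff else NA_real_,
       testable = n_eff > 0L)
}

#' Exact two-sided sign-test p-value
#'
#' Tests `k` successes in `n` informative pairs against Binomial(n, 0.5) by
#' doubling the smaller tail probability, capped at 1.
#'
#' @param k Number of pairs with tumor > normal (vectorized).
#' @param n Number of informative pairs (vectorized).
#' @return Two-sided p-value(s) in (0, 1].
#' @export
sign_test_p <- function(k, n) {
  if (any(n < 1L)) stop("n must be >= 1")
  if (any(k < 0L) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  lower <- stats::pbinom(k, n, 0.5)
  upper <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Beta-distribution confidence interval for f_up
#'
#' Equal-tailed interval from the beta distribution whose shape parameters
#' are set by the sign-test counts: Beta(k + 1, n - k + 1) under the default
#' uniform prior, or Beta(k + 1/2, n - k + 1/2) with `prior = "jeffreys"`.
#'
#' @param k,n Sign-test counts (vectorized).
#' @param level Confidence level in (0, 1). Default 0.95.
#' @param prior `"uniform"` (default) or `"jeffreys"`.
#' @return List with numeric `ci_low`, `ci_high`.
#' @export
beta_ci <- function(k, n, level = 0.95, prior = c("uniform", "jeffreys")) {
  prior <- match.arg(prior)
  if (!is.numeric(level) || any(level <= 0) || any(level >= 1))
    stop("level must lie strictly in (0, 1)")
  if (any(k < 0L) || any(k > n)) stop("k must satisfy 0 <= k <= n")
  off <- if (prior == "uniform") 1 else 0.5
  a <- k + off
  b <- n - k + off
  alpha <- (1 - level) / 2
  list(ci_low = stats::qbeta(alpha, a, b),
       ci_high = stats::qbeta(1 - alpha, a, b))
}

#' Adjust p-values for multiple testing
#'
#' Bonferroni (`min(m p, 1)`) or Benjamini-Hochberg step-up; input order is
#' preserved.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (`NA` allowed for
#'   untestable markers).
#' @param method `"bonferroni"` or `"bh"`.
#' @return Adjusted p-values, same length and order.
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Genome-wide f_up screen over a matched cohort
#'
#' For every marker: the upregulated-pair count `k`, informative-pair count
#' `n_eff`, `f_up = k / n_eff`, the exact two-sided sign-test p-value, a
#' beta-distribution confidence interval, and Bonferroni and BH adjusted
#' p-values. With `bonferroni_ci = TRUE` the interval is widened to the
#' simultaneous level `1 - (1 - level) / m` over the `m` testable markers
#' (the CI_Bonf convention).
#'
#' @param cohort A `matched_cohort` (typically after [filter_detectable()]).
#' @param level Nominal confidence level. Default 0.95.
#' @param bonferroni_ci Widen CIs to the simultaneous level. Default `FALSE`.
#' @param prior Beta CI prior, see [beta_ci()].
#' @return A `marker_table` data.frame with one row per marker: `marker_id`,
#'   `k`, `n_eff`, `f_up`, `p_value`, `p_bonf`, `p_bh`, `ci_low`, `ci_high`,
#'   `ci_level`; attributes `assay` and `n_patients`.
#' @export
fup_screen <- function(cohort, level = 0.95, bonferroni_ci = FALSE,
                       prior = "uniform") {
  stopifnot(inherits(cohort, "matched_cohort"))
  d <- cohort$tumor - cohort$normal
  informative <- !is.na(d) & d != 0
  k <- rowSums(informative & d > 0)
  n_eff <- rowSums(informative)
  f_up <- ifelse(n_eff > 0L, k / n_eff, NA_real_)
  p <- rep(NA_real_, length(k))
  ok <- n_eff > 0L
  p[ok] <- sign_test_p(k[ok], n_eff[ok])
  m <- sum(ok)
  ci_level <- if (bonferroni_ci && m > 0L) 1 - (1 - level) / m else level
  ci <- list(ci_low = rep(NA_real_, length(k)),
             ci_high = rep(NA_real_, length(k)))
  if (m > 0L) {
    cc <- beta_ci(k[ok], n_eff[ok], level = ci_level, prior = prior)
    ci$ci_low[ok] <- cc$ci_low
    ci$ci_high[ok] <- cc$ci_high
  }
  tab <- data.frame(
    marker_id = rownames(cohort$tumor), k = k, n_eff = n_eff, f_up = f_up,
    p_value = p,
    p_bonf = adjust_pvalues(p, "bonferroni"),
    p_bh = adjust_pvalues(p, "bh"),
    ci_low = ci$ci_low, ci_high = ci$ci_high, ci_level = ci_level,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(tab, "assay") <- cohort$assay
  attr(tab, "n_patients") <- length(cohort$patients)
  attr(tab, "ci_prior") <- prior
  class(tab) <- c("marker_table", class(tab))
  tab
}

#' Paired t-test screen (comparison harness)
#'
#' Classical paired t on the tumor - normal differences of every marker,
#' pairwise-complete. Markers with fewer than two informative pairs or
#' zero-variance differences are flagged untestable (`NA` statistics).
#'
#' @param cohort A `matched_cohort`.
#' @return data.frame with `marker_id`, `t`, `p_value`, `n`.
#' @export
paired_t_screen <- function(cohort) {
  stopifnot(inherits(cohort, "matched_cohort"))
  d <- cohort$tumor - cohort$normal
  n <- rowSums(!is.na(d))
  mean_d <- rowMeans(d, na.rm = TRUE)
  sd_d <- apply(d, 1L, stats::sd, na.rm = TRUE)
  tstat <- ifelse(n >= 2L & sd_d > 0, mean_d / (sd_d / sqrt(n)), NA_real_)
  p <- ifelse(is.na(tstat), NA_real_,
              2 * stats::pt(-abs(tstat), df = pmax(n - 1L, 1L)))
  data.frame(marker_id = rownames(d), t = tstat, p_value = p, n = n,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Consensus f_up across per-tissue screens
#'
#' Unweighted mean of per-tissue f_up over the tissues in which each marker
#' is testable, the convention for unbalanced multi-tissue collections.
#' Markers whose total informative-pair count summed over contributing
#' tissues falls below `min_total_n` are dropped. No pooled p-value is
#' produced (point consensus only).
#'
#' @param tables Named list of `marker_table`s, one per tissue.
#' @param min_total_n Minimum total matched sample count. Default 500.
#' @return data.frame with `marker_id`, `consensus_fup`, `n_tissues`,
#'   `total_n`.
#' @export
consensus_fup <- function(tables, min_total_n = 500) {
  if (!length(tables)) stop("need at least one per-tissue marker table")
  long <- do.call(rbind, lapply(tables, function(t)
    t[!is.na(t$f_up), c("marker_id", "f_up", "n_eff")]))
  if (!nrow(long)) stop("no testable markers in any tissue")
  agg <- stats::aggregate(cbind(f_sum = f_up, one = 1, n = n_eff) ~ marker_id,
                          data = long, FUN = sum)
  out <- data.frame(marker_id = agg$marker_id,
                    consensus_fup = agg$f_sum / agg$one,
                    n_tissues = agg$one, total_n = agg$n,
                    stringsAsFactors = FALSE)
  out <- out[out$total_n >= min_total_n, , drop = FALSE]
  out[order(out$marker_id), , drop = FALSE]
}

#' Write a marker table to TSV
#'
#' @param table A `marker_table` (or any data.frame).
#' @param path Output path.
#' @export
write_marker_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
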
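#' Per-sample meta-PCNA proliferation score
#'
#' The proliferation meta-gene of Venet et al.: for each sample, the median
#' expression over the signature genes present in the matrix. The published
#' signature has 131 genes co-expressed with PCNA; any gene list may be
#' supplied (the simulator emits its own). No standardization is applied
#' before the median. Duplicated signature entries and ordering are
#' irrelevant.
#'
#' @param expression A `marker_matrix` (or matrix with gene rownames).
#' @param signature Character vector of signature gene ids.
#' @param min_fraction Minimum fraction of signature genes that must be
#'   present in the matrix. Default 0.5.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `n_signature_found`.
#' @export
meta_pcna_score <- function(expression, signature, min_fraction = 0.5) {
  signature <- unique(signature)
  found <- intersect(signature, rownames(expression))
  if (length(found) < min_fraction * length(signature))
    stop(sprintf(
      "only %d of %d signature genes present (need >= %.0f%%)",
      length(found), length(signature), 100 * min_fraction))
  message(sprintf("meta-PCNA score: using %d of %d signature genes",
                  length(found), length(signature)))
  sub <- unclass(expression)[found, , drop = FALSE]
  scores <- apply(sub, 2L, stats::median, na.rm = TRUE)
  attr(scores, "n_signature_found") <- length(found)
  scores
}

#' Per-marker proliferation association
#'
#' Pearson correlation, across matched patients, between the tumor-normal
#' change in the proliferation score and the tumor-normal change in each
#' marker's level (pairwise-complete). Markers whose delta vector has zero
#' variance get `NA` (flagged undefined).
#'
#' @param cohort A `matched_cohort`.
#' @param scores Named per-sample score vector covering both members of the
#'   cohort's pairs. Names may be patient ids (when scores were computed on
#'   the cohort's own tumor/normal matrices) or original sample ids.
#' @return Named numeric vector `marker_corr` (one Pearson r per marker).
#' @export
proliferation_association <- function(cohort, scores) {
  stopifnot(inherits(cohort, "matched_cohort"))
  ds <- score_delta(cohort, scores)
  ok_pair <- !is.na(ds)
  if (sum(ok_pair) < 3L)
    stop("scores available for fewer than 3 matched pairs")
  dm <- (cohort$tumor - cohort$normal)[, ok_pair, drop = FALSE]
  ds <- ds[ok_pair]
  r <- suppressWarnings(
    as.vector(stats::cor(t(dm), ds, use = "pairwise.complete.obs")))
  stats::setNames(r, rownames(cohort$tumor))
}

# Per-patient tumor-minus-normal score difference; accepts scores keyed by
# patient id (tumor/normal matrices scored separately) or by sample id.
score_delta <- function(cohort, scores) {
  p <- cohort$patients
  if (is.list(scores) && all(c("tumor", "normal") %in% names(scores))) {
    st <- scores$tumor[p]
    sn <- scores$normal[p]
  } else if (all(cohort$sample_ids$tumor_sample %in% names(scores))) {
    st <- scores[cohort$sample_ids$tumor_sample]
    sn <- scores[cohort$sample_ids$normal_sample]
  } else {
    stop("scores must cover the cohort's samples: supply either a named ",
         "vector keyed by sample id or list(tumor=, normal=) keyed by patient")
  }
  stats::setNames(as.numeric(st) - as.numeric(sn), p)
}

#' Score both sides of a matched cohort
#'
#' Convenience wrapper: computes [meta_pcna_score()] on the tumor and normal
#' matrices separately and returns them keyed by patient id, the layout
#' expected by [proliferation_association()] and [detrend_markers()].
#'
#' @inheritParams meta_pcna_score
#' @param cohort A `matched_cohort`.
#' @return `list(tumor = scores, normal = scores)`, each named by patient.
#' @export
cohort_proliferation_scores <- function(cohort, signature,
                                        min_fraction = 0.5) {
  list(tumor = meta_pcna_score(cohort$tumor, signature, min_fraction),
       normal = meta_pcna_score(cohort$normal, signature, min_fraction))
}
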
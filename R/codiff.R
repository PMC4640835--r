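#' Patient-wise differential-expression matrix
#'
#' One column per matched patient, tumor minus normal.
#'
#' @param cohort A `matched_cohort`.
#' @return Numeric matrix markers x patients.
#' @export
differential_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "matched_cohort"))
  cohort$tumor - cohort$normal
}

#' Co-differential-expression profile of a target gene
#'
#' For the target gene, Pearson correlations against every gene computed in
#' two spaces: `dx` across the patient-wise differential (tumor - normal)
#' matrix and `dt` across the tumor-only matrix; `cx = dx - dt` measures
#' coordination specific to the tumor/normal transition. Only the target's
#' correlation row is materialized, never a full gene x gene matrix, so
#' memory is O(genes x patients).
#'
#' @param target Gene id present in the cohort.
#' @param cohort A `matched_cohort` with at least 3 patients.
#' @return A `codiff_profile` list: `target`, and named vectors `dx`, `dt`,
#'   `cx` over all genes (target entries are 1, 1, 0).
#' @export
codiff_profile <- function(target, cohort) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (!target %in% rownames(cohort$tumor))
    stop("target gene '", target, "' not present in the cohort")
  if (length(cohort$patients) < 3L) stop("need at least 3 matched patients")
  D <- differential_matrix(cohort)
  Tm <- cohort$tumor
  if (isTRUE(stats::sd(D[target, ], na.rm = TRUE) == 0) ||
      isTRUE(stats::sd(Tm[target, ], na.rm = TRUE) == 0))
    stop("target gene '", target, "' has zero variance")
  dx <- target_correlations(D, target)
  dt <- target_correlations(Tm, target)
  structure(list(target = target, dx = dx, dt = dt, cx = dx - dt),
            class = "codiff_profile")
}

# One row of the gene x gene correlation matrix, streamed.
target_correlations <- function(mat, target) {
  r <- suppressWarnings(as.vector(
    stats::cor(t(mat), mat[target, ], use = "pairwise.complete.obs")))
  stats::setNames(r, rownames(mat))
}

#' Pathway enrichment of co-differential expression
#'
#' Per gene set, the mean `cx` over member genes scored in the profile (the
#' target itself excluded so its self-correlation cannot inflate small
#' sets). When a cohort is supplied, the profile computation is repeated for
#' every candidate gene and the target's rank per set is reported (rank 1 =
#' largest mean cx among candidates).
#'
#' @param profile A `codiff_profile`.
#' @param collection Named list of gene sets.
#' @param cohort Optional `matched_cohort` for the cross-gene ranking.
#' @param candidates Candidate genes for the ranking; defaults to all cohort
#'   genes with nonzero variance, capped at `max_candidates`.
#' @param max_candidates Cap on the number of ranked candidates for
#'   desk-scale runs. Default `Inf`.
#' @return data.frame: `set_name`, `n_members_scored`, `mean_cx`, and (when
#'   ranked) `target_rank`, `n_candidates`; sorted by decreasing `mean_cx`.
#' @export
pathway_codiff_enrichment <- function(profile, collection, cohort = NULL,
                                      candidates = NULL,
                                      max_candidates = Inf) {
  if (!length(collection)) stop("empty gene-set collection")
  set_mean_cx <- function(cx, target) {
    vapply(collection, function(members) {
      members <- setdiff(unique(members), target)
      v <- cx[intersect(members, names(cx))]
      v <- v[!is.na(v)]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1L))
  }
  mean_cx <- set_mean_cx(profile$cx, profile$target)
  out <- data.frame(set_name = names(collection),
                    n_members_scored = vapply(collection, function(members) {
                      members <- setdiff(unique(members), profile$target)
                      sum(members %in% names(profile$cx)[!is.na(profile$cx)])
                    }, integer(1L)),
                    mean_cx = mean_cx, stringsAsFactors = FALSE)
  skipped <- is.na(out$mean_cx)
  if (any(skipped))
    warning("skipping set(s) with no scored members: ",
            paste(out$set_name[skipped], collapse = ", "))
  out <- out[!skipped, , drop = FALSE]
  if (!is.null(cohort)) {
    if (is.null(candidates)) {
      sds <- apply(differential_matrix(cohort), 1L, stats::sd, na.rm = TRUE)
      candidates <- rownames(cohort$tumor)[!is.na(sds) & sds > 0]
    }
    candidates <- union(profile$target, candidates)
    if (length(candidates) > max_candidates)
      candidates <- union(profile$target,
                          candidates[seq_len(max_candidates)])
    D <- differential_matrix(cohort)
    Tm <- cohort$tumor
    score <- matrix(NA_real_, length(candidates), nrow(out),
                    dimnames = list(candidates, out$set_name))
    for (g in candidates) {
      cx_g <- target_correlations(D, g) - target_correlations(Tm, g)
      score[g, ] <- set_mean_cx(cx_g, g)[out$set_name]
    }
    out$target_rank <- vapply(out$set_name, function(s) {
      v <- score[, s]
      as.integer(rank(-v, ties.method = "min", na.last = "keep")[profile$target])
    }, integer(1L))
    out$n_candidates <- length(candidates)
  }
  out <- out[order(-out$mean_cx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
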
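#' Remove proliferation and tissue trends from every marker
#'
#' Fits, per marker, the ordinary least-squares model
#' `marker_level ~ metaPCNA + tissue + metaPCNA:tissue` over the pooled
#' tumor and normal samples of the matched cohort, and returns the residual
#' matrices. Tumor/normal status is deliberately absent from the design:
#' tumor-specific shifts survive residualization while any component linear
#' in the proliferation score (within tissue) is removed. With a single
#' tissue the design degrades to intercept + metaPCNA. Rank-deficient
#' designs are resolved by the pivoted QR (collinear columns dropped, with
#' a warning).
#'
#' @param cohort A `matched_cohort`.
#' @param scores Proliferation scores: `list(tumor=, normal=)` named by
#'   patient (see [cohort_proliferation_scores()]) or a vector named by
#'   sample id.
#' @return A `detrend_result` list: `tumor`, `normal` (residual matrices
#'   aligned 1:1 with the input), `model_terms`, `per_marker_fit`
#'   (data.frame with `marker_id`, `r_squared`), `coefficients`
#'   (markers x design-columns matrix), `design` (samples x columns).
#' @export
detrend_markers <- function(cohort, scores) {
  stopifnot(inherits(cohort, "matched_cohort"))
  p <- cohort$patients
  if (is.list(scores) && all(c("tumor", "normal") %in% names(scores))) {
    s <- c(as.numeric(scores$tumor[p]), as.numeric(scores$normal[p]))
  } else {
    s <- as.numeric(scores[c(cohort$sample_ids$tumor_sample,
                             cohort$sample_ids$normal_sample)])
  }
  if (anyNA(s)) stop("proliferation scores missing for some cohort samples")
  tissue <- factor(rep(cohort$tissue_of[p], 2L))
  if (any(table(tissue) < 2L)) stop("need >= 2 samples per tissue level")
  single_tissue <- nlevels(tissue) < 2L
  if (single_tissue) {
    message("single-tissue cohort: design reduced to ~ metaPCNA")
    X <- stats::model.matrix(~ s)
    terms_desc <- "marker_level ~ metaPCNA"
  } else {
    X <- stats::model.matrix(~ s * tissue)
    terms_desc <- "marker_level ~ metaPCNA + tissue + metaPCNA:tissue"
  }
  colnames(X) <- sub("^s", "metaPCNA", colnames(X))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X))
    warning(sprintf("design rank-deficient (%d of %d columns); collinear columns dropped",
                    qr_x$rank, ncol(X)))
  Y <- cbind(cohort$tumor, cohort$normal)  # markers x 2n
  n_pat <- length(p)
  res <- matrix(NA_real_, nrow(Y), ncol(Y), dimnames = dimnames(Y))
  coefs <- matrix(NA_real_, nrow(Y), ncol(X),
                  dimnames = list(rownames(Y), colnames(X)))
  r2 <- rep(NA_real_, nrow(Y))
  complete <- !anyNA(Y)
  full_rows <- if (complete) seq_len(nrow(Y)) else which(rowSums(is.na(Y)) == 0L)
  if (length(full_rows)) {
    Yt <- t(Y[full_rows, , drop = FALSE])
    R <- qr.resid(qr_x, Yt)
    B <- qr.coef(qr_x, Yt)
    res[full_rows, ] <- t(R)
    coefs[full_rows, ] <- t(B)
    tss <- colSums(scale(Yt, scale = FALSE)^2)
    rss <- colSums(R^2)
    r2[full_rows] <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
  }
  na_rows <- setdiff(seq_len(nrow(Y)), full_rows)
  for (i in na_rows) {
    ok <- !is.na(Y[i, ])
    if (sum(ok) <= qr_x$rank) next
    qi <- qr(X[ok, , drop = FALSE])
    yi <- Y[i, ok]
    ri <- qr.resid(qi, yi)
    res[i, ok] <- ri
    coefs[i, ] <- qr.coef(qi, yi)
    tssi <- sum((yi - mean(yi))^2)
    if (tssi > 0) r2[i] <- 1 - sum(ri^2) / tssi
  }
  structure(list(
    tumor = res[, seq_len(n_pat), drop = FALSE],
    normal = res[, n_pat + seq_len(n_pat), drop = FALSE],
    model_terms = terms_desc,
    per_marker_fit = data.frame(marker_id = rownames(Y), r_squared = r2,
                                row.names = NULL, stringsAsFactors = FALSE),
    coefficients = coefs,
    design = X
  ), class = "detrend_result")
}

#' Detrended f_up screen
#'
#' Residualizes every marker with [detrend_markers()] and recomputes the
#' f_up sign-test screen on the residual pairs, exactly as [fup_screen()]
#' does on raw pairs. Output gains `r_proliferation` (each marker's Pearson
#' correlation of deltas with the proliferation score) and `model_r2`.
#'
#' @inheritParams detrend_markers
#' @inheritParams fup_screen
#' @return A `marker_table` labeled `"detrended_fup"` with the extra
#'   columns `r_proliferation` and `model_r2`.
#' @export
detrended_fup_screen <- function(cohort, scores, level = 0.95,
                                 bonferroni_ci = FALSE, prior = "uniform") {
  dt <- detrend_markers(cohort, scores)
  rc <- cohort
  rc$tumor <- dt$tumor
  rc$normal <- dt$normal
  # residual pairs differing by < 1e-8 of the marker's scale are numerical
  # zeros (e.g. a perfectly fitted or constant marker) and must count as ties
  pooled <- cbind(cohort$tumor, cohort$normal)
  scale <- pmax(apply(pooled, 1L, stats::sd, na.rm = TRUE),
                abs(rowMeans(pooled, na.rm = TRUE)), 1)
  tie <- abs(rc$tumor - rc$normal) < 1e-8 * scale
  tie[is.na(tie)] <- FALSE
  rc$tumor[tie] <- rc$normal[tie]
  tab <- fup_screen(rc, level = level, bonferroni_ci = bonferroni_ci,
                    prior = prior)
  tab$r_proliferation <- unname(proliferation_association(cohort, scores))
  tab$model_r2 <- dt$per_marker_fit$r_squared
  attr(tab, "statistic") <- "detrended_fup"
  tab
}
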
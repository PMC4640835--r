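#' Mann-Whitney U test of one gene set against the background
#'
#' Tests whether the per-marker statistic (f_up or detrended f_up) within
#' the set is stochastically shifted relative to the exclusive background
#' (all scored markers not in the set). Two-sided; exact enumeration when
#' both groups have at most 10 members and no ties are present, otherwise a
#' normal approximation with tie correction and continuity correction.
#'
#' @param stat Named numeric vector, one statistic per marker.
#' @param members Character vector of set member ids.
#' @param min_set_size Minimum number of members present in `stat`.
#'   Default 5.
#' @param set_name Label carried into the output row.
#' @return One-row data.frame: `set_name`, `n_in_set`, `n_background`,
#'   `u_statistic`, `p_value`, `effect` (median in-set minus median
#'   background), `direction` (`"up"`/`"down"`); or `NULL` when the set is
#'   skipped (too few members, or empty background).
#' @export
gene_set_test <- function(stat, members, min_set_size = 5,
                          set_name = NA_character_) {
  stat <- stat[!is.na(stat)]
  members <- unique(members)
  in_set <- names(stat) %in% members
  n1 <- sum(in_set)
  n2 <- sum(!in_set)
  if (n1 < min_set_size) {
    warning("set '", set_name, "' skipped: ", n1,
            " scored member(s) < min_set_size = ", min_set_size)
    return(NULL)
  }
  if (n2 == 0L) {
    warning("set '", set_name, "' skipped: empty background")
    return(NULL)
  }
  x <- stat[in_set]
  y <- stat[!in_set]
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 <= 10L && n2 <= 10L && !anyDuplicated(c(x, y))
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
  effect <- stats::median(x) - stats::median(y)
  direction <- if (effect > 0 || (effect == 0 && u > n1 * n2 / 2)) "up" else "down"
  data.frame(set_name = set_name, n_in_set = n1, n_background = n2,
             u_statistic = u, p_value = p, effect = effect,
             direction = direction, stringsAsFactors = FALSE)
}

#' Gene-set enrichment screen on a ranked marker statistic
#'
#' Applies [gene_set_test()] to every set of the collection, BH-adjusts
#' across all tested sets, and sorts by p-value.
#'
#' @param stat Named numeric vector of per-marker statistics.
#' @param collection Named list of character vectors (e.g. [read_gmt()]).
#' @param min_set_size Passed to [gene_set_test()]. Default 5.
#' @return data.frame with one row per eligible set, columns of
#'   [gene_set_test()] plus `p_bh`, sorted by `p_value`.
#' @export
enrichment_screen <- function(stat, collection, min_set_size = 5) {
  if (!length(collection)) stop("empty gene-set collection")
  rows <- lapply(names(collection), function(nm)
    gene_set_test(stat, collection[[nm]], min_set_size = min_set_size,
                  set_name = nm))
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) stop("no eligible gene sets after filtering")
  out <- do.call(rbind, rows)
  out$p_bh <- adjust_pvalues(out$p_value, "bh")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
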
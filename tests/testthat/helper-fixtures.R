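# Fixture builders and independent oracles shared across the suite.

# Build a matched_cohort directly from tumor/normal matrices (markers x
# patients), going through the package's own pairing path.
toy_cohort <- function(tumor, normal, tissues = NULL) {
  n <- ncol(tumor)
  patients <- sprintf("P%03d", seq_len(n))
  if (is.null(tissues)) tissues <- rep("T1", n)
  if (is.null(rownames(tumor)))
    rownames(tumor) <- rownames(normal) <- sprintf("M%04d", seq_len(nrow(tumor)))
  t_id <- paste0(patients, "-T")
  n_id <- paste0(patients, "-N")
  combined <- cbind(tumor, normal)
  colnames(combined) <- c(t_id, n_id)
  manifest <- data.frame(
    sample_id = c(t_id, n_id), patient_id = rep(patients, 2L),
    tissue = rep(tissues, 2L),
    status = rep(c("tumor", "normal"), each = n),
    stringsAsFactors = FALSE)
  suppressMessages(build_matched_cohort(marker_matrix(combined), manifest))
}

# Independent oracle for the two-sided sign test: literal enumeration of
# all 2^n sign patterns, doubling the smaller empirical tail.
brute_sign_p <- function(k, n) {
  patterns <- as.matrix(expand.grid(rep(list(c(0L, 1L)), n)))
  counts <- rowSums(patterns)
  lower <- mean(counts <= k)
  upper <- mean(counts >= k)
  min(1, 2 * min(lower, upper))
}

# Independent oracle for the co-differential profile: materializes the
# full gene x gene correlation matrices.
brute_codiff <- function(target, cohort) {
  D <- cohort$tumor - cohort$normal
  Cd <- stats::cor(t(D))
  Ct <- stats::cor(t(cohort$tumor))
  Cd[target, ] - Ct[target, ]
}

write_tsv_fixture <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
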
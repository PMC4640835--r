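#' Read a marker-by-sample matrix from TSV
#'
#' Reads a tab-delimited matrix with a header row of sample identifiers and
#' marker identifiers in the first column. `"NA"` cells are preserved as
#' missing values. Expression matrices are assumed to be on a normalized,
#' log-like scale (Level-3-style input); set `log2_transform = TRUE` only for
#' raw-count-like matrices.
#'
#' @param path Path to a TSV file.
#' @param assay One of `"mrna"`, `"mirna"`, `"methylation"`. Methylation
#'   values are checked to lie in \[0, 1\] (beta values).
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to the values after
#'   reading. Default `FALSE`.
#' @return A `marker_matrix`: a numeric matrix (markers x samples) with
#'   `rownames` = marker ids, `colnames` = sample ids, and an `"assay"`
#'   attribute.
#' @export
read_marker_matrix <- function(path, assay = c("mrna", "mirna", "methylation"),
                               log2_transform = FALSE) {
  assay <- match.arg(assay)
  if (!file.exists(path)) stop("marker matrix file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = "NA")
  if (ncol(raw) < 2L) stop("malformed header in ", path,
                           ": need a marker-id column plus >=1 sample column")
  marker_ids <- raw[[1L]]
  dup <- marker_ids[duplicated(marker_ids)]
  if (length(dup)) stop("duplicate marker id(s) in ", path, ": ",
                        paste(utils::head(unique(dup), 5L), collapse = ", "))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(vals <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(vals) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric cell in ", path, " at data line ", bad[1L, 1L],
         " (marker '", marker_ids[bad[1L, 1L]], "', column '",
         colnames(raw)[-1L][bad[1L, 2L]], "'): '",
         body[bad[1L, 1L, drop = FALSE], bad[1L, 2L, drop = FALSE]], "'")
  }
  dimnames(vals) <- list(marker_ids, colnames(raw)[-1L])
  if (log2_transform) vals <- log2(vals + 1)
  if (assay == "methylation") {
    rng <- range(vals, na.rm = TRUE)
    if (rng[1L] < 0 || rng[2L] > 1)
      stop("methylation beta values outside [0,1] in ", path,
           " (range ", signif(rng[1L], 4), "..", signif(rng[2L], 4), ")")
  }
  message(sprintf("read %d markers x %d samples (%s) from %s",
                  nrow(vals), ncol(vals), assay, path))
  marker_matrix(vals, assay)
}

#' Construct a marker matrix object
#'
#' @param values Numeric matrix, markers in rows, samples in columns; must
#'   carry row and column names.
#' @param assay Assay label (`"mrna"`, `"mirna"`, `"methylation"`).
#' @return The matrix with class `marker_matrix` and an `assay` attribute.
#' @export
marker_matrix <- function(values, assay = "mrna") {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("marker matrix needs marker ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate marker ids in matrix")
  attr(values, "assay") <- assay
  class(values) <- c("marker_matrix", class(values))
  values
}

#' Read a sample manifest
#'
#' The manifest is the pairing authority: a TSV with columns `sample_id`,
#' `patient_id`, `tissue` (cancer-type code, e.g. KIRC) and `status`
#' (`tumor` or `normal`).
#'
#' @param path Path to a manifest TSV.
#' @return A data.frame with the four columns, validated.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, header = TRUE, colClasses = "character")
  validate_manifest(m)
}

validate_manifest <- function(m) {
  need <- c("sample_id", "patient_id", "tissue", "status")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  m <- m[need]
  if (anyDuplicated(m$sample_id))
    stop("duplicate sample_id in manifest: ",
         m$sample_id[duplicated(m$sample_id)][1L])
  bad <- setdiff(unique(m$status), c("tumor", "normal"))
  if (length(bad)) stop("manifest status must be 'tumor' or 'normal', got: ",
                        paste(bad, collapse = ", "))
  m
}

#' Assemble a matched tumor/normal cohort
#'
#' Retains only patients contributing exactly one tumor and one normal column
#' to the matrix; unmatched samples are dropped (and counted in a message).
#' Tumor and normal sub-matrices are aligned on a common patient ordering so
#' that column `j` of each belongs to the same patient.
#'
#' @param matrix A `marker_matrix`.
#' @param manifest A manifest data.frame (see [read_manifest()]).
#' @return A `matched_cohort`: list with elements `tumor` and `normal`
#'   (marker x patient matrices, columns named by patient id), `patients`,
#'   `tissue_of` (named character vector), `assay`, and `sample_ids`
#'   (data.frame mapping patient to original tumor/normal sample ids).
#' @export
build_matched_cohort <- function(matrix, manifest) {
  manifest <- validate_manifest(manifest)
  sids <- colnames(matrix)
  miss <- setdiff(sids, manifest$sample_id)
  if (length(miss)) stop("manifest does not cover matrix sample(s): ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  m <- manifest[manifest$sample_id %in% sids, ]
  dup <- m[duplicated(m[c("patient_id", "status")]), ]
  if (nrow(dup)) stop("patient '", dup$patient_id[1L], "' has two '",
                      dup$status[1L], "' columns in the matrix")
  tum <- m[m$status == "tumor", ]
  nor <- m[m$status == "normal", ]
  patients <- sort(intersect(tum$patient_id, nor$patient_id))
  if (!length(patients)) stop("zero matched tumor/normal patients")
  n_drop <- nrow(m) - 2L * length(patients)
  if (n_drop > 0L)
    message(sprintf("dropped %d unmatched sample(s); %d matched patients kept",
                    n_drop, length(patients)))
  t_id <- tum$sample_id[match(patients, tum$patient_id)]
  n_id <- nor$sample_id[match(patients, nor$patient_id)]
  tissue <- tum$tissue[match(patients, tum$patient_id)]
  tumor <- unclass(matrix)[, t_id, drop = FALSE]
  normal <- unclass(matrix)[, n_id, drop = FALSE]
  colnames(tumor) <- colnames(normal) <- patients
  structure(list(
    tumor = tumor, normal = normal, patients = patients,
    tissue_of = stats::setNames(tissue, patients),
    assay = attr(matrix, "assay") %||% "mrna",
    sample_ids = data.frame(patient_id = patients, tumor_sample = t_id,
                            normal_sample = n_id, stringsAsFactors = FALSE)
  ), class = "matched_cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.matched_cohort <- function(x, ...) {
  cat(sprintf("matched_cohort: %d markers x %d patients (%s), %d tissue(s)\n",
              nrow(x$tumor), length(x$patients), x$assay,
              length(unique(x$tissue_of))))
  invisible(x)
}

#' Filter markers for a detectable tumor/normal change
#'
#' Keeps markers whose paired tumor and normal values differ (strict
#' non-equality, both values present; an `epsilon` threshold on the absolute
#' difference may be supplied) in at least `min_fraction` of patients. This
#' removes limit-of-detection markers whose values tie across most pairs.
#'
#' @param cohort A `matched_cohort`.
#' @param min_fraction Minimum fraction of patients with a detectable change;
#'   must lie in (0, 1]. Default 0.5.
#' @param epsilon Differences with absolute value `<= epsilon` count as ties.
#'   Default 0 (strict non-equality).
#' @return The cohort restricted to surviving markers.
#' @export
filter_detectable <- function(cohort, min_fraction = 0.5, epsilon = 0) {
  stopifnot(inherits(cohort, "matched_cohort"))
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must lie in (0, 1]")
  d <- cohort$tumor - cohort$normal
  detectable <- !is.na(d) & abs(d) > epsilon
  frac <- rowMeans(detectable)
  keep <- frac >= min_fraction
  message(sprintf("detectable-change filter (%s): kept %d of %d markers",
                  cohort$assay, sum(keep), length(keep)))
  subset_cohort_markers(cohort, which(keep))
}

subset_cohort_markers <- function(cohort, idx) {
  cohort$tumor <- cohort$tumor[idx, , drop = FALSE]
  cohort$normal <- cohort$normal[idx, , drop = FALSE]
  cohort
}

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `gene`, `region` (one of `tss`, `gene_body`,
#' `other`).
#'
#' @param path Path to the annotation TSV.
#' @return Validated data.frame.
#' @export
read_probe_annotation <- function(path) {
  a <- utils::read.delim(path, header = TRUE, colClasses = "character")
  validate_probe_annotation(a)
}

validate_probe_annotation <- function(a) {
  need <- c("probe_id", "gene", "region")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("probe annotation missing column(s): ",
                         paste(miss, collapse = ", "))
  a <- a[need]
  if (anyDuplicated(a$probe_id))
    stop("duplicate probe_id in annotation: ",
         a$probe_id[duplicated(a$probe_id)][1L])
  bad <- setdiff(unique(a$region), c("tss", "gene_body", "other"))
  if (length(bad)) stop("region must be tss/gene_body/other, got: ",
                        paste(bad, collapse = ", "))
  a
}

#' Average probes onto their annotated genes
#'
#' One output row per gene, the unweighted arithmetic mean of that gene's
#' probe rows; missing probe values are excluded per sample. Probes without
#' an annotation entry are dropped.
#'
#' @param matrix A `marker_matrix` of probe values.
#' @param annotation A probe annotation data.frame (`probe_id`, `gene`, ...).
#' @return A `marker_matrix` with gene rows.
#' @export
collapse_probes_to_genes <- function(matrix, annotation) {
  annotation <- validate_probe_annotation(
    if ("region" %in% names(annotation)) annotation
    else cbind(annotation, region = "other"))
  hit <- intersect(rownames(matrix), annotation$probe_id)
  if (!length(hit)) stop("no probes in the matrix are covered by the annotation")
  gene_of <- annotation$gene[match(hit, annotation$probe_id)]
  vals <- unclass(matrix)[hit, , drop = FALSE]
  genes <- sort(unique(gene_of))
  out <- rowsum(ifelse(is.na(vals), 0, vals), gene_of)[genes, , drop = FALSE] /
    rowsum((!is.na(vals)) * 1, gene_of)[genes, , drop = FALSE]
  out[is.nan(out)] <- NA_real_
  marker_matrix(out, attr(matrix, "assay") %||% "mrna")
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, fields `name`, `description`, then
#' tab-separated member ids. Duplicate members within a set are deduplicated;
#' sets with zero members are skipped with a warning.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (a gene-set collection).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      warning("skipping gene set '", f[1L], "': zero members")
      next
    }
    out[[f[1L]]] <- members
  }
  out
}

#' Write a gene-set collection to GMT
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, "na", collection[[nm]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
}

#' Write a marker matrix to TSV
#'
#' @param matrix A `marker_matrix` or plain matrix with dimnames.
#' @param path Output path.
#' @export
write_marker_matrix <- function(matrix, path) {
  df <- data.frame(marker_id = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
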
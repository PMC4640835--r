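#' Simulation configuration for synthetic matched cohorts
#'
#' Builds the configuration consumed by [simulate_cohort()],
#' [simulate_methylation()] and [simulate_gene_sets()]. Defaults describe a
#' desk-scale pan-cancer-like study: 3 tissues x 100 matched pairs, 2,000
#' markers of which 10% are proliferation-driven, 5% carry a
#' proliferation-independent tumor up-shift calibrated to up-probability
#' 0.9, 5% the mirrored down-shift, and 80% are null.
#'
#' The latent per-sample proliferation level is
#' `p = patient_baseline + status_shift + within_noise` with
#' `patient_baseline ~ N(0, prolif_sd_patient)`, a `prolif_shift` added to
#' tumor samples only, and `within_noise ~ N(0, prolif_sd_within)`.
#' Proliferation-driven markers load on `p` with slope `prolif_effect`;
#' the default 2.34 solves `Phi(beta mu / sqrt(2 beta^2 tau_w^2 +
#' 2 sigma^2)) = 0.9` under the default latent parameters, i.e. a raw
#' f_up of about 0.9. Independent shifts use `delta = sqrt(2) sigma
#' Phi^-1(q)`, which gives `Pr(tumor > normal) = q` exactly for Gaussian
#' noise.
#'
#' @param n_patients_per_tissue Matched pairs per tissue. Default 100.
#' @param tissues Tissue codes. Default `c("BRCA", "KIRC", "LUAD")`.
#' @param n_markers Number of (non-signature) markers. Default 2000.
#' @param class_fractions Named proportions over
#'   `null`, `prolif_driven`, `indep_up`, `indep_down`; must sum to 1.
#' @param prolif_effect Loading of proliferation-driven markers on the
#'   latent proliferation level. Default 2.34.
#' @param indep_up_prob Target `Pr(tumor > normal)` of independent-up
#'   markers (independent-down uses `1 -` this). Default 0.9.
#' @param noise_sd Marker noise SD on the log-like expression scale.
#'   Default 1.
#' @param n_signature_genes Proliferation-signature genes appended to the
#'   matrix (loading 1 on `p`). Default 30.
#' @param prolif_shift,prolif_sd_patient,prolif_sd_within,signature_noise_sd
#'   Latent proliferation parameters (see Details). Defaults 1, 0.8, 0.35,
#'   0.3.
#' @param patient_sd SD of the per-gene patient baseline added to both
#'   members of a pair (cancels in the matched design; dominates tumor-only
#'   variance, as patient-level expression heterogeneity does in real
#'   cohorts). Not applied to signature genes, which are modeled as tight
#'   proliferation trackers. Default 2.5.
#' @param codiff_module List: `n_genes` null-class genes forming a planted
#'   co-differential module (a shared patient-specific tumor-only shift
#'   `m_i ~ N(0, magnitude_sd)`, coordinating their tumor/normal
#'   differences without a net up/down effect) and `magnitude_sd`. The
#'   planted change in correlation has the closed form
#'   `cx = w^2/(w^2 + 2 s^2) - w^2/(w^2 + s^2 + patient_sd^2)` (w =
#'   `magnitude_sd`, s = `noise_sd`, single tissue); the defaults 30 genes
#'   and `magnitude_sd = 2` put the planted cx near 0.3, well clear of
#'   set-mean noise at desk-scale cohorts. Set `n_genes = 0` for a pure
#'   cohort.
#' @param methylation List: `probes_per_gene` (regions cycle tss,
#'   gene_body, other), `tss_hyper_effect` and `body_hypo_effect`
#'   (logit-scale tumor shifts planted on probes of independent-down
#'   genes), `noise_sd` and `baseline_sd` (logit scale).
#' @param planted_sets List: `set_size` (markers per planted class set)
#'   and `n_decoys` (random decoy sets).
#' @param seed Integer seed; every simulation draw derives from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients_per_tissue = 100,
                       tissues = c("BRCA", "KIRC", "LUAD"),
                       n_markers = 2000,
                       class_fractions = c(null = 0.80, prolif_driven = 0.10,
                                           indep_up = 0.05, indep_down = 0.05),
                       prolif_effect = 2.34,
                       indep_up_prob = 0.9,
                       noise_sd = 1,
                       n_signature_genes = 30,
                       prolif_shift = 1,
                       prolif_sd_patient = 0.8,
                       prolif_sd_within = 0.35,
                       signature_noise_sd = 0.3,
                       patient_sd = 2.5,
                       codiff_module = list(n_genes = 30,
                                            magnitude_sd = 2),
                       methylation = list(probes_per_gene = 2,
                                          tss_hyper_effect = 1.0,
                                          body_hypo_effect = 0.6,
                                          noise_sd = 0.5,
                                          baseline_sd = 1),
                       planted_sets = list(set_size = 50, n_decoys = 40),
                       seed = 1L) {
  cf <- class_fractions
  need <- c("null", "prolif_driven", "indep_up", "indep_down")
  if (!all(need %in% names(cf)) || abs(sum(cf) - 1) > 1e-8)
    stop("class_fractions must be named over ", paste(need, collapse = "/"),
         " and sum to 1")
  if (n_patients_per_tissue < 1 || n_markers < 1 || n_signature_genes < 1)
    stop("counts must be positive")
  if (noise_sd <= 0)
    stop("infeasible config: noise_sd must be > 0 (a target up-probability ",
         "other than 0/1 cannot be realized with zero noise)")
  if (indep_up_prob <= 0 || indep_up_prob >= 1)
    stop("indep_up_prob must lie strictly in (0, 1)")
  structure(list(
    n_patients_per_tissue = as.integer(n_patients_per_tissue),
    tissues = tissues, n_markers = as.integer(n_markers),
    class_fractions = cf[need], prolif_effect = prolif_effect,
    indep_up_prob = indep_up_prob, noise_sd = noise_sd,
    n_signature_genes = as.integer(n_signature_genes),
    prolif_shift = prolif_shift, prolif_sd_patient = prolif_sd_patient,
    prolif_sd_within = prolif_sd_within,
    signature_noise_sd = signature_noise_sd,
    patient_sd = patient_sd, codiff_module = codiff_module,
    methylation = methylation, planted_sets = planted_sets,
    seed = as.integer(seed)), class = "sim_config")
}

class_counts <- function(n, fractions) {
  cum <- round(cumsum(fractions) * n)
  stats::setNames(diff(c(0L, cum)), names(fractions))
}

# Analytic Pr(tumor > normal) for a marker loading beta on the latent
# proliferation level, given the config's latent parameters.
prolif_up_prob <- function(config, beta, marker_noise_sd = config$noise_sd) {
  mu <- config$prolif_shift
  tau_w <- config$prolif_sd_within
  stats::pnorm(beta * mu /
                 sqrt(2 * beta^2 * tau_w^2 + 2 * marker_noise_sd^2))
}

#' Simulate a matched multi-tissue tumor/normal expression cohort
#'
#' Generates a `matched_cohort` with known ground truth: a latent
#' proliferation level per sample (tumors shifted upward), signature genes
#' that track it (so [meta_pcna_score()] recovers it), proliferation-driven
#' markers loading on it, independent up/down markers with tumor-only
#' shifts `delta = sqrt(2) sigma Phi^-1(q)` calibrated to up-probability
#' `q`, null markers exchangeable between tumor and normal, and
#' tissue-specific per-marker baselines. Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List: `cohort` (a `matched_cohort`), `scores_true` (named vector
#'   of latent proliferation per sample id), `signature_genes`, `manifest`
#'   (data.frame), `matrix` (the combined `marker_matrix`), and `truth`
#'   (list with per-marker data.frame `markers`: `marker_id`, `class`,
#'   `true_up_prob`, `prolif_beta`, `delta`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_t <- length(config$tissues)
  npp <- config$n_patients_per_tissue
  n_pat <- n_t * npp
  patients <- sprintf("P%04d", seq_len(n_pat))
  tissue_of <- stats::setNames(rep(config$tissues, each = npp), patients)

  a <- stats::rnorm(n_pat, 0, config$prolif_sd_patient)
  p_normal <- a + stats::rnorm(n_pat, 0, config$prolif_sd_within)
  p_tumor <- a + config$prolif_shift +
    stats::rnorm(n_pat, 0, config$prolif_sd_within)

  counts <- class_counts(config$n_markers, config$class_fractions)
  classes <- rep(names(counts), counts)
  marker_ids <- sprintf("M%05d", seq_len(config$n_markers))
  sig_ids <- sprintf("SIG%04d", seq_len(config$n_signature_genes))

  beta <- ifelse(classes == "prolif_driven", config$prolif_effect, 0)
  q <- config$indep_up_prob
  delta_unit <- sqrt(2) * config$noise_sd * stats::qnorm(q)
  delta <- ifelse(classes == "indep_up", delta_unit,
                  ifelse(classes == "indep_down", -delta_unit, 0))

  n_all <- config$n_markers + config$n_signature_genes
  base <- matrix(stats::rnorm(n_all * n_t), n_all, n_t,
                 dimnames = list(c(marker_ids, sig_ids), config$tissues))
  base_cols <- base[, tissue_of, drop = FALSE]

  beta_all <- c(beta, rep(1, config$n_signature_genes))
  delta_all <- c(delta, rep(0, config$n_signature_genes))
  sd_all <- c(rep(config$noise_sd, config$n_markers),
              rep(config$signature_noise_sd, config$n_signature_genes))

  # patient baselines: shared by both members of a pair (cancel in the
  # matched design), on screened markers only
  pb <- rbind(matrix(stats::rnorm(config$n_markers * n_pat, 0,
                                  config$patient_sd),
                     config$n_markers, n_pat),
              matrix(0, config$n_signature_genes, n_pat))
  noise <- function() matrix(stats::rnorm(n_all * n_pat), n_all, n_pat) * sd_all
  normal <- base_cols + outer(beta_all, p_normal) + pb + noise()
  tumor <- base_cols + outer(beta_all, p_tumor) + delta_all + pb + noise()

  cm <- config$codiff_module
  module_genes <- character(0)
  if (!is.null(cm) && cm$n_genes > 0) {
    null_ids <- which(classes == "null")
    if (length(null_ids) < cm$n_genes)
      stop("infeasible config: codiff module larger than the null class")
    module_rows <- null_ids[seq_len(cm$n_genes)]
    module_genes <- marker_ids[module_rows]
    m <- stats::rnorm(n_pat, 0, cm$magnitude_sd)
    tumor[module_rows, ] <- tumor[module_rows, ] +
      matrix(m, cm$n_genes, n_pat, byrow = TRUE)
  }

  t_id <- paste0(patients, "-T")
  n_id <- paste0(patients, "-N")
  combined <- cbind(tumor, normal)
  colnames(combined) <- c(t_id, n_id)
  mat <- marker_matrix(combined, "mrna")
  manifest <- data.frame(
    sample_id = c(t_id, n_id),
    patient_id = rep(patients, 2L),
    tissue = rep(unname(tissue_of), 2L),
    status = rep(c("tumor", "normal"), each = n_pat),
    stringsAsFactors = FALSE)
  cohort <- suppressMessages(build_matched_cohort(mat, manifest))

  true_up <- stats::setNames(rep(0.5, config$n_markers), marker_ids)
  true_up[classes == "prolif_driven"] <-
    prolif_up_prob(config, config$prolif_effect)
  true_up[classes == "indep_up"] <- q
  true_up[classes == "indep_down"] <- 1 - q
  truth_markers <- data.frame(
    marker_id = c(marker_ids, sig_ids),
    class = c(classes, rep("signature", config$n_signature_genes)),
    true_up_prob = c(unname(true_up),
                     rep(prolif_up_prob(config, 1, config$signature_noise_sd),
                         config$n_signature_genes)),
    prolif_beta = beta_all, delta = delta_all,
    codiff_module = c(marker_ids, sig_ids) %in% module_genes,
    stringsAsFactors = FALSE)

  list(cohort = cohort,
       scores_true = stats::setNames(c(p_tumor, p_normal), c(t_id, n_id)),
       signature_genes = sig_ids,
       manifest = manifest,
       matrix = mat,
       truth = list(markers = truth_markers, patients = patients,
                    tissue_of = tissue_of, config = config))
}

#' Simulate matched methylation beta values with planted silencing
#'
#' Generates one probe cohort aligned with an expression simulation's
#' patients. Probes are simulated on the logit scale (baseline per probe,
#' Gaussian sample noise, a tumor-only logit shift planted on probes of
#' independent-down genes: TSS probes hypermethylated, gene-body probes
#' hypomethylated) and inverse-logit transformed, so values lie in (0, 1)
#' and clipping is essentially never active.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return List: `cohort` (methylation `matched_cohort`), `annotation`
#'   (probe annotation data.frame), `truth_probes` (data.frame `probe_id`,
#'   `gene`, `region`, `planted_direction`).
#' @export
simulate_methylation <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 1L) %% .Machine$integer.max)
  mc <- config$methylation
  genes <- truth$markers$marker_id[truth$markers$class != "signature"]
  gene_class <- truth$markers$class[truth$markers$class != "signature"]
  ppg <- mc$probes_per_gene
  regions <- rep(c("tss", "gene_body", "other"), length.out = ppg)
  probe_gene <- rep(genes, each = ppg)
  probe_region <- rep(regions, times = length(genes))
  probe_ids <- sprintf("cg%06d", seq_along(probe_gene))
  cls <- rep(gene_class, each = ppg)
  effect <- ifelse(cls == "indep_down" & probe_region == "tss",
                   mc$tss_hyper_effect,
                   ifelse(cls == "indep_down" & probe_region == "gene_body",
                          -mc$body_hypo_effect, 0))

  patients <- truth$patients
  n_pat <- length(patients)
  n_probe <- length(probe_ids)
  b0 <- stats::rnorm(n_probe, 0, mc$baseline_sd)
  noise <- function() matrix(stats::rnorm(n_probe * n_pat, 0, mc$noise_sd),
                             n_probe, n_pat)
  logit_normal <- b0 + noise()
  logit_tumor <- b0 + effect + noise()
  clip01 <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }
  tumor <- clip01(stats::plogis(logit_tumor))
  normal <- clip01(stats::plogis(logit_normal))
  t_id <- paste0(patients, "-T")
  n_id <- paste0(patients, "-N")
  combined <- cbind(tumor, normal)
  dimnames(combined) <- list(probe_ids, c(t_id, n_id))
  mat <- marker_matrix(combined, "methylation")
  manifest <- data.frame(
    sample_id = c(t_id, n_id), patient_id = rep(patients, 2L),
    tissue = rep(unname(truth$tissue_of[patients]), 2L),
    status = rep(c("tumor", "normal"), each = n_pat),
    stringsAsFactors = FALSE)
  annotation <- data.frame(probe_id = probe_ids, gene = probe_gene,
                           region = probe_region, stringsAsFactors = FALSE)
  list(cohort = suppressMessages(build_matched_cohort(mat, manifest)),
       annotation = annotation,
       truth_probes = data.frame(
         probe_id = probe_ids, gene = probe_gene, region = probe_region,
         planted_direction = sign(effect), stringsAsFactors = FALSE),
       matrix = mat, manifest = manifest)
}

#' Simulate a gene-set collection with planted and decoy sets
#'
#' One planted set per non-null marker class (members drawn from that
#' class, so e.g. the proliferation-driven markers form a cell-cycle-like
#' set), plus random decoy sets of matched sizes drawn uniformly from all
#' markers.
#'
#' @param config A [sim_config()].
#' @param truth The `truth` element returned by [simulate_cohort()].
#' @return List: `collection` (named list of member vectors) and `sets`
#'   (data.frame `set_name`, `class`, `enriched`).
#' @export
simulate_gene_sets <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 2L) %% .Machine$integer.max)
  ps <- config$planted_sets
  mk <- truth$markers[truth$markers$class != "signature", ]
  planted_classes <- intersect(c("prolif_driven", "indep_up", "indep_down"),
                               unique(mk$class))
  collection <- list()
  rows <- list()
  for (cl in planted_classes) {
    pool <- mk$marker_id[mk$class == cl]
    size <- min(ps$set_size, length(pool))
    nm <- paste0("planted_", cl)
    collection[[nm]] <- sample(pool, size)
    rows[[nm]] <- data.frame(set_name = nm, class = cl, enriched = TRUE,
                             stringsAsFactors = FALSE)
  }
  if (any(mk$codiff_module)) {
    collection[["planted_codiff"]] <- mk$marker_id[mk$codiff_module]
    rows[["planted_codiff"]] <- data.frame(
      set_name = "planted_codiff", class = "codiff_module", enriched = TRUE,
      stringsAsFactors = FALSE)
  }
  sizes <- vapply(collection, length, integer(1L))
  for (j in seq_len(ps$n_decoys)) {
    nm <- sprintf("decoy_%03d", j)
    size <- sizes[1L + (j - 1L) %% length(sizes)]
    collection[[nm]] <- sample(mk$marker_id, size)
    rows[[nm]] <- data.frame(set_name = nm, class = "decoy",
                             enriched = FALSE, stringsAsFactors = FALSE)
  }
  list(collection = collection, sets = do.call(rbind, c(rows,
       list(make.row.names = FALSE))))
}

#' Write a complete simulated input bundle to a directory
#'
#' Writes the expression matrix, manifest, signature gene list, gene sets
#' (GMT), methylation matrix, probe annotation and ground-truth tables as
#' plain-text files, the on-disk starting point for [run_pipeline()].
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(config)
  meth <- simulate_methylation(config, sim$truth)
  sets <- simulate_gene_sets(config, sim$truth)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    manifest = file.path(dir, "manifest.tsv"),
    signature = file.path(dir, "signature_genes.txt"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    methylation = file.path(dir, "methylation.tsv"),
    probe_annotation = file.path(dir, "probe_annotation.tsv"),
    truth_markers = file.path(dir, "truth_markers.tsv"),
    truth_sets = file.path(dir, "truth_sets.tsv"),
    truth_scores = file.path(dir, "truth_scores.tsv"))
  write_marker_matrix(sim$matrix, paths["expression"])
  utils::write.table(sim$manifest, paths["manifest"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(sim$signature_genes, paths["signature"])
  write_gmt(sets$collection, paths["gene_sets"])
  write_marker_matrix(meth$matrix, paths["methylation"])
  utils::write.table(meth$annotation, paths["probe_annotation"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$markers, paths["truth_markers"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sets$sets, paths["truth_sets"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$scores_true),
               score = unname(sim$scores_true)),
    paths["truth_scores"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
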
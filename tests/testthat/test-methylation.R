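test_that("classify_genes applies the Bonferroni threshold and direction", {
  tab <- data.frame(marker_id = c("a", "b", "c", "d"),
                    f_up = c(0.9, 0.1, 0.5, 0.2),
                    p_bonf = c(0.001, 0.2, 0.0001, 0.01))
  calls <- classify_genes(tab, alpha = 0.05)
  expect_equal(calls$call, c("up", "neutral", "neutral", "down"))
  expect_error(classify_genes(data.frame(marker_id = "a")), "missing column")
})

test_that("odds-ratio arithmetic: cross-product, inversion, CI narrowing", {
  or_from_counts <- function(a, b, c, d, ...) {
    probes <- sprintf("p%03d", 1:(a + b + c + d))
    # stats: above-median (1) vs below (0) constructed directly
    stat <- c(rep(1, a + b), rep(0, c + d))
    genes <- c(rep("gdown", a), paste0("go", seq_len(b)),
               rep("gdown", c), paste0("gu", seq_len(d)))
    names(stat) <- probes
    ann <- data.frame(probe_id = probes, gene = genes, region = "tss",
                      stringsAsFactors = FALSE)
    calls <- data.frame(gene = unique(genes),
                        call = ifelse(unique(genes) == "gdown", "down",
                                      "neutral"),
                        p_bonf = 0.01)
    # median of a 0/1 mix with majority structure: force the split with
    # jitter-free values; median is 0.5 when balanced, so stat > median
    # reproduces above/below exactly when a+b = c+d is not required
    methylation_odds_ratio(stat, ann, calls, "tss", ...)
  }
  r <- or_from_counts(20, 5, 10, 25)
  expect_equal(r$odds_ratio, 10)
  expect_equal(unname(r$table["above_median", ]), c(20, 5))
  # transposing the gene classification inverts the OR
  r_inv <- {
    probes <- sprintf("p%03d", 1:60)
    stat <- setNames(c(rep(1, 25), rep(0, 35)), probes)
    genes <- c(rep("gdown", 20), paste0("go", 1:5),
               rep("gdown", 10), paste0("gu", 1:25))
    ann <- data.frame(probe_id = probes, gene = genes, region = "tss")
    calls_sw <- data.frame(gene = unique(genes),
                           call = ifelse(unique(genes) == "gdown",
                                         "neutral", "down"),
                           p_bonf = 0.01)
    methylation_odds_ratio(stat, ann, calls_sw, "tss")
  }
  expect_equal(r_inv$odds_ratio, 1 / r$odds_ratio)
  # balanced table gives OR = 1
  bal <- or_from_counts(25, 25, 25, 25)
  expect_equal(bal$odds_ratio, 1)
  # doubling all cells keeps the OR, narrows the CI
  dbl <- or_from_counts(40, 10, 20, 50)
  expect_equal(dbl$odds_ratio, r$odds_ratio)
  expect_lt(dbl$ci_high - dbl$ci_low, r$ci_high - r$ci_low)
})

test_that("zero cells trigger the Haldane-Anscombe correction, empty strata error", {
  probes <- sprintf("p%02d", 1:40)
  stat <- setNames(c(rep(1, 20), rep(0, 20)), probes)
  genes <- c(rep("gdown", 20), paste0("g", 1:20))
  ann <- data.frame(probe_id = probes, gene = genes, region = "tss")
  calls <- data.frame(gene = unique(genes),
                      call = ifelse(unique(genes) == "gdown", "down",
                                    "neutral"), p_bonf = 0.01)
  r <- methylation_odds_ratio(stat, ann, calls, "tss")
  expect_equal(r$odds_ratio, (20.5 * 20.5) / (0.5 * 0.5))
  expect_true(is.finite(r$ci_high))
  calls_none <- transform(calls, call = "neutral")
  expect_error(methylation_odds_ratio(stat, ann, calls_none, "tss"),
               "empty stratum")
  expect_error(methylation_odds_ratio(stat, ann, calls, "gene_body"),
               "no scored probes")
})

test_that("gene_probe_view reports per-probe f_up consistent with fup_screen", {
  cfg <- sim_config(seed = 37, n_markers = 60, n_patients_per_tissue = 30,
                    tissues = "A",
                    codiff_module = list(n_genes = 0, magnitude_sd = 0))
  sim <- simulate_cohort(cfg)
  meth <- simulate_methylation(cfg, sim$truth)
  gene <- sim$truth$markers$marker_id[sim$truth$markers$class == "indep_down"][1]
  view <- gene_probe_view(gene, meth$cohort, meth$annotation)
  expect_equal(nrow(view),
               sum(meth$annotation$gene == gene))
  expect_setequal(view$region, c("tss", "gene_body"))
  full <- fup_screen(meth$cohort)
  expect_equal(view$f_up,
               full$f_up[match(view$probe_id, full$marker_id)])
  expect_error(gene_probe_view("nope", meth$cohort, meth$annotation),
               "no annotated probes")
})

test_that("planted TSS hypermethylation yields OR > 1, gene body OR < 1", {
  cfg <- sim_config(seed = 43, n_markers = 500, n_patients_per_tissue = 50,
                    tissues = c("A", "B"))
  sim <- simulate_cohort(cfg)
  co <- suppressMessages(filter_detectable(sim$cohort))
  scores <- suppressMessages(
    cohort_proliferation_scores(co, sim$signature_genes))
  det <- detrended_fup_screen(co, scores)
  calls <- classify_genes(det)
  meth <- simulate_methylation(cfg, sim$truth)
  mtab <- fup_screen(suppressMessages(filter_detectable(meth$cohort)))
  stat <- setNames(mtab$f_up, mtab$marker_id)
  tss <- methylation_odds_ratio(stat, meth$annotation, calls, "tss")
  body <- methylation_odds_ratio(stat, meth$annotation, calls, "gene_body")
  expect_gt(tss$ci_low, 1)
  expect_lt(body$ci_high, 1)
})
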
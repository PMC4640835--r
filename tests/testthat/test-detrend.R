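make_scored_cohort <- function(seed = 4, n = 60, m = 30,
                               tissues = c("A", "B")) {
  set.seed(seed)
  tiss <- rep(tissues, length.out = n)
  score_t <- rnorm(n, 1, 0.7)
  score_n <- rnorm(n, 0, 0.7)
  tumor <- matrix(rnorm(m * n), m, n)
  normal <- matrix(rnorm(m * n), m, n)
  co <- toy_cohort(tumor, normal, tissues = tiss)
  list(cohort = co,
       scores = list(tumor = setNames(score_t, co$patients),
                     normal = setNames(score_n, co$patients)))
}

test_that("a marker linear in metaPCNA within tissue has near-zero residuals", {
  x <- make_scored_cohort()
  co <- x$cohort
  s_t <- x$scores$tumor[co$patients]
  s_n <- x$scores$normal[co$patients]
  slope <- ifelse(co$tissue_of == "A", 2, -1)
  icpt <- ifelse(co$tissue_of == "A", 5, 3)
  co$tumor[1, ] <- icpt + slope * s_t
  co$normal[1, ] <- icpt + slope * s_n
  dt <- detrend_markers(co, x$scores)
  scale1 <- sd(c(co$tumor[1, ], co$normal[1, ]))
  expect_lt(max(abs(c(dt$tumor[1, ], dt$normal[1, ]))), 1e-8 * scale1)
  expect_gt(dt$per_marker_fit$r_squared[1], 1 - 1e-12)
})

test_that("a marker independent of score and tissue keeps its centered values", {
  x <- make_scored_cohort(seed = 6)
  dt <- detrend_markers(x$cohort, x$scores)
  y <- c(x$cohort$tumor[2, ], x$cohort$normal[2, ])
  r <- c(dt$tumor[2, ], dt$normal[2, ])
  expect_lt(max(abs(r - (y - mean(y)))), 0.6 * sd(y))
  expect_lt(dt$per_marker_fit$r_squared[2], 0.3)
})

test_that("residuals are orthogonal to every design column and centered", {
  x <- make_scored_cohort(seed = 7)
  dt <- detrend_markers(x$cohort, x$scores)
  R <- cbind(dt$tumor, dt$normal)
  ip <- abs(R %*% dt$design)
  expect_lt(max(ip), 1e-8 * max(abs(R)) * nrow(dt$design))
  expect_lt(max(abs(rowMeans(R))), 1e-10)
})

test_that("detrending is idempotent", {
  x <- make_scored_cohort(seed = 8)
  dt1 <- detrend_markers(x$cohort, x$scores)
  co2 <- x$cohort
  co2$tumor <- dt1$tumor
  co2$normal <- dt1$normal
  dt2 <- detrend_markers(co2, x$scores)
  expect_equal(dt2$tumor, dt1$tumor, tolerance = 1e-10)
  expect_equal(dt2$normal, dt1$normal, tolerance = 1e-10)
})

test_that("residuals do not depend on the tissue reference level", {
  x <- make_scored_cohort(seed = 9, tissues = c("A", "B", "C"))
  dt1 <- detrend_markers(x$cohort, x$scores)
  co2 <- x$cohort
  # relabel so the alphabetically first tissue differs
  co2$tissue_of[] <- chartr("ABC", "ZBC", co2$tissue_of)
  dt2 <- detrend_markers(co2, x$scores)
  expect_equal(dt2$tumor, dt1$tumor, tolerance = 1e-10)
})

test_that("single-tissue cohorts degrade to the metaPCNA-only design", {
  x <- make_scored_cohort(seed = 10, tissues = "ONLY")
  expect_message(dt <- detrend_markers(x$cohort, x$scores), "single-tissue")
  expect_equal(dt$model_terms, "marker_level ~ metaPCNA")
  expect_equal(ncol(dt$design), 2L)
})

test_that("tumor-only shifts survive residualization; residual ties stay ties", {
  x <- make_scored_cohort(seed = 12, n = 80)
  co <- x$cohort
  s_t <- x$scores$tumor[co$patients]
  s_n <- x$scores$normal[co$patients]
  delta <- 2
  co$tumor[3, ] <- 1.5 * s_t + delta + rnorm(80, 0, 0.3)
  co$normal[3, ] <- 1.5 * s_n + rnorm(80, 0, 0.3)
  co$tumor[4, ] <- 7
  co$normal[4, ] <- 7
  dt <- detrend_markers(co, x$scores)
  d3 <- dt$tumor[3, ] - dt$normal[3, ]
  expect_gt(mean(d3 > 0), 0.85)  # the planted shift keeps its sign
  tab <- detrended_fup_screen(co, x$scores)
  expect_true(is.na(tab$f_up[4]))  # constant marker untestable after detrending
  expect_true(all(c("r_proliferation", "model_r2") %in% names(tab)))
})

test_that("purely proliferation-driven signal is removed, independent signal kept", {
  cfg <- sim_config(seed = 41, n_markers = 400, n_patients_per_tissue = 80,
                    tissues = c("A", "B"))
  sim <- simulate_cohort(cfg)
  co <- suppressMessages(filter_detectable(sim$cohort))
  scores <- suppressMessages(
    cohort_proliferation_scores(co, sim$signature_genes))
  raw <- fup_screen(co)
  det <- detrended_fup_screen(co, scores)
  cls <- sim$truth$markers$class[match(raw$marker_id,
                                       sim$truth$markers$marker_id)]
  prolif <- cls == "prolif_driven"
  indep <- cls == "indep_up"
  expect_gt(mean(raw$f_up[prolif]), 0.8)
  expect_lt(abs(median(det$f_up[prolif]) - 0.5), 0.1)
  expect_gt(mean(det$f_up[indep]), 0.75)
  # separation property: detrending pulls the proliferation class toward
  # 0.5 harder than the independent class
  expect_lt(mean(abs(det$f_up[prolif] - 0.5)),
            mean(abs(det$f_up[indep] - 0.5)))
})
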
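test_that("fraction_upregulated counts strict exceedances, drops ties and NAs", {
  r <- fraction_upregulated(c(2, 3, 5, 1), c(1, 1, 1, 2))
  expect_equal(r[c("k", "n_eff", "f_up")], list(k = 3, n_eff = 4L, f_up = 0.75))

  tied <- fraction_upregulated(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$testable)
  expect_true(is.na(tied$f_up))

  r2 <- fraction_upregulated(c(rep(2, 9), 0), rep(1, 10))
  expect_equal(r2$f_up, 0.9)

  r3 <- fraction_upregulated(c(2, NA, 3, 1), c(1, 5, 3, 2))
  expect_equal(r3$n_eff, 2L)  # NA pair and tied pair excluded
  expect_error(fraction_upregulated(1:3, 1:2), "equal length")
})

test_that("sign_test_p matches closed forms and the enumeration oracle", {
  expect_equal(sign_test_p(5, 10), 1)
  expect_equal(sign_test_p(9, 10), 0.021484375)
  expect_equal(sign_test_p(0, 20), 2 * 2^-20)
  expect_error(sign_test_p(11, 10), "0 <= k <= n")
  # spot-check the 2^n enumeration oracle at a few (k, n)
  for (case in list(c(3, 7), c(0, 5), c(6, 12), c(4, 8))) {
    expect_equal(sign_test_p(case[1], case[2]),
                 brute_sign_p(case[1], case[2]), tolerance = 1e-12)
  }
})

test_that("beta_ci gives equal-tailed Beta(k+1, n-k+1) quantiles", {
  ci <- beta_ci(10, 10, 0.95)
  expect_equal(ci$ci_low, 0.025^(1 / 11))   # closed form for Beta(11, 1)
  expect_equal(ci$ci_high, 0.975^(1 / 11))
  # k = 0 interval mirrors k = n around 0.5
  ci0 <- beta_ci(0, 10, 0.95)
  expect_equal(ci0$ci_low, 1 - ci$ci_high)
  expect_equal(ci0$ci_high, 1 - ci$ci_low)
  # 99% interval strictly contains the 95% interval
  ci99 <- beta_ci(7, 10, 0.99)
  ci95 <- beta_ci(7, 10, 0.95)
  expect_lt(ci99$ci_low, ci95$ci_low)
  expect_gt(ci99$ci_high, ci95$ci_high)
  expect_error(beta_ci(5, 10, 1.5), "level")
  # Jeffreys prior shifts shapes by 1/2
  cj <- beta_ci(3, 8, 0.9, prior = "jeffreys")
  expect_equal(cj$ci_low, qbeta(0.05, 3.5, 5.5))
})

test_that("adjust_pvalues implements Bonferroni and BH with ordering intact", {
  expect_equal(adjust_pvalues(0.01, "bonferroni"), 0.01)
  expect_equal(adjust_pvalues(c(0.01, 0.04), "bonferroni"), c(0.02, 0.08))
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bh"), rep(0.03, 3))
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
  set.seed(5)
  p <- runif(50)
  expect_true(all(adjust_pvalues(p, "bh") >= p))
  expect_true(all(adjust_pvalues(p, "bonferroni") >= adjust_pvalues(p, "bh")))
})

test_that("fup_screen reports per-marker stats and the CI_Bonf convention", {
  set.seed(21)
  tumor <- matrix(rnorm(50 * 20, mean = 0.5), 50, 20)
  normal <- matrix(rnorm(50 * 20), 50, 20)
  co <- toy_cohort(tumor, normal)
  tab <- fup_screen(co, level = 0.95, bonferroni_ci = TRUE)
  expect_s3_class(tab, "marker_table")
  expect_equal(tab$f_up, tab$k / tab$n_eff)
  expect_true(all(tab$ci_low <= tab$f_up & tab$f_up <= tab$ci_high))
  expect_equal(unique(tab$ci_level), 1 - 0.05 / 50)
  expect_true(all(tab$p_bonf >= tab$p_value))

  one <- toy_cohort(matrix(c(2, 1), 2, 1, dimnames = list(c("a", "b"), NULL)),
                    matrix(c(1, 1), 2, 1))
  t1 <- fup_screen(one)
  expect_true(all(t1$f_up %in% c(0, 1) | is.na(t1$f_up)))
})

test_that("swapping tumor and normal reflects f_up and preserves p", {
  set.seed(8)
  # integer values force ties so tie handling is exercised too
  tumor <- matrix(sample(0:5, 300, TRUE), 30, 10)
  normal <- matrix(sample(0:5, 300, TRUE), 30, 10)
  a <- fup_screen(toy_cohort(tumor, normal))
  b <- fup_screen(toy_cohort(normal, tumor))
  expect_equal(b$f_up, 1 - a$f_up)
  expect_equal(b$p_value, a$p_value)
  expect_equal(b$n_eff, a$n_eff)
})

test_that("f_up and its p-value are invariant under strictly monotone transforms", {
  set.seed(13)
  tumor <- matrix(rnorm(200, 0.3), 20, 10)
  normal <- matrix(rnorm(200), 20, 10)
  a <- fup_screen(toy_cohort(tumor, normal))
  b <- fup_screen(toy_cohort(exp(tumor), exp(normal)))
  expect_equal(a$f_up, b$f_up)
  expect_equal(a$p_value, b$p_value)
})

test_that("paired_t_screen handles degenerate difference vectors", {
  co <- toy_cohort(rbind(rep(2, 6), c(1, -1, 2, -2, 3, -3)),
                   rbind(rep(1, 6), rep(0, 6)))
  tab <- paired_t_screen(co)
  expect_true(is.na(tab$t[1]))  # constant nonzero differences, zero variance
  expect_equal(tab$t[2], 0)     # symmetric differences
  expect_equal(tab$p_value[2], 1)
})

test_that("consensus_fup averages tissues and applies the sample floor", {
  t1 <- data.frame(marker_id = c("g1", "g2"), f_up = c(0.8, 0.7),
                   n_eff = c(300, 400))
  t2 <- data.frame(marker_id = c("g1", "g3"), f_up = c(0.6, 0.9),
                   n_eff = c(300, 400))
  out <- consensus_fup(list(A = t1, B = t2), min_total_n = 500)
  expect_equal(out$consensus_fup[out$marker_id == "g1"], 0.7)
  # g2 (400) and g3 (400) fall below the 500-sample floor
  expect_identical(out$marker_id, "g1")
  # permuting tissue order leaves the consensus unchanged
  out2 <- consensus_fup(list(B = t2, A = t1), min_total_n = 500)
  expect_equal(out, out2)
  expect_error(consensus_fup(list()), "at least one")
})
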
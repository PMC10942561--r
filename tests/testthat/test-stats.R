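test_that("one-way ANOVA matches the sum-of-squares oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- anova_oneway(g)
  ora <- oracle_anova(g)
  expect_equal(res$F, ora$F, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  expect_equal(res$df_between, 2)
  expect_equal(res$df_within, 6)
})

test_that("identical group means give F = 0, p = 1", {
  g <- list(c(1, 2, 3), c(0.5, 2, 3.5), c(1.5, 2, 2.5))
  res <- anova_oneway(g)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$p, 1)
})

test_that("ANOVA preconditions and degeneracies are caught", {
  expect_error(anova_oneway(list(c(1, 2, 3))), "two groups")
  expect_error(anova_oneway(list(c(1, 2), c(3))), "n >= 2")
  expect_error(anova_oneway(list(c(1, 1), c(2, 2))), "degenerate")
})

test_that("two-group ANOVA equals the squared pooled-variance t", {
  set.seed(7)
  a <- stats::rnorm(12)
  b <- stats::rnorm(15, mean = 0.8)
  res <- anova_oneway(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("post-hoc Welch t matches the textbook formula", {
  res <- posthoc_ttests(list(a = c(1, 2), b = c(3, 4)))
  ora <- oracle_welch(c(1, 2), c(3, 4))
  expect_equal(res$t, ora$t, tolerance = 1e-10)
  expect_equal(res$df, ora$df, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  # identical vectors: t = 0, p = 1
  same <- posthoc_ttests(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # near-complete separation
  sep <- posthoc_ttests(list(a = c(0, 0, 0, 0) + stats::rnorm(4, sd = 1e-9),
                             b = c(1, 1, 1, 1) + stats::rnorm(4, sd = 1e-9)))
  expect_lt(sep$p, 1e-6)
})

test_that("Pearson correlation matches the covariance oracle", {
  res <- pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4))
  ora <- oracle_pearson(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$p, ora$p, tolerance = 1e-10)
  x <- c(0.3, 1.7, 2.2, 5)
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(x, -x)$r, -1)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero-variance")
  expect_error(pearson_r(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("Pearson r is affine-invariant up to sign", {
  set.seed(11)
  x <- stats::rnorm(20)
  y <- stats::rnorm(20)
  r0 <- pearson_r(x, y)$r
  expect_equal(pearson_r(3 * x + 2, y)$r, r0, tolerance = 1e-12)
  expect_equal(pearson_r(-2 * x + 5, y)$r, -r0, tolerance = 1e-12)
})

test_that("Benjamini-Hochberg flags match the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04), 0.05),
               rep(TRUE, 4))
  expect_equal(benjamini_hochberg(c(0.9, 0.8, 0.7), 0.05), rep(FALSE, 3))
  expect_equal(benjamini_hochberg(numeric(0)), logical(0))
  set.seed(13)
  for (i in 1:50) {
    p <- stats::runif(sample(1:30, 1))
    flags <- benjamini_hochberg(p, 0.1)
    expect_identical(flags, oracle_bh(p, 0.1))
    # flags form a prefix of the sorted-p order
    expect_true(all(diff(flags[order(p)]) <= 0))
  }
})

test_that("the battery wires ANOVA, post-hoc gating and FDR together", {
  co <- simulate_cohort(child_cohort_spec(n_td = 6L, n_asd = 8L,
                                          trials_per_subject = 3L, seed = 17))
  ft <- extract_cohort_features(co$trials, co$manifest)
  bt <- run_battery(ft)
  expect_setequal(bt$anova$parameter, kinematic_feature_names())
  # post-hoc rows exist exactly for ANOVA-significant parameters
  expect_setequal(unique(bt$posthoc$parameter),
                  bt$anova$parameter[bt$anova$p < 0.05])
  expect_true(all(bt$correlations$r >= -1 & bt$correlations$r <= 1))
  expect_identical(bt$correlations$fdr_pass,
                   oracle_bh(bt$correlations$p, 0.05))
  # subject aggregation reduces the correlation df to subject counts
  bts <- run_battery(ft, aggregate = "subject")
  expect_true(all(bts$correlations$n <= 8))
})
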
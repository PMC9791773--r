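test_that("quartile categorization uses inclusive medium boundaries", {
  cc <- categorize_quality(c(10, 20, 30, 40))
  # P25 of (10,20,30,40) under type-7 interpolation is 17.5; the subject at
  # exactly a boundary must land in medium
  expect_equal(attr(cc, "p25"), 17.5)
  cc2 <- categorize_quality(c(17.5, 20, 30, 40, 50))
  p25 <- attr(cc2, "p25")
  at_boundary <- cc2$total == p25
  if (any(at_boundary)) expect_true(all(cc2$category[at_boundary] == "medium"))

  # degenerate: identical totals put everyone in medium
  all_same <- categorize_quality(rep(42, 10))
  expect_true(all(all_same$category == "medium"))

  # brute-force count under the documented linear-interpolation convention
  cc3 <- categorize_quality(1:100)
  expect_equal(unname(table(cc3$category)), c(25L, 50L, 25L),
               ignore_attr = TRUE)

  expect_error(categorize_quality(c(1, 2, 3)), "at least 4")
})

test_that("category counts partition the cohort and order by score", {
  coh <- demo_cohort(n = 120, seed = 5)
  res <- score_cohort(coh$records, coh$profiles)
  cc <- categorize_quality(res)
  expect_equal(sum(table(cc$category)), nrow(res))
  lows <- cc$total[cc$category == "low"]
  highs <- cc$total[cc$category == "high"]
  expect_true(max(lows) < min(highs))
})

test_that("nutrient adequacy ratios truncate at 1", {
  expect_equal(nutrient_adequacy_ratio(c(0.3, 1, 2), 1), c(0.3, 1, 1))
  expect_equal(nutrient_adequacy_ratio(50, 100), 0.5)
  expect_error(nutrient_adequacy_ratio(1, 0), "> 0")
  expect_error(nutrient_adequacy_ratio(-1, 1), ">= 0")
})

test_that("item-rest correlations match hand and simulation oracles", {
  # 3 subjects, 2 components: hand-ranked Spearman of (1,2,3) vs (2,1,3)
  m <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  ir <- item_rest_correlations(m)
  expect_equal(ir$item_rest_r[ir$component_id == "a"], 0.5)

  # perfectly rank-concordant columns
  m2 <- cbind(a = 1:10, b = (1:10)^2)
  ir2 <- item_rest_correlations(m2)
  expect_equal(ir2$item_rest_r, c(1, 1))

  # a component independent of the rest has r near 0 at large n
  set.seed(42)
  m3 <- cbind(simulate_factor_subscores(4000, 5, 0.7, seed = 8),
              indep = stats::rnorm(4000))
  ir3 <- item_rest_correlations(m3)
  expect_lt(abs(ir3$item_rest_r[ir3$component_id == "indep"]), 0.05)

  # zero-variance column is flagged, not fabricated
  m4 <- cbind(a = 1:5, b = rep(2, 5))
  ir4 <- item_rest_correlations(m4)
  expect_true(ir4$undefined[ir4$component_id == "b"])
  expect_true(is.na(ir4$item_rest_r[ir4$component_id == "b"]))

  # pairwise matrix has the full component layout
  expect_equal(dim(attr(ir3, "pairwise")), c(6, 6))
  expect_error(item_rest_correlations(cbind(1:2, 2:1)), ">= 3 subjects")
})

test_that("Cronbach's alpha matches its closed-form oracles", {
  # k = 2 with hand-computable variances/covariance
  m <- cbind(x = c(1, 2, 3, 4), y = c(1, 3, 2, 4))
  expect_equal(cronbach_alpha(m), oracle_alpha_raw(m))
  expect_equal(cronbach_alpha(m), 8 / 9, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m, standardized = TRUE), oracle_alpha_std(m))

  # identical columns give alpha 1 (both forms)
  m2 <- cbind(a = c(1, 5, 3, 7), b = c(1, 5, 3, 7), c = c(1, 5, 3, 7))
  expect_equal(cronbach_alpha(m2), 1)
  expect_equal(cronbach_alpha(m2, standardized = TRUE), 1)

  # independent columns: alpha near 0 at large n
  set.seed(1)
  m3 <- matrix(stats::rnorm(5000 * 6), 5000, 6)
  expect_lt(abs(cronbach_alpha(m3)), 0.08)
  expect_lt(abs(cronbach_alpha(m3, standardized = TRUE)), 0.08)

  expect_error(cronbach_alpha(cbind(rep(1, 5), rep(2, 5))),
               "zero variance")
})

test_that("adding a pure-noise component lowers standardized alpha", {
  m <- simulate_factor_subscores(3000, 10, 0.6, seed = 21)
  set.seed(22)
  m_noise <- cbind(m, noise = stats::rnorm(3000))
  expect_lt(cronbach_alpha(m_noise, standardized = TRUE),
            cronbach_alpha(m, standardized = TRUE))
})

test_that("PCA eigen screen behaves as the correlation-matrix theory says", {
  # independent standardized columns: all eigenvalues near 1
  m <- simulate_factor_subscores(5000, 8, 0, seed = 31)
  p <- pca_dimensions(m)
  expect_true(all(p$eigenvalues > 0.85 & p$eigenvalues < 1.15))
  expect_equal(sum(p$eigenvalues), 8, tolerance = 1e-8)  # trace conservation

  # near-rank-1 structure: first eigenvalue approaches k
  m2 <- simulate_factor_subscores(5000, 8, 0.99, seed = 32)
  p2 <- pca_dimensions(m2)
  expect_gt(p2$eigenvalues[1], 7.5)
  expect_equal(p2$n_eigen_gt_1, 1)
  expect_gt(p2$cumulative_variance_top_k, 0.9)

  # constant columns are dropped with a warning, not decomposed
  m3 <- cbind(m[1:50, 1:3], const = rep(1, 50))
  expect_warning(p3 <- pca_dimensions(m3), "constant")
  expect_equal(p3$n_components_retained, 3)
  expect_equal(p3$dropped, "const")
})

test_that("standardized alpha recovers the Spearman-Brown value at scale", {
  m <- simulate_factor_subscores(5000, 11, 0.6, seed = 33)
  expect_equal(cronbach_alpha(m, standardized = TRUE),
               spearman_brown(11, 0.6), tolerance = 0.03)
})

test_that("score-nutrient correlations track monotone structure", {
  totals <- tibble::tibble(subject_id = sprintf("s%03d", 1:50),
                           total = stats::runif(50, 0, 90))
  nut <- tibble::tibble(
    subject_id = totals$subject_id,
    mono = totals$total^3 + 5,
    anti = -2 * totals$total)
  res <- correlate_with_nutrients(totals, nut)
  expect_equal(res$rho[res$nutrient == "mono"], 1)
  expect_equal(res$rho[res$nutrient == "anti"], -1)

  set.seed(13)
  nut$permuted <- sample(nut$mono)
  res2 <- correlate_with_nutrients(totals, nut)
  expect_lt(abs(res2$rho[res2$nutrient == "permuted"]), 0.35)
  expect_gt(res2$p_value[res2$nutrient == "permuted"], 0.01)

  expect_error(correlate_with_nutrients(totals, nut[1:10, ]),
               "different subjects")
})

test_that("reliability_report bundles alphas, item-rest and PCA coherently", {
  coh <- demo_cohort(n = 150, seed = 17)
  scores <- score_cohort(coh$records, coh$profiles)
  rep <- reliability_report(scores)
  expect_s3_class(rep, "cpdi_reliability")
  expect_equal(rep$alpha_raw, oracle_alpha_raw(subscore_matrix_of(scores)))
  expect_equal(rep$alpha_standardized,
               oracle_alpha_std(subscore_matrix_of(scores)))
  expect_lte(rep$alpha_raw, 1)
  expect_lte(rep$alpha_standardized, 1)
  expect_equal(nrow(rep$item_rest), 11)
  expect_equal(sum(rep$pca$eigenvalues), 11, tolerance = 1e-8)
  g <- glance(rep)
  expect_equal(g$n_subjects, 150)
  expect_equal(tidy(rep), rep$item_rest)
})
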
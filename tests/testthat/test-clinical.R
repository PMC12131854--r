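# Sample-size formula, contingency tests, odds ratios, regression,
# stratified re-testing.

test_that("sample-size formula reproduces the validation design", {
  ss <- sample_size(d = 0.759, z_alpha = 1.96, z_beta = 1.28)
  expect_equal(ss$n_per_group, 37L)
  expect_equal(ss$n_total, 73L)
  # algebraic identity: d = (za+zb)*sqrt(2) gives exactly one per group
  ss1 <- sample_size(d = (1.96 + 1.28) * sqrt(2), z_alpha = 1.96, z_beta = 1.28)
  expect_equal(ss1$n_per_group, 1L)
  # (1.96+0.84)^2 * 2 / 0.25 = 62.72 -> 63
  expect_equal(sample_size(d = 0.5, z_alpha = 1.96, z_beta = 0.84)$n_per_group,
               63L)
})

test_that("sample size is monotone in effect size and power", {
  d <- c(0.3, 0.5, 0.759, 1.2)
  n <- vapply(d, function(di) sample_size(di)$n_raw, numeric(1L))
  expect_true(all(diff(n) < 0))
  pw <- c(0.7, 0.8, 0.9, 0.95)
  n2 <- vapply(pw, function(p) sample_size(0.5, power = p)$n_raw, numeric(1L))
  expect_true(all(diff(n2) > 0))
})

test_that("chi-square without continuity correction matches the cohort tables", {
  # hypertension, profiling (14/28) vs validation (47/84)
  htn <- chi_square_rc(rbind(c(14, 14), c(47, 37)))
  expect_equal(htn$p_value, 0.584, tolerance = 0.001)
  expect_equal(htn$statistic, 0.300, tolerance = 0.01)
  # sex, profiling (16 male/12 female) vs validation (46/38)
  sex <- chi_square_rc(rbind(c(16, 12), c(46, 38)))
  expect_equal(sex$p_value, 0.826, tolerance = 0.001)
  # balanced table: no association
  bal <- chi_square_rc(rbind(c(10, 10), c(10, 10)))
  expect_equal(bal$statistic, 0)
  expect_equal(bal$p_value, 1)
  expect_error(chi_square_rc(rbind(c(0, 0), c(1, 1))), "degenerate")
})

test_that("chi-square on 2x2 equals the squared two-proportion z statistic", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(20:80, 2)
    x <- c(sample(1:(n[1] - 1), 1), sample(1:(n[2] - 1), 1))
    tab <- rbind(c(x[1], n[1] - x[1]), c(x[2], n[2] - x[2]))
    p1 <- x[1] / n[1]; p2 <- x[2] / n[2]; pp <- sum(x) / sum(n)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    expect_equal(chi_square_rc(tab)$statistic, z^2, tolerance = 1e-10)
  }
})

test_that("Freeman-Halton exact test matches the sparse cohort comparisons", {
  # combined ophthalmic disease: 2/0/0 cases in groups of 37/38/9
  fh <- fisher_exact(rbind(c(2, 0, 0), c(35, 38, 9)))
  expect_equal(fh$p_value, 0.395, tolerance = 0.001)
  # 0 of 28 profiling vs 2 of 84 validation
  expect_equal(fisher_exact(rbind(c(0, 2), c(28, 82)))$p_value, 1.0,
               tolerance = 1e-9)
  # two permutation tables, each probability 0.5
  expect_equal(fisher_exact(rbind(c(1, 0), c(0, 1)))$p_value, 1.0)
})

test_that("enumerated table probabilities sum to one and match fisher.test", {
  set.seed(9)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    tab <- matrix(rpois(2 * k, 4), nrow = 2)
    tab[1, ] <- pmin(tab[1, ], 6)
    if (any(colSums(tab) == 0)) next
    fh <- fisher_exact(tab)
    expect_equal(fh$prob_total, 1, tolerance = 1e-12)
    expect_equal(fh$p_value, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("odds ratios, zero-cell correction, and symmetries", {
  expect_equal(odds_ratio(rbind(c(10, 10), c(10, 10)))$or, 1)
  o <- odds_ratio(rbind(c(20, 10), c(10, 20)))
  expect_equal(o$or, 4)
  expect_equal(o$log2_or, 2)
  expect_true(o$ci[1] < 4 && o$ci[2] > 4)
  oz <- odds_ratio(rbind(c(5, 0), c(5, 5)))
  expect_true(is.finite(oz$or) && oz$corrected)
  set.seed(5)
  for (i in 1:20) {
    tab <- matrix(sample(1:30, 4), 2)
    expect_equal(odds_ratio(t(tab))$or, odds_ratio(tab)$or, tolerance = 1e-12)
    expect_equal(odds_ratio(tab[2:1, ])$or, 1 / odds_ratio(tab)$or,
                 tolerance = 1e-12)
  }
})

test_that("covariate regression recovers a planted age slope", {
  set.seed(21)
  design <- cohort_design()
  clin <- generate_clinical_table(design, seed = 21)
  q <- matrix(2^(2 * clin$age + rnorm(nrow(clin), 0, 0.1)), nrow = 1,
              dimnames = list("pepA", clin$patient_id))
  fit <- covariate_regression(q, clin, covariate = "age",
                              adjust_for = "group")
  expect_equal(fit$estimate, 2, tolerance = 0.05)
  expect_lt(fit$p_adj, 0.05)
})

test_that("covariate regression flags degenerate designs", {
  design <- cohort_design()
  clin <- generate_clinical_table(design, seed = 4)
  q <- matrix(2^rnorm(nrow(clin)), nrow = 1,
              dimnames = list("pepA", clin$patient_id))
  expect_error(covariate_regression(q, clin, covariate = "age",
                                    adjust_for = c("group", "age")),
               "identical")
  clin$const <- 1
  fit <- covariate_regression(q, clin, covariate = "const",
                              adjust_for = "group")
  expect_identical(fit$flag, "covariate constant")
})

test_that("null covariate has near-zero estimate and uniform p", {
  set.seed(33)
  design <- cohort_design()
  clin <- generate_clinical_table(design, seed = 33)
  npep <- 40L
  q <- matrix(2^rnorm(npep * nrow(clin)), nrow = npep,
              dimnames = list(sprintf("pep%02d", 1:npep), clin$patient_id))
  fit <- covariate_regression(q, clin, covariate = "hypertension")
  expect_lt(abs(mean(fit$estimate)), 0.1)
  expect_gt(min(fit$p), 0)   # p spread out, not degenerate
  expect_lt(mean(fit$p < 0.05), 0.2)
})

test_that("stratified re-testing: constant stratum reproduces pooled result", {
  set.seed(8)
  design <- cohort_design()
  clin <- generate_clinical_table(design, seed = 8)
  q <- setNames(2^(rnorm(nrow(clin)) + (clin$group == "PDR")),
                clin$patient_id)
  clin$allone <- "all"
  res <- stratified_recheck(q, clin, contrast = c("PDR", "NPDR"),
                            stratify_by = "allone")
  expect_equal(nrow(res), 1L)
  pooled <- wilcoxon_rank_sum(q[clin$group == "PDR"],
                              q[clin$group == "NPDR"])$p_value
  expect_equal(res$p, pooled)
  expect_true(res$evaluable)
})

test_that("stratified re-testing localizes a stratum-specific effect", {
  set.seed(13)
  design <- cohort_design(n_per_group = c(NPDR = 40L, PDR = 40L, NVG = 2L))
  clin <- generate_clinical_table(design, seed = 13)
  clin$age_band <- ifelse(clin$age >= 60, "60plus", "under60")
  eff <- ifelse(clin$group == "PDR" & clin$age_band == "60plus", 2, 0)
  q <- setNames(2^(rnorm(nrow(clin), 0, 0.3) + eff), clin$patient_id)
  res <- stratified_recheck(q, clin, contrast = c("PDR", "NPDR"),
                            stratify_by = "age_band")
  res <- res[res$evaluable, ]
  hit <- res[res$stratum == "60plus", ]
  other <- res[res$stratum == "under60", ]
  expect_lt(hit$p, 0.01)
  expect_gt(other$p, 0.05)
})

test_that("summary-statistic t tests expose the published-age discrepancy", {
  # profiling 61.6 +/- 12.1 (n=28) vs validation 59.8 +/- 10.6 (n=84)
  res <- t_from_summary(61.6, 12.1, 28, 59.8, 10.6, 84)
  expect_identical(res$method, c("pooled", "welch"))
  expect_equal(res$p_value[res$method == "pooled"], 0.454, tolerance = 0.005)
  expect_equal(res$p_value[res$method == "welch"], 0.486, tolerance = 0.005)
  # neither variant reproduces the table's printed 0.700
  expect_true(all(abs(res$p_value - 0.700) > 0.1))
  # equal summaries: t = 0, p = 1
  eq <- t_from_summary(10, 2, 20, 10, 2, 20)
  expect_equal(eq$p_value, c(1, 1))
})

test_that("cohort summary table formats counts and p-values per group", {
  clin <- generate_clinical_table(cohort_design(seed = 77))
  tab <- table1_summary(clin)
  expect_identical(tab$characteristic[1], "Age, years")
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  expect_match(tab$NPDR[2], "^\\d+ \\(\\d+\\.\\d%\\)")
})
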
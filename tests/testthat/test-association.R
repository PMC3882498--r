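test_that("allele tables count risk and non-risk alleles by group", {
  tab <- allele_table(c(2, 1, 0, 1), c("case", "case", "control", "control"))
  expect_equal(unname(tab), matrix(c(3L, 1L, 1L, 3L), 2))

  tab0 <- allele_table(c(0, 0, 0), c("case", "case", "control"))
  expect_equal(unname(tab0["risk", ]), c(0L, 0L))

  expect_error(allele_table(c(NA, 1), c("case", "control")), "group 'case'")

  # margins equal twice the non-missing group sizes on a simulated cohort
  sim <- simulate_cohort(small_spec(seed = 41, missing_rate = 0.1))
  d <- unclass(sim$genotypes)[, "rsA"]
  st <- sim$status
  tabA <- allele_table(d, st)
  expect_equal(unname(colSums(tabA)),
    2 * c(sum(!is.na(d) & st == "case"), sum(!is.na(d) & st == "control")))
})

test_that("allele counts reconstruct from printed frequencies by rounding", {
  expect_equal(reconstruct_counts_from_maf(0.478, 179), 171L)  # 358 * 0.478 = 171.124
  expect_equal(reconstruct_counts_from_maf(0, 100), 0L)
  expect_equal(reconstruct_counts_from_maf(0.5, 100), 100L)
  expect_equal(reconstruct_counts_from_maf(0.0025, 100), 1L)   # ties away from zero
})

test_that("two-sided Fisher p matches enumeration and the reference test", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1.0)

  t28 <- matrix(c(2, 8, 5, 5), 2)
  expect_equal(fisher_exact_two_sided(t28), oracle_fisher_p(t28), tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(t28), 0.3498, tolerance = 1e-3)

  expect_message(p0 <- fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2)), "zero margin")
  expect_equal(p0, 1.0)

  set.seed(42)
  for (i in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab), fisher.test(tab)$p.value,
      tolerance = 1e-9)
  }
})

test_that("the stage-1 tables reconstructed from printed frequencies give the printed statistics", {
  # 171/187 risk/non-risk case alleles vs 107/181 in controls
  tab <- matrix(c(171, 187, 107, 181), 2)
  # the printed p (0.0094) reflects pre-rounding counts; reconstruction from
  # 3-decimal frequencies can only match it approximately
  expect_lt(abs(fisher_exact_two_sided(tab) - 0.0094), 2e-3)
  orr <- allelic_odds_ratio(tab)
  expect_equal(orr$or, 1.54, tolerance = 0.01)

  tab2 <- matrix(c(42, 316, 20, 268), 2)
  orr2 <- allelic_odds_ratio(tab2)
  expect_gt(orr2$or, 1.77); expect_lt(orr2$or, 1.80)
})

test_that("allelic odds ratio: cross product, symmetry, Haldane and errors", {
  expect_equal(allelic_odds_ratio(matrix(c(3, 1, 1, 3), 2))$or, 9.0)

  sym <- allelic_odds_ratio(matrix(c(6, 4, 6, 4), 2))
  expect_equal(sym$or, 1.0)
  expect_lte(sym$ci_low, 1); expect_gte(sym$ci_high, 1)

  h <- allelic_odds_ratio(matrix(c(0, 10, 5, 5), 2))
  expect_true(h$haldane)
  expect_equal(h$or, (0.5 * 5.5) / (10.5 * 5.5))

  expect_error(allelic_odds_ratio(matrix(c(0, 0, 5, 5), 2)), "zero margin")

  # OR(table) * OR(rows swapped) == 1 exactly; CI narrows when counts scale up
  set.seed(43)
  for (i in 1:100) {
    tab <- matrix(sample(1:50, 4, replace = TRUE), 2)
    a <- allelic_odds_ratio(tab)
    b <- allelic_odds_ratio(tab[2:1, ])
    expect_equal(a$or * b$or, 1.0, tolerance = 1e-12)
    big <- allelic_odds_ratio(tab * 4L)
    expect_lt(log(big$ci_high / big$ci_low), log(a$ci_high / a$ci_low))
  }
})

test_that("per-SNP association recovers simulated effects and flags degenerate SNPs", {
  sim <- simulate_cohort(small_spec(n_cases = 2000, n_controls = 2000, seed = 44))
  assoc <- per_allele_association(sim$genotypes, sim$phenotypes,
    panel_for(sim$genotypes))
  expect_s3_class(assoc, "assoc_table")
  rsA <- assoc[assoc$snp_id == "rsA", ]
  expect_equal(rsA$or, 1.54, tolerance = 0.12)
  # the allelic and dosage-logistic estimates agree closely at this size
  expect_equal(rsA$or_logistic, rsA$or, tolerance = 0.03)
  rsD <- assoc[assoc$snp_id == "rsD", ]
  expect_lt(rsD$or, 1)

  g2 <- force_monomorphic(sim$genotypes, "rsB")
  expect_warning(a2 <- per_allele_association(g2, sim$phenotypes, panel_for(g2)),
    "monomorphic")
  expect_false("rsB" %in% a2$snp_id)

  pan3 <- panel_for(sim$genotypes); pan3 <- pan3[pan3$snp_id != "rsC", ]
  expect_warning(a3 <- per_allele_association(sim$genotypes, sim$phenotypes, pan3),
    "absent from panel")
  expect_false("rsC" %in% a3$snp_id)
})

test_that("covariate-adjusted dosage logistic runs and leaves the null null", {
  sim <- simulate_cohort(small_spec(n_cases = 400, n_controls = 400, seed = 45))
  assoc <- per_allele_association(sim$genotypes, sim$phenotypes,
    panel_for(sim$genotypes), covariates = "age")
  expect_true(all(is.finite(assoc$or_logistic)))
  rsB <- assoc[assoc$snp_id == "rsB", ]  # simulated null SNP
  expect_gt(rsB$p_fisher, 0.001)
})
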
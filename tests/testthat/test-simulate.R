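test_that("a fixed seed gives byte-identical cohorts; distinct seeds differ", {
  a <- simulate_cohort(small_spec(seed = 7))
  b <- simulate_cohort(small_spec(seed = 7))
  expect_identical(unclass(a$genotypes), unclass(b$genotypes))
  expect_identical(a$phenotypes, b$phenotypes)
  c <- simulate_cohort(small_spec(seed = 8))
  expect_false(identical(unclass(a$genotypes), unclass(c$genotypes)))
})

test_that("control genotypes follow Hardy-Weinberg proportions", {
  spec <- small_spec(n_cases = 50, n_controls = 5000, seed = 21,
    snps = data.frame(snp_id = "rsQ", control_raf = 0.3, true_or = 1.8))
  g <- simulate_genotypes(spec)
  ctrl <- unclass(g)[attr(g, "status") == "control", 1]
  q <- 0.3
  expected <- c((1 - q)^2, 2 * q * (1 - q), q^2)
  obs <- tabulate(ctrl + 1L, 3L) / length(ctrl)
  for (k in 1:3) {
    sd_k <- sqrt(expected[k] * (1 - expected[k]) / length(ctrl))
    expect_lt(abs(obs[k] - expected[k]), 3 * sd_k)
  }
})

test_that("a null SNP shows no case-control frequency difference at large n", {
  spec <- small_spec(n_cases = 5000, n_controls = 5000, seed = 22,
    snps = data.frame(snp_id = "rsN", control_raf = 0.25, true_or = 1))
  g <- simulate_genotypes(spec)
  st <- attr(g, "status")
  f1 <- mean(unclass(g)[st == "case", 1]) / 2
  f0 <- mean(unclass(g)[st == "control", 1]) / 2
  se <- sqrt(2 * 0.25 * 0.75 / (2 * 5000))
  expect_lt(abs(f1 - f0), 3 * se)
})

test_that("the tilted case model yields the simulated allelic odds ratio", {
  # analytic check of the tilting identity plus a large-sample estimate
  q <- 0.372; or <- 1.54
  p_case <- c((1 - q)^2, 2 * q * (1 - q) * or, q^2 * or^2)
  p_case <- p_case / sum(p_case)
  raf_case <- sum(p_case * 0:2) / 2
  odds_case <- raf_case / (1 - raf_case)
  odds_ctrl <- q / (1 - q)
  expect_equal(odds_case / odds_ctrl, or, tolerance = 1e-12)

  spec <- small_spec(n_cases = 20000, n_controls = 20000, seed = 23,
    snps = data.frame(snp_id = "rsE", control_raf = q, true_or = or))
  g <- simulate_genotypes(spec)
  tab <- allele_table(unclass(g)[, 1], attr(g, "status"))
  expect_equal(allelic_odds_ratio(tab)$or, or, tolerance = 0.06)
})

test_that("PSA stochastically dominates in cases (AUC > 0.5)", {
  spec <- small_spec(n_cases = 1000, n_controls = 1000, seed = 24)
  sim <- simulate_cohort(spec)
  auc <- auc_mann_whitney(sim$phenotypes$psa, sim$phenotypes$status)$auc
  expect_gt(auc, 0.5)
  expect_gt(auc, 0.8)  # the generator targets the high-discrimination regime
})

test_that("binary covariate effects are recovered by logistic regression", {
  spec <- simulation_spec(n_cases = 10000, n_controls = 10000,
    snps = data.frame(snp_id = "rs0", control_raf = 0.3, true_or = 1),
    covariates = list(family_history_cancer = list(type = "binary", p0 = 0.05, or = 2.6)),
    seed = 25)
  sim <- simulate_cohort(spec)
  x <- as.integer(sim$phenotypes$family_history_cancer == "yes")
  y <- as.integer(sim$phenotypes$status == "case")
  fit <- logistic_fit(cbind(1, fh = x), y)
  expect_lt(abs(fit$coef["fh"] - log(2.6)), 2 * fit$se["fh"])
})

test_that("a null covariate rejects at about the nominal 5% rate", {
  spec <- simulation_spec(n_cases = 150, n_controls = 150,
    snps = data.frame(snp_id = "rs0", control_raf = 0.3, true_or = 1),
    covariates = list(diabetes = list(type = "binary", p0 = 0.3, or = 1)),
    seed = 0)
  hits <- 0L
  for (r in seq_len(400)) {
    spec$seed <- 1000L + r
    sim <- simulate_cohort(spec)
    tab <- table(sim$phenotypes$diabetes, sim$phenotypes$status)
    p <- chi_square_yates(matrix(as.integer(tab), 2, 2))$p
    hits <- hits + (p <= 0.05)
  }
  # Yates correction is conservative; the rate must not exceed nominal and
  # must stay in a plausible band below it
  expect_lt(hits / 400, 0.075)
  expect_gt(hits / 400, 0.005)
})

test_that("spec validation rejects out-of-domain parameters", {
  expect_error(small_spec(snps = data.frame(snp_id = "a", control_raf = 0, true_or = 1)),
    "control_raf")
  expect_error(small_spec(snps = data.frame(snp_id = "a", control_raf = 0.2, true_or = 0)),
    "true_or")
  expect_error(simulation_spec(missing_rate = 1), "missing_rate")
  expect_error(simulation_spec(covariates = list(x = list(type = "binary", p0 = 1.2, or = 1))),
    "prevalences")
})

test_that("inject_missingness hits only its targets and is identity with none", {
  spec <- small_spec(n_cases = 30, n_controls = 30, seed = 9,
    snps = data.frame(snp_id = sprintf("rs%02d", 1:20),
      control_raf = rep(0.3, 20), true_or = 1))
  g <- simulate_genotypes(spec)
  expect_identical(unclass(inject_missingness(g)), unclass(g))
  g2 <- inject_missingness(g, sample_targets = c(S0003 = 0.85))
  expect_lt(call_rates(g2)$sample[["S0003"]], 0.85)
  untouched <- setdiff(rownames(g), "S0003")
  expect_identical(unclass(g2)[untouched, ], unclass(g)[untouched, ])
  qc <- apply_qc(g2, sample_call_rate = 0.9)
  expect_identical(qc$report$excluded_samples$sample_id, "S0003")
  expect_error(inject_missingness(g, sample_targets = c(nope = 0.5)), "unknown sample")
  expect_error(inject_missingness(g, snp_targets = c(nope = 0.5)), "unknown SNP")
})

test_that("force_monomorphic triggers the MAF = 0 exclusion", {
  spec <- small_spec(n_cases = 40, n_controls = 40, seed = 10)
  g <- force_monomorphic(simulate_genotypes(spec), "rsB")
  expect_true(all(unclass(g)[, "rsB"] == 0, na.rm = TRUE))
  qc <- apply_qc(g)
  expect_equal(qc$report$excluded_snps$snp_id, "rsB")
  expect_equal(qc$report$excluded_snps$reason, "monomorphic")
})
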
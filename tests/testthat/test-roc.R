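test_that("AUC follows the Mann-Whitney pair rule", {
  expect_equal(auc_mann_whitney(c(5, 6, 1, 2), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(auc_mann_whitney(c(3, 1, 2, 0),
    c("case", "case", "control", "control"))$auc, 0.75)
  expect_equal(auc_mann_whitney(rep(2, 6), rep(c(1, 0), 3))$auc, 0.5)
  expect_error(auc_mann_whitney(1:3, c(1, 1, 1)), "at least one")
  expect_error(auc_mann_whitney(1:3, c("case", "ctrl", "case")), "labels")
})

test_that("AUC equals the pairwise oracle across many small datasets", {
  set.seed(81)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    n1 <- sample(seq_len(n - 1), 1)
    lab <- sample(rep(c("case", "control"), c(n1, n - n1)))
    s <- sample(0:3, n, replace = TRUE)  # integer scores force ties
    expect_equal(auc_mann_whitney(s, lab)$auc, oracle_auc(s, lab), tolerance = 1e-12)
  }
  # and exhaustively over every dosage-valued score vector at n = 5
  grid <- expand.grid(rep(list(0:2), 5))
  lab <- c("case", "case", "control", "control", "control")
  for (r in seq_len(nrow(grid))) {
    s <- as.numeric(grid[r, ])
    expect_equal(auc_mann_whitney(s, lab)$auc, oracle_auc(s, lab), tolerance = 1e-12)
  }
})

test_that("AUC is transform-invariant and complements under negation", {
  set.seed(82)
  s <- rnorm(60); lab <- rep(c("case", "control"), 30)
  a <- auc_mann_whitney(s, lab)$auc
  expect_identical(auc_mann_whitney(exp(s), lab)$auc, a)
  expect_identical(auc_mann_whitney(rank(s), lab)$auc, a)
  expect_identical(auc_mann_whitney(-s, lab)$auc + a, 1)
})

test_that("ROC points run monotonically from (0,0) to (1,1) with trapezoid = AUC", {
  set.seed(83)
  s <- c(rnorm(40, 1), rnorm(60)); lab <- rep(c("case", "control"), c(40, 60))
  roc <- roc_curve(s, lab)
  pts <- roc$points
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  trap <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(trap, roc$auc, tolerance = 1e-12)
})

test_that("AUC and DeLong variance agree with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(84)
  s <- c(rnorm(50, 0.8), rnorm(70)); lab <- rep(c(1, 0), c(50, 70))
  mine <- auc_mann_whitney(s, lab)
  ref <- pROC::roc(lab, s, quiet = TRUE, direction = "<")
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
  expect_equal(sqrt(mine$var_delong), sqrt(pROC::var(ref)), tolerance = 1e-10)

  s2 <- 0.5 * s + rnorm(120)
  cmp <- delong_compare(s, s2, lab)
  ref2 <- pROC::roc.test(pROC::roc(lab, s, quiet = TRUE, direction = "<"),
    pROC::roc(lab, s2, quiet = TRUE, direction = "<"), method = "delong")
  expect_equal(cmp$p, ref2$p.value, tolerance = 1e-9)
})

test_that("paired DeLong comparison: degenerate, null-calibration and errors", {
  s <- rnorm(40); lab <- rep(c(1, 0), 20)
  same <- delong_compare(s, s, lab)
  expect_equal(same$delta_auc, 0)
  expect_equal(same$p, 1)
  expect_error(delong_compare(s, s[-1], lab), "equal length")

  set.seed(85)
  pvals <- replicate(400, {
    lab <- rep(c(1, 0), c(30, 30))
    delong_compare(rnorm(60), rnorm(60), lab)$p
  })
  ks <- stats::ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("DeLong SE matches a paired bootstrap on fixed data", {
  set.seed(86)
  n1 <- 40; n0 <- 50
  lab <- rep(c("case", "control"), c(n1, n0))
  sa <- c(rnorm(n1, 0.9), rnorm(n0))
  sb <- 0.6 * sa + rnorm(n1 + n0, sd = 0.8)
  cmp <- delong_compare(sa, sb, lab)
  boot <- replicate(4000, {
    i1 <- sample(n1, replace = TRUE); i0 <- n1 + sample(n0, replace = TRUE)
    rank_auc(sa[i1], sa[i0]) - rank_auc(sb[i1], sb[i0])
  })
  expect_equal(cmp$se, stats::sd(boot), tolerance = 0.15)
})

test_that("combining PSA with a risk score behaves at the boundaries", {
  set.seed(87)
  n <- 400
  lab <- rep(c("case", "control"), each = n / 2)
  psa <- exp(rnorm(n, ifelse(lab == "case", 3, 1.6), 1))
  grs <- rnorm(n, ifelse(lab == "case", 0.4, 0), 1)

  expect_message(flat <- combine_psa_grs(psa, rep(1, n), lab), "constant component")
  auc_psa <- auc_mann_whitney(log(psa + 1), lab)$auc
  expect_equal(auc_mann_whitney(flat$combined, flat$labels)$auc, auc_psa,
    tolerance = 1e-9)

  both <- combine_psa_grs(psa, grs, lab)
  auc_comb <- auc_mann_whitney(both$combined, both$labels)$auc
  auc_grs <- auc_mann_whitney(grs, lab)$auc
  expect_gte(auc_comb, max(auc_psa, auc_grs) - 0.01)

  perm <- combine_psa_grs(psa, grs, sample(lab))
  expect_lt(abs(auc_mann_whitney(perm$combined, perm$labels)$auc - 0.5), 0.08)
  expect_error(combine_psa_grs(rep(1, n), rep(1, n), lab), "both components")
})
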
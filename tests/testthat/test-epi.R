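test_that("Yates chi-square matches the hand formula and the reference test", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_yates(even)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tab <- matrix(c(30, 10, 10, 30), 2)
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  by_hand <- sum((abs(tab - E) - 0.5)^2 / E)
  res2 <- chi_square_yates(tab)
  expect_equal(res2$statistic, by_hand, tolerance = 1e-12)
  ref <- stats::chisq.test(tab, correct = TRUE)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p, ref$p.value, tolerance = 1e-12)

  expect_error(chi_square_yates(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("Yates statistic never exceeds the uncorrected Pearson statistic", {
  pearson <- function(tab) {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  for (a in seq(0, 30, 3)) for (b in seq(1, 28, 3)) for (c in seq(1, 28, 3)) {
    tab <- matrix(c(a, b, c, 31 - a %% 7), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_lte(chi_square_yates(tab)$statistic, pearson(tab) + 1e-12)
  }
})

test_that("Welch t handles unequal variances and reduces to pooled at equality", {
  x <- c(1, 2, 3); res <- welch_t(x, x)
  expect_equal(res$t, 0); expect_equal(res$p, 1)

  set.seed(91)
  x <- rnorm(500, 0, 1); y <- rnorm(500, 0.1, 1)
  w <- welch_t(x, y)
  pooled <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(w$p, pooled$p.value, tolerance = 0.02)

  expect_error(welch_t(1, c(1, 2)), "at least 2")
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("Welch rejection rate tracks theoretical power under a location shift", {
  set.seed(92)
  rej <- mean(replicate(300, welch_t(rnorm(100, 1), rnorm(100))$p < 0.05))
  theo <- stats::power.t.test(n = 100, delta = 1, sd = 1, sig.level = 0.05)$power
  expect_lt(abs(rej - theo), 0.05)
})

test_that("reference level is the condition most equally represented", {
  v <- c(rep("A", 30), rep("B", 60), rep("C", 10),
         rep("A", 30), rep("B", 20), rep("C", 50))
  s <- rep(c("case", "control"), each = 100)
  expect_equal(choose_reference_level(v, s), "A")

  expect_message(ref <- choose_reference_level(rep(c("b", "a"), 10),
    rep(c("case", "control"), each = 10)), "tie")
  expect_equal(ref, "a")

  # brute-force argmin oracle on random tables
  set.seed(93)
  for (i in 1:50) {
    v <- sample(letters[1:4], 120, replace = TRUE)
    s <- sample(rep(c("case", "control"), 60))
    share <- function(grp) prop.table(table(factor(v[s == grp], levels = letters[1:4])))
    d <- abs(share("case") - share("control"))
    best <- suppressMessages(choose_reference_level(v, s))
    expect_equal(d[[best]], min(d))
  }
})

test_that("PSA bins use the study thresholds with <4 as reference", {
  b <- bin_psa(c(1, 4, 9.9, 15, 50, 120))
  expect_equal(as.character(b), c("<4", "4-10", "4-10", "10-20", "20-100", ">=100"))
  expect_equal(levels(b)[1], "<4")
  expect_error(bin_psa(1, edges = c(10, 4)), "increasing")
})

test_that("adjusted model equals the crude logistic fit with no confounders", {
  sim <- simulate_cohort(simulation_spec(n_cases = 400, n_controls = 300, seed = 94))
  ph <- sim$phenotypes
  res <- adjusted_variable_model("diabetes", ph, confounders = character(0))
  x <- as.integer(ph$diabetes == "yes"); y <- as.integer(ph$status == "case")
  crude_fit <- logistic_fit(cbind(1, x = x), y)
  expect_equal(res$or, unname(crude_fit$or["x"]), tolerance = 1e-10)
  expect_equal(res$reference, "no")
})

test_that("adjustment removes confounding that biases the crude estimate", {
  set.seed(95)
  n <- 10000
  age <- rnorm(n, 65, 9)
  # exposure more common in the old; age itself raises risk
  x <- rbinom(n, 1, plogis(-3 + 0.05 * age))
  y <- rbinom(n, 1, plogis(-4 + log(1.83) * x + 0.05 * age))
  ph <- data.frame(sample_id = sprintf("i%05d", 1:n),
    status = ifelse(y == 1, "case", "control"),
    diabetes = ifelse(x == 1, "yes", "no"), age = age,
    stringsAsFactors = FALSE)
  adj <- adjusted_variable_model("diabetes", ph, confounders = "age")
  fit <- attr(adj, "fit")
  expect_lt(abs(log(adj$or) - log(1.83)), 2 * fit$se[".vyes"])
  crude <- adjusted_variable_model("diabetes", ph, confounders = character(0))
  expect_gt(crude$or, adj$or)  # positive confounding inflates the crude OR
})

test_that("a status-independent variable shows an adjusted OR near 1", {
  sim <- simulate_cohort(simulation_spec(n_cases = 2500, n_controls = 2500, seed = 96))
  res <- adjusted_variable_model("std_history", sim$phenotypes)  # simulated null
  fit <- attr(res, "fit")
  expect_lt(abs(log(res$or)), 3 * fit$se[grep("^\\.v", names(fit$se))])
})

test_that("multi-level and binned variables report per-level ORs vs the reference", {
  sim <- simulate_cohort(simulation_spec(seed = 97))
  res <- adjusted_variable_model("balding", sim$phenotypes)
  expect_equal(nrow(res), 3L)  # 4 levels minus reference
  expect_false(unique(res$reference) %in% res$level)

  psa <- adjusted_variable_model("psa_bin", sim$phenotypes)
  expect_equal(unique(psa$reference), "<4")
  # simulated PSA rises steeply with case status: top bins carry large ORs
  expect_gt(psa$or[psa$level == ">=100"], psa$or[psa$level == "4-10"])
})

test_that("case-only outcome models estimate RRs against the stated reference", {
  set.seed(98)
  n <- 5000
  x <- rbinom(n, 1, 0.4)
  eta7 <- -0.3 + 0 * x; eta_hi <- -0.6 + log(2) * x
  den <- 1 + exp(eta7) + exp(eta_hi)
  u <- runif(n)
  band <- ifelse(u < exp(eta_hi) / den, ">7",
    ifelse(u < (exp(eta_hi) + exp(eta7)) / den, "=7", "<7"))
  gl <- ifelse(band == "<7", 6L, ifelse(band == "=7", 7L, 9L))
  cases <- data.frame(sample_id = sprintf("c%04d", 1:n), status = "case",
    gleason = gl, grade = NA_character_,
    aspirin = ifelse(x == 1, "yes", "no"), stringsAsFactors = FALSE)
  fit <- caseonly_outcome_model("aspirin", cases, outcome = "gleason_band")
  expect_equal(fit$reference, "<7")
  expect_lt(abs(fit$coef[">7", ".vyes"] - log(2)), 2 * fit$se[">7", ".vyes"])
  expect_lt(abs(fit$coef["=7", ".vyes"]), 3 * fit$se["=7", ".vyes"])

  # two surviving categories reduce to binary logistic
  two <- cases[cases$gleason != 7, ]
  fit2 <- caseonly_outcome_model("aspirin", two, outcome = "gleason_band")
  yb <- as.integer(two$gleason > 7)
  bin <- logistic_fit(cbind(1, x = as.integer(two$aspirin == "yes")), yb)
  expect_equal(unname(fit2$coef[">7", ]), unname(bin$coef), tolerance = 1e-6)

  expect_error(caseonly_outcome_model("aspirin",
    data.frame(status = c("case", "control"))), "case-only")
})
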
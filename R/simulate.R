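# Synthetic cohort generator. Control genotypes follow Hardy-Weinberg
# proportions at the control risk-allele frequency q; case genotypes come from
# the exponentially tilted distribution P_case(g) proportional to HWE(g)*OR^g,
# which is exactly the sampling model implied by a per-allele logistic effect,
# so the population allelic odds ratio equals the simulated OR in expectation.
# SNPs are independent (no linkage disequilibrium).

#' Default per-SNP simulation table
#'
#' The 46 SNPs of the shipped synthetic panel: the six markers followed
#' through both genotyping stages keep their observed control risk-allele
#' frequencies and stage-1 allelic odds ratios as the generative truth; the
#' other ten named panel SNPs and the thirty synthetic ones are null
#' (OR = 1) with control frequencies evenly spaced over 0.05-0.45.
#'
#' @return Data frame with columns `snp_id`, `control_raf`, `true_or`.
#' @export
default_snp_effects <- function() {
  effect <- data.frame(
    snp_id = c("rs6983561", "rs1859962", "rs13254738", "rs10090154",
      "rs4242382", "rs1465618"),
    control_raf = c(0.372, 0.197, 0.416, 0.226, 0.325, 0.069),
    true_or = c(1.54, 1.50, 0.70, 0.55, 0.85, 1.80),
    stringsAsFactors = FALSE
  )
  null_ids <- c("rs7000448", "rs10993994", "rs8102476", "rs12500426",
    "rs1016343", "rs620861", "rs12621278", "rs6983267", "rs7210100",
    "Bd11934905", sprintf("syn%03d", seq_len(30)))
  null <- data.frame(
    snp_id = null_ids,
    control_raf = seq(0.05, 0.45, length.out = length(null_ids)),
    true_or = 1,
    stringsAsFactors = FALSE
  )
  rbind(effect, null)
}

#' Default covariate simulation specs
#'
#' Binary questionnaire covariates with a control prevalence `p0` and a
#' conditional odds ratio on case status; categorical covariates carry control
#' level probabilities and per-level odds ratios against the first level.
#' Effect sizes mirror the adjusted epidemiological associations the pipeline
#' is designed to estimate (family history of cancer 2.60, diabetes 1.83,
#' current sexual activity 0.48, erectile dysfunction 1.53, aspirin 1.68,
#' frontal+vertex balding 1.60); prevalences are chosen as plausible for an
#' older urology-clinic population.
#'
#' @return A named list of covariate specs.
#' @export
default_covariates <- function() {
  list(
    family_history_pca = list(type = "binary", p0 = 0.04, or = 1.50),
    family_history_cancer = list(type = "binary", p0 = 0.05, or = 2.60),
    diabetes = list(type = "binary", p0 = 0.10, or = 1.83),
    sexual_activity = list(type = "binary", p0 = 0.60, or = 0.48),
    ed = list(type = "binary", p0 = 0.25, or = 1.53),
    aspirin = list(type = "binary", p0 = 0.25, or = 1.68),
    acne = list(type = "binary", p0 = 0.05, or = 1.00),
    male_breasts = list(type = "binary", p0 = 0.05, or = 1.00),
    std_history = list(type = "binary", p0 = 0.15, or = 1.00),
    balding = list(type = "categorical",
      levels = c("none", "frontal", "vertex", "frontal_vertex"),
      p0 = c(0.40, 0.22, 0.20, 0.18), or = c(1, 1.1, 1.0, 1.60)),
    population_group = list(type = "categorical",
      levels = c("Tsonga", "Pedi", "Venda", "Tswana", "other"),
      p0 = c(0.30, 0.30, 0.15, 0.15, 0.10), or = c(1, 1.0, 1.81, 1.0, 1.0)),
    occupation = list(type = "categorical",
      levels = c("manual", "office", "health_education", "unemployed"),
      p0 = c(0.45, 0.20, 0.10, 0.25), or = c(1, 1.0, 1.5, 1.0))
  )
}

#' Build a cohort simulation specification
#'
#' Defaults emulate the full pilot cohort: 522 cases and 315 controls
#' (roughly 1.6:1), the 46-SNP panel of [default_snp_effects()], log-normal
#' PSA separated by status in the regime where PSA alone discriminates with
#' AUC near 0.9, the covariate effects of [default_covariates()], and 2%
#' uniform genotype missingness.
#'
#' @param n_cases,n_controls Group sizes.
#' @param snps Data frame with `snp_id`, `control_raf` in (0,1), `true_or` > 0.
#' @param psa List with `meanlog_control`, `sdlog_control`, `meanlog_case`,
#'   `sdlog_case` (log-normal PSA in ug/L per status).
#' @param covariates Covariate spec list, see [default_covariates()].
#' @param age List with `mean_control`, `mean_case`, `sd`.
#' @param gleason_probs Case-only distribution over Gleason scores 4..10,
#'   biased towards aggressive disease.
#' @param grade_probs Case-only probabilities for well/moderate/poor.
#' @param missing_rate Uniform genotype missingness in `[0, 1)`.
#' @param seed Integer seed; a fixed seed makes every simulated table
#'   byte-identical across runs.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_cases = 522, n_controls = 315,
                            snps = default_snp_effects(),
                            psa = list(meanlog_control = log(5), sdlog_control = 1.0,
                                       meanlog_case = log(40), sdlog_case = 1.2),
                            covariates = default_covariates(),
                            age = list(mean_control = 65, mean_case = 66, sd = 9),
                            gleason_probs = c(`4` = 0.03, `5` = 0.07, `6` = 0.25,
                                              `7` = 0.25, `8` = 0.20, `9` = 0.12, `10` = 0.08),
                            grade_probs = c(well = 0.18, moderate = 0.45, poor = 0.37),
                            missing_rate = 0.02, seed = 4973L) {
  stopifnot(n_cases >= 1, n_controls >= 1)
  stopifnot(all(c("snp_id", "control_raf", "true_or") %in% names(snps)))
  if (any(snps$control_raf <= 0 | snps$control_raf >= 1)) stop("control_raf must lie in (0, 1)")
  if (any(snps$true_or <= 0)) stop("true_or must be > 0")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  if (abs(sum(gleason_probs) - 1) > 1e-8 || abs(sum(grade_probs) - 1) > 1e-8) {
    stop("gleason_probs and grade_probs must each sum to 1")
  }
  for (nm in names(covariates)) {
    cv <- covariates[[nm]]
    if (any(cv$p0 <= 0 | cv$p0 >= 1)) stop("covariate '", nm, "': prevalences must lie in (0, 1)")
    if (any(cv$or <= 0)) stop("covariate '", nm, "': odds ratios must be > 0")
  }
  structure(list(
    n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
    snps = snps, psa = psa, covariates = covariates, age = age,
    gleason_probs = gleason_probs, grade_probs = grade_probs,
    missing_rate = missing_rate, seed = as.integer(seed)
  ), class = "simulation_spec")
}

# HWE genotype probabilities at risk-allele frequency q, optionally tilted by
# OR^g for the case sampling distribution.
tilted_genotype_probs <- function(q, or = 1) {
  p <- c((1 - q)^2, 2 * q * (1 - q), q^2) * or^(0:2)
  p / sum(p)
}

#' Simulate the genotype matrix of a case-control cohort
#'
#' Controls are drawn from Hardy-Weinberg proportions at each SNP's control
#' risk-allele frequency; cases from the OR-tilted distribution
#' `P(g) ~ HWE(g) * OR^g`. Uniform missingness is applied at
#' `spec$missing_rate`. Sample order is cases first, then controls; the
#' case/control assignment is attached as the `"status"` attribute.
#'
#' @param spec A [simulation_spec()].
#' @return A [genotype_matrix()] with a `"status"` attribute (named character
#'   vector, `"case"`/`"control"`).
#' @export
simulate_genotypes <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  n1 <- spec$n_cases; n0 <- spec$n_controls
  n <- n1 + n0
  ids <- sprintf("S%04d", seq_len(n))
  status <- c(rep("case", n1), rep("control", n0))
  names(status) <- ids
  m <- nrow(spec$snps)
  mat <- matrix(NA_integer_, n, m)
  for (j in seq_len(m)) {
    q <- spec$snps$control_raf[j]; or <- spec$snps$true_or[j]
    mat[seq_len(n1), j] <- sample(0:2, n1, replace = TRUE, prob = tilted_genotype_probs(q, or))
    mat[n1 + seq_len(n0), j] <- sample(0:2, n0, replace = TRUE, prob = tilted_genotype_probs(q, 1))
  }
  if (spec$missing_rate > 0) {
    mat[matrix(stats::runif(n * m) < spec$missing_rate, n, m)] <- NA_integer_
  }
  g <- genotype_matrix(mat, sample_ids = ids, snp_ids = spec$snps$snp_id)
  attr(g, "status") <- status
  g
}

draw_binary <- function(n, p) ifelse(stats::runif(n) < p, "yes", "no")

# odds p0/(1-p0) * or -> case prevalence
case_prev <- function(p0, or) {
  odds <- p0 / (1 - p0) * or
  odds / (1 + odds)
}

#' Simulate phenotypes for a simulated cohort
#'
#' PSA is log-normal per status; each binary covariate has control prevalence
#' `p0` and case odds `p0/(1-p0) * OR`; categorical covariates tilt the control
#' level probabilities by per-level ORs on the odds scale. Gleason score and
#' tumor grade are assigned to cases only from the spec's categorical
#' distributions; age is normal per status, truncated to 40-90 years.
#'
#' @param spec A [simulation_spec()].
#' @param genotypes Output of [simulate_genotypes()] for the same spec (its
#'   `"status"` attribute fixes each sample's group).
#' @return A validated phenotype data frame (see [read_phenotypes()]).
#' @export
simulate_phenotypes <- function(spec, genotypes) {
  stopifnot(inherits(spec, "simulation_spec"))
  status <- attr(genotypes, "status")
  if (is.null(status)) stop("genotypes carry no status attribute; simulate them first")
  set.seed(spec$seed + 2L)
  n <- length(status)
  case <- status == "case"
  psa <- ifelse(case,
    stats::rlnorm(n, spec$psa$meanlog_case, spec$psa$sdlog_case),
    stats::rlnorm(n, spec$psa$meanlog_control, spec$psa$sdlog_control))
  age <- stats::rnorm(n, ifelse(case, spec$age$mean_case, spec$age$mean_control), spec$age$sd)
  age <- pmin(pmax(age, 40), 90)
  ph <- data.frame(sample_id = names(status), status = unname(status),
    psa = psa, age = age, stringsAsFactors = FALSE)
  for (nm in names(spec$covariates)) {
    cv <- spec$covariates[[nm]]
    if (cv$type == "binary") {
      p <- ifelse(case, case_prev(cv$p0, cv$or), cv$p0)
      ph[[nm]] <- draw_binary(n, p)
    } else {
      w0 <- cv$p0
      w1 <- cv$p0 * cv$or; w1 <- w1 / sum(w1)
      v <- character(n)
      v[!case] <- sample(cv$levels, sum(!case), replace = TRUE, prob = w0)
      v[case] <- sample(cv$levels, sum(case), replace = TRUE, prob = w1)
      ph[[nm]] <- v
    }
  }
  ph$gleason <- NA_integer_
  ph$grade <- NA_character_
  n1 <- sum(case)
  ph$gleason[case] <- as.integer(sample(names(spec$gleason_probs), n1,
    replace = TRUE, prob = spec$gleason_probs))
  ph$grade[case] <- sample(names(spec$grade_probs), n1,
    replace = TRUE, prob = spec$grade_probs)
  validate_phenotypes(ph)
}

#' Simulate a full cohort (genotypes + phenotypes + truth values)
#'
#' @param spec A [simulation_spec()].
#' @return A list with `genotypes`, `phenotypes`, `status`, and `truth` (the
#'   per-SNP and per-covariate generative parameters).
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  g <- simulate_genotypes(spec)
  ph <- simulate_phenotypes(spec, g)
  list(genotypes = g, phenotypes = ph, status = attr(g, "status"),
    truth = list(snps = spec$snps, covariates = spec$covariates, psa = spec$psa))
}

#' Force call rates below a target for chosen samples/SNPs
#'
#' Used to construct QC test fixtures: for each targeted margin the smallest
#' number of cells is blanked (deterministically, from the first cell) so the
#' resulting call rate falls strictly below the requested value. Untouched
#' cells are preserved.
#'
#' @param genotypes A [genotype_matrix()].
#' @param sample_targets Named numeric vector `sample_id -> target rate`.
#' @param snp_targets Named numeric vector `snp_id -> target rate`.
#' @return The modified [genotype_matrix()].
#' @export
inject_missingness <- function(genotypes, sample_targets = NULL, snp_targets = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  st <- attr(genotypes, "status")
  g <- unclass(genotypes)
  blank_margin <- function(vec_len, current_missing, target) {
    # need (non-missing)/len < target
    need_missing <- floor(vec_len * (1 - target)) + 1L
    max(need_missing, current_missing)
  }
  if (!is.null(sample_targets)) {
    unknown <- setdiff(names(sample_targets), rownames(g))
    if (length(unknown)) stop("unknown sample ids: ", paste(unknown, collapse = ", "))
    for (id in names(sample_targets)) {
      k <- blank_margin(ncol(g), sum(is.na(g[id, ])), sample_targets[[id]])
      g[id, seq_len(k)] <- NA_integer_
    }
  }
  if (!is.null(snp_targets)) {
    unknown <- setdiff(names(snp_targets), colnames(g))
    if (length(unknown)) stop("unknown SNP ids: ", paste(unknown, collapse = ", "))
    for (id in names(snp_targets)) {
      k <- blank_margin(nrow(g), sum(is.na(g[, id])), snp_targets[[id]])
      g[seq_len(k), id] <- NA_integer_
    }
  }
  out <- genotype_matrix(g)
  attr(out, "status") <- st
  out
}

#' Force SNPs monomorphic (all non-missing dosages zero)
#'
#' Constructs the MAF = 0 failure mode the QC stage must detect.
#'
#' @param genotypes A [genotype_matrix()].
#' @param snp_ids SNPs to flatten.
#' @return The modified [genotype_matrix()].
#' @export
force_monomorphic <- function(genotypes, snp_ids) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  unknown <- setdiff(snp_ids, colnames(genotypes))
  if (length(unknown)) stop("unknown SNP ids: ", paste(unknown, collapse = ", "))
  st <- attr(genotypes, "status")
  g <- unclass(genotypes)
  for (id in snp_ids) g[!is.na(g[, id]), id] <- 0L
  out <- genotype_matrix(g)
  attr(out, "status") <- st
  out
}
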
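# Per-SNP allelic association: 2x2 allele tables, Fisher's exact test, the
# allelic cross-product odds ratio with Woolf confidence limits, and the
# dosage-logistic per-allele model.

#' Build the 2x2 allele-count table for one SNP
#'
#' Rows are risk / non-risk allele counts, columns case / control. Each
#' non-missing sample contributes two alleles; the risk-allele count in a
#' group is the sum of dosages, the non-risk count the complement to twice
#' the group size.
#'
#' @param dosage Integer vector of risk-allele dosages (`NA` = missing).
#' @param status Character/factor vector, `"case"`/`"control"`, aligned with
#'   `dosage`.
#' @return A 2x2 integer matrix with dimnames
#'   `list(c("risk","nonrisk"), c("case","control"))`.
#' @examples
#' allele_table(c(2, 1, 0, 1), c("case", "case", "control", "control"))
#' @export
allele_table <- function(dosage, status) {
  if (length(dosage) != length(status)) stop("dosage and status lengths differ")
  status <- as.character(status)
  ok <- !is.na(dosage)
  for (grp in c("case", "control")) {
    if (!any(ok & status == grp)) stop("no non-missing dosages in group '", grp, "'")
  }
  cnt <- function(grp) {
    d <- dosage[ok & status == grp]
    c(risk = sum(d), nonrisk = 2L * length(d) - sum(d))
  }
  tab <- cbind(case = cnt("case"), control = cnt("control"))
  storage.mode(tab) <- "integer"
  tab
}

#' Reconstruct an allele count from a printed frequency
#'
#' Inverts the rounding used when a table prints a risk-allele frequency to a
#' few decimals: `round(2 * n * maf)` with ties rounded away from zero.
#'
#' @param maf Frequency in `[0, 1]`.
#' @param n_samples Number of diploid samples in the group.
#' @return Integer allele count.
#' @export
reconstruct_counts_from_maf <- function(maf, n_samples) {
  stopifnot(maf >= 0, maf <= 1, n_samples >= 0)
  as.integer(floor(2 * n_samples * maf + 0.5))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditions on both margins; the two-sided p-value sums the hypergeometric
#' probabilities of every table (with the observed margins) whose point
#' probability does not exceed the observed one, the comparison made with a
#' relative tolerance of 1e-7 to absorb floating-point noise. A table with a
#' zero margin carries no information and returns p = 1 with a message.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table))) stop("counts must be nonnegative integers")
  m <- sum(table[1, ])   # row-1 margin (risk alleles)
  n <- sum(table[2, ])
  k <- sum(table[, 1])   # column-1 margin (case alleles)
  if (m == 0 || n == 0 || k == 0 || sum(table[, 2]) == 0) {
    message("Fisher test on a table with a zero margin: p = 1")
    return(1.0)
  }
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  d_obs <- stats::dhyper(table[1, 1], m, n, k)
  p <- sum(dens[dens <= d_obs * (1 + 1e-7)])
  min(p, 1.0)
}

#' Allelic odds ratio with Woolf confidence interval
#'
#' Cross-product ratio of the 2x2 allele table with the Woolf (log) interval
#' `exp(log OR +/- z * sqrt(sum 1/cell))`. A single zero cell triggers the
#' Haldane-Anscombe correction (+0.5 to every cell), flagged in the result;
#' a zero row or column margin leaves the odds ratio undefined and errors.
#'
#' @param table 2x2 count matrix, rows risk/nonrisk, columns case/control.
#' @param conf_level Confidence level (default 0.95).
#' @return List with `or`, `ci_low`, `ci_high`, `log_or`, `se_log_or`, and
#'   `haldane` (logical, correction applied).
#' @export
allelic_odds_ratio <- function(table, conf_level = 0.95) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("odds ratio undefined: table has a zero margin")
  }
  haldane <- any(table == 0)
  tt <- table + if (haldane) 0.5 else 0
  log_or <- log(tt[1, 1]) + log(tt[2, 2]) - log(tt[1, 2]) - log(tt[2, 1])
  se <- sqrt(sum(1 / tt))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or), ci_low = exp(log_or - z * se), ci_high = exp(log_or + z * se),
    log_or = log_or, se_log_or = se, haldane = haldane)
}

#' Per-SNP allelic association over a QC'd cohort
#'
#' For every panel SNP present in the genotype matrix: risk-allele
#' frequencies by group, the 2x2 allele table, Fisher's exact p, the allelic
#' cross-product OR with Woolf CI (the primary estimate), and the per-allele
#' dosage-logistic OR (secondary, reported alongside; with optional
#' covariate adjustment). Samples missing a SNP's call are dropped for that
#' SNP only. SNPs absent from the panel, or monomorphic in the analysed
#' samples, are skipped with a warning.
#'
#' @param genotypes A QC-filtered [genotype_matrix()].
#' @param phenotypes Phenotype data frame with `sample_id` and `status` (used
#'   for status and any covariates); alternatively `NULL` if the matrix
#'   carries a `"status"` attribute.
#' @param panel SNP panel data frame.
#' @param covariates Optional character vector of phenotype columns to adjust
#'   the logistic model for.
#' @return A data frame of class `"assoc_table"`, one row per analysed SNP.
#' @export
per_allele_association <- function(genotypes, phenotypes = NULL, panel,
                                   covariates = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (is.null(phenotypes)) {
    status <- attr(genotypes, "status")
    if (is.null(status)) stop("phenotypes (or a status attribute) required")
    status <- status[rownames(genotypes)]
    covdat <- NULL
  } else {
    idx <- match(rownames(genotypes), phenotypes$sample_id)
    if (anyNA(idx)) stop("phenotype table is missing samples: ",
      paste(utils::head(rownames(genotypes)[is.na(idx)], 5), collapse = ", "))
    status <- phenotypes$status[idx]
    covdat <- if (!is.null(covariates)) phenotypes[idx, covariates, drop = FALSE] else NULL
  }
  rows <- list()
  for (snp in colnames(genotypes)) {
    if (!snp %in% panel$snp_id) {
      warning("SNP ", snp, " absent from panel; skipped")
      next
    }
    d <- unclass(genotypes)[, snp]
    ok <- !is.na(d)
    if (length(unique(d[ok])) < 2L) {
      warning("SNP ", snp, " is monomorphic in the analysed samples; skipped")
      next
    }
    tab <- allele_table(d, status)
    orr <- allelic_odds_ratio(tab)
    # dosage logistic (secondary estimate)
    y <- as.integer(status[ok] == "case")
    X <- cbind(`(Intercept)` = 1, dosage = d[ok])
    if (!is.null(covdat)) {
      cc <- stats::model.matrix(~ ., data = covdat[ok, , drop = FALSE])[, -1, drop = FALSE]
      X <- cbind(X, cc)
    }
    lf <- tryCatch(logistic_fit(X, y), error = function(e) NULL)
    n1 <- sum(ok & status == "case"); n0 <- sum(ok & status == "control")
    rows[[snp]] <- data.frame(
      snp_id = snp, n_cases = n1, n_controls = n0,
      maf_cases = tab["risk", "case"] / (2 * n1),
      maf_controls = tab["risk", "control"] / (2 * n0),
      risk_cases = tab["risk", "case"], nonrisk_cases = tab["nonrisk", "case"],
      risk_controls = tab["risk", "control"], nonrisk_controls = tab["nonrisk", "control"],
      or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
      or_logistic = if (is.null(lf)) NA_real_ else unname(lf$or["dosage"]),
      or_logistic_low = if (is.null(lf)) NA_real_ else unname(lf$ci_low["dosage"]),
      or_logistic_high = if (is.null(lf)) NA_real_ else unname(lf$ci_high["dosage"]),
      p_logistic = if (is.null(lf)) NA_real_ else unname(lf$p["dosage"]),
      p_fisher = fisher_exact_two_sided(tab),
      risk_allele_is_minor = tab["risk", "control"] / (2 * n0) <= 0.5,
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) stop("no analysable SNPs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("assoc_table", "data.frame")
  out
}

#' @export
print.assoc_table <- function(x, ...) {
  cat(sprintf("Allelic association: %d SNPs, %d with Fisher p <= 0.05\n",
    nrow(x), sum(x$p_fisher <= 0.05)))
  df <- data.frame(snp_id = x$snp_id,
    maf_cases = round(x$maf_cases, 3), maf_controls = round(x$maf_controls, 3),
    or = sprintf("%.2f (%.2f-%.2f)", x$or, x$ci_low, x$ci_high),
    p_fisher = signif(x$p_fisher, 3),
    q_value = if (is.null(x$q_value)) NA else signif(x$q_value, 3))
  print(df[order(x$p_fisher), ], row.names = FALSE, ...)
  invisible(x)
}
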
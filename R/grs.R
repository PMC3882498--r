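# Three genetic risk score models over a SNP subset.
#   Model 1 (cGRS): count of risk alleles.
#   Model 2 (wGRS): sum of dosages weighted by ln(study OR).
#   Model 3: genotypic risk OR^g relative to the average population risk
#            sum_g HWE(g) OR^g, combined multiplicatively over SNPs; the
#            population genotype frequencies are Hardy-Weinberg at the
#            control risk-allele frequency.
# On complete data ln(model-3 score) = wGRS - a per-subset constant, so
# models 2 and 3 rank samples identically and share the same ROC curve.
# Missing genotypes: a sample's score is computed over its non-missing SNPs
# without rescaling (the count of contributing SNPs is recorded); mean-dosage
# imputation is available as a sensitivity mode.

#' Count genetic risk score (model 1)
#'
#' @param dosages Numeric matrix (samples x subset SNPs) of risk-allele
#'   dosages; `NA` allowed.
#' @return Integer scores, `NA` (with a warning) where every SNP is missing.
#' @export
cgrs <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (ncol(dosages) == 0L) stop("empty SNP subset")
  n_used <- rowSums(!is.na(dosages))
  s <- rowSums(dosages, na.rm = TRUE)
  s[n_used == 0L] <- NA
  if (anyNA(s)) warning(sum(is.na(s)), " sample(s) with no non-missing genotype: score NA")
  s
}

#' Weighted genetic risk score (model 2)
#'
#' `wGRS = sum_i dosage_i * ln(OR_i)` over non-missing SNPs.
#'
#' @param dosages Samples x SNPs dosage matrix.
#' @param study_ors Per-SNP odds ratios (> 0), aligned with the columns.
#' @return Numeric scores; `NA` where every SNP is missing.
#' @export
wgrs <- function(dosages, study_ors) {
  dosages <- as.matrix(dosages)
  if (length(study_ors) != ncol(dosages)) stop("one OR per SNP required")
  if (any(study_ors <= 0)) stop("odds ratios must be strictly positive")
  w <- log(study_ors)
  n_used <- rowSums(!is.na(dosages))
  s <- rowSums(sweep(dosages, 2, w, `*`), na.rm = TRUE)
  s[n_used == 0L] <- NA
  s
}

#' Relative population risk score (model 3)
#'
#' Per SNP the genotype risk is `OR^g` and the average population risk is
#' `sum_g HWE(g) OR^g` with Hardy-Weinberg genotype frequencies at the
#' control risk-allele frequency; the per-sample score is the product of
#' `OR^g / mean risk` over non-missing SNPs, so the expected score in the
#' control population is 1 per SNP.
#'
#' @param dosages Samples x SNPs dosage matrix.
#' @param study_ors Per-SNP odds ratios (> 0).
#' @param control_rafs Per-SNP control risk-allele frequencies in `(0, 1)`.
#' @return Positive numeric scores; `NA` where every SNP is missing.
#' @export
relative_population_risk <- function(dosages, study_ors, control_rafs) {
  dosages <- as.matrix(dosages)
  if (length(study_ors) != ncol(dosages) || length(control_rafs) != ncol(dosages)) {
    stop("one OR and one control frequency per SNP required")
  }
  if (any(study_ors <= 0)) stop("odds ratios must be strictly positive")
  if (any(control_rafs <= 0 | control_rafs >= 1)) {
    stop("control risk-allele frequencies must lie strictly inside (0, 1)")
  }
  q <- control_rafs
  mean_risk <- (1 - q)^2 + 2 * q * (1 - q) * study_ors + q^2 * study_ors^2
  # log-scale accumulation for numerical stability over many SNPs
  logr <- sweep(dosages, 2, log(study_ors), `*`)
  logr <- sweep(logr, 2, log(mean_risk), `-`)
  n_used <- rowSums(!is.na(dosages))
  s <- exp(rowSums(logr, na.rm = TRUE))
  s[n_used == 0L] <- NA
  s
}

#' Build a risk score set for a cohort
#'
#' Estimates the study weights from the cohort itself — per-SNP allelic odds
#' ratios and control risk-allele frequencies — and scores every sample under
#' the requested model. Using in-cohort weights is a deliberate, documented
#' circularity: the scores describe this cohort's risk gradient, they are not
#' externally validated predictors.
#'
#' @param genotypes A QC-filtered [genotype_matrix()] (status attached or via
#'   `phenotypes`).
#' @param phenotypes Optional phenotype data frame supplying `status`.
#' @param panel SNP panel (rows for every scored SNP).
#' @param model 1 (count), 2 (log-OR weighted) or 3 (relative population risk).
#' @param snps Character vector naming the SNP subset; every id must be
#'   present in the matrix.
#' @param weights Optional data frame `snp_id`, `study_or`, `control_raf` to
#'   override the in-cohort estimates (e.g. stage-specific estimates).
#' @param impute `"none"` (default: scores over non-missing SNPs) or
#'   `"mean"` (mean-dosage imputation sensitivity mode).
#' @return An object of class `"risk_score_set"`: `scores` (named), `model`,
#'   `snps`, `weights` (the ORs/frequencies used), `n_used`, `status`.
#' @export
build_scores <- function(genotypes, phenotypes = NULL, panel, model,
                         snps = colnames(genotypes), weights = NULL,
                         impute = c("none", "mean")) {
  stopifnot(inherits(genotypes, "genotype_matrix"), model %in% 1:3)
  impute <- match.arg(impute)
  missing_snps <- setdiff(snps, colnames(genotypes))
  if (length(missing_snps)) {
    stop("subset references SNP(s) absent from the (QC-filtered) matrix: ",
      paste(missing_snps, collapse = ", "))
  }
  status <- if (is.null(phenotypes)) attr(genotypes, "status")[rownames(genotypes)] else
    phenotypes$status[match(rownames(genotypes), phenotypes$sample_id)]
  if (is.null(status) || anyNA(status)) stop("case/control status required for every sample")
  d <- unclass(genotypes)[, snps, drop = FALSE]
  if (is.null(weights)) {
    ctrl <- rownames(d)[status == "control"]
    raf <- risk_allele_freq(genotypes, samples = ctrl)[snps]
    ors <- vapply(snps, function(s) {
      allelic_odds_ratio(allele_table(d[, s], status))$or
    }, 0)
    weights <- data.frame(snp_id = snps, study_or = unname(ors),
      control_raf = unname(raf), stringsAsFactors = FALSE)
  } else {
    idx <- match(snps, weights$snp_id)
    if (anyNA(idx)) stop("weights missing for: ", paste(snps[is.na(idx)], collapse = ", "))
    weights <- weights[idx, , drop = FALSE]
  }
  if (impute == "mean") {
    for (j in seq_len(ncol(d))) d[is.na(d[, j]), j] <- mean(d[, j], na.rm = TRUE)
  }
  scores <- switch(model,
    cgrs(d),
    wgrs(d, weights$study_or),
    relative_population_risk(d, weights$study_or, weights$control_raf))
  names(scores) <- rownames(d)
  structure(list(scores = scores, model = model, snps = snps,
    weights = weights, n_used = rowSums(!is.na(d)),
    status = status, impute = impute),
    class = "risk_score_set")
}

#' @export
print.risk_score_set <- function(x, ...) {
  cat(sprintf("Risk score set: model %d over %d SNPs (impute = %s)\n",
    x$model, length(x$snps), x$impute))
  cat(sprintf("  mean score cases %.3f, controls %.3f\n",
    mean(x$scores[x$status == "case"], na.rm = TRUE),
    mean(x$scores[x$status == "control"], na.rm = TRUE)))
  invisible(x)
}

#' Nested SNP subsets from an association table
#'
#' Reproduces the staged subset logic: the full post-QC panel, the SNPs with
#' uncorrected Fisher p at or below `p_threshold`, and the `n_top` smallest-p
#' SNPs among those. Subsets are nested by construction.
#'
#' @param assoc An `"assoc_table"` from [per_allele_association()].
#' @param p_threshold Inclusion threshold for the middle subset (default 0.05).
#' @param n_top Size of the innermost subset (default 3).
#' @return Named list of SNP id vectors: `all`, `significant`, `top`.
#' @export
grs_subsets <- function(assoc, p_threshold = 0.05, n_top = 3) {
  sig <- assoc$snp_id[assoc$p_fisher <= p_threshold]
  ord <- assoc[assoc$snp_id %in% sig, ]
  top <- ord$snp_id[order(ord$p_fisher)][seq_len(min(n_top, nrow(ord)))]
  list(all = assoc$snp_id, significant = sig, top = top)
}
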
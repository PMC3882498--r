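# Quality control: samples first, then SNPs. Threshold comparisons are
# strict (a margin is kept only when its call rate exceeds the threshold),
# matching the "call rate > 0.9" inclusion rule; a SNP that becomes
# monomorphic only after sample removal is still excluded.

#' Apply sample and SNP quality control
#'
#' Exclusion proceeds in a fixed, documented order: (1) samples with call
#' rate `<=` `sample_call_rate`; (2) on the retained samples, SNPs with call
#' rate `<=` `snp_call_rate`; (3) SNPs with a panel GenTrain score `<=`
#' `gentrain_threshold` (only when the panel carries the annotation); (4)
#' monomorphic SNPs (risk-allele frequency 0 or 1 after sample filtering,
#' i.e. MAF = 0). Each excluded id is reported with exactly one primary
#' reason, the first rule that caught it.
#'
#' @param genotypes A [genotype_matrix()].
#' @param panel Optional SNP panel data frame (for `gentrain_score`).
#' @param sample_call_rate,snp_call_rate Retention thresholds in `(0, 1]`;
#'   a margin is kept when rate > threshold.
#' @param gentrain_threshold GenTrain retention threshold (default 0.5);
#'   applied only where the panel annotation is present and non-missing.
#' @param drop_monomorphic Exclude MAF = 0 SNPs (default `TRUE`).
#' @return A list with `genotypes` (filtered matrix) and `report`
#'   (a `"qc_report"`).
#' @export
apply_qc <- function(genotypes, panel = NULL,
                     sample_call_rate = 0.9, snp_call_rate = 0.9,
                     gentrain_threshold = 0.5, drop_monomorphic = TRUE) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (sample_call_rate <= 0 || sample_call_rate > 1 ||
      snp_call_rate <= 0 || snp_call_rate > 1) {
    stop("call-rate thresholds must lie in (0, 1]")
  }
  status <- attr(genotypes, "status")
  rates <- call_rates(genotypes)

  drop_samples <- rates$sample <= sample_call_rate
  excluded_samples <- data.frame(
    sample_id = names(rates$sample)[drop_samples],
    call_rate = unname(rates$sample[drop_samples]),
    stringsAsFactors = FALSE
  )
  g <- genotypes[!drop_samples, , drop = FALSE]
  if (nrow(g) == 0L) stop("empty cohort: every sample failed the call-rate threshold")

  snp_rates <- call_rates(g)$snp
  reason <- rep(NA_character_, ncol(g))
  names(reason) <- colnames(g)
  reason[snp_rates <= snp_call_rate] <- "call_rate"
  if (!is.null(panel) && !is.null(panel$gentrain_score)) {
    gs <- panel$gentrain_score[match(colnames(g), panel$snp_id)]
    fail_gt <- !is.na(gs) & gs <= gentrain_threshold
    reason[is.na(reason) & fail_gt] <- "gentrain"
  }
  if (drop_monomorphic) {
    raf <- risk_allele_freq(g)
    mono <- !is.nan(raf) & (raf == 0 | raf == 1)
    reason[is.na(reason) & mono] <- "monomorphic"
  }
  excluded_snps <- data.frame(
    snp_id = names(reason)[!is.na(reason)],
    reason = unname(reason[!is.na(reason)]),
    call_rate = unname(snp_rates[!is.na(reason)]),
    stringsAsFactors = FALSE
  )
  g <- g[, is.na(reason), drop = FALSE]
  if (!is.null(status)) attr(g, "status") <- status[rownames(g)]

  report <- structure(list(
    excluded_samples = excluded_samples,
    excluded_snps = excluded_snps,
    thresholds = list(sample_call_rate = sample_call_rate,
      snp_call_rate = snp_call_rate,
      gentrain_threshold = if (!is.null(panel) && !is.null(panel$gentrain_score)) gentrain_threshold else NA_real_,
      drop_monomorphic = drop_monomorphic),
    n_samples_in = nrow(genotypes), n_samples_out = nrow(g),
    n_snps_in = ncol(genotypes), n_snps_out = ncol(g)
  ), class = "qc_report")
  list(genotypes = g, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: samples %d -> %d, SNPs %d -> %d\n",
    x$n_samples_in, x$n_samples_out, x$n_snps_in, x$n_snps_out))
  if (nrow(x$excluded_samples)) {
    cat(sprintf("  excluded samples (call rate <= %g): %s\n",
      x$thresholds$sample_call_rate,
      paste(x$excluded_samples$sample_id, collapse = ", ")))
  }
  if (nrow(x$excluded_snps)) {
    for (r in unique(x$excluded_snps$reason)) {
      cat(sprintf("  excluded SNPs [%s]: %s\n", r,
        paste(x$excluded_snps$snp_id[x$excluded_snps$reason == r], collapse = ", ")))
    }
  }
  invisible(x)
}
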
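#' Construct a genotype dosage matrix
#'
#' The central genotype container: an integer matrix of risk-allele dosages
#' (0, 1, 2, or `NA` for a failed call) with samples in rows and SNPs in
#' columns. Dosage counts copies of the panel's *risk* allele, not the minor
#' allele; missing calls are a distinct `NA` sentinel so that call-rate QC can
#' tell an absent call from a homozygous non-risk genotype.
#'
#' @param x A numeric matrix with values in `{0, 1, 2, NA}`.
#' @param sample_ids Optional character vector of unique sample identifiers;
#'   defaults to `rownames(x)`.
#' @param snp_ids Optional character vector of unique SNP identifiers;
#'   defaults to `colnames(x)`.
#' @return An integer matrix of class `"genotype_matrix"` with sample ids as
#'   row names and SNP ids as column names.
#' @examples
#' g <- genotype_matrix(matrix(c(0, 1, 2, NA), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("rs1", "rs2"))))
#' call_rates(g)
#' @export
genotype_matrix <- function(x, sample_ids = rownames(x), snp_ids = colnames(x)) {
  if (!is.matrix(x)) stop("`x` must be a matrix")
  if (is.null(sample_ids) || is.null(snp_ids)) {
    stop("sample and SNP identifiers are required (row/column names)")
  }
  sample_ids <- as.character(sample_ids)
  snp_ids <- as.character(snp_ids)
  if (length(sample_ids) != nrow(x) || length(snp_ids) != ncol(x)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids: ",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(snp_ids)) stop("duplicate SNP ids: ",
    paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  vals <- x[!is.na(x)]
  if (length(vals) && !all(vals %in% c(0L, 1L, 2L))) {
    stop("dosages must be 0, 1, 2 or NA; found: ",
      paste(utils::head(setdiff(unique(vals), 0:2), 5), collapse = ", "))
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(sample_ids, snp_ids)
  class(x) <- c("genotype_matrix", class(matrix()))
  x
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d SNPs, %.1f%% missing\n",
    nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' @export
`[.genotype_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) class(out) <- c("genotype_matrix", class(matrix()))
  out
}

#' Per-sample and per-SNP call rates
#'
#' Call rate is the fraction of non-missing genotype calls along a margin of
#' the dosage matrix; the QC stage excludes margins whose rate fails a
#' threshold.
#'
#' @param genotypes A [genotype_matrix()].
#' @return A list with named numeric vectors `sample` and `snp`, each in
#'   `[0, 1]`.
#' @export
call_rates <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (nrow(genotypes) == 0L || ncol(genotypes) == 0L) {
    stop("empty genotype matrix")
  }
  ok <- !is.na(unclass(genotypes))
  list(
    sample = rowMeans(ok),
    snp = colMeans(ok)
  )
}

#' Risk-allele frequency per SNP
#'
#' Frequency of the risk allele among non-missing calls, optionally within a
#' sample subset (e.g. controls, for Hardy-Weinberg population frequencies in
#' risk model 3).
#'
#' @param genotypes A [genotype_matrix()].
#' @param samples Optional character vector of sample ids to restrict to.
#' @return Named numeric vector of frequencies in `[0, 1]`; `NaN` where a SNP
#'   has no non-missing call in the subset.
#' @export
risk_allele_freq <- function(genotypes, samples = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  g <- unclass(genotypes)
  if (!is.null(samples)) {
    missing_ids <- setdiff(samples, rownames(g))
    if (length(missing_ids)) stop("unknown sample ids: ",
      paste(utils::head(missing_ids, 5), collapse = ", "))
    g <- g[samples, , drop = FALSE]
  }
  colSums(g, na.rm = TRUE) / (2 * colSums(!is.na(g)))
}
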
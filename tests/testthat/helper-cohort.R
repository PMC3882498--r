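# Shared fixtures and independent oracles. Oracles are deliberately naive
# (enumeration, double loops) so they stay independent of the implementation
# paths they check.

# Hypergeometric enumeration oracle for the two-sided Fisher p-value:
# probability of each table with the observed margins from first principles
# (binomial coefficients), summing those no more probable than observed.
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  prob <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- prob[support == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# Pairwise-comparison AUC oracle: explicit double loop over case-control
# pairs with the 0.5 tie rule.
oracle_auc <- function(scores, labels) {
  x <- scores[labels == "case"]; y <- scores[labels == "control"]
  s <- 0
  for (xi in x) for (yj in y) s <- s + (xi > yj) + 0.5 * (xi == yj)
  s / (length(x) * length(y))
}

# Fast rank-based AUC used only inside the bootstrap oracle (itself checked
# against oracle_auc elsewhere).
rank_auc <- function(x, y) {
  r <- rank(c(x, y))
  (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) / (length(x) * length(y))
}

make_geno <- function(mat) {
  genotype_matrix(mat,
    sample_ids = sprintf("s%02d", seq_len(nrow(mat))),
    snp_ids = sprintf("snp%02d", seq_len(ncol(mat))))
}

# A small effect-plus-null simulation spec for fast tests.
small_spec <- function(n_cases = 179, n_controls = 144, seed = 1,
                       snps = NULL, missing_rate = 0) {
  if (is.null(snps)) {
    snps <- data.frame(
      snp_id = c("rsA", "rsB", "rsC", "rsD"),
      control_raf = c(0.372, 0.2, 0.3, 0.4),
      true_or = c(1.54, 1, 1, 0.7),
      stringsAsFactors = FALSE)
  }
  simulation_spec(n_cases = n_cases, n_controls = n_controls, snps = snps,
    missing_rate = missing_rate, seed = seed)
}

panel_for <- function(genotypes, gentrain = NULL) {
  ids <- colnames(genotypes)
  pan <- data.frame(snp_id = ids, locus = "locus", risk_allele = "A",
    other_allele = "G", stringsAsFactors = FALSE)
  if (!is.null(gentrain)) pan$gentrain_score <- gentrain
  pan
}

shipped_panel <- function() {
  read_snp_panel(system.file("extdata", "panel_synthetic_46.csv", package = "snppanel"))
}
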
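# Two-proportion power and sample size for case-control exposure or allele
# comparisons, by the normal approximation to the uncorrected chi-square test
# (continuity-corrected as an option). The exposure probability among cases
# is derived from the control probability and the odds ratio.

#' Case exposure probability from a control probability and odds ratio
#'
#' `p1 = OR p0 / (1 + p0 (OR - 1))`.
#'
#' @param p0 Exposure probability in controls, in `(0, 1)`.
#' @param odds_ratio Odds ratio (> 0).
#' @return The implied exposure probability in cases.
#' @export
or_to_p1 <- function(p0, odds_ratio) {
  stopifnot(p0 > 0, p0 < 1, odds_ratio > 0)
  odds_ratio * p0 / (1 + p0 * (odds_ratio - 1))
}

#' Power of the two-proportion comparison
#'
#' `power = Phi((|p1 - p0| - z_{alpha/2} SE0 - cc) / SE1)` with `SE0` the
#' pooled standard error under the null, `SE1` the unpooled standard error
#' under the alternative, and `cc = (1/n1 + 1/n0)/2` the optional continuity
#' correction. In `allele_level` mode each subject contributes two
#' observations (2N alleles at a given allele frequency).
#'
#' @param p0 Exposure (or allele) probability in controls.
#' @param odds_ratio Effect size as an odds ratio.
#' @param n_cases,n_controls Group sizes (subjects).
#' @param alpha Significance level (default 0.05).
#' @param two_sided Two-sided test (default `TRUE`).
#' @param continuity_correction Apply the continuity correction (default
#'   `FALSE`).
#' @param allele_level Treat observations as alleles, i.e. 2N per group
#'   (default `FALSE`, subject-level).
#' @return Power in `(0, 1)`.
#' @export
power_two_proportions <- function(p0, odds_ratio, n_cases, n_controls = n_cases,
                                  alpha = 0.05, two_sided = TRUE,
                                  continuity_correction = FALSE,
                                  allele_level = FALSE) {
  stopifnot(n_cases > 0, n_controls > 0, alpha > 0, alpha < 1)
  p1 <- or_to_p1(p0, odds_ratio)
  n1 <- if (allele_level) 2 * n_cases else n_cases
  n0 <- if (allele_level) 2 * n_controls else n_controls
  za <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  pbar <- (n1 * p1 + n0 * p0) / (n1 + n0)
  se0 <- sqrt(pbar * (1 - pbar) * (1 / n1 + 1 / n0))
  se1 <- sqrt(p1 * (1 - p1) / n1 + p0 * (1 - p0) / n0)
  delta <- abs(p1 - p0)
  if (continuity_correction) delta <- max(delta - (1 / n1 + 1 / n0) / 2, 0)
  stats::pnorm((delta - za * se0) / se1)
}

#' Smallest case-group size achieving a target power
#'
#' Closed-form normal-approximation seed followed by an exact integer search
#' for the smallest `n_cases` (with `n_controls = ratio * n_cases`) whose
#' [power_two_proportions()] meets `target_power`.
#'
#' @inheritParams power_two_proportions
#' @param target_power Required power, in `(alpha, 1)`.
#' @param ratio Controls per case (default 1).
#' @return List with `n_cases`, `n_controls`, `achieved_power`.
#' @export
sample_size_two_proportions <- function(p0, odds_ratio, target_power = 0.8,
                                        alpha = 0.05, two_sided = TRUE,
                                        ratio = 1, continuity_correction = FALSE,
                                        allele_level = FALSE) {
  stopifnot(target_power > alpha, target_power < 1, ratio > 0)
  p1 <- or_to_p1(p0, odds_ratio)
  if (p1 == p0) stop("infeasible: the odds ratio implies no difference in proportions")
  za <- stats::qnorm(1 - if (two_sided) alpha / 2 else alpha)
  zb <- stats::qnorm(target_power)
  pbar <- (p1 + ratio * p0) / (1 + ratio)
  # closed-form seed (per case group, unequal allocation)
  n_seed <- (za * sqrt((1 + 1 / ratio) * pbar * (1 - pbar)) +
             zb * sqrt(p1 * (1 - p1) + p0 * (1 - p0) / ratio))^2 / (p1 - p0)^2
  if (allele_level) n_seed <- n_seed / 2
  n <- max(2L, as.integer(floor(n_seed)) - 2L)
  pw <- function(n) power_two_proportions(p0, odds_ratio, n, ceiling(ratio * n),
    alpha = alpha, two_sided = two_sided,
    continuity_correction = continuity_correction, allele_level = allele_level)
  while (pw(n) < target_power) n <- n + 1L
  while (n > 2L && pw(n - 1L) >= target_power) n <- n - 1L
  list(n_cases = n, n_controls = as.integer(ceiling(ratio * n)),
    achieved_power = pw(n))
}
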
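# ROC curves, the Mann-Whitney AUC with DeLong variance, paired DeLong AUC
# comparison, and the PSA + GRS combined score.

mw_psi <- function(case_scores, control_scores) {
  # placement matrix psi(x_i, y_j): 1 if case > control, 0.5 on ties
  outer(case_scores, control_scores, function(x, y) (x > y) + 0.5 * (x == y))
}

#' AUC by the Mann-Whitney statistic, with DeLong variance
#'
#' `AUC = sum over case-control pairs of [score_case > score_control] /
#' (n1 n0)` with ties contributing 0.5. The variance is DeLong's, from the
#' empirical variances of the per-case and per-control structural components
#' (placements).
#'
#' @param scores Numeric score vector.
#' @param labels `"case"`/`"control"` (or logical/0-1, `TRUE`/1 = case).
#' @return List with `auc`, `var_delong`, `n_cases`, `n_controls`, and the
#'   placement vectors `v10` (cases), `v01` (controls).
#' @export
auc_mann_whitney <- function(scores, labels) {
  lab <- normalise_labels(labels)
  if (length(scores) != length(lab)) stop("scores and labels lengths differ")
  ok <- !is.na(scores) & !is.na(lab)
  x <- scores[ok & lab == "case"]
  y <- scores[ok & lab == "control"]
  if (!length(x) || !length(y)) stop("need at least one case and one control")
  psi <- mw_psi(x, y)
  v10 <- rowMeans(psi)       # per-case placements
  v01 <- colMeans(psi)       # per-control placements
  auc <- mean(v10)
  s10 <- if (length(x) > 1) stats::var(v10) else 0
  s01 <- if (length(y) > 1) stats::var(v01) else 0
  list(auc = auc, var_delong = s10 / length(x) + s01 / length(y),
    n_cases = length(x), n_controls = length(y), v10 = v10, v01 = v01)
}

normalise_labels <- function(labels) {
  if (is.logical(labels) || all(labels %in% c(0, 1))) {
    ifelse(as.numeric(labels) == 1, "case", "control")
  } else {
    lab <- as.character(labels)
    bad <- setdiff(unique(lab[!is.na(lab)]), c("case", "control"))
    if (length(bad)) stop("labels must be case/control (or 0/1); found: ",
      paste(bad, collapse = ", "))
    lab
  }
}

#' ROC curve for a score
#'
#' Points are swept over every distinct score threshold (predicting "case"
#' for score >= threshold), from (0, 0) to (1, 1); the trapezoidal area of
#' the curve equals the Mann-Whitney AUC.
#'
#' @param scores Numeric score vector.
#' @param labels `"case"`/`"control"` (or 0/1).
#' @return An object of class `"roc_result"`: data frame `points` (`fpr`,
#'   `tpr`, `threshold`), `auc`, `var_delong`, `n_cases`, `n_controls`.
#' @export
roc_curve <- function(scores, labels) {
  lab <- normalise_labels(labels)
  ok <- !is.na(scores) & !is.na(lab)
  scores <- scores[ok]; lab <- lab[ok]
  au <- auc_mann_whitney(scores, lab)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- au$n_cases; n0 <- au$n_controls
  tpr <- vapply(thr, function(t) sum(scores >= t & lab == "case") / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & lab == "control") / n0, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr), threshold = c(Inf, thr))
  structure(list(points = pts, auc = au$auc, var_delong = au$var_delong,
    n_cases = n1, n_controls = n0), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (DeLong SE %.4f), %d cases / %d controls\n",
    x$auc, sqrt(x$var_delong), x$n_cases, x$n_controls))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "l",
    xlab = "False positive rate", ylab = "True positive rate",
    main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Paired DeLong comparison of two AUCs
#'
#' Both scores must be measured on the same samples; the covariance between
#' the two AUCs is estimated from the shared structural components, giving
#' the two-sided z-test on the AUC difference and its Wald interval.
#'
#' @param scores_a,scores_b Score vectors on the same samples.
#' @param labels `"case"`/`"control"` (or 0/1).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `"auc_comparison"`: `auc_a`, `auc_b`,
#'   `delta_auc`, `se`, `ci_low`, `ci_high`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, conf_level = 0.95) {
  if (length(scores_a) != length(scores_b)) stop("paired scores must have equal length")
  lab <- normalise_labels(labels)
  if (length(lab) != length(scores_a)) stop("labels length mismatch")
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(lab)
  a <- auc_mann_whitney(scores_a[ok], lab[ok])
  b <- auc_mann_whitney(scores_b[ok], lab[ok])
  n1 <- a$n_cases; n0 <- a$n_controls
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  S <- s10 / n1 + s01 / n0
  delta <- a$auc - b$auc
  se <- sqrt(max(S[1, 1] + S[2, 2] - 2 * S[1, 2], 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- if (se == 0) {
    if (delta == 0) 1 else 0
  } else 2 * stats::pnorm(-abs(delta / se))
  structure(list(auc_a = a$auc, auc_b = b$auc, delta_auc = delta, se = se,
    ci_low = delta - z * se, ci_high = delta + z * se, p = p,
    n_cases = n1, n_controls = n0), class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("DeLong comparison: AUC %.3f vs %.3f, difference %.3f (95%% CI %.3f-%.3f), p = %.4g\n",
    x$auc_a, x$auc_b, x$delta_auc, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Combine PSA with a genetic risk score
#'
#' Fits a logistic model of case status on `ln(PSA + 1)` (PSA spans orders of
#' magnitude; set `log_psa = FALSE` for raw PSA) and the risk score, and
#' returns the linear predictor as the combined score. A constant component
#' is dropped with a message, so an uninformative GRS reduces the combination
#' to PSA alone.
#'
#' @param psa PSA values (ug/L).
#' @param grs_scores Risk score values on the same samples.
#' @param labels `"case"`/`"control"` (or 0/1).
#' @param log_psa Transform PSA to `ln(PSA + 1)` (default `TRUE`).
#' @return List with `combined` (named score vector over complete cases),
#'   `fit` (the [logistic_fit()]), `labels` (the analysed labels).
#' @export
combine_psa_grs <- function(psa, grs_scores, labels, log_psa = TRUE) {
  lab <- normalise_labels(labels)
  ok <- !is.na(psa) & !is.na(grs_scores) & !is.na(lab)
  if (!any(ok)) stop("no complete observations")
  x1 <- if (log_psa) log(psa[ok] + 1) else psa[ok]
  x2 <- grs_scores[ok]
  y <- as.integer(lab[ok] == "case")
  cols <- list(psa = x1, grs = x2)
  keep <- vapply(cols, function(v) length(unique(v)) > 1L, TRUE)
  if (!any(keep)) stop("both components are constant")
  if (!all(keep)) message("dropping constant component(s): ",
    paste(names(cols)[!keep], collapse = ", "))
  X <- cbind(`(Intercept)` = 1, do.call(cbind, cols[keep]))
  fit <- logistic_fit(X, y)
  lp <- drop(X %*% fit$coef)
  names(lp) <- which(ok)
  list(combined = lp, fit = fit, labels = lab[ok])
}
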
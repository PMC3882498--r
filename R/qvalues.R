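# False discovery rate control. Benjamini-Hochberg step-up q-values, and
# Storey-Tibshirani q-values where the null proportion pi0 is estimated by
# smoothing pi0(lambda) = #{p > lambda} / (m (1 - lambda)) with a cubic
# smoothing spline (df = 3) and reading it off at the largest lambda.

#' Benjamini-Hochberg q-values
#'
#' `q(i) = min over j with p(j) >= p(i) of min(1, m p(j) / rank(j))`, the
#' standard step-up rule (computed via `stats::p.adjust(method = "BH")`).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return An object of class `"qvalue_result"` with `method = "bh"` and
#'   `q_values` aligned with the input order.
#' @export
bh_qvalues <- function(pvalues) {
  check_pvalues(pvalues)
  structure(list(method = "bh", pi0_hat = 1,
    q_values = stats::p.adjust(pvalues, method = "BH")),
    class = "qvalue_result")
}

check_pvalues <- function(p) {
  if (!length(p)) stop("at least one p-value is required")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  invisible(p)
}

#' Storey-Tibshirani smoothed q-values
#'
#' Estimates the proportion of true nulls pi0 from the flat right tail of the
#' p-value histogram: `pi0(lambda) = #{p > lambda} / (m (1 - lambda))` over
#' `lambda_grid`, smoothed by a cubic smoothing spline with `spline_df`
#' equivalent degrees of freedom and evaluated at `max(lambda_grid)`. The
#' estimate is clipped to `[1/m, 1]` (the lower guard avoids zero q-values).
#' Q-values are `pi0_hat` times the BH step-up quantity, with the running
#' minimum already enforcing monotonicity. With fewer than 20 tests the tail
#' is too sparse to smooth and the method falls back to `pi0 = 1` (equal to
#' BH) with a warning.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param lambda_grid Grid of tuning values (default `seq(0, 0.95, 0.01)`).
#' @param spline_df Spline degrees of freedom (default 3).
#' @return An object of class `"qvalue_result"` with `method = "storey"`,
#'   `pi0_hat`, `q_values`, `lambda_grid`, and the raw `pi0_lambda` curve.
#' @export
storey_qvalues <- function(pvalues, lambda_grid = seq(0, 0.95, by = 0.01),
                           spline_df = 3) {
  check_pvalues(pvalues)
  m <- length(pvalues)
  lambda_grid <- sort(unique(lambda_grid))
  if (any(lambda_grid < 0 | lambda_grid >= 1)) stop("lambda grid must lie in [0, 1)")
  if (m < 20L) {
    warning("fewer than 20 tests: pi0 smoother unreliable, using pi0 = 1")
    pi0 <- 1
    pi0_lambda <- rep(NA_real_, length(lambda_grid))
  } else {
    pi0_lambda <- vapply(lambda_grid, function(l) sum(pvalues > l) / (m * (1 - l)), 0)
    sp <- stats::smooth.spline(lambda_grid, pi0_lambda, df = spline_df)
    pi0 <- stats::predict(sp, x = max(lambda_grid))$y
    pi0 <- min(max(pi0, 1 / m), 1)
  }
  structure(list(method = "storey", pi0_hat = pi0,
    q_values = pmin(pi0 * stats::p.adjust(pvalues, method = "BH"), 1),
    lambda_grid = lambda_grid, pi0_lambda = pi0_lambda,
    spline_df = spline_df),
    class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("q-values [%s]: %d tests", x$method, length(x$q_values)))
  if (x$method == "storey") cat(sprintf(", pi0_hat = %.3f", x$pi0_hat))
  cat(sprintf(", %d with q <= 0.05\n", sum(x$q_values <= 0.05)))
  invisible(x)
}
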
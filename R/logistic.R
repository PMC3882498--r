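# Binary logistic and multinomial logistic fits, wrapped so downstream
# stages get a uniform result object with odds ratios, Wald intervals and
# explicit convergence / separation diagnostics.

#' Fit a binary logistic regression on a design matrix
#'
#' Maximum likelihood by iteratively reweighted least squares (via
#' `stats::glm.fit`, binomial family, tight tolerance, 50 iterations). The
#' design must contain its own intercept column. Rank deficiency is an error
#' naming the collinear columns. Complete or quasi-complete separation is
#' detected as a diverging coefficient (|beta| > 15 on the logit scale) and
#' reported by `separation = TRUE`, `converged = FALSE`; Wald statistics are
#' still returned but are meaningless in that case.
#'
#' @param design Numeric matrix, n x p, including an intercept column;
#'   column names are used as coefficient names.
#' @param outcome Binary 0/1 vector (or logical) of length n.
#' @param conf_level Confidence level for Wald intervals (default 0.95).
#' @return An object of class `"logistic_fit"`: `coef`, `se`, `or`, `ci_low`,
#'   `ci_high`, `p` (Wald), `converged`, `separation`, `iterations`,
#'   `loglik`, `n`.
#' @export
logistic_fit <- function(design, outcome, conf_level = 0.95) {
  design <- as.matrix(design)
  y <- as.numeric(outcome)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  if (nrow(design) != length(y)) stop("design and outcome sizes differ")
  if (nrow(design) <= ncol(design)) stop("more coefficients than observations")
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  nonconst <- apply(design, 2, function(col) length(unique(col)) > 1L)
  if (ncol(design) > 1 && any(!nonconst[-1] & colnames(design)[-1] != "(Intercept)")) {
    # a constant non-intercept column is indistinguishable from the intercept
    stop("constant predictor column(s): ",
      paste(colnames(design)[-1][!nonconst[-1]], collapse = ", "))
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("rank-deficient design; collinear column(s): ", paste(dropped, collapse = ", "))
  }
  fit <- suppressWarnings(stats::glm.fit(design, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 50)))
  beta <- fit$coefficients
  separation <- any(abs(beta) > 15)
  converged <- fit$converged && !separation
  # Wald covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(design * sqrt(W))
  vc <- tryCatch(solve(XtWX), error = function(e) matrix(NA_real_, ncol(design), ncol(design)))
  se <- sqrt(diag(vc))
  names(se) <- names(beta)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coef = beta, se = se,
    or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    converged = converged, separation = separation,
    iterations = fit$iter,
    loglik = -fit$deviance / 2,
    n = length(y)
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Logistic fit (n = %d, logLik = %.2f%s)\n", x$n, x$loglik,
    if (x$separation) ", SEPARATION DETECTED" else if (!x$converged) ", NOT CONVERGED" else ""))
  print(data.frame(coef = round(x$coef, 4), se = round(x$se, 4),
    OR = round(x$or, 3), ci_low = round(x$ci_low, 3), ci_high = round(x$ci_high, 3),
    p = signif(x$p, 3)))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coef

#' Per-allele genotype-phenotype model
#'
#' Logistic regression of a binary phenotype (e.g. PSA >= 20 ug/L, or poor
#' tumor grade vs the rest) on risk-allele dosage, optionally adjusted for
#' covariates such as age.
#'
#' @param dosage Integer dosage vector (`NA` dropped together with the
#'   matching outcome rows).
#' @param outcome Binary 0/1 (or logical) phenotype vector.
#' @param covariates Optional data frame of adjustment covariates.
#' @return A [logistic_fit()] whose `"dosage"` coefficient is the per-allele
#'   log odds ratio for the phenotype.
#' @export
genotype_phenotype_model <- function(dosage, outcome, covariates = NULL) {
  y <- as.numeric(outcome)
  ok <- !is.na(dosage) & !is.na(y)
  if (!is.null(covariates)) ok <- ok & stats::complete.cases(covariates)
  y <- y[ok]
  if (length(unique(y)) < 2L) stop("outcome is constant on the analysed samples")
  X <- cbind(`(Intercept)` = 1, dosage = dosage[ok])
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = covariates[ok, , drop = FALSE])
    X <- cbind(X, mm[, -1, drop = FALSE])
  }
  logistic_fit(X, y)
}

#' Multinomial logistic regression with a stated reference category
#'
#' Maximum-likelihood multinomial logit (via `nnet::multinom`, tight
#' tolerance). Coefficients of each non-reference category are reported as
#' relative risk ratios `RR = exp(coef)` with Wald intervals; the reference
#' category carries zero coefficients by construction. With a 2-category
#' outcome the fit reduces to binary logistic regression.
#'
#' @param design Numeric matrix including an intercept column.
#' @param outcome Factor (or coercible) with >= 2 categories, each non-empty.
#' @param reference Reference category (default: first level).
#' @param conf_level Confidence level for Wald intervals.
#' @return An object of class `"multinomial_fit"`: matrices `coef`, `se`,
#'   `rr`, `ci_low`, `ci_high`, `p` (rows = non-reference categories), plus
#'   `reference`, `levels`, `n`.
#' @export
multinomial_fit <- function(design, outcome, reference = NULL, conf_level = 0.95) {
  design <- as.matrix(design)
  if (is.factor(outcome) && any(table(outcome) == 0L)) stop("empty outcome category")
  outcome <- factor(outcome)
  if (nlevels(outcome) < 2L) stop("outcome must have at least 2 categories")
  if (is.null(reference)) reference <- levels(outcome)[1]
  if (!reference %in% levels(outcome)) stop("reference '", reference, "' is not an outcome level")
  outcome <- stats::relevel(outcome, ref = reference)
  if (is.null(colnames(design))) colnames(design) <- paste0("x", seq_len(ncol(design)))
  # multinom supplies its own intercept: drop the design's constant column(s)
  keep <- apply(design, 2, function(col) length(unique(col)) > 1L)
  df <- as.data.frame(design[, keep, drop = FALSE])
  df$.y <- outcome
  fit <- nnet::multinom(.y ~ ., data = df, trace = FALSE,
    maxit = 1000, reltol = 1e-14, abstol = 1e-12, Hess = TRUE)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) {
    cf <- matrix(cf, nrow = 1, dimnames = list(levels(outcome)[2], names(cf)))
  }
  vc <- solve(fit$Hessian)
  se <- matrix(sqrt(diag(vc)), nrow = nrow(cf), byrow = TRUE,
    dimnames = dimnames(cf))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(
    coef = cf, se = se, rr = exp(cf),
    ci_low = exp(cf - z * se), ci_high = exp(cf + z * se),
    p = 2 * stats::pnorm(-abs(cf / se)),
    reference = reference, levels = levels(outcome), n = length(outcome)
  ), class = "multinomial_fit")
}

#' @export
print.multinomial_fit <- function(x, ...) {
  cat(sprintf("Multinomial fit (n = %d, reference = '%s')\n", x$n, x$reference))
  for (lev in rownames(x$coef)) {
    cat(" category", lev, "vs", x$reference, "\n")
    print(data.frame(RR = round(x$rr[lev, ], 3),
      ci_low = round(x$ci_low[lev, ], 3), ci_high = round(x$ci_high[lev, ], 3),
      p = signif(x$p[lev, ], 3)))
  }
  invisible(x)
}
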
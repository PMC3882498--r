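# Stage-3 epidemiology: crude tests (Yates chi-square for dichotomous
# variables, Pearson chi-square for wider contingency tables, Welch t for
# continuous), confounder-adjusted logistic regression per variable with the
# "most equally represented" reference rule, and case-only multinomial
# models for Gleason band and tumor grade.

#' Pearson chi-square with Yates continuity correction (2x2)
#'
#' `X^2 = sum (max(|O - E| - 0.5, 0))^2 / E`, the correction capped so a
#' deviation smaller than 0.5 contributes zero; p from the chi-square(1)
#' upper tail.
#'
#' @param table 2x2 count matrix with positive margins.
#' @return List with `statistic`, `df = 1`, `p`.
#' @export
chi_square_yates <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("chi-square undefined: table has a zero margin")
  }
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum(pmax(abs(table - E) - 0.5, 0)^2 / E)
  list(statistic = stat, df = 1L, p = stats::pchisq(stat, 1, lower.tail = FALSE))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom (via
#' `stats::t.test(var.equal = FALSE)`).
#'
#' @param x,y Numeric samples (each with at least 2 values).
#' @return List with `t`, `df`, `p`, and the group means.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0) stop("zero variance in both groups")
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value,
    mean_x = mean(x), mean_y = mean(y))
}

#' Reference level: the condition most equally represented in both groups
#'
#' For a categorical variable, computes each level's share within cases and
#' within controls and returns the level minimising the absolute difference
#' of shares; ties break lexicographically (with a message).
#'
#' @param variable Character/factor vector of levels.
#' @param status `"case"`/`"control"` vector aligned with `variable`.
#' @return The reference level (character scalar).
#' @export
choose_reference_level <- function(variable, status) {
  ok <- !is.na(variable) & !is.na(status)
  v <- as.character(variable[ok]); s <- as.character(status[ok])
  levs <- sort(unique(v))
  share <- function(grp) {
    n <- sum(s == grp)
    vapply(levs, function(l) sum(v == l & s == grp) / n, 0)
  }
  diff <- abs(share("case") - share("control"))
  best <- levs[diff == min(diff)]
  if (length(best) > 1L) message("reference tie among {",
    paste(best, collapse = ", "), "}; taking '", best[1], "'")
  best[1]
}

#' Bin PSA at the study thresholds
#'
#' Ordered bins `<4`, `4-10`, `10-20`, `20-100`, `>=100` ug/L; `<4` is the
#' reference category in adjusted models.
#'
#' @param psa Numeric PSA values.
#' @param edges Increasing bin edges (default `c(4, 10, 20, 100)`).
#' @return Factor of bins with `<4` first.
#' @export
bin_psa <- function(psa, edges = c(4, 10, 20, 100)) {
  if (is.unsorted(edges, strictly = TRUE)) stop("PSA bin edges must be strictly increasing")
  labs <- c(paste0("<", edges[1]),
    paste0(utils::head(edges, -1), "-", utils::tail(edges, -1)),
    paste0(">=", utils::tail(edges, 1)))
  cut(psa, breaks = c(-Inf, edges, Inf), labels = labs, right = FALSE)
}

#' Crude plus confounder-adjusted analysis of one epidemiological variable
#'
#' Complete-case analysis over the variable, the confounders and status.
#' Crude association: Welch t for continuous variables, Yates-corrected
#' chi-square for dichotomous, Pearson chi-square for wider tables.
#' Adjusted: logistic regression of status on the variable plus confounders
#' (default age, family history of prostate cancer, population group);
#' categorical variables are coded against the reference chosen by
#' [choose_reference_level()] (binary "no"/"yes" against "no"); PSA is
#' analysed as the ordered bins of [bin_psa()] against `<4`. When the
#' variable itself appears in the confounder list that confounder is dropped
#' with a message.
#'
#' @param variable Column name in `phenotypes`, or `"psa_bin"` for binned PSA.
#' @param phenotypes Phenotype data frame.
#' @param confounders Character vector of confounder columns.
#' @return A data frame of class `"epi_result"`: one row per non-reference
#'   level (or one row for a continuous variable) with the crude statistic/p
#'   and the adjusted OR, CI and p; the reference level appears with OR 1.
#' @export
adjusted_variable_model <- function(variable, phenotypes,
                                    confounders = c("age", "family_history_pca", "population_group")) {
  ph <- phenotypes
  if (variable == "psa_bin") {
    if (!"psa" %in% names(ph)) stop("no psa column")
    ph$psa_bin <- bin_psa(ph$psa)
  }
  if (!variable %in% names(ph)) stop("unknown variable: ", variable)
  confounders <- setdiff(confounders, variable)
  if (length(setdiff(confounders, names(ph)))) {
    stop("missing confounder column(s): ",
      paste(setdiff(confounders, names(ph)), collapse = ", "))
  }
  keep <- stats::complete.cases(ph[, c("status", variable, confounders), drop = FALSE])
  ph <- ph[keep, , drop = FALSE]
  v <- ph[[variable]]
  y <- as.integer(ph$status == "case")
  continuous <- is.numeric(v) && !is.factor(v)

  if (continuous) {
    crude <- welch_t(v[y == 1], v[y == 0])
    crude_stat <- crude$t; crude_p <- crude$p
    vfac <- NULL; ref <- NA_character_
  } else {
    vfac <- factor(v)
    tab <- table(vfac, ph$status)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    if (nrow(tab) < 2L) stop("variable '", variable, "' is constant after missing-data removal")
    if (nrow(tab) == 2L) {
      crude <- chi_square_yates(matrix(as.integer(tab), 2, 2))
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      crude <- list(statistic = unname(ct$statistic), p = ct$p.value)
    }
    crude_stat <- crude$statistic; crude_p <- crude$p
    ref <- if (variable == "psa_bin") levels(vfac)[1]
      else if (nlevels(vfac) == 2L && "no" %in% levels(vfac)) "no"
      else choose_reference_level(vfac, ph$status)
    vfac <- stats::relevel(vfac, ref = ref)
    empty <- setdiff(levels(factor(v)), levels(droplevels(vfac)))
    if (length(empty)) warning("dropping empty level(s): ", paste(empty, collapse = ", "))
    vfac <- droplevels(vfac)
  }

  dat <- data.frame(.v = if (continuous) v else vfac, ph[, confounders, drop = FALSE])
  X <- stats::model.matrix(~ ., data = dat)
  fit <- logistic_fit(X, y)
  vcols <- grep("^\\.v", colnames(X), value = TRUE)
  lev_names <- if (continuous) variable else sub("^\\.v", "", vcols)
  out <- data.frame(
    variable = variable,
    level = lev_names,
    reference = ref,
    n = nrow(ph),
    crude_stat = crude_stat, crude_p = crude_p,
    or = unname(fit$or[vcols]), ci_low = unname(fit$ci_low[vcols]),
    ci_high = unname(fit$ci_high[vcols]), p = unname(fit$p[vcols]),
    stringsAsFactors = FALSE
  )
  attr(out, "fit") <- fit
  class(out) <- c("epi_result", "data.frame")
  out
}

#' Gleason score bands used for case-only outcome models
#'
#' @param gleason Integer Gleason scores.
#' @return Factor with levels `<7`, `=7`, `>7` (reference `<7`).
#' @export
gleason_band <- function(gleason) {
  factor(ifelse(gleason < 7, "<7", ifelse(gleason == 7, "=7", ">7")),
    levels = c("<7", "=7", ">7"))
}

#' Case-only model of an aggressive-disease outcome
#'
#' Multinomial logistic regression of the Gleason band (`<7`, `=7`, `>7`,
#' reference `<7`) or tumor grade (`well`/`moderate`/`poor`, reference
#' `well`) on one covariate, among cases only. With only two non-empty
#' outcome categories the multinomial fit coincides with binary logistic
#' regression.
#'
#' @param variable Covariate column name in `cases`.
#' @param cases Phenotype rows with `status == "case"`.
#' @param outcome `"gleason_band"` or `"grade"`.
#' @return A [multinomial_fit()].
#' @export
caseonly_outcome_model <- function(variable, cases, outcome = c("gleason_band", "grade")) {
  outcome <- match.arg(outcome)
  if (any(cases$status != "case")) stop("case-only analysis: drop controls first")
  yv <- if (outcome == "gleason_band") gleason_band(cases$gleason)
    else factor(cases$grade, levels = c("well", "moderate", "poor"))
  v <- cases[[variable]]
  if (is.null(v)) stop("unknown variable: ", variable)
  ok <- !is.na(yv) & !is.na(v)
  yv <- droplevels(yv[ok]); v <- v[ok]
  if (nlevels(yv) < 2L) stop("fewer than 2 non-empty outcome categories")
  dat <- data.frame(.v = v)
  X <- stats::model.matrix(~ ., data = dat)
  multinomial_fit(X, yv, reference = levels(yv)[1])
}
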
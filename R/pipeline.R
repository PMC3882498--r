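# End-to-end staged pipeline: simulate (or read) -> qc -> assoc -> qvalue ->
# grs -> roc -> power -> epi, with plain TSV/JSON stage outputs so a run can
# be diffed and every reported number traced to a stage file.

default_config <- function() {
  list(
    seed = 4973L,
    simulate = TRUE,
    n_cases = 522L, n_controls = 315L,
    genotypes = NULL, phenotypes = NULL, genotype_dialect = "tsv",
    panel = NULL,
    sample_call_rate = 0.9, snp_call_rate = 0.9,
    gentrain_threshold = 0.5, drop_monomorphic = TRUE,
    psa_bin_edges = c(4, 10, 20, 100),
    grs_p_threshold = 0.05, grs_n_top = 3L,
    power = list(p0 = 0.1, odds_ratio = 1.4, alpha = 0.05, target_power = 0.8, ratio = 1),
    confounders = c("age", "family_history_pca", "population_group"),
    epi_variables = c("family_history_cancer", "diabetes", "balding",
      "sexual_activity", "ed", "aspirin", "population_group", "psa_bin"),
    stages = c("simulate", "qc", "assoc", "qvalue", "grs", "roc", "power", "epi")
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a named list or a YAML file path; unknown fields and violated
#' constraints are reported with the offending field name; a missing seed is
#' filled with the default (and noted). The returned config is normalised
#' (all defaults resolved), so re-validating it is the identity.
#'
#' @param config Named list of overrides, or a YAML file path.
#' @return A complete, validated config list of class `"cohort_config"`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  stopifnot(is.list(config))
  base <- default_config()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed) && length(config)) message("no seed supplied; using default ", base$seed)
  cfg <- base
  for (nm in names(config)) cfg[nm] <- list(config[[nm]])  # keeps explicit NULLs
  for (f in c("sample_call_rate", "snp_call_rate")) {
    if (cfg[[f]] <= 0 || cfg[[f]] > 1) stop("config field '", f, "' must lie in (0, 1]")
  }
  if (is.unsorted(cfg$psa_bin_edges, strictly = TRUE)) {
    stop("config field 'psa_bin_edges' must be strictly increasing")
  }
  bad_stage <- setdiff(cfg$stages, default_config()$stages)
  if (length(bad_stage)) stop("unknown stage(s) in config: ", paste(bad_stage, collapse = ", "))
  if (!cfg$simulate && (is.null(cfg$genotypes) || is.null(cfg$phenotypes))) {
    stop("config: either simulate = TRUE or genotype/phenotype input paths are required")
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("cohort_config", "list")
  cfg
}

#' Run the staged analysis pipeline
#'
#' Executes the configured stages in order on a simulated or supplied cohort,
#' writing each stage's table (TSV) or summary (JSON) under `out_dir`. A
#' fixed config and seed reproduce byte-identical outputs.
#'
#' @param config A config list/path, see [validate_config()].
#' @param out_dir Output directory (created if needed).
#' @return A list of class `"pipeline_run"`: `config`, `stages`, `outputs`
#'   (named file paths), and the in-memory stage results.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("pipeline")) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list(); results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  panel <- if (is.null(cfg$panel)) {
    read_snp_panel(system.file("extdata", "panel_synthetic_46.csv", package = "snppanel"))
  } else read_snp_panel(cfg$panel)

  if ("simulate" %in% cfg$stages && cfg$simulate) {
    sim <- stage("simulate", simulate_cohort(simulation_spec(
      n_cases = cfg$n_cases, n_controls = cfg$n_controls, seed = cfg$seed)))
    g <- sim$genotypes; ph <- sim$phenotypes
    outputs$genotypes <- file.path(out_dir, "genotypes.tsv")
    utils::write.table(cbind(sample_id = rownames(g), as.data.frame(unclass(g))),
      outputs$genotypes, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$phenotypes <- file.path(out_dir, "phenotypes.csv")
    utils::write.csv(ph, outputs$phenotypes, row.names = FALSE)
  } else {
    g <- stage("read", read_genotypes(cfg$genotypes, cfg$genotype_dialect, panel = panel))
    ph <- stage("read", read_phenotypes(cfg$phenotypes))
  }
  st <- ph$status[match(rownames(g), ph$sample_id)]
  names(st) <- rownames(g)
  attr(g, "status") <- st

  if ("qc" %in% cfg$stages) {
    qc <- stage("qc", apply_qc(g, panel = panel,
      sample_call_rate = cfg$sample_call_rate, snp_call_rate = cfg$snp_call_rate,
      gentrain_threshold = cfg$gentrain_threshold,
      drop_monomorphic = cfg$drop_monomorphic))
    g <- qc$genotypes
    results$qc <- qc$report
    outputs$qc <- file.path(out_dir, "qc_report.json")
    jsonlite::write_json(list(
      excluded_samples = qc$report$excluded_samples,
      excluded_snps = qc$report$excluded_snps,
      n_samples = c(qc$report$n_samples_in, qc$report$n_samples_out),
      n_snps = c(qc$report$n_snps_in, qc$report$n_snps_out)),
      outputs$qc, auto_unbox = TRUE, digits = NA)
  }

  assoc <- NULL
  if ("assoc" %in% cfg$stages) {
    assoc <- stage("assoc", per_allele_association(g, ph, panel))
    results$assoc <- assoc
  }
  if (!is.null(assoc) && "qvalue" %in% cfg$stages) {
    qv <- stage("qvalue", if (nrow(assoc) >= 20)
      storey_qvalues(assoc$p_fisher) else bh_qvalues(assoc$p_fisher))
    assoc$q_value <- qv$q_values
    results$assoc <- assoc
    results$qvalues <- qv
    outputs$assoc <- file.path(out_dir, "association.tsv")
    write_association_table(assoc, outputs$assoc)
  }

  scores <- NULL
  if (!is.null(assoc) && "grs" %in% cfg$stages) {
    subsets <- grs_subsets(assoc, cfg$grs_p_threshold, cfg$grs_n_top)
    scores <- list()
    for (sub in names(subsets)) {
      if (length(subsets[[sub]]) == 0) next
      for (mdl in 1:3) {
        scores[[paste0("model", mdl, "_", sub)]] <-
          stage("grs", build_scores(g, ph, panel, model = mdl, snps = subsets[[sub]]))
      }
    }
    results$grs <- scores
    outputs$grs <- file.path(out_dir, "risk_scores.tsv")
    sc_tab <- data.frame(sample_id = rownames(g),
      lapply(scores, function(s) unname(s$scores)), check.names = FALSE)
    utils::write.table(sc_tab, outputs$grs, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(scores) && "roc" %in% cfg$stages) {
    best <- scores[["model2_all"]]
    psa <- ph$psa[match(rownames(g), ph$sample_id)]
    lab <- st[rownames(g)]
    roc_grs <- stage("roc", roc_curve(best$scores, lab))
    ok <- !is.na(psa)
    roc_psa <- stage("roc", roc_curve(psa[ok], lab[ok]))
    comb <- stage("roc", combine_psa_grs(psa, best$scores, lab))
    roc_comb <- stage("roc", roc_curve(comb$combined, comb$labels))
    cmp <- stage("roc", delong_compare(psa[ok & !is.na(best$scores)],
      best$scores[ok & !is.na(best$scores)], lab[ok & !is.na(best$scores)]))
    results$roc <- list(grs = roc_grs, psa = roc_psa, combined = roc_comb,
      psa_vs_grs = cmp)
    outputs$roc <- file.path(out_dir, "roc_summary.json")
    jsonlite::write_json(list(
      auc_grs_model2_all = roc_grs$auc, auc_psa = roc_psa$auc,
      auc_combined = roc_comb$auc,
      psa_vs_grs = list(delta_auc = cmp$delta_auc, ci_low = cmp$ci_low,
        ci_high = cmp$ci_high, p = cmp$p)),
      outputs$roc, auto_unbox = TRUE, digits = NA)
  }

  if ("power" %in% cfg$stages) {
    pw <- cfg$power
    ss <- stage("power", sample_size_two_proportions(pw$p0, pw$odds_ratio,
      target_power = pw$target_power, alpha = pw$alpha, ratio = pw$ratio))
    achieved <- power_two_proportions(pw$p0, pw$odds_ratio,
      n_cases = sum(st == "case"), n_controls = sum(st == "control"),
      alpha = pw$alpha)
    results$power <- list(required = ss, power_at_study_size = achieved)
    outputs$power <- file.path(out_dir, "power.json")
    jsonlite::write_json(list(required_n_cases = ss$n_cases,
      required_n_controls = ss$n_controls,
      power_at_study_size = achieved), outputs$power, auto_unbox = TRUE, digits = NA)
  }

  if ("epi" %in% cfg$stages) {
    epi <- list()
    for (v in cfg$epi_variables) {
      epi[[v]] <- tryCatch(
        adjusted_variable_model(v, ph, confounders = cfg$confounders),
        error = function(e) {
          warning("epi variable '", v, "' skipped: ", conditionMessage(e))
          NULL
        })
    }
    epi_tab <- do.call(rbind, epi[!vapply(epi, is.null, TRUE)])
    results$epi <- epi_tab
    outputs$epi <- file.path(out_dir, "epi_results.tsv")
    utils::write.table(epi_tab, outputs$epi, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  structure(list(config = cfg, stages = cfg$stages, outputs = outputs,
    results = results, version = as.character(utils::packageVersion("snppanel"))),
    class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (seed", x$config$seed, ") stages:",
    paste(x$stages, collapse = " -> "), "\n")
  for (nm in names(x$outputs)) cat("  ", nm, ": ", x$outputs[[nm]], "\n", sep = "")
  invisible(x)
}
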
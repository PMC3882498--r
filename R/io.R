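# Readers/writers for the pipeline's tabular formats: genotype TSV, a minimal
# biallelic VCF dialect, the phenotype CSV, the SNP panel CSV and the
# association results table.

#' Controlled vocabularies for the phenotype table
#'
#' Questionnaire and clinical fields are stored as explicit strings, not
#' integer codes, and validated on read. A single `NA` sentinel covers every
#' form of missingness (the source questionnaires do not distinguish refused
#' from not-asked).
#'
#' @format A named list mapping column name to the vector of admissible
#'   levels (`NULL` for free/numeric fields).
#' @export
phenotype_vocabulary <- list(
  status = c("case", "control"),
  grade = c("well", "moderate", "poor"),
  balding = c("none", "frontal", "vertex", "frontal_vertex"),
  family_history_pca = c("no", "yes"),
  family_history_cancer = c("no", "yes"),
  diabetes = c("no", "yes"),
  sexual_activity = c("no", "yes"),
  ed = c("no", "yes"),
  aspirin = c("no", "yes"),
  acne = c("no", "yes"),
  male_breasts = c("no", "yes"),
  std_history = c("no", "yes")
)

#' Read a genotype dosage matrix
#'
#' Two dialects are supported. `"tsv"`: a tab-delimited table whose first
#' column is `sample_id` and whose remaining columns are SNP ids, cells in
#' `{0, 1, 2, NA}` (already coded as risk-allele dosage). `"vcf"`: a minimal
#' biallelic VCF 4.x reader using only the GT subfield (phase is ignored,
#' `0/1` and `0|1` are equivalent); genotypes are recoded to risk-allele
#' dosage against the supplied panel, so the panel's `risk_allele` must match
#' either REF or ALT at every record.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param panel SNP panel data frame (required for `"vcf"`), see
#'   [read_snp_panel()].
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"), panel = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_genotypes_tsv(path) else read_genotypes_vcf(path, panel)
}

read_genotypes_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error in ", path, ": need a header and at least one sample row")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[[1]] != "sample_id") {
    stop("parse error in ", path, " line 1: expected header starting with 'sample_id'")
  }
  snp_ids <- header[-1]
  n <- length(lines) - 1L
  mat <- matrix(NA_integer_, n, length(snp_ids))
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) {
      stop("parse error in ", path, " line ", i + 1L, ": expected ",
        length(header), " fields, found ", length(f))
    }
    ids[i] <- f[[1]]
    v <- f[-1]
    v[v %in% c("NA", ".", "")] <- NA
    num <- suppressWarnings(as.integer(v))
    bad <- which(!is.na(v) & (is.na(num) | !num %in% 0:2))
    if (length(bad)) {
      stop("parse error in ", path, " line ", i + 1L, ": invalid dosage '",
        v[bad[1]], "' for ", snp_ids[bad[1]])
    }
    mat[i, ] <- num
  }
  genotype_matrix(mat, sample_ids = ids, snp_ids = snp_ids)
}

read_genotypes_vcf <- function(path, panel) {
  if (is.null(panel)) stop("a SNP panel is required to recode VCF genotypes to risk-allele dosage")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1L) stop("parse error in ", path, ": missing #CHROM header line")
  cols <- strsplit(lines[[hdr]], "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("parse error in ", path, ": VCF has no sample columns")
  sample_ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[!startsWith(body, "#")]
  if (!length(body)) stop("parse error in ", path, ": no variant records")
  n_snp <- length(body)
  mat <- matrix(NA_integer_, length(sample_ids), n_snp)
  snp_ids <- character(n_snp)
  errors <- character(0)
  for (k in seq_len(n_snp)) {
    f <- strsplit(body[[k]], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(cols)) {
      stop("parse error in ", path, ": record ", k, " has ", length(f),
        " fields, expected ", length(cols))
    }
    id <- f[[3]]
    ref <- f[[4]]; alt <- f[[5]]
    snp_ids[k] <- id
    if (grepl(",", alt, fixed = TRUE)) {
      stop("record ", id, " is multi-allelic; only biallelic records are supported")
    }
    prow <- panel[panel$snp_id == id, , drop = FALSE]
    if (nrow(prow) == 0L) {
      errors <- c(errors, sprintf("%s: not in panel", id))
      next
    }
    risk <- prow$risk_allele[[1]]
    if (!risk %in% c(ref, alt)) {
      errors <- c(errors, sprintf("%s: risk allele %s matches neither REF %s nor ALT %s",
        id, risk, ref, alt))
      next
    }
    fmt <- strsplit(f[[9]], ":", fixed = TRUE)[[1]]
    gt_idx <- match("GT", fmt)
    if (is.na(gt_idx)) stop("record ", id, " has no GT subfield")
    risk_code <- if (risk == alt) "1" else "0"
    for (s in seq_along(sample_ids)) {
      gt <- strsplit(strsplit(f[[9 + s]], ":", fixed = TRUE)[[1]][gt_idx],
        "[/|]")[[1]]
      if (length(gt) != 2L || any(gt == ".")) next  # stays NA
      if (!all(gt %in% c("0", "1"))) {
        stop("record ", id, " sample ", sample_ids[s], ": unsupported GT code")
      }
      mat[s, k] <- sum(gt == risk_code)
    }
  }
  if (length(errors)) {
    stop("VCF/panel allele mismatches:\n  ", paste(errors, collapse = "\n  "))
  }
  genotype_matrix(mat, sample_ids = sample_ids, snp_ids = snp_ids)
}

#' Read the SNP panel annotation
#'
#' The panel lists each candidate SNP with its risk allele, locus label and
#' (optionally) the discovery odds ratio and the array GenTrain clustering
#' score. GenTrain is a pass-through annotation: it is consumed by QC when an
#' optional threshold is set, never computed here.
#'
#' @param path CSV with columns `snp_id`, `locus`, `risk_allele` and
#'   optionally `other_allele`, `discovery_or`, `gentrain_score`.
#' @return A data frame, one row per SNP.
#' @export
read_snp_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pan <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("snp_id", "locus", "risk_allele")
  miss <- setdiff(required, names(pan))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  validate_snp_panel(pan)
}

#' Validate a SNP panel data frame
#'
#' @param pan Data frame with at least `snp_id` and `risk_allele`.
#' @return The validated data frame (invisibly identical to the input).
#' @export
validate_snp_panel <- function(pan) {
  if (anyDuplicated(pan$snp_id)) {
    stop("duplicate snp_id in panel: ",
      paste(unique(pan$snp_id[duplicated(pan$snp_id)]), collapse = ", "))
  }
  bases <- c("A", "C", "G", "T")
  if (!all(pan$risk_allele %in% bases)) {
    stop("risk_allele must be one of A/C/G/T")
  }
  if (!is.null(pan$other_allele)) {
    known <- !is.na(pan$other_allele) & pan$other_allele != ""
    if (!all(pan$other_allele[known] %in% bases)) stop("other_allele must be one of A/C/G/T or missing")
    if (any(known & pan$other_allele == pan$risk_allele)) {
      stop("risk_allele equals other_allele for: ",
        paste(pan$snp_id[known & pan$other_allele == pan$risk_allele], collapse = ", "))
    }
  }
  for (col in c("discovery_or", "study_or")) {
    v <- pan[[col]]
    if (!is.null(v) && any(!is.na(v) & v <= 0)) stop(col, " must be strictly positive")
  }
  gs <- pan$gentrain_score
  if (!is.null(gs) && any(!is.na(gs) & (gs < 0 | gs > 1))) {
    stop("gentrain_score must lie in [0, 1]")
  }
  pan
}

#' Read the phenotype table
#'
#' CSV with one row per participant. Required columns: `sample_id`, `status`
#' (`case`/`control`). Recognised optional columns: `psa` (serum PSA, ug/L,
#' nonnegative), `age` (years), `gleason` (integer 2-10, cases only), `grade`
#' (`well`/`moderate`/`poor`, cases only), `population_group`, `occupation`,
#' `clinic`, and the questionnaire fields listed in [phenotype_vocabulary].
#' Categorical levels are validated against the vocabulary; any unknown level
#' or a clinical field on a control is an error.
#'
#' @param path CSV file path.
#' @return A data frame of participant records.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ph <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_phenotypes(ph)
}

#' Validate a phenotype data frame against the column vocabularies
#'
#' @param ph Data frame as produced by [read_phenotypes()] or
#'   [simulate_phenotypes()].
#' @return The validated data frame.
#' @export
validate_phenotypes <- function(ph) {
  if (!all(c("sample_id", "status") %in% names(ph))) {
    stop("phenotype table requires sample_id and status columns")
  }
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample_id in phenotype table")
  if (anyNA(ph$status)) {
    stop("status missing for: ",
      paste(utils::head(ph$sample_id[is.na(ph$status)], 5), collapse = ", "))
  }
  for (col in intersect(names(phenotype_vocabulary), names(ph))) {
    lv <- phenotype_vocabulary[[col]]
    bad <- !is.na(ph[[col]]) & !ph[[col]] %in% lv
    if (any(bad)) {
      stop("unknown level(s) in '", col, "': ",
        paste(unique(ph[[col]][bad]), collapse = ", "),
        " (allowed: ", paste(lv, collapse = ", "), ")")
    }
  }
  ctrl <- ph$status == "control"
  for (col in c("gleason", "grade")) {
    if (col %in% names(ph) && any(ctrl & !is.na(ph[[col]]))) {
      stop(col, " present on control sample(s): ",
        paste(utils::head(ph$sample_id[ctrl & !is.na(ph[[col]])], 5), collapse = ", "))
    }
  }
  if ("gleason" %in% names(ph)) {
    g <- ph$gleason
    if (any(!is.na(g) & (g < 2 | g > 10 | g != round(g)))) stop("gleason must be an integer in 2..10")
  }
  if ("psa" %in% names(ph) && any(!is.na(ph$psa) & ph$psa < 0)) stop("psa must be nonnegative")
  if ("age" %in% names(ph) && any(!is.na(ph$age) & ph$age <= 0)) stop("age must be positive")
  ph
}

#' Write / read the per-SNP association table
#'
#' One row per SNP with group sizes, risk-allele frequencies, the allelic
#' odds ratio with its Woolf interval (also formatted as `OR (lo-hi)`), the
#' dosage-logistic odds ratio, the Fisher exact p and the q-value. Numeric
#' values are written at 4 decimal places (frequencies, p, q) or 4 significant
#' digits (odds ratios), and `read_association_table()` recovers them at that
#' printed precision.
#'
#' @param results Association results data frame from
#'   [per_allele_association()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path) {
  if (!is.data.frame(results) || nrow(results) == 0L) stop("`results` must be a non-empty data frame")
  num4 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 4, format = "f"))
  sig4 <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 4, format = "g"))
  out <- data.frame(
    snp_id = results$snp_id,
    n_cases = results$n_cases,
    n_controls = results$n_controls,
    maf_cases = num4(results$maf_cases),
    maf_controls = num4(results$maf_controls),
    or_allelic = sig4(results$or),
    ci_low = sig4(results$ci_low),
    ci_high = sig4(results$ci_high),
    or_ci = sprintf("%s (%s-%s)", sig4(results$or), sig4(results$ci_low), sig4(results$ci_high)),
    or_logistic = sig4(results$or_logistic),
    p_fisher = num4(results$p_fisher),
    q_value = if (is.null(results$q_value)) "NA" else num4(results$q_value),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  tab$or <- tab$or_allelic
  tab
}
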
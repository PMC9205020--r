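# Cohort readers/writers with schema validation, the participant
# exclusion cascade, and SAS transport (XPT) ingestion for survey files.

cohort_required_columns <- function() {
  c("participant_id", metal_columns(), "creatinine", "oa_status",
    covariate_columns(), kdm_biomarker_columns(), pheno_biomarker_columns(),
    "telomere_ts", "survey_weight")
}

#' Validate a cohort table against the fixed schema
#'
#' Checks that all mandatory columns are present, `oa_status` is 0/1,
#' survey weights are positive and telomere T/S ratios are positive.
#' Missing values are allowed (they are handled by [apply_exclusions()]
#' and [impute_covariates()]).
#'
#' @param cohort a `data.frame`.
#' @return the cohort, invisibly, if valid; otherwise an error.
#' @export
validate_cohort <- function(cohort) {
  absent <- setdiff(cohort_required_columns(), names(cohort))
  if (length(absent) > 0) {
    stop("schema error: missing mandatory column(s): ",
         paste(absent, collapse = ", "))
  }
  if (!all(cohort$oa_status %in% c(0, 1, NA))) {
    stop("schema error: oa_status must be binary 0/1")
  }
  if (any(cohort$survey_weight <= 0, na.rm = TRUE)) {
    stop("schema error: survey_weight must be positive")
  }
  if (any(cohort$telomere_ts <= 0, na.rm = TRUE)) {
    stop("schema error: telomere_ts must be positive")
  }
  invisible(cohort)
}

#' Read a cohort table
#'
#' Reads a participant-level cohort from CSV (the canonical interchange
#' format, documented header) or from SAS transport (XPT) files with a
#' variable-name map. The table is validated against the fixed schema.
#'
#' @param path file path; for `format = "xpt"` a character vector of one
#'   or more transport files merged on the mapped `participant_id`.
#' @param format `"csv"` or `"xpt"`.
#' @param schema_map named character vector for XPT input mapping source
#'   variable names to cohort column names,
#'   e.g. `c(SEQN = "participant_id", URXUCD = "metal_cd", ...)`.
#' @return a validated cohort `data.frame`.
#' @export
read_cohort <- function(path, format = c("csv", "xpt"), schema_map = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    cohort <- read.csv(path, stringsAsFactors = FALSE)
  } else {
    if (is.null(schema_map)) stop("xpt input requires a schema_map")
    parts <- lapply(path, function(p) {
      df <- foreign::read.xport(p)
      names(df) <- toupper(names(df))
      known <- intersect(names(df), toupper(names(schema_map)))
      df <- df[, known, drop = FALSE]
      names(df) <- unname(schema_map[match(names(df), toupper(names(schema_map)))])
      df
    })
    cohort <- Reduce(function(a, b) merge(a, b, by = "participant_id"), parts)
  }
  validate_cohort(cohort)
  cohort
}

#' Write a cohort table as CSV
#'
#' @param cohort cohort `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' Participant exclusion cascade
#'
#' Applies the study's exclusion rules in order: drop participants with
#' any of the nine urinary metals missing, then those with missing
#' urinary creatinine. Returns the retained cohort plus a chained
#' exclusion log (one row per stage, `n_after` of each stage equal to
#' `n_before` of the next).
#'
#' @param cohort validated cohort `data.frame`.
#' @return list with `cohort` and `log` (a `data.frame` with columns
#'   `stage`, `n_before`, `n_excluded`, `n_after`, `reason`).
#' @export
apply_exclusions <- function(cohort) {
  stages <- list(
    list(stage = "metals",
         rule = function(d) complete.cases(d[, metal_columns()]),
         reason = "missing one or more of the 9 urinary metals"),
    list(stage = "creatinine",
         rule = function(d) !is.na(d$creatinine),
         reason = "missing urinary creatinine"))
  log <- data.frame(stage = character(0), n_before = integer(0),
                    n_excluded = integer(0), n_after = integer(0),
                    reason = character(0), stringsAsFactors = FALSE)
  for (st in stages) {
    n_before <- nrow(cohort)
    cohort <- cohort[st$rule(cohort), , drop = FALSE]
    log <- rbind(log, data.frame(stage = st$stage, n_before = n_before,
                                 n_excluded = n_before - nrow(cohort),
                                 n_after = nrow(cohort), reason = st$reason,
                                 stringsAsFactors = FALSE))
  }
  if (nrow(cohort) == 0) stop("all participants excluded")
  rownames(cohort) <- NULL
  list(cohort = cohort, log = log)
}
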
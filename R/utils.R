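#' Weighted quantiles
#'
#' Quantiles of a sample under observation weights, defined as the smallest
#' observed value whose cumulative weight share reaches the target
#' probability. With unit weights this reduces to a type-1 sample quantile.
#'
#' @param x numeric vector.
#' @param w positive weights, same length as `x`.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w > 0), all(probs >= 0 & probs <= 1))
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p - 1e-12)[1]], numeric(1))
}

# internal: named metal identifiers used throughout
metal_names <- function() c("ba", "cd", "co", "cs", "mo", "pb", "sb", "tl", "tu")

metal_columns <- function() paste0("metal_", metal_names())

kdm_biomarker_columns <- function() {
  paste0("kdm_", c("lncrp", "creatinine", "hba1c", "albumin",
                   "totchol", "bun", "alp", "sbp"))
}

pheno_biomarker_columns <- function() {
  paste0("pheno_", c("albumin", "creatinine", "glucose", "lncrp",
                     "lymph_pct", "mcv", "rdw", "alp", "wbc"))
}

covariate_columns <- function() {
  c("age", "sex", "race_ethnicity", "education", "marital_status",
    "physical_activity", "alcohol", "bmi", "pir", "cotinine")
}

#' Default adjustment covariate set
#'
#' The standard multivariable adjustment set for the OA models: dichotomized
#' age (<60 / >=60 years), sex, race/ethnicity, education, family
#' income-to-poverty ratio, marital status, BMI, physical activity, drinking
#' status, and serum cotinine. Education can be dropped via
#' `include_education = FALSE` for sensitivity fits.
#'
#' @param include_education logical; keep education in the set.
#' @return character vector of cohort column names.
#' @export
oa_covariates <- function(include_education = TRUE) {
  out <- c("age_group", "sex", "race_ethnicity", "education", "pir",
           "marital_status", "bmi", "physical_activity", "alcohol", "cotinine")
  if (!include_education) out <- setdiff(out, "education")
  out
}

# internal: coerce categorical covariates to factors and add age_group
prepare_model_frame <- function(data, columns) {
  if ("age_group" %in% columns && !"age_group" %in% names(data)) {
    data$age_group <- ifelse(data$age >= 60, ">=60", "<60")
  }
  missing_cols <- setdiff(columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing model columns: ", paste(missing_cols, collapse = ", "))
  }
  for (cl in columns) {
    if (is.character(data[[cl]])) data[[cl]] <- factor(data[[cl]])
  }
  data
}

`%||%` <- function(a, b) if (is.null(a)) b else a
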
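#' Creatinine correction of urinary concentrations
#'
#' Divides a urinary analyte concentration (ug/L) by urinary creatinine
#' expressed in g/L (input in mg/dL, so g/L = mg/dL * 0.01), yielding
#' micrograms per gram creatinine.
#'
#' @param metal_ugL analyte concentration(s), ug/L.
#' @param creatinine_mgdL urinary creatinine, mg/dL; must be > 0.
#' @return concentration in ug/g creatinine.
#' @examples
#' creatinine_correct(1, 100) # 1 ug/g
#' @export
creatinine_correct <- function(metal_ugL, creatinine_mgdL) {
  if (any(creatinine_mgdL <= 0, na.rm = TRUE)) {
    stop("data error: non-positive urinary creatinine; exclude the participant")
  }
  metal_ugL / (creatinine_mgdL * 0.01)
}

#' Quartile encoding of an exposure
#'
#' Cuts a continuous exposure into quartiles Q1-Q4 at the (optionally
#' survey-weighted) 25th/50th/75th percentiles of the analysis sample,
#' using intervals (-Inf, c1], (c1, c2], (c2, c3], (c3, Inf).
#'
#' @param values numeric exposure vector with at least 8 distinct values.
#' @param weights optional positive weights for weighted percentiles.
#' @return list of class `exposure_encoding` with `quartile` (ordered
#'   factor Q1-Q4), `score` (integer 1-4), and `cutpoints`.
#' @export
quartile_encode <- function(values, weights = NULL) {
  values <- as.numeric(values)
  if (anyNA(values)) stop("quartile_encode requires complete values")
  if (length(unique(values)) < 8) {
    stop("quartile encoding needs at least 8 distinct values")
  }
  probs <- c(0.25, 0.50, 0.75)
  cut_pts <- if (is.null(weights)) {
    unname(quantile(values, probs))
  } else {
    weighted_quantile(values, weights, probs)
  }
  if (any(diff(cut_pts) <= 0)) {
    stop("tied quartile cutpoints collapse a quartile; ",
         "consider encoding ranks before quartiling")
  }
  score <- cut(values, breaks = c(-Inf, cut_pts, Inf), labels = FALSE,
               right = TRUE)
  if (any(tabulate(score, 4) == 0)) {
    stop("a quartile is empty on the defining sample; ",
         "consider encoding ranks before quartiling")
  }
  structure(list(quartile = factor(paste0("Q", score),
                                   levels = paste0("Q", 1:4)),
                 score = as.integer(score),
                 cutpoints = cut_pts),
            class = "exposure_encoding")
}

#' Add creatinine-corrected and Ln-transformed exposure columns
#'
#' For each of the nine metals, appends `cc_<metal>` (ug/g creatinine) and
#' `ln_<metal>` (Ln of the creatinine-corrected concentration) columns.
#'
#' @param cohort cohort `data.frame` with `metal_*` (ug/L) and
#'   `creatinine` (mg/dL) columns.
#' @return cohort with 18 exposure columns appended.
#' @export
add_exposure_columns <- function(cohort) {
  for (m in metal_names()) {
    cc <- creatinine_correct(cohort[[paste0("metal_", m)]], cohort$creatinine)
    cohort[[paste0("cc_", m)]] <- cc
    cohort[[paste0("ln_", m)]] <- log(cc)
  }
  cohort
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, capped at 1.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Pearson correlation matrix of Ln-transformed metals
#'
#' @param ln_metals numeric matrix/data.frame (rows = participants,
#'   columns = Ln metals), at least 3 rows.
#' @return symmetric correlation matrix with unit diagonal; columns with
#'   zero variance produce `NA` entries and a warning.
#' @export
pearson_correlation_matrix <- function(ln_metals) {
  x <- as.matrix(ln_metals)
  if (nrow(x) < 3) stop("correlation requires n >= 3")
  zero_var <- apply(x, 2, var) == 0
  if (any(zero_var)) {
    warning("zero-variance column(s): ",
            paste(colnames(x)[zero_var], collapse = ", "),
            "; correlations undefined (NA)")
  }
  suppressWarnings(r <- cor(x))
  diag(r) <- 1
  r
}

#' Impute missing covariates
#'
#' Missing categorical covariates become an explicit `"missing"` level;
#' missing continuous covariates are imputed with the median of the
#' observed values. A per-column imputation log is emitted as a message.
#'
#' @param cohort cohort `data.frame`.
#' @param columns covariate columns to process; default the standard
#'   adjustment covariates present in the cohort.
#' @return cohort with imputed covariates.
#' @export
impute_covariates <- function(cohort, columns = intersect(covariate_columns(),
                                                          names(cohort))) {
  for (cl in columns) {
    v <- cohort[[cl]]
    n_miss <- sum(is.na(v))
    if (n_miss == length(v)) stop("column entirely missing: ", cl)
    if (n_miss == 0) next
    if (is.numeric(v)) {
      med <- median(v, na.rm = TRUE)
      v[is.na(v)] <- med
      message(sprintf("imputed %d missing '%s' values with median %.4g",
                      n_miss, cl, med))
    } else {
      v <- as.character(v)
      v[is.na(v)] <- "missing"
      message(sprintf("coded %d missing '%s' values as level 'missing'",
                      n_miss, cl))
    }
    cohort[[cl]] <- v
  }
  cohort
}
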
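#' Fit Klemera-Doubal biological-age parameters
#'
#' Regresses each biomarker on chronological age by ordinary least squares
#' to obtain, per biomarker j, the slope `k_j`, intercept `q_j`, root mean
#' squared error `s_j` and signed age correlation `r_j`; then computes the
#' characteristic correlation `r_char` and the age-correction variance
#' `s_BA^2` from the uncorrected estimator's residuals on the training
#' sample. `s_BA^2` can be negative in small or weakly age-structured
#' samples; it is clamped to a positive floor (default
#' `1e-4 * (age range)^2`) with a warning, since the corrected estimator
#' requires positivity.
#'
#' @param training_biomarkers numeric matrix or data.frame, one column per
#'   biomarker, one row per training participant.
#' @param chronological_age numeric vector of ages in years.
#' @param s_ba2_floor positive clamp floor for `s_BA^2`; `NULL` for the
#'   default `1e-4 * (max(age) - min(age))^2`; `0` disables clamping.
#' @return an object of class `kdm_parameters` with elements `biomarkers`,
#'   `k`, `q`, `s`, `r`, `r_char`, `s_ba2`, `s_ba2_raw`, `clamped`,
#'   `ca_min`, `ca_max`, `m`, `n`.
#' @seealso [compute_biological_age()]
#' @export
fit_kdm <- function(training_biomarkers, chronological_age, s_ba2_floor = NULL) {
  x <- as.matrix(training_biomarkers)
  ca <- as.numeric(chronological_age)
  n <- length(ca)
  if (nrow(x) != n) stop("biomarker rows must match chronological_age length")
  if (n < 30) stop("fit error: KDM training requires n >= 30")
  if (anyNA(x) || anyNA(ca)) stop("fit error: missing values; impute first")
  if (max(ca) - min(ca) < 1e-8 || var(ca) == 0) {
    stop("fit error: chronological age has no variance in the training sample")
  }
  keep <- apply(x, 2, var) > 0
  if (!all(keep)) {
    warning("dropping zero-variance biomarker(s): ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  m <- ncol(x)
  if (m < 1) stop("fit error: no usable biomarkers")

  ca_c <- ca - mean(ca)
  sxx <- sum(ca_c^2)
  k <- q <- s <- r <- numeric(m)
  for (j in seq_len(m)) {
    xj <- x[, j]
    k[j] <- sum(ca_c * (xj - mean(xj))) / sxx
    q[j] <- mean(xj) - k[j] * mean(ca)
    resid <- xj - (q[j] + k[j] * ca)
    s[j] <- sqrt(sum(resid^2) / n) # root mean squared error
    r[j] <- cor(xj, ca)
  }
  names(k) <- names(q) <- names(s) <- names(r) <- colnames(x)

  # cap |r| just below 1 so near-deterministic biomarkers keep the
  # characteristic-correlation terms finite
  r_c <- sign(r) * pmin(abs(r), 1 - 1e-9)
  r_char <- sum(r_c^2 / sqrt(1 - r_c^2)) / sum(r_c / sqrt(1 - r_c^2))
  ba_e <- kdm_ba_e(x, k, q, s)
  d <- ba_e - ca
  ca_min <- min(ca); ca_max <- max(ca)
  s_ba2_raw <- mean((d - mean(d))^2) -
    ((1 - r_char^2) / r_char^2) * ((ca_max - ca_min)^2 / (12 * m))
  floor_val <- if (is.null(s_ba2_floor)) 1e-4 * (ca_max - ca_min)^2 else s_ba2_floor
  clamped <- s_ba2_raw < floor_val
  s_ba2 <- if (clamped) floor_val else s_ba2_raw
  if (clamped && floor_val > 0) {
    warning(sprintf("s_BA^2 = %.4g below floor; clamped to %.4g",
                    s_ba2_raw, floor_val))
  }
  structure(list(biomarkers = colnames(x), k = k, q = q, s = s, r = r,
                 r_char = r_char, s_ba2 = s_ba2, s_ba2_raw = s_ba2_raw,
                 clamped = clamped, ca_min = ca_min, ca_max = ca_max,
                 m = m, n = n),
            class = "kdm_parameters")
}

# internal: uncorrected Klemera-Doubal estimator
kdm_ba_e <- function(x, k, q, s) {
  num <- drop(sweep(as.matrix(x), 2, q) %*% (k / s^2))
  num / sum((k / s)^2)
}

#' Klemera-Doubal biological age (chronological-age-corrected estimator)
#'
#' Evaluates the corrected Klemera-Doubal estimator: a precision-weighted
#' combination of the biomarker-only estimate and chronological age,
#' weighting chronological age by `1/s_BA^2`. When `s_BA^2` is not
#' positive the function falls back to the uncorrected biomarker-only
#' estimate with a warning.
#'
#' @param params a fitted [fit_kdm()] object.
#' @param biomarkers numeric vector (one participant) or matrix/data.frame
#'   (rows = participants) with the fitted biomarker columns.
#' @param ca chronological age(s) in years.
#' @return biological age in years (vector).
#' @export
compute_biological_age <- function(params, biomarkers, ca) {
  stopifnot(inherits(params, "kdm_parameters"))
  x <- if (is.null(dim(biomarkers))) matrix(biomarkers, nrow = 1) else as.matrix(biomarkers)
  if (!is.null(colnames(x)) && all(params$biomarkers %in% colnames(x))) {
    x <- x[, params$biomarkers, drop = FALSE]
  }
  if (ncol(x) != params$m) stop("biomarker columns do not match fitted parameters")
  if (anyNA(x) || anyNA(ca)) stop("missing biomarker or age values")
  k <- params$k; q <- params$q; s <- params$s
  if (params$s_ba2 <= 0) {
    warning("s_BA^2 <= 0; falling back to the uncorrected biomarker-only estimate")
    return(kdm_ba_e(x, k, q, s))
  }
  num <- drop(sweep(x, 2, q) %*% (k / s^2)) + ca / params$s_ba2
  den <- sum((k / s)^2) + 1 / params$s_ba2
  num / den
}

#' Phenotypic age from nine clinical biomarkers
#'
#' Closed-form phenotypic age in years from a 10-year mortality-risk score
#' built on nine biomarkers plus chronological age. The linear predictor is
#' \deqn{xb = -19.907 - 0.0336\,alb + 0.0095\,creat + 0.1953\,gluc +
#'  0.0954\,LnCRP - 0.0120\,lymph + 0.0268\,MCV + 0.3306\,RDW +
#'  0.00188\,ALP + 0.0554\,WBC + 0.0804\,CA,}
#' mapped through the Gompertz-based transform with constants 141.50,
#' 0.00553, 1.51714, 0.0076927 and 0.09165. Assumed units (printed in all
#' logs): albumin g/L, creatinine umol/L, glucose mmol/L, CRP stored as
#' Ln(mg/dL), lymphocytes %, MCV fL, RDW %, ALP U/L, WBC 10^9/L.
#'
#' @param biomarkers_pheno numeric 9-vector or matrix/data.frame with
#'   columns in the order albumin, creatinine, glucose, Ln-CRP, lymphocyte
#'   percent, mean cell volume, red-cell distribution width, alkaline
#'   phosphatase, white-cell count (the `pheno_*` cohort columns).
#' @param ca chronological age(s) in years.
#' @return phenotypic age in years (vector).
#' @export
compute_phenotypic_age <- function(biomarkers_pheno, ca) {
  x <- if (is.null(dim(biomarkers_pheno))) {
    matrix(biomarkers_pheno, nrow = 1)
  } else {
    as.matrix(biomarkers_pheno)
  }
  if (ncol(x) != 9) stop("phenotypic age needs exactly 9 biomarkers")
  if (!is.null(colnames(x)) && all(pheno_biomarker_columns() %in% colnames(x))) {
    x <- x[, pheno_biomarker_columns(), drop = FALSE]
  }
  cf <- c(-0.0336, 0.0095, 0.1953, 0.0954, -0.0120,
          0.0268, 0.3306, 0.00188, 0.0554)
  xb <- -19.907 + drop(x %*% cf) + 0.0804 * ca
  # log of the 10-year survival term, written directly (the printed
  # Ln(exp(.)) pair collapses analytically; avoids underflow at extreme xb)
  log_surv <- -1.51714 * exp(xb) / 0.0076927
  pheno <- 141.50 + log(-0.00553 * log_surv) / 0.09165
  bad <- which(!is.finite(pheno))
  if (length(bad) > 0) {
    stop("data error: non-finite phenotypic age for participant(s) ",
         paste(bad, collapse = ", "))
  }
  pheno
}

#' Attach biological and phenotypic age to a cohort
#'
#' Scores every participant with the Klemera-Doubal biological age and the
#' phenotypic age, appending `biological_age` and `phenotypic_age` columns;
#' the telomere T/S ratio is validated and passed through. If no fitted
#' parameters are supplied, KDM parameters are fitted on the cohort itself
#' (the analysis sample is the training sample).
#'
#' @param cohort a validated cohort `data.frame`.
#' @param params optional externally fitted [fit_kdm()] parameters.
#' @param quiet suppress the per-column summary message.
#' @return the cohort with `biological_age` and `phenotypic_age` appended;
#'   the fitted parameters are attached as attribute `"kdm_parameters"`.
#' @export
attach_aging_markers <- function(cohort, params = NULL, quiet = FALSE) {
  if (nrow(cohort) == 0) stop("validation error: empty cohort")
  need <- c(kdm_biomarker_columns(), pheno_biomarker_columns(), "age", "telomere_ts")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0) {
    stop("missing biomarker columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(cohort$telomere_ts <= 0, na.rm = TRUE)) {
    stop("validation error: telomere_ts must be positive")
  }
  if (is.null(params)) {
    params <- fit_kdm(cohort[, kdm_biomarker_columns()], cohort$age)
  }
  cohort$biological_age <- compute_biological_age(
    params, cohort[, params$biomarkers], cohort$age)
  cohort$phenotypic_age <- compute_phenotypic_age(
    cohort[, pheno_biomarker_columns()], cohort$age)
  if (!quiet) {
    message(sprintf(
      "aging markers attached (phenotypic-age units: albumin g/L, creatinine umol/L, glucose mmol/L, CRP Ln(mg/dL), lymph %%, MCV fL, RDW %%, ALP U/L, WBC 10^9/L): biological_age mean %.1f, phenotypic_age mean %.1f, telomere_ts mean %.2f",
      mean(cohort$biological_age), mean(cohort$phenotypic_age),
      mean(cohort$telomere_ts)))
  }
  attr(cohort, "kdm_parameters") <- params
  cohort
}

#' Serialize fitted Klemera-Doubal parameters
#'
#' Writes/reads fitted parameters as YAML so a training fit can be reused
#' across runs or supplied externally.
#'
#' @param params a `kdm_parameters` object.
#' @param path file path.
#' @return `write_kdm_parameters` returns `path` invisibly;
#'   `read_kdm_parameters` returns a `kdm_parameters` object.
#' @export
write_kdm_parameters <- function(params, path) {
  stopifnot(inherits(params, "kdm_parameters"))
  obj <- unclass(params)
  obj$k <- as.list(params$k); obj$q <- as.list(params$q)
  obj$s <- as.list(params$s); obj$r <- as.list(params$r)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_kdm_parameters
#' @export
read_kdm_parameters <- function(path) {
  obj <- yaml::read_yaml(path)
  for (fld in c("k", "q", "s", "r")) obj[[fld]] <- unlist(obj[[fld]])
  obj$biomarkers <- as.character(obj$biomarkers)
  structure(obj, class = "kdm_parameters")
}

#' @export
print.kdm_parameters <- function(x, ...) {
  cat(sprintf("Klemera-Doubal parameters: %d biomarkers, n = %d, age %.0f-%.0f\n",
              x$m, x$n, x$ca_min, x$ca_max))
  cat(sprintf("  r_char = %.3f, s_BA^2 = %.2f%s\n", x$r_char, x$s_ba2,
              if (x$clamped) " (clamped)" else ""))
  print(data.frame(k = x$k, q = x$q, s = x$s, r = x$r), digits = 3)
  invisible(x)
}
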
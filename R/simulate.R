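#' Default Ln-scale correlation structure of the nine urinary metals
#'
#' Pairwise correlation matrix of Ln-transformed urinary metal
#' concentrations used by the default simulation configuration. The three
#' moderate pairs observed in U.S. survey data are encoded explicitly
#' (Cs-Tl 0.58, Ba-Co 0.41, Cd-Pb 0.40); all remaining pairs share a weak
#' background correlation of 0.15.
#'
#' @return a 9x9 symmetric positive-definite correlation matrix with
#'   dimnames `ba, cd, co, cs, mo, pb, sb, tl, tu`.
#' @export
default_metal_correlation <- function() {
  nm <- metal_names()
  r <- matrix(0.15, 9, 9, dimnames = list(nm, nm))
  diag(r) <- 1
  r["cs", "tl"] <- r["tl", "cs"] <- 0.58
  r["ba", "co"] <- r["co", "ba"] <- 0.41
  r["cd", "pb"] <- r["pb", "cd"] <- 0.40
  r
}

# internal: default Ln-scale means (Ln ug/L) and SDs, roughly geometric
# means of spot-urine metals in U.S. adults
default_ln_metal_mean <- function() {
  c(ba = 0.18, cd = -1.40, co = -1.05, cs = 1.50, mo = 3.80,
    pb = -0.36, sb = -2.80, tl = -1.80, tu = -4.90)
}

default_ln_metal_sd <- function() {
  c(ba = 0.90, cd = 0.90, co = 0.70, cs = 0.60, mo = 0.70,
    pb = 0.80, sb = 0.80, tl = 0.70, tu = 1.10)
}

#' Simulation configuration for synthetic survey-like cohorts
#'
#' Builds and validates the configuration of the synthetic cohort
#' generator. Defaults encode the study conditions the package is tested
#' under: nine log-normal correlated urinary metals with realistic
#' detection limits, an adverse Cd/Co/Cs/Pb/Tl effect on a latent
#' biological-aging mediator, a smaller direct Cd/Co/Cs effect on OA, a
#' metal-to-telomere path for Cd and Cs, and an aging-to-OA log-odds slope
#' of 0.055 per year (odds ratio ~1.06/year).
#'
#' @param n_participants cohort size (>= 50).
#' @param seed integer seed; fully determines the generated cohort.
#' @param ln_metal_mean named 9-vector of Ln-scale means (Ln ug/L).
#' @param ln_metal_cov 9x9 symmetric positive-semidefinite Ln-scale
#'   covariance matrix.
#' @param lod named 9-vector of detection limits (ug/L), all > 0.
#' @param beta_metal_to_aging named 9-vector: years of mediator age per
#'   Ln-unit of each metal.
#' @param beta_metal_to_telomere named 9-vector: T/S units per Ln-unit.
#' @param beta_telomere_to_aging years of mediator age per T/S unit of
#'   telomere deviation (negative: shorter telomeres, older).
#' @param beta_aging_to_oa log-odds of OA per year of mediator age.
#' @param beta_metal_direct named 9-vector: direct log-odds of OA per
#'   Ln-unit of each metal (not through aging).
#' @param covariate_effects named list; each element is
#'   `c(mediator = ..., outcome = ...)` for the internal numeric features
#'   `female`, `bmi_c` (BMI centered at 28) and `activity_moderate`.
#' @param baseline_oa_logit intercept of the OA logit at reference levels.
#' @param aging_noise_sd SD (years) of the latent aging acceleration noise.
#' @param weight_distribution `c(shape, rate)` of the gamma distribution
#'   survey weights are drawn from (i.i.d., independent of the outcome).
#' @param missing_rates optional named vector of per-column
#'   missing-completely-at-random rates in `[0, 1)`; default none.
#' @return an object of class `simulation_config`.
#' @seealso [generate_cohort()]
#' @export
simulation_config <- function(n_participants = 5000,
                              seed = 1L,
                              ln_metal_mean = default_ln_metal_mean(),
                              ln_metal_cov = NULL,
                              lod = NULL,
                              beta_metal_to_aging = c(ba = 0, cd = 2.2, co = 1.0,
                                                      cs = 0.8, mo = 0, pb = 0.6,
                                                      sb = 0, tl = 0.3, tu = 0),
                              beta_metal_to_telomere = c(ba = 0, cd = -0.02, co = 0,
                                                         cs = -0.015, mo = 0, pb = 0,
                                                         sb = 0, tl = 0, tu = 0),
                              beta_telomere_to_aging = -4,
                              beta_aging_to_oa = 0.055,
                              beta_metal_direct = c(ba = 0, cd = 0.05, co = 0.08,
                                                    cs = 0.07, mo = 0, pb = 0,
                                                    sb = 0, tl = 0, tu = 0),
                              covariate_effects = list(
                                female = c(mediator = 0, outcome = 0.45),
                                bmi_c = c(mediator = 0.08, outcome = 0.03)),
                              baseline_oa_logit = -2.6,
                              aging_noise_sd = 3.5,
                              weight_distribution = c(shape = 4, rate = 4),
                              missing_rates = NULL) {
  nm <- metal_names()
  if (is.null(ln_metal_cov)) {
    s <- default_ln_metal_sd()
    ln_metal_cov <- diag(s) %*% default_metal_correlation() %*% diag(s)
    dimnames(ln_metal_cov) <- list(nm, nm)
  }
  if (is.null(lod)) {
    s <- sqrt(diag(ln_metal_cov))
    lod <- exp(ln_metal_mean - 1.7 * s)
  }
  cfg <- list(n_participants = as.integer(n_participants), seed = as.integer(seed),
              metal_names = nm, ln_metal_mean = ln_metal_mean,
              ln_metal_cov = ln_metal_cov, lod = lod,
              beta_metal_to_aging = beta_metal_to_aging,
              beta_metal_to_telomere = beta_metal_to_telomere,
              beta_telomere_to_aging = beta_telomere_to_aging,
              beta_aging_to_oa = beta_aging_to_oa,
              beta_metal_direct = beta_metal_direct,
              covariate_effects = covariate_effects,
              baseline_oa_logit = baseline_oa_logit,
              aging_noise_sd = aging_noise_sd,
              weight_distribution = weight_distribution,
              missing_rates = missing_rates)
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  nm <- metal_names()
  if (cfg$n_participants < 50) {
    stop("config error: n_participants must be >= 50 (downstream fits unidentifiable)")
  }
  for (fld in c("ln_metal_mean", "lod", "beta_metal_to_aging",
                "beta_metal_to_telomere", "beta_metal_direct")) {
    v <- cfg[[fld]]
    if (length(v) != 9 || !all(nm %in% names(v))) {
      stop("config error: '", fld, "' must be a named 9-vector over ",
           paste(nm, collapse = ", "))
    }
  }
  if (any(cfg$lod <= 0)) stop("config error: all LODs must be strictly positive")
  cv <- cfg$ln_metal_cov
  if (!isTRUE(all.equal(cv, t(cv), tolerance = 1e-8))) {
    stop("config error: ln_metal_cov must be symmetric")
  }
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(abs(ev)))) {
    stop("config error: ln_metal_cov is not positive semidefinite")
  }
  if (!is.null(cfg$missing_rates) &&
      (any(cfg$missing_rates < 0) || any(cfg$missing_rates >= 1))) {
    stop("config error: missing_rates must lie in [0, 1)")
  }
  invisible(cfg)
}

#' Substitute values below the limit of detection
#'
#' Replaces any concentration strictly below its limit of detection (LOD)
#' by LOD divided by the square root of two; values at or above the LOD
#' are untouched. Works on a vector with one LOD, a vector with per-element
#' LODs, or a matrix with per-column LODs. When given a matrix the
#' per-metal detection rate (share of values at or above the LOD) is
#' attached as attribute `"detection_rate"`.
#'
#' @param values nonnegative concentrations (ug/L).
#' @param lod positive detection limit(s) (ug/L).
#' @return censored values, same shape as `values`.
#' @examples
#' censor_below_lod(c(0.0, 0.2, 0.05), lod = 0.1)
#' @export
censor_below_lod <- function(values, lod) {
  if (any(lod <= 0)) stop("lod must be strictly positive")
  if (any(values < 0, na.rm = TRUE)) {
    stop("data error: negative concentration supplied to censor_below_lod")
  }
  if (is.matrix(values) || is.data.frame(values)) {
    values <- as.matrix(values)
    if (length(lod) == 1) lod <- rep(lod, ncol(values))
    stopifnot(length(lod) == ncol(values))
    below <- sweep(values, 2, lod, `<`)
    out <- values
    for (j in seq_len(ncol(values))) {
      out[below[, j], j] <- lod[j] / sqrt(2)
    }
    attr(out, "detection_rate") <- 1 - colMeans(below, na.rm = TRUE)
    return(out)
  }
  if (length(lod) == 1) lod <- rep(lod, length(values))
  stopifnot(length(lod) == length(values))
  ifelse(values < lod, lod / sqrt(2), values)
}

#' Generate a synthetic survey-like cohort
#'
#' Draws a cohort with known ground truth under the configured structural
#' model. Ln metals are multivariate normal with the configured covariance;
#' raw concentrations are left-censored at the LOD (LOD/sqrt(2)
#' substitution). A latent mediator age is built as chronological age plus
#' an acceleration driven by Ln metals, the telomere path, covariates and
#' Gaussian noise; OA is Bernoulli on the configured logit. Biomarker
#' panels are generated by inverting the two aging scores around the latent
#' mediator age so that downstream scoring recovers it up to noise. Latent
#' truth is kept in `truth_*` columns.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` cohort (one row per participant) with metals,
#'   creatinine, covariates, both biomarker panels, telomere T/S, OA status,
#'   survey weights and truth columns. Per-metal detection rates are
#'   attached as attribute `"detection_rate"`.
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  nm <- config$metal_names

  # covariates (marginals loosely matching U.S. adult survey composition)
  age <- runif(n, 20, 80)
  sex <- ifelse(runif(n) < 0.51, "female", "male")
  race_ethnicity <- sample(c("mexican_american", "other_hispanic",
                             "nh_white", "nh_black", "other"),
                           n, replace = TRUE,
                           prob = c(0.18, 0.08, 0.44, 0.21, 0.09))
  education <- sample(c("under_hs", "hs", "above_hs"), n, replace = TRUE,
                      prob = c(0.26, 0.23, 0.51))
  marital_status <- sample(c("married", "wid_div_sep", "never"), n,
                           replace = TRUE, prob = c(0.61, 0.19, 0.20))
  physical_activity <- sample(c("moderate", "vigorous"), n, replace = TRUE,
                              prob = c(0.65, 0.35))
  alcohol <- sample(c("never", "ever"), n, replace = TRUE, prob = c(0.71, 0.29))
  bmi <- pmax(15, rnorm(n, 28.4, 5.5))
  pir <- pmin(5, pmax(0, rnorm(n, 3.0, 1.6)))
  cotinine <- rlnorm(n, meanlog = 0.5, sdlog = 2.2)

  # Ln-scale metals: the configured covariance is the dilution-free
  # (creatinine-corrected) exposure scale; spot-urine ug/L values add a
  # shared Ln-dilution term (urinary creatinine), which creatinine
  # correction later removes, so analysis-sample Ln correlations converge
  # to the configured matrix
  ln_true <- MASS::mvrnorm(n, mu = config$ln_metal_mean[nm],
                           Sigma = config$ln_metal_cov[nm, nm])
  colnames(ln_true) <- nm
  creatinine <- rlnorm(n, meanlog = log(110), sdlog = 0.45) # mg/dL
  ln_dilution <- log(creatinine * 0.01)                     # Ln g/L
  metals_true <- exp(ln_true + ln_dilution)                 # ug/L
  metals_raw <- censor_below_lod(metals_true, config$lod[nm])
  detection <- attr(metals_raw, "detection_rate")

  # internal numeric covariate features available for structural effects
  features <- cbind(female = as.numeric(sex == "female"),
                    bmi_c = bmi - 28,
                    activity_moderate = as.numeric(physical_activity == "moderate"))
  med_shift <- rep(0, n)
  out_shift <- rep(0, n)
  for (fn in names(config$covariate_effects)) {
    eff <- config$covariate_effects[[fn]]
    med_shift <- med_shift + features[, fn] * eff[["mediator"]]
    out_shift <- out_shift + features[, fn] * eff[["outcome"]]
  }

  ln_centered <- sweep(ln_true, 2, config$ln_metal_mean[nm])

  # telomere T/S: declines with age, shortened by the configured metals
  ts_mu <- 1.30 - 0.004 * age +
    drop(ln_centered %*% config$beta_metal_to_telomere[nm])
  telomere_ts <- pmax(0.05, ts_mu + rnorm(n, 0, 0.12))
  ts_dev <- telomere_ts - (1.30 - 0.004 * age) # metal + noise part only

  # latent aging acceleration and mediator age
  accel <- drop(ln_centered %*% config$beta_metal_to_aging[nm]) +
    config$beta_telomere_to_aging * ts_dev +
    med_shift + rnorm(n, 0, config$aging_noise_sd)
  mediator_age <- age + accel

  # OA outcome
  oa_logit <- config$baseline_oa_logit +
    config$beta_aging_to_oa * (mediator_age - 50) +
    drop(ln_centered %*% config$beta_metal_direct[nm]) +
    out_shift
  oa_status <- rbinom(n, 1, plogis(oa_logit))

  kdm <- simulate_kdm_panel(mediator_age)
  pheno <- simulate_pheno_panel(mediator_age, age)

  survey_weight <- rgamma(n, shape = config$weight_distribution[["shape"]],
                          rate = config$weight_distribution[["rate"]])

  cohort <- data.frame(participant_id = sprintf("P%06d", seq_len(n)),
                       metals_raw, creatinine = creatinine,
                       oa_status = oa_status,
                       age = age, sex = sex, race_ethnicity = race_ethnicity,
                       education = education, marital_status = marital_status,
                       physical_activity = physical_activity, alcohol = alcohol,
                       bmi = bmi, pir = pir, cotinine = cotinine,
                       kdm, pheno, telomere_ts = telomere_ts,
                       survey_weight = survey_weight,
                       truth_mediator_age = mediator_age,
                       truth_accel = accel,
                       truth_oa_logit = oa_logit,
                       stringsAsFactors = FALSE)
  names(cohort)[seq_along(nm) + 1] <- metal_columns()

  if (!is.null(config$missing_rates)) {
    for (cl in names(config$missing_rates)) {
      miss <- runif(n) < config$missing_rates[[cl]]
      cohort[[cl]][miss] <- NA
    }
  }
  attr(cohort, "detection_rate") <- detection
  cohort
}

# internal: population regression constants of the 8 Klemera-Doubal panel
# biomarkers on mediator age (slope k, intercept q, residual SD s)
kdm_panel_constants <- function() {
  data.frame(
    biomarker = kdm_biomarker_columns(),
    q = c(-2.60, 70, 4.8, 47, 150, 10, 60, 95),
    k = c(0.035, 0.60, 0.035, -0.15, 1.20, 0.18, 0.50, 0.90),
    s = c(0.90, 14, 0.45, 2.5, 30, 3.0, 16, 10),
    stringsAsFactors = FALSE)
}

# internal: KDM biomarkers linear in mediator age plus independent noise
simulate_kdm_panel <- function(mediator_age) {
  cst <- kdm_panel_constants()
  n <- length(mediator_age)
  out <- vapply(seq_len(nrow(cst)), function(j) {
    cst$q[j] + cst$k[j] * mediator_age + rnorm(n, 0, cst$s[j])
  }, numeric(n))
  colnames(out) <- cst$biomarker
  as.data.frame(out)
}

# internal: phenotypic-age panel built by inversion -- eight biomarkers are
# drawn around realistic means, then glucose closes the linear-predictor gap
# so the phenotypic-age closed form lands on mediator age plus noise
simulate_pheno_panel <- function(mediator_age, age) {
  n <- length(mediator_age)
  albumin <- rnorm(n, 43, 2.5)        # g/L
  creatinine <- rnorm(n, 80, 12)      # umol/L
  lncrp <- rnorm(n, -1.9, 0.8)        # Ln(mg/dL)
  lymph_pct <- rnorm(n, 30, 7)        # %
  mcv <- rnorm(n, 90, 5)              # fL
  rdw <- rnorm(n, 13, 0.8)            # %
  alp <- rnorm(n, 70, 15)             # U/L
  wbc <- rnorm(n, 7, 1.7)             # 10^9/L
  xb_target <- 0.09165 * (mediator_age - 141.50) -
    log(0.00553 * 1.51714 / 0.0076927)
  xb_partial <- -19.907 - 0.0336 * albumin + 0.0095 * creatinine +
    0.0954 * lncrp - 0.0120 * lymph_pct + 0.0268 * mcv + 0.3306 * rdw +
    0.00188 * alp + 0.0554 * wbc + 0.0804 * age
  glucose <- (xb_target - xb_partial) / 0.1953 + rnorm(n, 0, 0.9) # mmol/L
  out <- data.frame(albumin, creatinine, glucose, lncrp, lymph_pct,
                    mcv, rdw, alp, wbc)
  names(out) <- pheno_biomarker_columns()
  out
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  participants:", x$n_participants, " seed:", x$seed, "\n")
  cat("  metals:", paste(x$metal_names, collapse = ", "), "\n")
  act <- x$metal_names[x$beta_metal_to_aging[x$metal_names] != 0 |
                         x$beta_metal_direct[x$metal_names] != 0]
  cat("  metals with nonzero OA paths:",
      if (length(act)) paste(act, collapse = ", ") else "none", "\n")
  cat("  aging -> OA log-odds/year:", x$beta_aging_to_oa, "\n")
  invisible(x)
}
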
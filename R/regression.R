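# Single-exposure regression surfaces: metal -> OA (logistic),
# metal -> aging marker (linear), aging marker -> OA (logistic),
# quartile trend tests, and the FDR bookkeeping across metals.

# internal: one adjusted fit; term_values is numeric or a factor.
# Weighted fits use quasi-likelihood (identical point estimates) with
# heteroskedasticity-robust (HC0 sandwich) standard errors, replacing the
# survey Taylor-linearized variance; unweighted fits use model-based SEs.
fit_adjusted <- function(data, outcome, term_values, term_label, covariates,
                         weights, family = c("logistic", "linear"),
                         conf_level = 0.95) {
  family <- match.arg(family)
  data <- prepare_model_frame(data, covariates)
  df <- data.frame(.y = data[[outcome]], .term = term_values,
                   data[, covariates, drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  w <- resolve_weights(data, weights)
  keep <- complete.cases(df) & if (is.null(w)) TRUE else !is.na(w)
  df <- df[keep, , drop = FALSE]
  if (!is.null(w)) w <- w[keep]
  rhs <- paste(c(".term", sprintf("`%s`", covariates)), collapse = " + ")
  fml <- as.formula(paste(".y ~", rhs))

  if (family == "logistic") {
    if (!all(df$.y %in% c(0, 1))) stop("outcome must be binary 0/1")
    fam <- if (is.null(w)) stats::binomial() else stats::quasibinomial()
    fit <- glm(fml, data = df, family = fam, weights = w,
               control = glm.control(epsilon = 1e-12, maxit = 100))
    if (!fit$converged) stop("logistic fit did not converge for ", term_label)
    mu <- fit$fitted.values
    cf <- coef(fit)
    term_idx <- grep("^\\.term", names(cf))
    if (any(mu < 1e-8 | mu > 1 - 1e-8) && any(abs(cf[term_idx]) > 10)) {
      stop("separation detected for term ", term_label)
    }
  } else {
    fit <- lm(fml, data = df, weights = w)
  }
  vc <- if (is.null(w)) vcov(fit) else sandwich::vcovHC(fit, type = "HC0")
  cf <- coef(fit)
  term_idx <- grep("^\\.term", names(cf))
  se <- sqrt(diag(vc))[term_idx]
  est <- cf[term_idx]
  z <- qnorm(1 - (1 - conf_level) / 2)
  transf <- if (family == "logistic") exp else identity
  out <- data.frame(
    term = if (is.factor(term_values)) {
      sub("^\\.term", "", names(cf)[term_idx])
    } else {
      term_label
    },
    estimate = unname(est),
    se = unname(se),
    or_or_beta = unname(transf(est)),
    ci_low = unname(transf(est - z * se)),
    ci_high = unname(transf(est + z * se)),
    p_value = unname(2 * pnorm(-abs(est / se))),
    n_used = nrow(df),
    model_family = family,
    weighted = !is.null(w),
    stringsAsFactors = FALSE)
  attr(out, "fit") <- fit
  out
}

resolve_weights <- function(data, weights) {
  if (is.null(weights)) return(NULL)
  if (is.character(weights) && length(weights) == 1) {
    w <- data[[weights]]
    if (is.null(w)) stop("weight column not found: ", weights)
  } else {
    w <- as.numeric(weights)
  }
  if (any(w <= 0, na.rm = TRUE)) stop("weights must be positive")
  w
}

#' Multivariable logistic regression for one exposure term
#'
#' Maximum-likelihood logistic regression of a binary outcome on a single
#' exposure term plus adjustment covariates, optionally survey-weighted
#' (robust HC0 sandwich standard errors when weighted). The exposure may
#' be continuous (e.g. an Ln-transformed metal or an aging marker) or
#' quartile-encoded, in which case Q2-Q4 are contrasted against Q1 and a
#' trend test over the integer scores 1-4 is appended.
#'
#' @param data cohort `data.frame`.
#' @param outcome name of the binary 0/1 outcome column.
#' @param exposure name of the exposure column, or an
#'   [quartile_encode()] object.
#' @param covariates character vector of adjustment columns (use
#'   [oa_covariates()] for the standard set).
#' @param weights `NULL`, a weight column name, or a numeric vector.
#' @param encoding `"continuous"` or `"quartile"`.
#' @param conf_level confidence level, default 0.95.
#' @return a tidy `data.frame` of class `regression_result`, one row per
#'   term (plus `p_trend` for quartile fits).
#' @export
fit_logistic <- function(data, outcome, exposure, covariates = character(),
                         weights = NULL, encoding = c("continuous", "quartile"),
                         conf_level = 0.95) {
  fit_exposure_model(data, outcome, exposure, covariates, weights,
                     match.arg(encoding), "logistic", conf_level)
}

#' Multivariable linear regression for one exposure term
#'
#' Identity-link analogue of [fit_logistic()] for continuous responses
#' (the aging markers): coefficients are reported per Ln-unit of exposure
#' or per quartile contrast against Q1.
#'
#' @inheritParams fit_logistic
#' @param outcome name of the continuous response column.
#' @return a tidy `data.frame` of class `regression_result`.
#' @export
fit_linear <- function(data, outcome, exposure, covariates = character(),
                       weights = NULL, encoding = c("continuous", "quartile"),
                       conf_level = 0.95) {
  fit_exposure_model(data, outcome, exposure, covariates, weights,
                     match.arg(encoding), "linear", conf_level)
}

fit_exposure_model <- function(data, outcome, exposure, covariates, weights,
                               encoding, family, conf_level) {
  if (inherits(exposure, "exposure_encoding")) {
    enc <- exposure
    label <- "exposure"
    encoding <- "quartile"
  } else {
    label <- exposure
    enc <- NULL
  }
  if (encoding == "quartile") {
    if (is.null(enc)) enc <- quartile_encode(data[[exposure]])
    res <- fit_adjusted(data, outcome, enc$quartile, label, covariates,
                        weights, family, conf_level)
    res$term <- paste0(label, ":", res$term)
    tr <- trend_test_values(data, outcome, enc$score, label, covariates,
                            weights, family, conf_level)
    res$p_trend <- tr$p_trend
  } else {
    res <- fit_adjusted(data, outcome, data[[label]], label, covariates,
                        weights, family, conf_level)
    res$p_trend <- NA_real_
  }
  res$exposure <- label
  res$encoding <- encoding
  res$p_fdr <- NA_real_
  class(res) <- c("regression_result", "data.frame")
  res
}

#' Trend test across exposure quartiles
#'
#' Refits the adjusted model with the quartile factor replaced by its
#' integer score (1, 2, 3, 4) and returns the Wald test of that
#' coefficient.
#'
#' @inheritParams fit_logistic
#' @param family `"logistic"` or `"linear"`.
#' @return list with `p_trend`, `estimate`, `se`, `statistic`.
#' @export
trend_test <- function(data, outcome, exposure, covariates = character(),
                       weights = NULL, family = c("logistic", "linear"),
                       conf_level = 0.95) {
  family <- match.arg(family)
  enc <- if (inherits(exposure, "exposure_encoding")) {
    exposure
  } else {
    quartile_encode(data[[exposure]])
  }
  trend_test_values(data, outcome, enc$score, "trend", covariates, weights,
                    family, conf_level)
}

trend_test_values <- function(data, outcome, score, label, covariates,
                              weights, family, conf_level) {
  res <- fit_adjusted(data, outcome, as.numeric(score), label, covariates,
                      weights, family, conf_level)
  list(p_trend = res$p_value, estimate = res$estimate, se = res$se,
       statistic = res$estimate / res$se)
}

# internal: run continuous + quartile fits of `outcome` on each of the nine
# metals and FDR-adjust within each encoding family across the metals
sweep_metals <- function(cohort, outcome, covariates, weights, family,
                         conf_level = 0.95) {
  cohort <- add_exposure_columns_if_needed(cohort)
  rows <- list()
  for (m in metal_names()) {
    cont <- fit_exposure_model(cohort, outcome, paste0("ln_", m), covariates,
                               weights, "continuous", family, conf_level)
    quart <- fit_exposure_model(cohort, outcome, paste0("cc_", m), covariates,
                                weights, "quartile", family, conf_level)
    cont$metal <- m
    quart$metal <- m
    rows[[m]] <- rbind(cont, quart)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # FDR families per result figure: the 9 continuous p-values together,
  # and the 9 quartile trend p-values together
  is_cont <- out$encoding == "continuous"
  out$p_fdr[is_cont] <- fdr_adjust(out$p_value[is_cont])
  qt <- !is_cont & !duplicated(paste(out$metal, out$encoding))
  trend_fdr <- setNames(fdr_adjust(out$p_trend[qt]), out$metal[qt])
  out$p_trend_fdr <- NA_real_
  out$p_trend_fdr[!is_cont] <- trend_fdr[out$metal[!is_cont]]
  out$outcome <- outcome
  class(out) <- c("regression_result", "data.frame")
  out
}

add_exposure_columns_if_needed <- function(cohort) {
  if (!all(paste0("ln_", metal_names()) %in% names(cohort))) {
    cohort <- add_exposure_columns(cohort)
  }
  cohort
}

#' Single-metal associations with OA
#'
#' Adjusted logistic regressions of OA status on each of the nine urinary
#' metals, both Ln-continuous and in quartiles (Q2-Q4 vs Q1 with an
#' integer-coded trend test). Continuous p-values and quartile trend
#' p-values are each FDR-adjusted across the nine metals.
#'
#' @param cohort cohort with exposure columns (added automatically).
#' @param outcome binary outcome column, default `"oa_status"`.
#' @param covariates adjustment set, default [oa_covariates()].
#' @param weights optional survey-weight column name or vector.
#' @return tidy `regression_result` data.frame.
#' @export
fit_single_metals <- function(cohort, outcome = "oa_status",
                              covariates = oa_covariates(), weights = NULL) {
  sweep_metals(cohort, outcome, covariates, weights, "logistic")
}

#' Single-metal associations with the aging markers
#'
#' Adjusted linear regressions of each biological-aging marker on each of
#' the nine metals (continuous and quartiles with trend tests), FDR
#' adjusted across metals within marker.
#'
#' @inheritParams fit_single_metals
#' @param markers continuous marker columns to model.
#' @return tidy `regression_result` data.frame.
#' @export
fit_metal_markers <- function(cohort,
                              markers = c("biological_age", "phenotypic_age",
                                          "telomere_ts"),
                              covariates = oa_covariates(), weights = NULL) {
  out <- do.call(rbind, lapply(markers, function(mk) {
    sweep_metals(cohort, mk, covariates, weights, "linear")
  }))
  rownames(out) <- NULL
  class(out) <- c("regression_result", "data.frame")
  out
}

#' Aging-marker associations with OA
#'
#' Adjusted logistic regressions of OA on each aging marker, continuous
#' (per year, or per T/S unit for telomere length) and in marker quartiles
#' with trend tests.
#'
#' @inheritParams fit_metal_markers
#' @return tidy `regression_result` data.frame.
#' @export
fit_marker_oa <- function(cohort, markers = c("biological_age",
                                              "phenotypic_age", "telomere_ts"),
                          outcome = "oa_status",
                          covariates = oa_covariates(), weights = NULL) {
  rows <- lapply(markers, function(mk) {
    cont <- fit_exposure_model(cohort, outcome, mk, covariates, weights,
                               "continuous", "logistic", 0.95)
    quart <- fit_exposure_model(cohort, outcome, mk, covariates, weights,
                                "quartile", "logistic", 0.95)
    rbind(cont, quart)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  is_cont <- out$encoding == "continuous"
  out$p_fdr[is_cont] <- fdr_adjust(out$p_value[is_cont])
  out$outcome <- outcome
  class(out) <- c("regression_result", "data.frame")
  out
}
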
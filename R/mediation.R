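# Quasi-Bayesian Monte Carlo mediation: parallel (one mediator) and serial
# (two ordered mediators). Component models are ordinary lm/glm fits;
# parameter vectors are drawn from each fit's asymptotic normal, and
# average indirect/direct effects are evaluated on the response scale
# (risk differences for a binary outcome) through potential-outcome
# simulation of counterfactual mediator values.

# internal: fit a component model from parts, return coef/vcov/sigma
fit_component <- function(y, X, family, weights = NULL) {
  if (family == "logistic") {
    fam <- if (is.null(weights)) stats::binomial() else stats::quasibinomial()
    fit <- suppressWarnings(glm.fit(X, y, weights = weights %||% rep(1, length(y)),
                                    family = fam,
                                    control = glm.control(epsilon = 1e-10,
                                                          maxit = 100)))
    if (!fit$converged) stop("component model did not converge")
    p <- length(fit$coefficients)
    # dispersion fixed at 1 for the binomial information
    XtWX <- crossprod(X * sqrt(fit$weights), X * sqrt(fit$weights))
    vc <- solve(XtWX)
    list(coef = fit$coefficients, vcov = vc, sigma = NA_real_)
  } else {
    fit <- lm.wfit(X, y, w = weights %||% rep(1, length(y)))
    rss <- sum((weights %||% rep(1, length(y))) * fit$residuals^2)
    dfres <- length(y) - fit$rank
    sigma2 <- rss / dfres
    R <- qr.R(fit$qr)
    vc <- chol2inv(R) * sigma2
    dimnames(vc) <- list(names(fit$coefficients), names(fit$coefficients))
    list(coef = fit$coefficients, vcov = vc, sigma = sqrt(sigma2))
  }
}

check_columns <- function(data, cols) {
  absent <- setdiff(cols, names(data))
  if (length(absent) > 0) {
    stop("column(s) not found in data: ", paste(absent, collapse = ", "))
  }
}

mediation_design <- function(data, covariates) {
  if (length(covariates) == 0) {
    return(matrix(numeric(0), nrow(data), 0))
  }
  data <- prepare_model_frame(data, covariates)
  model.matrix(as.formula(paste("~", paste(sprintf("`%s`", covariates),
                                           collapse = " + "))),
               data = data)[, -1, drop = FALSE]
}

mediation_summary <- function(draws, point = NULL) {
  point <- point %||% mean(draws)
  p <- 2 * min(mean(draws <= 0), mean(draws >= 0))
  c(estimate = point,
    ci_low = unname(quantile(draws, 0.025)),
    ci_high = unname(quantile(draws, 0.975)),
    p_value = max(p, 2 / length(draws)))
}

#' Parallel mediation by quasi-Bayesian Monte Carlo simulation
#'
#' Estimates the indirect (through the mediator), direct, and total effect
#' of a one-unit exposure contrast on the outcome, with a continuous
#' mediator modeled linearly and a binary outcome modeled logistically
#' (continuous outcomes use a linear outcome model). `n_sim` parameter
#' vectors are drawn from each fitted model's asymptotic normal
#' distribution; for each draw, counterfactual mediator values at the
#' control and treated exposure levels (including residual noise) are
#' propagated through the outcome model and averaged over the sample, so
#' effects are average risk differences (binary outcome) or mean
#' differences (continuous outcome). The reported IE and DE average the
#' two exposure-arm definitions, so IE + DE equals TE exactly.
#'
#' @param data cohort `data.frame`.
#' @param exposure continuous exposure column (Ln metal or WQS index).
#' @param mediator continuous mediator column.
#' @param outcome outcome column (binary 0/1 or continuous).
#' @param covariates adjustment columns for both component models.
#' @param n_sim number of quasi-Bayesian draws (default 1000).
#' @param seed integer seed; fixes the draws bit-for-bit.
#' @param weights optional weight column name or vector.
#' @param control_value,treat_value exposure contrast; defaults to the
#'   observed exposure mean and mean + 1.
#' @return object of class `mediation_result` with a tidy `effects` table
#'   (IE, DE, TE, prop_mediated with CIs and p-values) and metadata.
#' @export
mediate_parallel <- function(data, exposure, mediator, outcome,
                             covariates = character(), n_sim = 1000,
                             seed = 1L, weights = NULL,
                             control_value = NULL, treat_value = NULL) {
  check_columns(data, c(exposure, mediator, outcome))
  x <- data[[exposure]]
  m <- data[[mediator]]
  y <- data[[outcome]]
  if (!is.numeric(m)) stop("mediator must be continuous")
  stopifnot(length(x) == length(y))
  C <- mediation_design(data, covariates)
  keep <- complete.cases(cbind(x, m, y, C))
  x <- x[keep]; m <- m[keep]; y <- y[keep]
  C <- C[keep, , drop = FALSE]
  w <- resolve_weights(data, weights)
  if (!is.null(w)) w <- w[keep]
  n <- length(y)
  binary <- all(y %in% c(0, 1))
  yfam <- if (binary) "logistic" else "linear"
  x0 <- control_value %||% mean(x)
  x1 <- treat_value %||% (x0 + 1)

  Xm <- cbind(1, x, C)
  mf <- fit_component(m, Xm, "linear", w)
  Xy <- cbind(1, x, m, C)
  yf <- fit_component(y, Xy, yfam, w)

  set.seed(seed)
  theta_m <- MASS::mvrnorm(n_sim, mf$coef, mf$vcov)
  theta_y <- MASS::mvrnorm(n_sim, yf$coef, yf$vcov)
  linkinv <- if (binary) plogis else identity

  base0 <- cbind(1, x0, C)   # mediator-model design at the contrast levels
  base1 <- cbind(1, x1, C)
  ie <- de <- te <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    tm <- theta_m[s, ]
    ty <- theta_y[s, ]
    m0 <- drop(base0 %*% tm) + rnorm(n, 0, mf$sigma)
    m1 <- drop(base1 %*% tm) + rnorm(n, 0, mf$sigma)
    cov_part <- if (ncol(C) > 0) drop(C %*% ty[-(1:3)]) else 0
    p00 <- linkinv(ty[1] + ty[2] * x0 + ty[3] * m0 + cov_part)
    p01 <- linkinv(ty[1] + ty[2] * x0 + ty[3] * m1 + cov_part)
    p10 <- linkinv(ty[1] + ty[2] * x1 + ty[3] * m0 + cov_part)
    p11 <- linkinv(ty[1] + ty[2] * x1 + ty[3] * m1 + cov_part)
    ie[s] <- (mean(p01 - p00) + mean(p11 - p10)) / 2
    de[s] <- (mean(p10 - p00) + mean(p11 - p01)) / 2
    te[s] <- mean(p11 - p00)
  }
  finalize_mediation(exposure, mediator, outcome, ie, de, te,
                     n_sim, seed, n, x0, x1, mode = "parallel")
}

#' Serial two-mediator mediation by quasi-Bayesian simulation
#'
#' Estimates the path-specific indirect effect along the ordered chain
#' exposure -> mediator 1 -> mediator 2 -> outcome (e.g. telomere length
#' then whole-body biological age). Three component models are fit
#' (`m1 ~ x + C`, `m2 ~ x + m1 + C`, `y ~ x + m1 + m2 + C`) and parameter
#' vectors are drawn independently per model from their asymptotic
#' normals. The serial indirect effect flips the exposure only inside the
#' mediator-1 model and propagates the change through mediator 2 to the
#' outcome, holding the exposure and the direct mediator-1 input to the
#' outcome at the control level; the direct effect flips only the
#' exposure in the outcome model. Counterfactual pairs share residual
#' draws (variance reduction; same estimand under additive errors).
#'
#' @inheritParams mediate_parallel
#' @param mediators character vector of two mediator columns in causal
#'   order (`mediators[1]` prior to `mediators[2]`).
#' @return a `mediation_result` for the serial path.
#' @export
mediate_serial <- function(data, exposure, mediators, outcome,
                           covariates = character(), n_sim = 1000,
                           seed = 1L, weights = NULL,
                           control_value = NULL, treat_value = NULL) {
  stopifnot(length(mediators) == 2)
  check_columns(data, c(exposure, mediators, outcome))
  x <- data[[exposure]]
  m1 <- data[[mediators[1]]]
  m2 <- data[[mediators[2]]]
  y <- data[[outcome]]
  if (!is.numeric(m1) || !is.numeric(m2)) stop("mediators must be continuous")
  C <- mediation_design(data, covariates)
  keep <- complete.cases(cbind(x, m1, m2, y, C))
  x <- x[keep]; m1 <- m1[keep]; m2 <- m2[keep]; y <- y[keep]
  C <- C[keep, , drop = FALSE]
  w <- resolve_weights(data, weights)
  if (!is.null(w)) w <- w[keep]
  n <- length(y)
  binary <- all(y %in% c(0, 1))
  linkinv <- if (binary) plogis else identity
  x0 <- control_value %||% mean(x)
  x1 <- treat_value %||% (x0 + 1)

  f1 <- fit_component(m1, cbind(1, x, C), "linear", w)
  f2 <- fit_component(m2, cbind(1, x, m1, C), "linear", w)
  fy <- fit_component(y, cbind(1, x, m1, m2, C),
                      if (binary) "logistic" else "linear", w)

  set.seed(seed)
  th1 <- MASS::mvrnorm(n_sim, f1$coef, f1$vcov)
  th2 <- MASS::mvrnorm(n_sim, f2$coef, f2$vcov)
  thy <- MASS::mvrnorm(n_sim, fy$coef, fy$vcov)

  cov1 <- function(t) if (ncol(C) > 0) drop(C %*% t[-(1:2)]) else 0
  cov2 <- function(t) if (ncol(C) > 0) drop(C %*% t[-(1:3)]) else 0
  covy <- function(t) if (ncol(C) > 0) drop(C %*% t[-(1:4)]) else 0

  ie <- de <- te <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    t1 <- th1[s, ]; t2 <- th2[s, ]; ty <- thy[s, ]
    e1 <- rnorm(n, 0, f1$sigma)
    e2 <- rnorm(n, 0, f2$sigma)
    m1_0 <- t1[1] + t1[2] * x0 + cov1(t1) + e1
    m1_1 <- t1[1] + t1[2] * x1 + cov1(t1) + e1
    m2_00 <- t2[1] + t2[2] * x0 + t2[3] * m1_0 + cov2(t2) + e2
    m2_01 <- t2[1] + t2[2] * x0 + t2[3] * m1_1 + cov2(t2) + e2
    m2_11 <- t2[1] + t2[2] * x1 + t2[3] * m1_1 + cov2(t2) + e2
    yhat <- function(xv, m1v, m2v) {
      linkinv(ty[1] + ty[2] * xv + ty[3] * m1v + ty[4] * m2v + covy(ty))
    }
    p_ref <- yhat(x0, m1_0, m2_00)
    ie[s] <- mean(yhat(x0, m1_0, m2_01) - p_ref)
    de[s] <- mean(yhat(x1, m1_0, m2_00) - p_ref)
    te[s] <- mean(yhat(x1, m1_1, m2_11) - p_ref)
  }
  finalize_mediation(exposure, paste(mediators, collapse = " -> "), outcome,
                     ie, de, te, n_sim, seed, n, x0, x1, mode = "serial")
}

finalize_mediation <- function(exposure, mediator, outcome, ie, de, te,
                               n_sim, seed, n, x0, x1, mode) {
  ie_s <- mediation_summary(ie)
  de_s <- mediation_summary(de)
  te_s <- mediation_summary(te)
  prop_draws <- ie / (ie + de)
  prop_point <- proportion_mediated(ie_s[["estimate"]], de_s[["estimate"]])
  prop_s <- mediation_summary(prop_draws, point = prop_point)
  effects <- data.frame(
    effect = c("IE", "DE", "TE", "prop_mediated"),
    estimate = c(ie_s[["estimate"]], de_s[["estimate"]], te_s[["estimate"]],
                 prop_s[["estimate"]]),
    ci_low = c(ie_s[["ci_low"]], de_s[["ci_low"]], te_s[["ci_low"]],
               prop_s[["ci_low"]]),
    ci_high = c(ie_s[["ci_high"]], de_s[["ci_high"]], te_s[["ci_high"]],
                prop_s[["ci_high"]]),
    p_value = c(ie_s[["p_value"]], de_s[["p_value"]], te_s[["p_value"]],
                prop_s[["p_value"]]),
    stringsAsFactors = FALSE)
  structure(list(exposure = exposure, mediators = mediator, outcome = outcome,
                 mode = mode, effects = effects,
                 draws = list(ie = ie, de = de, te = te),
                 n_sim = n_sim, seed = as.integer(seed), n = n,
                 control_value = x0, treat_value = x1),
            class = "mediation_result")
}

#' Proportion of the total effect transmitted through the mediator
#'
#' `IE / (IE + DE)`; undefined (error) when the denominator is below
#' tolerance.
#'
#' @param IE indirect effect estimate.
#' @param DE direct effect estimate.
#' @param tol smallest admissible `|IE + DE|`.
#' @return the proportion mediated (reported as a percentage in printed
#'   outputs).
#' @export
proportion_mediated <- function(IE, DE, tol = 1e-12) {
  if (abs(IE + DE) < tol) {
    stop("proportion mediated undefined: |IE + DE| below tolerance")
  }
  IE / (IE + DE)
}

#' @export
print.mediation_result <- function(x, digits = 4, ...) {
  cat(sprintf("%s mediation: %s -> %s -> %s (n = %d, %d draws, seed %d)\n",
              if (x$mode == "serial") "Serial" else "Parallel",
              x$exposure, x$mediators, x$outcome, x$n, x$n_sim, x$seed))
  cat(sprintf("  exposure contrast: %.4g -> %.4g\n",
              x$control_value, x$treat_value))
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    if (eff$effect[i] == "prop_mediated") {
      cat(sprintf("  proportion mediated: %.2f%% (%.2f%%, %.2f%%), p = %.3g\n",
                  100 * eff$estimate[i], 100 * eff$ci_low[i],
                  100 * eff$ci_high[i], eff$p_value[i]))
    } else {
      cat(sprintf("  %s: %.*g (%.*g, %.*g), p = %.3g\n", eff$effect[i],
                  digits, eff$estimate[i], digits, eff$ci_low[i], digits,
                  eff$ci_high[i], eff$p_value[i]))
    }
  }
  invisible(x)
}
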
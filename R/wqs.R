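# Weighted quantile sum (WQS) regression, implemented from scratch:
# per-metal quantile scoring, bootstrap estimation of a simplex-constrained
# weight vector via softmax reparameterization (analytic gradients, BFGS),
# and a final covariate-adjusted fit of the fixed-weight index on a
# held-out validation split.

#' Quantile-score an exposure matrix
#'
#' Scores each column into `n_quantiles` groups coded 0 to
#' `n_quantiles - 1` by the column's sample quantile cutpoints, with
#' intervals closed on the right as in [quartile_encode()].
#'
#' @param metals numeric matrix/data.frame of exposures (e.g. ug/g
#'   creatinine), one column per metal.
#' @param n_quantiles number of groups, >= 2 (default 4).
#' @return integer matrix of scores with the input's dimnames.
#' @export
quantile_score <- function(metals, n_quantiles = 4) {
  x <- as.matrix(metals)
  if (n_quantiles < 2) stop("n_quantiles must be >= 2")
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  probs <- seq_len(n_quantiles - 1) / n_quantiles
  for (j in seq_len(ncol(x))) {
    if (length(unique(x[, j])) < 2 * n_quantiles) {
      stop("too few distinct values to quantile-score column ",
           colnames(x)[j] %||% j)
    }
    cuts <- unname(quantile(x[, j], probs))
    if (any(diff(cuts) <= 0)) {
      stop("tied quantile cutpoints in column ", colnames(x)[j] %||% j)
    }
    out[, j] <- cut(x[, j], breaks = c(-Inf, cuts, Inf), labels = FALSE,
                    right = TRUE) - 1L
  }
  out
}

# internal: negative (quasi-)log-likelihood of the constrained WQS model
# and its analytic gradient. Parameters: theta (softmax weights, length p),
# nu (log of |index coefficient|), alpha (intercept + covariate
# coefficients). eta = alpha0 + sign * exp(nu) * (Q w) + C gamma.
wqs_objective <- function(par, Q, y, C, wts, sign, family) {
  p <- ncol(Q)
  theta <- par[seq_len(p)]
  nu <- par[p + 1]
  alpha <- par[-seq_len(p + 1)]
  w <- exp(theta - max(theta))
  w <- w / sum(w)
  b1 <- sign * exp(nu)
  z <- drop(Q %*% w)
  eta <- alpha[1] + b1 * z + if (ncol(C) > 0) drop(C %*% alpha[-1]) else 0
  if (family == "logistic") {
    nll <- sum(wts * (log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta))
    r <- wts * (plogis(eta) - y)
  } else {
    nll <- 0.5 * sum(wts * (y - eta)^2)
    r <- -wts * (y - eta)
  }
  g_alpha0 <- sum(r)
  g_nu <- b1 * sum(r * z)
  g_gamma <- if (ncol(C) > 0) drop(crossprod(C, r)) else numeric(0)
  g_w <- b1 * drop(crossprod(Q, r))
  g_theta <- w * (g_w - sum(g_w * w))
  list(value = nll, gradient = c(g_theta, g_nu, g_alpha0, g_gamma))
}

# internal: one constrained fit on (Q, y, C); returns weights and
# convergence flag
wqs_solve <- function(Q, y, C, wts, sign, family, maxit = 300) {
  p <- ncol(Q)
  start_alpha <- if (family == "logistic") {
    suppressWarnings(coef(glm.fit(cbind(1, C), y, weights = wts,
                                  family = stats::quasibinomial())))
  } else {
    coef(lm.wfit(cbind(1, C), y, w = wts))
  }
  start_alpha[!is.finite(start_alpha)] <- 0
  par0 <- c(rep(0, p), log(0.1), start_alpha)
  fn <- function(par) wqs_objective(par, Q, y, C, wts, sign, family)$value
  gr <- function(par) wqs_objective(par, Q, y, C, wts, sign, family)$gradient
  opt <- optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = maxit, reltol = 1e-10))
  theta <- opt$par[seq_len(p)]
  w <- exp(theta - max(theta))
  w <- w / sum(w)
  list(weights = w, b1 = sign * exp(opt$par[p + 1]),
       converged = opt$convergence == 0)
}

#' Weighted quantile sum regression
#'
#' Estimates the joint ("mixture") association of the nine metals with an
#' outcome as a weighted sum of per-metal quantile scores, with weights
#' constrained nonnegative and summing to 1 and the index coefficient's
#' sign fixed by `direction`. The sample is split into a training and a
#' validation part; on each of `n_bootstrap` resamples of the training
#' part the simplex-constrained model (including covariates) is fit by
#' maximum likelihood via a softmax reparameterization with analytic
#' gradients; weights are averaged across converged bootstraps (optionally
#' weighted by the index term's absolute test statistic); the final
#' covariate-adjusted model of the outcome on the fixed-weight index is
#' fit on the validation part and reported per one-quantile increase.
#'
#' @param data cohort `data.frame`.
#' @param outcome outcome column: binary 0/1 (logistic) or continuous
#'   (linear; chosen automatically).
#' @param metals character vector of exposure columns; defaults to the
#'   creatinine-corrected `cc_*` metal columns (added if absent).
#' @param covariates adjustment columns, included both in the bootstrap
#'   weight-estimation fits and in the final validation fit.
#' @param weights optional survey-weight column name or vector.
#' @param direction `"positive"` or `"negative"`: fixed sign of the index
#'   coefficient during weight estimation.
#' @param n_bootstrap bootstrap resamples (default 100).
#' @param n_quantiles quantile groups (default 4).
#' @param train_fraction fraction assigned to the training split
#'   (default 0.4; the rest validates).
#' @param seed integer seed governing the split and the bootstraps.
#' @param aggregation `"mean"` (default) averages weight vectors across
#'   converged bootstraps; `"signif_weighted"` weights the average by the
#'   bootstrap index term's absolute z statistic.
#' @param conf_level confidence level for the final fit.
#' @return object of class `wqs_fit`: simplex `weights`, final-model
#'   `index_coefficient`, `or_or_beta`, `ci_low`, `ci_high`, `p_value`,
#'   `converged_fraction`, the per-bootstrap weight matrix, and metadata.
#' @export
fit_wqs <- function(data, outcome, metals = paste0("cc_", metal_names()),
                    covariates = character(), weights = NULL,
                    direction = c("positive", "negative"),
                    n_bootstrap = 100, n_quantiles = 4,
                    train_fraction = 0.4, seed = 1L,
                    aggregation = c("mean", "signif_weighted"),
                    conf_level = 0.95) {
  direction <- match.arg(direction)
  aggregation <- match.arg(aggregation)
  if (identical(metals, paste0("cc_", metal_names())) &&
      !all(metals %in% names(data))) {
    data <- add_exposure_columns_if_needed(data)
  }
  if (!all(metals %in% names(data))) {
    stop("missing metal columns: ",
         paste(setdiff(metals, names(data)), collapse = ", "))
  }
  data <- prepare_model_frame(data, covariates)
  y <- data[[outcome]]
  binary <- all(y %in% c(0, 1))
  family <- if (binary) "logistic" else "linear"
  Q <- quantile_score(data[, metals, drop = FALSE], n_quantiles)
  C <- if (length(covariates) > 0) {
    model.matrix(as.formula(paste("~", paste(sprintf("`%s`", covariates),
                                             collapse = " + "))),
                 data = data)[, -1, drop = FALSE]
  } else {
    matrix(numeric(0), nrow(data), 0)
  }
  wts <- resolve_weights(data, weights) %||% rep(1, nrow(data))
  sign <- if (direction == "positive") 1 else -1

  set.seed(seed)
  n <- nrow(data)
  train <- sample.int(n, size = round(train_fraction * n))
  valid <- setdiff(seq_len(n), train)

  p <- length(metals)
  W <- matrix(NA_real_, n_bootstrap, p, dimnames = list(NULL, metals))
  zstat <- rep(NA_real_, n_bootstrap)
  conv <- logical(n_bootstrap)
  for (b in seq_len(n_bootstrap)) {
    idx <- sample(train, length(train), replace = TRUE)
    fit_b <- wqs_solve(Q[idx, , drop = FALSE], y[idx], C[idx, , drop = FALSE],
                       wts[idx], sign, family)
    conv[b] <- fit_b$converged
    W[b, ] <- fit_b$weights
    # index z statistic from a plain refit at the estimated weights
    zstat[b] <- tryCatch({
      rb <- fit_adjusted(data[idx, , drop = FALSE], outcome,
                         drop(Q[idx, , drop = FALSE] %*% fit_b$weights),
                         "index", covariates,
                         if (is.null(weights)) NULL else wts[idx],
                         family)
      rb$estimate / rb$se
    }, error = function(e) NA_real_)
  }
  converged_fraction <- mean(conv)
  if (converged_fraction < 0.5) {
    stop(sprintf("only %.0f%% of bootstrap fits converged", 100 * converged_fraction))
  }
  use <- conv
  agg_w <- if (aggregation == "mean") {
    rep(1, sum(use))
  } else {
    aw <- abs(zstat[use])
    aw[!is.finite(aw)] <- 0
    if (sum(aw) == 0) rep(1, sum(use)) else aw
  }
  w_final <- drop(crossprod(W[use, , drop = FALSE], agg_w)) / sum(agg_w)
  w_final <- w_final / sum(w_final)

  index_valid <- drop(Q[valid, , drop = FALSE] %*% w_final)
  final <- fit_adjusted(data[valid, , drop = FALSE], outcome, index_valid,
                        "wqs_index", covariates,
                        if (is.null(weights)) NULL else wts[valid],
                        family, conf_level)
  if (sign * final$estimate < 0) {
    warning("final index coefficient has the opposite sign to `direction`; ",
            "the constrained direction may be misspecified")
  }
  structure(list(weights = w_final,
                 index_coefficient = final$estimate,
                 se = final$se,
                 or_or_beta = final$or_or_beta,
                 ci_low = final$ci_low, ci_high = final$ci_high,
                 p_value = final$p_value,
                 model_family = family,
                 direction = direction,
                 n_bootstrap = n_bootstrap,
                 n_quantiles = n_quantiles,
                 train_fraction = train_fraction,
                 split_seed = as.integer(seed),
                 aggregation = aggregation,
                 converged_fraction = converged_fraction,
                 bootstrap_weights = W,
                 bootstrap_z = zstat,
                 n_train = length(train), n_valid = length(valid),
                 metals = metals),
            class = "wqs_fit")
}

#' Compute the WQS index for a cohort from fitted weights
#'
#' Recomputes the fixed-weight index (per-quantile scale) on a full
#' sample, e.g. for use as the mixture exposure in mediation models.
#'
#' @param fit a [fit_wqs()] object.
#' @param data cohort containing the fitted metal columns.
#' @return numeric index vector, one value per row of `data`.
#' @export
wqs_index <- function(fit, data) {
  stopifnot(inherits(fit, "wqs_fit"))
  data <- add_exposure_columns_if_needed(data)
  Q <- quantile_score(data[, fit$metals, drop = FALSE], fit$n_quantiles)
  drop(Q %*% fit$weights)
}

#' @export
print.wqs_fit <- function(x, digits = 3, ...) {
  lab <- if (x$model_family == "logistic") "OR" else "beta"
  cat(sprintf("WQS regression (%s, direction %s): %s = %.3f (%.3f, %.3f), p = %.3g\n",
              x$model_family, x$direction, lab, x$or_or_beta, x$ci_low,
              x$ci_high, x$p_value))
  cat(sprintf("  %d bootstraps (%.0f%% converged), %d quantiles, train %d / validation %d\n",
              x$n_bootstrap, 100 * x$converged_fraction, x$n_quantiles,
              x$n_train, x$n_valid))
  w <- sort(x$weights, decreasing = TRUE)
  cat("  weights:", paste(sprintf("%s %.3f", names(w), w), collapse = ", "), "\n")
  invisible(x)
}
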
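# Independent oracles used to freeze expected values. Each is a direct,
# single-purpose transcription kept deliberately separate from the package
# implementation paths it checks.

# literal nested transcription of the phenotypic-age closed form
pheno_age_oracle <- function(alb, creat, gluc, lncrp, lymph, mcv, rdw,
                             alp, wbc, ca) {
  xb <- -19.907 - 0.0336 * alb + 0.0095 * creat + 0.1953 * gluc +
    0.0954 * lncrp - 0.0120 * lymph + 0.0268 * mcv + 0.3306 * rdw +
    0.00188 * alp + 0.0554 * wbc + 0.0804 * ca
  141.50 + log(-0.00553 * log(exp(-1.51714 * exp(xb) / 0.0076927))) / 0.09165
}

# single-expression transcription of the corrected biological-age estimator
kdm_eq4_oracle <- function(x, k, q, s, s_ba2, ca) {
  (sum((x - q) * k / s^2) + ca / s_ba2) / (sum((k / s)^2) + 1 / s_ba2)
}

# closed-form OLS of y on x via the normal equations, with RMSE (divisor n)
ols_oracle <- function(x, y) {
  n <- length(x)
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  intercept <- (sum(y) - slope * sum(x)) / n
  rmse <- sqrt(sum((y - intercept - slope * x)^2) / n)
  list(slope = slope, intercept = intercept, rmse = rmse)
}

# brute-force BH adjusted p-values: for each hypothesis, the smallest level
# alpha (searched over all candidate thresholds) at which the step-up
# procedure rejects it
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  candidates <- sort(unique(c(m * p[ord] / seq_len(m), 1)))
  rejected_at <- function(alpha) {
    ps <- p[ord]
    # tolerance guards boundary candidates against floating-point round-off
    k <- suppressWarnings(max(which(ps <= seq_len(m) / m * alpha + 1e-12)))
    if (!is.finite(k)) return(rep(FALSE, m))
    rej_sorted <- seq_len(m) <= k
    rej <- logical(m)
    rej[ord] <- rej_sorted
    rej
  }
  adj <- rep(1, m)
  for (alpha in candidates) {
    rej <- rejected_at(alpha)
    adj[rej] <- pmin(adj[rej], alpha)
  }
  adj
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  smaller <- all_permutations(n - 1)
  out <- list()
  for (p in smaller) {
    for (i in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = i)
    }
  }
  out
}

# linear mediation chains with known path coefficients
sim_chain <- function(n, a, b, cp, seed, sd_m = 1, sd_y = 1) {
  set.seed(seed)
  x <- rnorm(n)
  m <- a * x + rnorm(n, 0, sd_m)
  y <- cp * x + b * m + rnorm(n, 0, sd_y)
  data.frame(x = x, m = m, y = y)
}

sim_serial_chain <- function(n, a1, d21, b2, cp, seed,
                             x_to_m2 = 0.2, m1_to_y = 0.2) {
  set.seed(seed)
  x <- rnorm(n)
  m1 <- a1 * x + rnorm(n)
  m2 <- d21 * m1 + x_to_m2 * x + rnorm(n)
  y <- cp * x + m1_to_y * m1 + b2 * m2 + rnorm(n)
  data.frame(x = x, m1 = m1, m2 = m2, y = y)
}
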
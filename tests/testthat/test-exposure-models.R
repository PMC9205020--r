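test_that("creatinine correction converts to micrograms per gram", {
  expect_equal(creatinine_correct(1, 100), 1)   # 100 mg/dL = 1 g/L
  expect_equal(creatinine_correct(0.5, 50), 1)
  expect_equal(creatinine_correct(c(2, 3), c(100, 200)), c(2, 1.5))
  expect_error(creatinine_correct(1, 0), "creatinine")
  expect_error(creatinine_correct(1, -5), "creatinine")
})

test_that("quartile encoding partitions the sample at the right cutpoints", {
  enc <- quartile_encode(1:8)
  expect_equal(enc$score, c(1, 1, 2, 2, 3, 3, 4, 4))
  expect_error(quartile_encode(rep(2, 20)), "distinct")

  set.seed(9)
  x <- rlnorm(1000)
  enc <- quartile_encode(x)
  expect_equal(unname(table(enc$score)), rep(250L, 4), ignore_attr = TRUE)
  expect_true(all(diff(enc$cutpoints) > 0))
  # interval convention: (-inf, c1], (c1, c2], (c2, c3], (c3, inf)
  expect_true(all(x[enc$score == 1] <= enc$cutpoints[1]))
  expect_true(all(x[enc$score == 4] > enc$cutpoints[3]))

  # weighted percentiles shift the cutpoints toward heavy observations
  w <- ifelse(x > median(x), 10, 1)
  encw <- quartile_encode(x, weights = w)
  expect_lt(enc$cutpoints[1], encw$cutpoints[1])
})

test_that("quartile counts differ by at most one for distinct values", {
  set.seed(10)
  for (n in c(80, 101, 1003)) {
    tab <- table(quartile_encode(rnorm(n))$score)
    expect_lte(max(tab) - min(tab), 1)
  }
})

test_that("logistic OR on a covariate-free 2x2 table equals ad/bc", {
  # a=10 exposed cases, b=20 exposed controls, c=20 unexposed cases,
  # d=10 unexposed controls
  d <- data.frame(y = rep(c(1, 0, 1, 0), c(10, 20, 20, 10)),
                  x = rep(c(1, 1, 0, 0), c(10, 20, 20, 10)))
  res <- fit_logistic(d, "y", "x")
  expect_equal(res$or_or_beta, (10 * 10) / (20 * 20), tolerance = 1e-6)
})

test_that("constant weights reproduce the unweighted point estimates", {
  coh <- default_cohort()
  unw <- fit_logistic(coh, "oa_status", "ln_cd",
                      covariates = c("age_group", "sex", "bmi"))
  w <- fit_logistic(coh, "oa_status", "ln_cd",
                    covariates = c("age_group", "sex", "bmi"),
                    weights = rep(2.5, nrow(coh)))
  expect_equal(w$estimate, unw$estimate, tolerance = 1e-8)
  lin_u <- fit_linear(coh, "biological_age", "ln_cd", covariates = "sex")
  lin_w <- fit_linear(coh, "biological_age", "ln_cd", covariates = "sex",
                      weights = rep(0.4, nrow(coh)))
  expect_equal(lin_w$estimate, lin_u$estimate, tolerance = 1e-8)
})

test_that("linear fits match the closed-form normal-equation oracle", {
  # fixed 20-point fixture
  x <- c(0.62, -1.4, 1.1, 0.25, -0.04, 1.93, -0.77, 0.51, -1.2, 0.3,
         2.1, -0.6, 0.05, 1.4, -2.2, 0.9, -0.3, 0.7, -1.0, 1.6)
  y <- c(1.5, -2.3, 2.6, 0.2, 0.4, 4.1, -1.1, 1.4, -2.2, 0.8,
         4.5, -0.9, -0.3, 3.2, -4.6, 1.7, -0.8, 1.9, -2.4, 3.0)
  d <- data.frame(x = x, y = y)
  res <- fit_linear(d, "y", "x")
  oracle <- ols_oracle(x, y)
  expect_equal(res$estimate, oracle$slope, tolerance = 1e-10)

  # near-noiseless slope recovery
  set.seed(12)
  d2 <- data.frame(x = rnorm(500))
  d2$y <- 2 * d2$x + rnorm(500, 0, 1e-6)
  expect_equal(fit_linear(d2, "y", "x")$estimate, 2, tolerance = 1e-4)
})

test_that("trend test uses integer quartile scores and matches a Wald oracle", {
  set.seed(13)
  n <- 4000
  x <- rlnorm(n)
  lp <- -2 + 0.5 * as.numeric(quartile_encode(x)$score)
  y <- rbinom(n, 1, plogis(lp))
  d <- data.frame(x = x, y = y)
  res <- fit_logistic(d, "y", "x", encoding = "quartile")
  expect_equal(nrow(res), 3) # Q2-Q4 vs the Q1 reference
  expect_lt(res$p_trend[1], 0.001)

  # oracle: refit on the integer score by hand and compare the Wald p
  sc <- as.numeric(quartile_encode(x)$score)
  fit <- glm(y ~ sc, family = binomial())
  z <- coef(summary(fit))["sc", "z value"]
  tr <- trend_test(d, "y", "x", family = "logistic")
  expect_equal(tr$p_trend, 2 * pnorm(-abs(z)), tolerance = 1e-6)
  expect_equal(tr$statistic, z, tolerance = 1e-6)
})

test_that("permuted exposure gives uniform trend p-values", {
  set.seed(14)
  coh <- default_cohort()
  pvals <- vapply(1:60, function(i) {
    d <- coh[sample(nrow(coh), 500), ]
    d$shuffled <- sample(d$cc_cd)
    fit_logistic(d, "oa_status", "shuffled", encoding = "quartile")$p_trend[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("BH adjustment matches exhaustive step-up enumeration", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(rep(1, 5)), rep(1, 5))
  expect_error(fdr_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(15)
  base_sets <- list(c(0.01, 0.04, 0.03, 0.2), runif(5), runif(6),
                    c(0.001, 0.001, 0.5, 0.9, 0.02, 0.02))
  for (p in base_sets) {
    perms <- if (length(p) <= 4) {
      all_permutations(length(p))
    } else {
      replicate(30, sample(length(p)), simplify = FALSE)
    }
    for (idx in perms) {
      expect_equal(fdr_adjust(p[idx]), bh_stepup_oracle(p[idx]),
                   tolerance = 1e-12)
    }
  }
  # monotonicity guarantee: adjusted never below raw
  for (i in 1:20) {
    p <- runif(6)
    expect_true(all(fdr_adjust(p) >= p))
  }
})

test_that("correlation matrix matches the sum-formula oracle on a fixture", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(0.5, 1.9, 1.1, 2.4, 2.6)
  z <- c(2.0, 1.0, 3.0, 0.5, 1.5)
  m <- cbind(x = x, y = y, z = z)
  r <- pearson_correlation_matrix(m)
  n <- 5
  rxy <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(r["x", "y"], rxy, tolerance = 1e-12)
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 3))
  expect_equal(pearson_correlation_matrix(cbind(a = x, b = 2 * x))["a", "b"], 1)
  expect_warning(rz <- pearson_correlation_matrix(cbind(a = x, c = rep(1, 5))),
                 "zero-variance")
  expect_true(is.na(rz["a", "c"]))
})

test_that("covariate imputation follows the median / missing-level rules", {
  d <- data.frame(bmi = c(1.0, NA, 3.0), education = c("hs", NA, "hs"),
                  stringsAsFactors = FALSE)
  out <- suppressMessages(impute_covariates(d, c("bmi", "education")))
  expect_equal(out$bmi, c(1.0, 2.0, 3.0))
  expect_equal(out$education, c("hs", "missing", "hs"))
  # identity on complete data
  d2 <- data.frame(bmi = c(1, 2), education = c("hs", "hs"),
                   stringsAsFactors = FALSE)
  expect_identical(suppressMessages(impute_covariates(d2, names(d2))), d2)
  d3 <- data.frame(bmi = c(NA_real_, NA_real_))
  expect_error(impute_covariates(d3, "bmi"), "entirely missing")
})
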
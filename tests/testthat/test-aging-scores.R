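test_that("KDM regression constants match a closed-form OLS oracle", {
  # 10-point single-biomarker fixture with known generating line; n >= 30
  # enforced by the fitter, so replicate the fixture to length 30
  x_fix <- c(21, 27, 33, 39, 45, 51, 57, 63, 69, 75)
  y_fix <- c(101.3, 103.9, 108.1, 110.2, 113.8, 116.9, 121.4, 122.7,
             127.5, 130.8)
  ca <- rep(x_fix, 3)
  bio <- matrix(rep(y_fix, 3), ncol = 1, dimnames = list(NULL, "sbp"))
  # with a single biomarker the age-correction variance is clamped
  fit <- suppressWarnings(fit_kdm(bio, ca))
  oracle <- ols_oracle(ca, bio[, 1])
  expect_equal(unname(fit$k["sbp"]), oracle$slope, tolerance = 1e-12)
  expect_equal(unname(fit$q["sbp"]), oracle$intercept, tolerance = 1e-12)
  expect_equal(unname(fit$s["sbp"]), oracle$rmse, tolerance = 1e-12)
  expect_equal(unname(fit$r["sbp"]), cor(ca, bio[, 1]), tolerance = 1e-12)
})

test_that("noise-free linear biomarkers are recovered and give BA = CA", {
  set.seed(11)
  n <- 1000
  ca <- runif(n, 20, 80)
  k_true <- c(0.5, -0.2, 1.1)
  q_true <- c(10, 50, -3)
  bio <- sapply(1:3, function(j) q_true[j] + k_true[j] * ca)
  bio <- bio + matrix(rnorm(3 * n, 0, 1e-8), n, 3) # tiny jitter keeps s > 0
  colnames(bio) <- c("b1", "b2", "b3")
  fit <- fit_kdm(bio, ca)
  expect_equal(unname(fit$k), k_true, tolerance = 1e-6)
  expect_equal(unname(fit$q), q_true, tolerance = 1e-6)
  ba <- suppressWarnings(compute_biological_age(fit, bio, ca))
  expect_equal(ba, ca, tolerance = 1e-6)
})

test_that("degenerate KDM inputs error or drop cleanly", {
  ca <- rep(50, 40)
  bio <- matrix(rnorm(40), ncol = 1)
  expect_error(fit_kdm(bio, ca), "variance")
  expect_error(fit_kdm(matrix(rnorm(20), ncol = 1), runif(20, 20, 80)),
               "n >= 30")
  set.seed(2)
  ca <- runif(60, 20, 80)
  bio <- cbind(b1 = 2 + 0.5 * ca + rnorm(60), flat = rep(3, 60))
  expect_warning(fit <- fit_kdm(bio, ca), "zero-variance")
  expect_equal(fit$m, 1)
})

test_that("corrected biological age matches a direct transcription and its limits", {
  set.seed(3)
  ca_train <- runif(500, 20, 80)
  cst <- data.frame(k = c(0.9, -0.15, 0.035), q = c(95, 47, 4.8),
                    s = c(10, 2.5, 0.45))
  bio <- sapply(1:3, function(j) {
    cst$q[j] + cst$k[j] * ca_train + rnorm(500, 0, cst$s[j])
  })
  colnames(bio) <- c("sbp", "alb", "hba1c")
  fit <- fit_kdm(bio, ca_train)

  x0 <- c(sbp = 141.2, alb = 40.3, hba1c = 6.1)
  ca0 <- 57.5
  expect_equal(compute_biological_age(fit, x0, ca0),
               kdm_eq4_oracle(x0[fit$biomarkers], fit$k, fit$q, fit$s,
                              fit$s_ba2, ca0),
               tolerance = 1e-12)

  # s_BA^2 -> Inf limit: the corrected estimator converges to the
  # biomarker-only estimate
  fit_inf <- fit
  fit_inf$s_ba2 <- 1e12
  ba_e <- (sum((x0[fit$biomarkers] - fit$q) * fit$k / fit$s^2)) /
    sum((fit$k / fit$s)^2)
  expect_equal(compute_biological_age(fit_inf, x0, ca0), ba_e,
               tolerance = 1e-6)

  # non-positive s_BA^2 falls back to the biomarker-only estimate
  fit_bad <- fit
  fit_bad$s_ba2 <- 0
  expect_warning(ba_fb <- compute_biological_age(fit_bad, x0, ca0),
                 "biomarker-only")
  expect_equal(ba_fb, ba_e, tolerance = 1e-12)
})

test_that("corrected biological age lies between the raw estimate and CA", {
  set.seed(4)
  ca <- runif(300, 25, 75)
  bio <- cbind(a = 10 + 0.4 * ca + rnorm(300, 0, 6),
               b = 100 - 0.7 * ca + rnorm(300, 0, 10))
  fit <- suppressWarnings(fit_kdm(bio, ca))
  ba <- compute_biological_age(fit, bio, ca)
  ba_e <- (sweep(bio, 2, fit$q) %*% (fit$k / fit$s^2)) / sum((fit$k / fit$s)^2)
  expect_true(all(ba >= pmin(ba_e, ca) - 1e-9))
  expect_true(all(ba <= pmax(ba_e, ca) + 1e-9))
})

test_that("mean biological-age bias is small on a linear training sample", {
  set.seed(5)
  n <- 5000
  ca <- runif(n, 20, 80)
  cst <- kdm_panel_constants_for_tests()
  bio <- sapply(seq_len(nrow(cst)), function(j) {
    cst$q[j] + cst$k[j] * ca + rnorm(n, 0, cst$s[j])
  })
  colnames(bio) <- cst$biomarker
  fit <- fit_kdm(bio, ca)
  ba <- compute_biological_age(fit, bio, ca)
  expect_lt(abs(mean(ba - ca)), 0.5)
})

test_that("phenotypic age equals the literal printed-formula transcription", {
  set.seed(6)
  for (i in 1:100) {
    v <- c(alb = runif(1, 35, 50), creat = runif(1, 50, 120),
           gluc = runif(1, 4, 9), lncrp = runif(1, -3.5, 0.5),
           lymph = runif(1, 15, 45), mcv = runif(1, 80, 100),
           rdw = runif(1, 11.5, 15), alp = runif(1, 40, 120),
           wbc = runif(1, 4, 11))
    ca <- runif(1, 20, 80)
    expect_equal(compute_phenotypic_age(unname(v), ca),
                 pheno_age_oracle(v["alb"], v["creat"], v["gluc"], v["lncrp"],
                                  v["lymph"], v["mcv"], v["rdw"], v["alp"],
                                  v["wbc"], ca),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("phenotypic age is monotone with the sign of each coefficient", {
  base <- c(43, 80, 5.5, -1.9, 30, 90, 13, 70, 7)
  ca <- 50
  p0 <- compute_phenotypic_age(base, ca)
  signs <- c(-1, 1, 1, 1, -1, 1, 1, 1, 1) # printed coefficient signs
  for (j in seq_along(base)) {
    up <- base; up[j] <- up[j] + 1
    expect_equal(sign(compute_phenotypic_age(up, ca) - p0), signs[j])
  }
  # age itself has a positive coefficient
  expect_gt(compute_phenotypic_age(base, ca + 5), p0)
})

test_that("attaching markers appends columns and recovers latent aging", {
  coh <- default_cohort()
  expect_true(all(c("biological_age", "phenotypic_age") %in% names(coh)))
  expect_gt(cor(coh$biological_age, coh$truth_mediator_age), 0.8)
  expect_gt(cor(coh$phenotypic_age, coh$truth_mediator_age), 0.8)

  one <- suppressMessages(attach_aging_markers(coh[1, intersect(names(coh),
    c("participant_id", "age", "telomere_ts",
      grep("^(kdm|pheno)_", names(coh), value = TRUE)))],
    params = attr(coh, "kdm_parameters")))
  expect_true(all(c("biological_age", "phenotypic_age", "telomere_ts") %in%
                    names(one)))
  expect_error(attach_aging_markers(coh[0, ]), "empty")
})

test_that("aging scores are invariant to row order", {
  coh <- default_cohort()
  params <- attr(coh, "kdm_parameters")
  idx <- rev(seq_len(200))
  ba_fwd <- compute_biological_age(params, coh[1:200, params$biomarkers],
                                   coh$age[1:200])
  ba_rev <- compute_biological_age(params, coh[idx, params$biomarkers],
                                   coh$age[idx])
  expect_equal(ba_fwd, rev(ba_rev))
  ph_fwd <- compute_phenotypic_age(coh[1:200, pheno_cols_for_tests()],
                                   coh$age[1:200])
  ph_rev <- compute_phenotypic_age(coh[idx, pheno_cols_for_tests()],
                                   coh$age[idx])
  expect_equal(ph_fwd, rev(ph_rev))
})

test_that("fitted KDM parameters round-trip through YAML", {
  coh <- default_cohort()
  params <- attr(coh, "kdm_parameters")
  f <- tempfile(fileext = ".yml")
  write_kdm_parameters(params, f)
  back <- read_kdm_parameters(f)
  expect_equal(back$k, params$k, tolerance = 1e-8)
  expect_equal(back$s_ba2, params$s_ba2, tolerance = 1e-8)
  ba1 <- compute_biological_age(params, coh[1:50, params$biomarkers],
                                coh$age[1:50])
  ba2 <- compute_biological_age(back, coh[1:50, params$biomarkers],
                                coh$age[1:50])
  expect_equal(ba1, ba2, tolerance = 1e-6)
})
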
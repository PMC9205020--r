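test_that("proportion mediated follows IE/(IE + DE)", {
  expect_equal(proportion_mediated(0.5, 0.5), 0.5)
  expect_equal(proportion_mediated(0, 0.4), 0)
  expect_equal(proportion_mediated(0.2, 0.6), 0.25)
  expect_error(proportion_mediated(0.3, -0.3), "tolerance")
})

test_that("mediation draws are bit-identical under a fixed seed", {
  d <- sim_chain(400, a = 0.6, b = 0.5, cp = 0.4, seed = 30)
  r1 <- mediate_parallel(d, "x", "m", "y", n_sim = 200, seed = 17)
  r2 <- mediate_parallel(d, "x", "m", "y", n_sim = 200, seed = 17)
  expect_identical(r1$effects, r2$effects)
  expect_identical(r1$draws, r2$draws)
  r3 <- mediate_parallel(d, "x", "m", "y", n_sim = 200, seed = 18)
  expect_false(identical(r1$draws$ie, r3$draws$ie))
})

test_that("linear parallel mediation matches the product-of-coefficients oracle", {
  a <- 0.8; b <- 0.5; cp <- 0.6
  d <- sim_chain(8000, a = a, b = b, cp = cp, seed = 31)
  res <- mediate_parallel(d, "x", "m", "y", n_sim = 400, seed = 2)
  ie <- res$effects[res$effects$effect == "IE", ]
  se <- sd(res$draws$ie)
  expect_lt(abs(ie$estimate - a * b), 2 * se)
  # TE = IE + DE holds exactly for the averaged parallel decomposition
  expect_equal(res$draws$te, res$draws$ie + res$draws$de, tolerance = 1e-12)
  # and matches the no-mediator total-effect regression within MC error
  te_fit <- coef(lm(y ~ x, data = d))["x"]
  te <- res$effects[res$effects$effect == "TE", ]
  expect_lt(abs(te$estimate - te_fit), 3 * sd(res$draws$te))
})

test_that("null exposure-mediator path gives IE near zero with covering CI", {
  d <- sim_chain(6000, a = 0, b = 0.8, cp = 0.5, seed = 32)
  res <- mediate_parallel(d, "x", "m", "y", n_sim = 400, seed = 3)
  ie <- res$effects[res$effects$effect == "IE", ]
  expect_lt(ie$ci_low, 0)
  expect_gt(ie$ci_high, 0)
  expect_gt(ie$p_value, 0.05)
  prop <- res$effects[res$effects$effect == "prop_mediated", ]
  expect_lt(abs(prop$estimate), 0.1)
})

test_that("pure mediation puts the proportion-mediated CI around one", {
  d <- sim_chain(10000, a = 0.9, b = 0.6, cp = 0, seed = 33)
  res <- mediate_parallel(d, "x", "m", "y", n_sim = 400, seed = 4)
  prop <- res$effects[res$effects$effect == "prop_mediated", ]
  expect_lt(prop$ci_low, 1)
  expect_gt(prop$ci_high, 1 - 0.05)
})

test_that("IE sign tracks the sign of the generating paths", {
  for (paths in list(c(0.7, 0.5), c(-0.7, 0.5), c(0.7, -0.5))) {
    d <- sim_chain(4000, a = paths[1], b = paths[2], cp = 0.3,
                   seed = 34 + sum(paths > 0))
    res <- mediate_parallel(d, "x", "m", "y", n_sim = 300, seed = 5)
    ie <- res$effects[res$effects$effect == "IE", "estimate"]
    expect_equal(sign(ie), sign(prod(paths)))
  }
})

test_that("serial mediation matches the three-coefficient product oracle", {
  a1 <- 0.7; d21 <- 0.6; b2 <- 0.4
  d <- sim_serial_chain(8000, a1 = a1, d21 = d21, b2 = b2, cp = 0.3,
                        seed = 35)
  res <- mediate_serial(d, "x", c("m1", "m2"), "y", n_sim = 400, seed = 6)
  ie <- res$effects[res$effects$effect == "IE", "estimate"]
  expect_lt(abs(ie - a1 * d21 * b2), 2 * sd(res$draws$ie))
})

test_that("a broken first-to-second mediator link removes the serial path", {
  d <- sim_serial_chain(6000, a1 = 0.8, d21 = 0, b2 = 0.6, cp = 0.3,
                        seed = 36)
  res <- mediate_serial(d, "x", c("m1", "m2"), "y", n_sim = 400, seed = 7)
  ie <- res$effects[res$effects$effect == "IE", ]
  expect_lt(ie$ci_low, 0)
  expect_gt(ie$ci_high, 0)
})

test_that("swapping mediator order attenuates a strictly ordered serial path", {
  d <- sim_serial_chain(8000, a1 = 0.8, d21 = 0.7, b2 = 0.5, cp = 0.2,
                        seed = 37, x_to_m2 = 0, m1_to_y = 0)
  fwd <- mediate_serial(d, "x", c("m1", "m2"), "y", n_sim = 300, seed = 8)
  rev <- mediate_serial(d, "x", c("m2", "m1"), "y", n_sim = 300, seed = 8)
  ie_fwd <- fwd$effects[fwd$effects$effect == "IE", "estimate"]
  ie_rev <- rev$effects[rev$effects$effect == "IE", "estimate"]
  expect_lt(abs(ie_rev), abs(ie_fwd) / 2)
})

test_that("binary-outcome mediation on a synthetic cohort recovers the structure", {
  coh <- default_cohort()
  res <- mediate_parallel(coh, "ln_cd", "biological_age", "oa_status",
                          covariates = c("age_group", "sex"), n_sim = 300,
                          seed = 9)
  eff <- res$effects
  expect_gt(eff[eff$effect == "IE", "estimate"], 0)
  prop <- eff[eff$effect == "prop_mediated", "estimate"]
  expect_gt(prop, 0)
  expect_lt(prop, 1)
  # risk-difference scale: effects are small probabilities
  expect_lt(abs(eff[eff$effect == "TE", "estimate"]), 0.5)
})

test_that("mediation rejects malformed inputs", {
  d <- sim_chain(200, 0.5, 0.5, 0.5, seed = 38)
  expect_error(mediate_parallel(d, "x", "nope", "y", n_sim = 10, seed = 1),
               "not found")
  d$mb <- as.integer(d$m > 0)
  dd <- d; dd$mb <- as.character(dd$mb)
  expect_error(mediate_parallel(dd, "x", "mb", "y", n_sim = 10, seed = 1),
               "continuous")
  expect_error(mediate_serial(d, "x", c("m"), "y", n_sim = 10, seed = 1))
})
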
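test_that("uncertainty specs follow the published distribution assignments", {
  sp <- psa_specs(base_params)
  pn <- dplyr::filter(sp, parameter == "pn")
  expect_equal(pn$type, "beta")
  expect_equal(pn$alpha, 39)
  expect_equal(pn$beta, 892)
  # expert-opinion MV without counts: beta with configurable effective n
  mv <- dplyr::filter(sp, parameter == "pn_mv")
  expect_equal(mv$type, "beta")
  expect_equal(mv$alpha + mv$beta, 39)
  expect_equal(mv$alpha / (mv$alpha + mv$beta), 0.25)
  # fixed expert-opinion probabilities stay point masses
  expect_equal(dplyr::filter(sp, parameter == "np_mv")$type, "fixed")
  expect_equal(dplyr::filter(sp, parameter == "np_mv_died")$type, "fixed")
  # gamma costs: shape 1/cv^2, scale mean*cv^2 so the mean is preserved
  bd <- dplyr::filter(sp, parameter == "bed_day")
  expect_equal(bd$type, "gamma")
  expect_equal(bd$alpha, 1 / 0.2^2)
  expect_equal(bd$alpha * bd$beta, 71)
  expect_equal(attr(sp, "cost_cv"), 0.2)
  expect_equal(attr(sp, "mv_effective_n"), 39)
})

test_that("parameter draws have the specified means", {
  sp <- psa_specs(base_params)
  draws <- sample_parameter_draws(sp, 10000, seed = 5)
  expect_equal(mean(draws$pn), 39 / 931, tolerance = 0.0002 / 0.0419)
  expect_equal(mean(draws$bed_day), 71, tolerance = 0.3 / 71)
  expect_true(all(draws$pn > 0 & draws$pn < 1))
  expect_true(all(draws$bed_day > 0))
  expect_true(all(draws$np_mv == 0.24))
})

test_that("per-parameter substreams are stable under spec changes", {
  sp <- psa_specs(base_params)
  d1 <- sample_parameter_draws(sp, 100, seed = 3)
  # dropping one parameter leaves every other stream untouched
  d2 <- sample_parameter_draws(dplyr::filter(sp, parameter != "bed_day"),
                               100, seed = 3)
  expect_identical(d1$pn, d2$pn)
  expect_identical(d1$icu_day, d2$icu_day)
})

test_that("a sampled parameter set re-applies the RRR derivation to the draw", {
  ps_draw <- sample_parameter_set(base_params, seed = 17)
  expect_s3_class(ps_draw, "parameter_set")
  p_ctrl <- arm_probabilities(ps_draw, "no_mouthwash")
  p_mw <- arm_probabilities(ps_draw, "mouthwash")
  expect_equal(p_mw[["pn"]], p_ctrl[["pn"]] * 0.7, tolerance = 1e-12)
  expect_equal(p_mw[["pn_ccu"]], p_ctrl[["pn_ccu"]] * 0.7, tolerance = 1e-12)
  # the mouthwash MV probability keeps its fixed derived value
  expect_equal(p_mw[["pn_mv"]], 0.25 * 0.7, tolerance = 1e-12)
  expect_false(p_ctrl[["pn"]] == 39 / 931) # actually drawn
})

test_that("degenerate distributions reproduce the deterministic base case", {
  sp <- psa_specs(base_params)
  sp$type <- "fixed"
  psa <- run_psa(base_params, n = 25, seed = 1, specs = sp)
  ctrl <- evaluate_arm(base_params, "no_mouthwash")
  mw <- evaluate_arm(base_params, "mouthwash")
  expect_equal(psa$draws$cost_no_mouthwash, rep(ctrl$expected_cost, 25))
  expect_equal(psa$draws$cost_mouthwash, rep(mw$expected_cost, 25))
  expect_equal(psa$draws$delta_effect,
               rep(0.3 * ctrl$pneumonia_proportion, 25), tolerance = 1e-12)
  expect_equal(psa$summary$mean_delta_cost,
               mw$expected_cost - ctrl$expected_cost)
  cc <- ceac(psa)
  expect_true(all(cc$probability_cost_effective == 1))
})

test_that("fixed seeds reproduce the PSA bitwise", {
  a <- run_psa(base_params, n = 300, seed = 99)
  b <- run_psa(base_params, n = 300, seed = 99)
  expect_identical(a$draws, b$draws)
  c_ <- run_psa(base_params, n = 300, seed = 100)
  expect_false(identical(a$draws, c_$draws))
})

test_that("PSA mean incremental effect matches the published value", {
  psa <- run_psa(base_params, n = 10000, seed = 2024)
  expect_equal(psa$summary$mean_delta_effect, 0.012, tolerance = 0.001 / 0.012)
  # converges to rrr * E[beta draw of the control pneumonia probability]
  mc_se <- sd(psa$draws$delta_effect) / sqrt(psa$n_iterations)
  expect_lt(abs(psa$summary$mean_delta_effect - 0.3 * 39 / 931), 3 * mc_se)
  # all CEAC values from the output lie in [0,1]
  cc <- ceac(psa)
  expect_true(all(cc$probability_cost_effective >= 0 &
                    cc$probability_cost_effective <= 1))
  expect_equal(psa$metadata$cost_cv, 0.2)
  expect_equal(psa$metadata$mv_effective_n, 39)
})

test_that("PSA under the COVID overlay shifts the control pneumonia draws", {
  ps2 <- scenario_parameters(base_params, 2, "absolute_pp")
  psa <- run_psa(ps2, n = 2000, seed = 8)
  expect_equal(mean(psa$draws$delta_effect), 0.3 * (39 / 931 + 0.018),
               tolerance = 0.01)
  expect_equal(psa$metadata$covid_mode, "absolute_pp")
})
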
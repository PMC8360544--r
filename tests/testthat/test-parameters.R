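test_that("bundled fixture loads the published probability table", {
  pr <- base_params$probabilities
  pn <- dplyr::filter(pr, name == "pn")
  expect_equal(pn$events, 39)
  expect_equal(pn$total, 931)
  expect_equal(pn$value, 0.04)
  # every counted row agrees with events/total to printed rounding
  cc <- dplyr::filter(pr, !is.na(events))
  expect_true(all(abs(cc$value - cc$events / cc$total) <= 0.005))
  expect_setequal(base_params$los$pathway_class,
                  c("pn_ccu_mv", "pn_ccu_nomv", "pn_ward",
                    "np_ccu_mv", "np_ccu_nomv", "np_ward"))
  expect_equal(base_params$rrr, 0.3)
})

test_that("validation rejects malformed inputs with named errors", {
  bad <- base_params$probabilities
  bad$value[bad$name == "pn"] <- 1.2
  expect_error(new_parameter_set(bad, base_params$costs, base_params$los),
               "out of \\[0,1\\].*pn")

  no_icu <- dplyr::filter(base_params$costs, name != "icu_day")
  expect_error(new_parameter_set(base_params$probabilities, no_icu, base_params$los),
               "ICU day")

  off <- base_params$probabilities
  off$value[off$name == "pn"] <- 0.10 # far from 39/931
  expect_error(new_parameter_set(off, base_params$costs, base_params$los),
               "inconsistent with events/total")

  bad_los <- base_params$los
  bad_los$pathway_class[1] <- "pn_icu_mv"
  expect_error(new_parameter_set(base_params$probabilities, base_params$costs, bad_los),
               "pathway class|missing")
})

test_that("beta_from_counts parameterises by raw counts with continuity at edges", {
  bc <- beta_from_counts(39, 931)
  expect_equal(bc$alpha, 39)
  expect_equal(bc$beta, 892)
  expect_equal(bc$mean, 0.0418904, tolerance = 1e-5)
  expect_false(bc$degenerate)

  zero <- beta_from_counts(0, 10)
  expect_true(zero$degenerate)
  all_events <- beta_from_counts(931, 931)
  expect_true(all_events$degenerate)
  expect_error(beta_from_counts(10, 5), "events <= total")

  # sampling substitutes the +0.5/+0.5 correction for degenerate counts
  ps0 <- base_params
  ps0$probabilities$events[ps0$probabilities$name == "pn_ward_died"] <- 0
  ps0$probabilities$value[ps0$probabilities$name == "pn_ward_died"] <- 0
  sp <- psa_specs(ps0)
  row <- dplyr::filter(sp, parameter == "pn_ward_died")
  expect_equal(row$alpha, 0.5)
  expect_equal(row$beta, 75.5)
})

test_that("mouthwash arm derivation scales exactly the RRR-designated nodes", {
  p0 <- arm_probabilities(base_params, "no_mouthwash")
  p1 <- arm_probabilities(base_params, "mouthwash", rrr = 0.3)
  # published checks: 21/39 * 0.7 prints 0.38; 10/21 * 0.7 prints 0.33
  expect_equal(p1[["pn_ccu"]], (21 / 39) * 0.7, tolerance = 1e-12)
  expect_equal(round(p1[["pn_ccu"]], 2), 0.38)
  expect_equal(round(p1[["pn_mv_died"]], 2), 0.33)
  expect_equal(p1[["pn_mv"]], 0.25 * 0.7)
  # pneumonia ward death and all no-pneumonia nodes are copied unchanged
  same <- c("pn_ward_died", "np_ccu", "np_mv", "np_mv_died",
            "np_ccu_nomv_died", "np_ward_died")
  expect_equal(p1[same], p0[same])
  # identity at rrr = 0
  expect_equal(arm_probabilities(base_params, "mouthwash", rrr = 0), p0)
  expect_error(arm_probabilities(base_params, "mouthwash", rrr = 1), "rrr")

  ps_d <- derive_intervention_arm(base_params, 0.3)
  expect_equal(
    ps_d$probabilities$mouthwash_value[ps_d$probabilities$name == "pn_ccu"],
    (21 / 39) * 0.7
  )
})

test_that("derivation is monotone in rrr for scaled nodes", {
  rrrs <- seq(0, 0.9, by = 0.1)
  scaled <- c("pn", "pn_ccu", "pn_mv", "pn_mv_died", "pn_ccu_nomv_died")
  vals <- sapply(rrrs, function(r) arm_probabilities(base_params, "mouthwash", rrr = r)[scaled])
  expect_true(all(apply(vals, 1, function(v) all(diff(v) <= 0))))
})

test_that("covid overlay increments the control pneumonia probability", {
  null_ov <- covid_overlay("absolute_pp", pneumonia_increment = 0,
                           per_patient_cost = 0)
  ps0 <- apply_covid_overlay(base_params, null_ov)
  expect_equal(arm_probabilities(ps0, "no_mouthwash"),
               arm_probabilities(base_params, "no_mouthwash"))

  ps_abs <- scenario_parameters(base_params, 2, "absolute_pp")
  expect_equal(arm_probabilities(ps_abs, "no_mouthwash")[["pn"]],
               p_pn_control + 0.018, tolerance = 1e-12)

  ps_cal <- scenario_parameters(base_params, 2, "calibrated")
  p_cal <- arm_probabilities(ps_cal, "no_mouthwash")[["pn"]]
  expect_equal(p_cal, p_pn_control + 0.0028, tolerance = 1e-12)
  expect_equal(round(p_cal, 3), 0.045)

  big <- covid_overlay("absolute_pp", pneumonia_increment = 0.97,
                       per_patient_cost = 0)
  expect_error(apply_covid_overlay(base_params, big), "above 1")
})

test_that("overlay-then-derive commutes with derive-then-scaled-overlay", {
  # algebraic identity: (p + d) * (1 - r) == p * (1 - r) + (1 - r) * d
  for (d in c(0.005, 0.018, 0.05)) {
    for (r in c(0.1, 0.3, 0.6)) {
      ov <- covid_overlay("absolute_pp", pneumonia_increment = d,
                          per_patient_cost = 0)
      lhs <- arm_probabilities(apply_covid_overlay(base_params, ov),
                               "mouthwash", rrr = r)[["pn"]]
      rhs <- arm_probabilities(base_params, "mouthwash", rrr = r)[["pn"]] +
        (1 - r) * d
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
})

test_that("parameter sets round-trip through JSON", {
  path <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(base_params, path)
  ps2 <- read_parameter_set(path)
  expect_equal(ps2$probabilities, base_params$probabilities)
  expect_equal(ps2$costs, base_params$costs)
  expect_equal(ps2$los, base_params$los)
  expect_equal(ps2$rrr, base_params$rrr)
  expect_equal(arm_probabilities(ps2, "mouthwash"),
               arm_probabilities(base_params, "mouthwash"))
})
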
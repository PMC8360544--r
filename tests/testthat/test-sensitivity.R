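test_that("RRR sweep reproduces the published rows within tolerance", {
  sw <- rrr_sweep(base_params, c(0.3, 0.2, 0.1, 0.05, 0.01))
  expect_equal(sw$delta_cost[sw$tested_value == 0.2], -197, tolerance = 12 / 197)
  expect_equal(sw$delta_cost[sw$tested_value == 0.1], -101, tolerance = 10 / 101)
  expect_equal(sw$incremental_benefit[sw$tested_value == 0.2], 0.0084,
               tolerance = 0.005) # printed 4-dp rounding
  expect_equal(sw$incremental_benefit,
               sw$tested_value * p_pn_control, tolerance = 1e-12)
  expect_true(all(sw$classification == "intervention_dominates"))
})

test_that("zero RRR leaves only the chlorhexidine cost difference", {
  sw0 <- rrr_sweep(base_params, 0, breakoff = FALSE)
  expect_equal(sw0$delta_cost, 3, tolerance = 1e-9)
  expect_equal(sw0$incremental_benefit, 0)
})

test_that("sweep delta cost is monotone nonincreasing in rrr", {
  sw <- rrr_sweep(base_params, seq(0, 0.6, by = 0.1), breakoff = FALSE)
  expect_true(all(diff(sw$delta_cost) <= 1e-9))
})

test_that("one-way variation at conservative RRR fixes the incremental benefit", {
  bounds <- load_dsa_bounds()
  non_pn <- dplyr::filter(bounds, parameter != "pn")
  rows <- purrr::pmap(non_pn, function(parameter, kind, arm, lower, upper) {
    one_way(base_params, parameter, lower,
            arm = if (is.na(arm)) NULL else arm, rrr = 0.01)
  }) |> purrr::list_rbind()
  # 0.01 * 39/931 = 0.000419, printed 0.0004, for every non-pneumonia row
  expect_equal(rows$incremental_benefit,
               rep(0.01 * p_pn_control, nrow(rows)), tolerance = 1e-12)
  expect_equal(unique(round(rows$incremental_benefit, 4)), 4e-04)

  pc <- one_way(base_params, "pneumonia_episode", 121, rrr = 0.01)
  expect_equal(pc$incremental_benefit, 0.01 * p_pn_control, tolerance = 1e-12)
  expect_equal(pc$classification, "intervention_dominates")

  low_pn <- one_way(base_params, "pn", 0.03, arm = "no_mouthwash", rrr = 0.01)
  expect_lt(low_pn$incremental_benefit, 0)
  expect_equal(low_pn$classification, "comparator_dominates")
})

test_that("one-way at the base value reproduces the base row", {
  base_row <- rrr_sweep(base_params, 0.01, breakoff = FALSE)
  same <- one_way(base_params, "bed_day", 71, rrr = 0.01)
  expect_equal(same$delta_cost, base_row$delta_cost, tolerance = 1e-12)
  expect_equal(same$incremental_benefit, base_row$incremental_benefit,
               tolerance = 1e-12)

  same_p <- one_way(base_params, "pn_mv", 0.25, arm = "no_mouthwash", rrr = 0.01)
  expect_equal(same_p$delta_cost, base_row$delta_cost, tolerance = 1e-12)

  expect_error(one_way(base_params, "not_a_parameter", 1), "unknown parameter")
})

test_that("gel-cost break-off matches the published thresholds", {
  bo_base <- breakoff_search(base_params, "chlorhexidine", rrr = 0.3)
  expect_equal(bo_base, 289, tolerance = 15 / 289)
  bo_cons <- breakoff_search(base_params, "chlorhexidine", rrr = 0.01)
  expect_equal(bo_cons, 11, tolerance = 3 / 11)

  # consistency identity: break-off ~ current gel cost + |delta cost|
  ce <- run_comparison(base_params)
  expect_equal(bo_base, 3 + abs(ce$delta_cost), tolerance = 1e-2)
})

test_that("break-off substituted back leaves near-zero incremental cost", {
  for (r in c(0.3, 0.05)) {
    bo <- breakoff_search(base_params, "chlorhexidine", rrr = r)
    resid <- run_comparison(set_cost(base_params, "chlorhexidine", bo),
                            rrr = r)$delta_cost
    expect_lt(abs(resid), 0.5)
  }
  # a length-of-stay break-off, searched in days
  bo_los <- breakoff_search(base_params, "pn_ward", arm = "no_mouthwash",
                            rrr = 0.01)
  ps2 <- set_los(base_params, "pn_ward", bo_los, "no_mouthwash")
  expect_lt(abs(run_comparison(ps2, rrr = 0.01)$delta_cost), 0.2)
})

test_that("break-off search flags parameters with no crossing in range", {
  # comparator already dominates: gel cost can only increase delta cost
  ps_bad <- set_probability(base_params, "pn", 0.03, "no_mouthwash")
  expect_warning(bo <- breakoff_search(ps_bad, "chlorhexidine", rrr = 0.01),
                 "no break-off")
  expect_true(is.na(bo))
  expect_equal(attr(bo, "reason"), "no break-off in range")
})

test_that("extreme scenarios follow the published bound assignments", {
  no_mv <- extreme(base_params, "no_mv")
  expect_equal(no_mv$classification, "intervention_dominates")
  expect_lt(no_mv$delta_cost, 0)
  expect_gt(no_mv$delta_cost, -20)
  expect_equal(no_mv$delta_effect, 0.01 * p_pn_control, tolerance = 1e-12)

  best <- extreme(base_params, "best_case")
  expect_equal(best$classification, "intervention_dominates")
  # mouthwash pneumonia pinned at its 0.03 lower bound
  expect_equal(best$delta_effect, p_pn_control - 0.03, tolerance = 1e-12)
  expect_equal(round(best$delta_effect, 4), 0.0119)

  worst <- extreme(base_params, "worst_case")
  expect_equal(worst$classification, "comparator_dominates")
  expect_equal(round(worst$delta_effect, 4), -0.0081)

  # bounds equal to base values reproduce the base row
  bounds_same <- load_dsa_bounds()
  base_vals <- purrr::pmap_dbl(bounds_same, function(parameter, kind, arm, ...) {
    switch(kind,
      cost = cost_values(base_params)[[parameter]],
      prob = arm_probabilities(base_params, arm, rrr = 0.01)[[parameter]],
      los = los_values(base_params, arm)[[parameter]]
    )
  })
  bounds_same$lower <- base_vals
  bounds_same$upper <- base_vals
  base_row <- rrr_sweep(base_params, 0.01, breakoff = FALSE)
  best_same <- extreme(base_params, "best_case", bounds = bounds_same)
  expect_equal(best_same$delta_cost, base_row$delta_cost, tolerance = 1e-9)
})

test_that("the full DSA table has the expected row inventory", {
  bounds <- load_dsa_bounds()
  tbl <- dsa_table(base_params)
  # base + 4 sweep rows + two directions per bound + 3 extremes
  expect_equal(nrow(tbl), 1 + 4 + 2 * nrow(bounds) + 3)
  expect_named(tbl, c("parameter", "arm", "tested_value", "delta_cost",
                      "delta_cost_zar", "incremental_benefit", "breakoff",
                      "classification", "icer"))
  # empty bounds: sweep and extremes only
  tbl0 <- dsa_table(base_params, bounds = bounds[0, ])
  expect_equal(nrow(tbl0), 1 + 4 + 3)
  # Rand column mirrors the display factor
  expect_equal(tbl$delta_cost_zar, tbl$delta_cost * 17.35, tolerance = 1e-9)
})
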
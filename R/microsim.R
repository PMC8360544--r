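#' Microsimulation of individual patients through the pathway tree
#'
#' Routes `n` simulated patients through the decision tree by independent
#' Bernoulli draws at every branch node and costs each patient with the
#' same pathway costing as the cohort model. This is a brute-force
#' Monte-Carlo estimator of the analytic cohort expectations, used as an
#' independent oracle. Length of stay is deterministic at the class mean by
#' default (matching the cohort model exactly in expectation); an optional
#' gamma mode draws per-patient stays around the class mean for stress
#' testing.
#'
#' @param ps A `parameter_set`.
#' @param arm `"no_mouthwash"` or `"mouthwash"`.
#' @param n Number of simulated patients.
#' @param seed RNG seed.
#' @param rrr Relative risk reduction used to derive the mouthwash arm.
#' @param los_mode `"fixed"` (class mean) or `"gamma"` (per-patient draw
#'   with coefficient of variation `los_cv`, mean preserved).
#' @param los_cv Coefficient of variation for the gamma LoS mode.
#' @return Object of class `microsim_result`: the patient table, and
#'   estimates with Monte-Carlo standard errors.
#' @export
#' @examples
#' sim <- simulate_cohort(load_parameter_set(), "no_mouthwash", n = 5000, seed = 1)
#' sim$estimates
simulate_cohort <- function(ps, arm = c("no_mouthwash", "mouthwash"),
                            n = 200000, seed = 1, rrr = ps$rrr,
                            los_mode = c("fixed", "gamma"), los_cv = 0.3) {
  arm <- match.arg(arm)
  los_mode <- match.arg(los_mode)
  if (n < 1) abort("n must be at least 1")
  p <- arm_probabilities(ps, arm, rrr = rrr)
  co <- cost_values(ps)
  lo <- los_values(ps, arm)
  covid_cost <- if (is.null(ps$covid)) 0 else ps$covid$per_patient_cost

  set.seed(seed)
  pneumonia <- rbinom(n, 1, p[["pn"]]) == 1
  p_ccu <- if_else(pneumonia, p[["pn_ccu"]], p[["np_ccu"]])
  ccu <- rbinom(n, 1, p_ccu) == 1
  p_mv <- if_else(pneumonia, p[["pn_mv"]], p[["np_mv"]])
  mv <- ccu & (rbinom(n, 1, p_mv) == 1)
  p_die <- dplyr::case_when(
    pneumonia & mv ~ p[["pn_mv_died"]],
    pneumonia & ccu ~ p[["pn_ccu_nomv_died"]],
    pneumonia ~ p[["pn_ward_died"]],
    mv ~ p[["np_mv_died"]],
    ccu ~ p[["np_ccu_nomv_died"]],
    .default = p[["np_ward_died"]]
  )
  died <- rbinom(n, 1, p_die) == 1

  cls <- paste0(
    if_else(pneumonia, "pn", "np"),
    dplyr::case_when(mv ~ "_ccu_mv", ccu ~ "_ccu_nomv", .default = "_ward")
  )
  los_days <- unname(lo[cls])
  if (los_mode == "gamma") {
    los_days <- rgamma(n, shape = 1 / los_cv^2, scale = los_days * los_cv^2)
  }
  day_rate <- if_else(ccu, co[["icu_day"]], co[["bed_day"]])
  cost <- co[["procedure"]] + covid_cost +
    (arm == "mouthwash") * co[["chlorhexidine"]] +
    pneumonia * co[["pneumonia_episode"]] +
    los_days * day_rate +
    mv * co[["mv_episode"]]

  patients <- tibble(
    id = seq_len(n),
    arm = arm,
    pneumonia = pneumonia,
    location = if_else(ccu, "ccu", "ward"),
    mv = mv,
    outcome = if_else(died, "died", "discharged"),
    los_days = los_days,
    cost = cost
  )
  estimates <- tibble(
    arm = arm,
    n = n,
    mean_cost = mean(cost),
    se_cost = sd(cost) / sqrt(n),
    pneumonia_proportion = mean(pneumonia),
    se_pneumonia = sd(pneumonia) / sqrt(n)
  )
  structure(list(patients = patients, estimates = estimates, seed = seed),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat("<microsim_result>", x$estimates$arm, "n =", x$estimates$n, "\n")
  cat("  mean cost: $", format(round(x$estimates$mean_cost, 2)),
      " (se ", format(round(x$estimates$se_cost, 2)), ")\n", sep = "")
  invisible(x)
}

#' Synthesize a cohort event-count table
#'
#' Generates a surgical-cohort-style count table in the layout of the
#' published probability table by hierarchical binomial sampling down the
#' tree: the pneumonia events become the denominator of the downstream
#' pneumonia nodes, and so on. Feeding the counts back through
#' [new_parameter_set()] / [beta_from_counts()] recovers a parameter set,
#' enabling parameter-recovery tests without any deposited data.
#'
#' @param ps The generating (true) `parameter_set`.
#' @param n_patients Cohort size (the published control cohort is 931).
#' @param seed RNG seed.
#' @return Tibble with columns `name`, `events`, `total`, `value`,
#'   `distribution`; attributes carry the truth, seed and a
#'   `low_information` flag for degenerate cohorts.
#' @export
synthesize_cohort_tables <- function(ps, n_patients = 931, seed = 1) {
  if (n_patients < 1) abort("n_patients must be at least 1")
  p <- arm_probabilities(ps, "no_mouthwash")
  set.seed(seed)
  draw <- function(size, prob) if (size == 0) 0L else rbinom(1, size, prob)

  n_pn <- draw(n_patients, p[["pn"]])
  n_np <- n_patients - n_pn
  n_pn_ccu <- draw(n_pn, p[["pn_ccu"]])
  n_pn_ward <- n_pn - n_pn_ccu
  n_pn_mv <- draw(n_pn_ccu, p[["pn_mv"]])
  n_pn_nomv <- n_pn_ccu - n_pn_mv
  n_np_ccu <- draw(n_np, p[["np_ccu"]])
  n_np_ward <- n_np - n_np_ccu
  n_np_mv <- draw(n_np_ccu, p[["np_mv"]])
  n_np_nomv <- n_np_ccu - n_np_mv

  counts <- tibble(
    name = .prob_nodes,
    events = c(
      n_pn, n_pn_ccu, n_pn_mv,
      draw(n_pn_mv, p[["pn_mv_died"]]),
      draw(n_pn_nomv, p[["pn_ccu_nomv_died"]]),
      draw(n_pn_ward, p[["pn_ward_died"]]),
      n_np_ccu, n_np_mv,
      draw(n_np_mv, p[["np_mv_died"]]),
      draw(n_np_nomv, p[["np_ccu_nomv_died"]]),
      draw(n_np_ward, p[["np_ward_died"]])
    ),
    total = c(
      n_patients, n_pn, n_pn_ccu, n_pn_mv, n_pn_nomv, n_pn_ward,
      n_np, n_np_ccu, n_np_mv, n_np_nomv, n_np_ward
    )
  ) |>
    mutate(
      value = if_else(.data$total > 0, round(.data$events / .data$total, 2), 0),
      distribution = "beta_counts"
    )
  structure(
    counts,
    truth = p,
    seed = seed,
    low_information = any(counts$total == 0) ||
      any(counts$events == counts$total) || any(counts$events == 0),
    class = c("tbl_df", "tbl", "data.frame")
  )
}

#' Recover a parameter set from a synthetic cohort table
#'
#' Replaces the probability counts of a template parameter set with the
#' synthesized counts (nodes with an empty denominator keep the template's
#' value and lose their counts).
#'
#' @param ps Template `parameter_set` (costs, LoS and configuration reused).
#' @param cohort_table Output of [synthesize_cohort_tables()].
#' @return A validated `parameter_set`.
#' @export
recover_parameter_set <- function(ps, cohort_table) {
  tmpl <- ps$probabilities
  new_pr <- left_join(select(tmpl, "name", "label", "distribution"),
                      select(cohort_table, "name", "events", "total"),
                      by = "name") |>
    mutate(
      events = as.numeric(.data$events),
      total = as.numeric(.data$total),
      value = if_else(.data$total > 0, .data$events / .data$total,
                      tmpl$value[match(.data$name, tmpl$name)]),
      events = if_else(.data$total > 0, .data$events, NA_real_),
      total = if_else(.data$total > 0, .data$total, NA_real_)
    )
  new_parameter_set(new_pr, ps$costs, ps$los, ps$config)
}
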
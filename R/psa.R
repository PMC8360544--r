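# Deterministic per-parameter substream seed derived from one root seed, so
# adding or removing a parameter does not perturb the other draws.
.substream_seed <- function(root, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(root) + h * 1009) %% (.Machine$integer.max - 1L))
}

#' Uncertainty specifications for the probabilistic sensitivity analysis
#'
#' Builds the per-parameter distribution table: branch probabilities tagged
#' `beta_counts` become beta distributions parameterised by their recorded
#' counts (`alpha = events`, `beta = total - events`, with a +0.5/+0.5
#' continuity correction for all-or-nothing counts); the expert-opinion
#' ventilation probability without counts becomes a beta with a configurable
#' effective sample size; `fixed` probabilities are point masses. Costs take
#' gamma distributions with `shape = 1/cv^2`, `scale = mean * cv^2`, so each
#' draw mean equals the base cost.
#'
#' @param ps A `parameter_set`.
#' @param cost_cv Coefficient of variation for the gamma cost draws
#'   (the published analysis states no cost variance; default 0.2).
#' @param mv_effective_n Effective sample size for the expert-opinion MV
#'   beta (default 39, the pneumonia cohort size).
#' @return Tibble with one row per uncertain or fixed parameter.
#' @export
psa_specs <- function(ps,
                      cost_cv = ps$config$psa$cost_cv %||% 0.2,
                      mv_effective_n = ps$config$psa$mv_effective_n %||% 39) {
  pr <- ps$probabilities
  base_p <- .control_prob_values(ps)
  prob_specs <- pmap(pr, function(name, events, total, value, distribution, ...) {
    base <- base_p[[name]]
    if (distribution == "fixed") {
      tibble(parameter = name, kind = "prob", type = "fixed",
             alpha = NA_real_, beta = NA_real_, base = base)
    } else if (!is.na(events) && !is.na(total)) {
      bc <- beta_from_counts(events, total)
      a <- bc$alpha
      b <- bc$beta
      if (bc$degenerate) {
        a <- a + 0.5
        b <- b + 0.5
      }
      tibble(parameter = name, kind = "prob", type = "beta",
             alpha = a, beta = b, base = base)
    } else {
      tibble(parameter = name, kind = "prob", type = "beta",
             alpha = base * mv_effective_n, beta = (1 - base) * mv_effective_n,
             base = base)
    }
  }) |> list_rbind()

  base_c <- cost_values(ps)
  cost_specs <- pmap(ps$costs, function(name, distribution, ...) {
    base <- base_c[[name]]
    if (distribution == "fixed" || cost_cv == 0 || base == 0) {
      tibble(parameter = name, kind = "cost", type = "fixed",
             alpha = NA_real_, beta = NA_real_, base = base)
    } else {
      tibble(parameter = name, kind = "cost", type = "gamma",
             alpha = 1 / cost_cv^2, beta = base * cost_cv^2, base = base)
    }
  }) |> list_rbind()

  out <- bind_rows(prob_specs, cost_specs)
  attr(out, "cost_cv") <- cost_cv
  attr(out, "mv_effective_n") <- mv_effective_n
  out
}

#' Draw parameter values from their uncertainty specifications
#'
#' Each parameter uses its own deterministic substream derived from the
#' root seed (beta for probabilities, gamma for costs, constant for fixed
#' parameters); draws are independent across parameters.
#'
#' @param specs Spec table from [psa_specs()].
#' @param n Number of draws.
#' @param seed Root seed.
#' @return Tibble of `n` rows, one column per parameter.
#' @export
sample_parameter_draws <- function(specs, n, seed) {
  cols <- pmap(specs, function(parameter, kind, type, alpha, beta, base) {
    if (type == "fixed") return(rep(base, n))
    set.seed(.substream_seed(seed, parameter))
    switch(type,
      beta = rbeta(n, alpha, beta),
      gamma = rgamma(n, shape = alpha, scale = beta)
    )
  })
  names(cols) <- specs$parameter
  as_tibble(cols)
}

#' Sample one probabilistic parameter set
#'
#' Draws every uncertain parameter once and returns a full `parameter_set`
#' carrying the drawn values, so the RRR derivation of the mouthwash arm is
#' re-applied to the draw. The mouthwash-arm ventilation probability keeps
#' its fixed derived value, matching the published distribution
#' assignments.
#'
#' @param ps Base `parameter_set`.
#' @param specs Spec table from [psa_specs()].
#' @param seed Root seed.
#' @return A `parameter_set` with drawn values.
#' @export
sample_parameter_set <- function(ps, specs = psa_specs(ps), seed = 1) {
  draw <- sample_parameter_draws(specs, 1, seed)
  out <- ps
  out$probabilities <- mutate(
    ps$probabilities,
    value = unname(unlist(draw[.data$name])),
    events = NA_integer_, total = NA_integer_
  )
  out$costs <- mutate(
    ps$costs,
    adjusted_2020_intl_usd = unname(unlist(draw[.data$name]))
  )
  # keep the mouthwash MV probability at its fixed derived value
  out <- set_probability(out, "pn_mv",
                         .control_prob_values(ps)[["pn_mv"]] * (1 - ps$rrr),
                         "mouthwash")
  validate_parameter_set(out)
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' Draws all parameters simultaneously for each iteration, re-applies the
#' RRR derivation to every draw, evaluates both arms through the pathway
#' tree, and records the per-iteration incremental cost and incremental
#' effect (reduction in pneumonia proportion).
#'
#' @param ps A `parameter_set` (scenario attached, if any).
#' @param n Number of Monte Carlo iterations (default 10,000).
#' @param seed Root seed; fixed seeds reproduce draws bitwise.
#' @param specs Spec table from [psa_specs()].
#' @return Object of class `psa_output` with the draw table, summary
#'   statistics (means, 95% intervals, cost-effectiveness-plane quadrant
#'   fractions) and sampling metadata.
#' @export
#' @examples
#' psa <- run_psa(load_parameter_set(), n = 200, seed = 7)
#' glance(psa)
run_psa <- function(ps, n = ps$config$psa$n_iterations %||% 10000,
                    seed = ps$config$psa$seed %||% 1,
                    specs = psa_specs(ps)) {
  if (n < 1) abort("n must be at least 1")
  draws <- sample_parameter_draws(specs, n, seed)

  p_ctrl <- as.list(draws[.prob_nodes])
  if (!is.null(ps$covid)) {
    p_ctrl$pn <- p_ctrl$pn + ps$covid$pneumonia_increment
    if (any(p_ctrl$pn > 1)) abort("covid overlay pushes a drawn pneumonia probability above 1")
  }
  p_mw <- p_ctrl
  for (nm in .rrr_scaled_nodes) p_mw[[nm]] <- p_ctrl[[nm]] * (1 - ps$rrr)
  # fixed derived value, not re-drawn (expert-opinion assignment)
  p_mw$pn_mv <- rep(.control_prob_values(ps)[["pn_mv"]] * (1 - ps$rrr), n)

  co <- as.list(draws[.cost_items])
  lo_ctrl <- as.list(los_values(ps, "no_mouthwash"))
  lo_mw <- as.list(los_values(ps, "mouthwash"))
  covid_cost <- if (is.null(ps$covid)) 0 else ps$covid$per_patient_cost

  ctrl <- .arm_values(p_ctrl, co, lo_ctrl, mouthwash = FALSE, covid_cost = covid_cost)
  mw <- .arm_values(p_mw, co, lo_mw, mouthwash = TRUE, covid_cost = covid_cost)

  draw_tbl <- tibble(
    iteration = seq_len(n),
    cost_mouthwash = mw$expected_cost,
    cost_no_mouthwash = ctrl$expected_cost,
    delta_cost = mw$expected_cost - ctrl$expected_cost,
    delta_effect = ctrl$pneumonia_proportion - mw$pneumonia_proportion
  )
  if (!all(is.finite(draw_tbl$delta_cost)) || !all(is.finite(draw_tbl$delta_effect))) {
    abort("non-finite PSA draw")
  }

  summary_tbl <- tibble(
    n_iterations = n,
    mean_cost_mouthwash = mean(draw_tbl$cost_mouthwash),
    mean_cost_no_mouthwash = mean(draw_tbl$cost_no_mouthwash),
    mean_delta_cost = mean(draw_tbl$delta_cost),
    mean_delta_effect = mean(draw_tbl$delta_effect),
    delta_cost_lo = unname(quantile(draw_tbl$delta_cost, 0.025)),
    delta_cost_hi = unname(quantile(draw_tbl$delta_cost, 0.975)),
    frac_se = mean(draw_tbl$delta_cost < 0 & draw_tbl$delta_effect > 0),
    frac_ne = mean(draw_tbl$delta_cost >= 0 & draw_tbl$delta_effect > 0),
    frac_sw = mean(draw_tbl$delta_cost < 0 & draw_tbl$delta_effect <= 0),
    frac_nw = mean(draw_tbl$delta_cost >= 0 & draw_tbl$delta_effect <= 0)
  )

  structure(
    list(
      draws = draw_tbl,
      seed = seed,
      n_iterations = n,
      summary = summary_tbl,
      metadata = list(
        cost_cv = attr(specs, "cost_cv"),
        mv_effective_n = attr(specs, "mv_effective_n"),
        rrr = ps$rrr,
        covid_mode = if (is.null(ps$covid)) NA_character_ else ps$covid$mode
      )
    ),
    class = "psa_output"
  )
}

#' @export
print.psa_output <- function(x, ...) {
  cat("<psa_output>", x$n_iterations, "iterations, seed", x$seed, "\n")
  cat("  mean delta cost: $", format(round(x$summary$mean_delta_cost, 1)),
      "  mean delta effect: ", format(round(x$summary$mean_delta_effect, 4)),
      "\n", sep = "")
  cat("  fraction cheaper & more effective:",
      format(round(x$summary$frac_se, 3)), "\n")
  invisible(x)
}

#' Tidiers for PSA output
#'
#' `tidy()` returns the per-iteration draw table; `glance()` the one-row
#' summary.
#'
#' @param x A `psa_output`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.psa_output <- function(x, ...) x$draws

#' @rdname tidy.psa_output
#' @export
glance.psa_output <- function(x, ...) x$summary
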
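#' Compare the mouthwash and no-mouthwash arms
#'
#' Computes the incremental cost (intervention minus comparator), the
#' incremental effect as the reduction in the proportion of pneumonia
#' patients (comparator minus intervention), and the dominance
#' classification. The intervention dominates when it is cheaper and more
#' effective; the comparator dominates when the intervention is dearer and
#' less effective; otherwise an incremental cost-effectiveness ratio
#' (dollars per unit reduction in pneumonia proportion) is reported. A
#' zero-effect tie yields an ICER flagged indeterminate (`Inf`) unless the
#' cost difference is also zero.
#'
#' @param intervention,comparator `arm_result` objects from [evaluate_arm()]
#'   evaluated under the same scenario.
#' @return An object of class `cea_result`.
#' @export
#' @examples
#' ps <- load_parameter_set()
#' compare_arms(evaluate_arm(ps, "mouthwash"), evaluate_arm(ps, "no_mouthwash"))
compare_arms <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "arm_result"), inherits(comparator, "arm_result"))
  delta_cost <- intervention$expected_cost - comparator$expected_cost
  delta_effect <- comparator$pneumonia_proportion - intervention$pneumonia_proportion
  if (delta_cost < 0 && delta_effect > 0) {
    classification <- "intervention_dominates"
    icer <- NA_real_
  } else if (delta_cost > 0 && delta_effect < 0) {
    classification <- "comparator_dominates"
    icer <- NA_real_
  } else {
    classification <- "icer"
    icer <- if (delta_effect == 0) {
      if (delta_cost == 0) NA_real_ else Inf
    } else {
      delta_cost / delta_effect
    }
  }
  structure(
    list(
      delta_cost = delta_cost,
      delta_effect = delta_effect,
      classification = classification,
      icer_value = icer,
      intervention = intervention,
      comparator = comparator
    ),
    class = "cea_result"
  )
}

#' Evaluate both arms and compare them
#'
#' Convenience wrapper: evaluates the comparator and the RRR-derived
#' mouthwash arm under the parameter set's scenario and compares them.
#'
#' @param ps A `parameter_set`.
#' @param rrr Relative risk reduction.
#' @return A `cea_result`.
#' @export
run_comparison <- function(ps, rrr = ps$rrr) {
  compare_arms(
    evaluate_arm(ps, "mouthwash", rrr = rrr),
    evaluate_arm(ps, "no_mouthwash", rrr = rrr)
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat("  delta cost: $", format(round(x$delta_cost, 2)),
      "  delta effect: ", format(round(x$delta_effect, 4)), "\n", sep = "")
  cat("  classification:", x$classification, "\n")
  if (x$classification == "icer") {
    cat("  ICER: $", format(round(x$icer_value)), " per unit reduction\n", sep = "")
  }
  invisible(x)
}

#' Tidiers for arm comparisons
#'
#' `glance()` returns the one-row incremental summary; `tidy()` returns the
#' per-arm summaries side by side.
#'
#' @param x A `cea_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.cea_result <- function(x, ...) {
  tibble(
    delta_cost = x$delta_cost,
    delta_effect = x$delta_effect,
    classification = x$classification,
    icer_value = x$icer_value
  )
}

#' @rdname glance.cea_result
#' @export
tidy.cea_result <- function(x, ...) {
  bind_rows(glance(x$intervention), glance(x$comparator))
}

#' Net monetary benefit
#'
#' `NMB = wtp * delta_effect - delta_cost`, with willingness to pay
#' expressed per unit reduction in the proportion of pneumonia patients.
#'
#' @param ce A `cea_result`, or a data frame of draws with columns
#'   `delta_cost` and `delta_effect`.
#' @param wtp Nonnegative willingness-to-pay threshold(s).
#' @return For a `cea_result`, a numeric vector along `wtp`; for a draws
#'   table, a tibble of draws by thresholds in long format.
#' @export
net_benefit <- function(ce, wtp) {
  if (any(wtp < 0)) abort("willingness to pay must be nonnegative")
  if (inherits(ce, "cea_result")) {
    return(wtp * ce$delta_effect - ce$delta_cost)
  }
  df <- as_tibble(ce)
  stopifnot(all(c("delta_cost", "delta_effect") %in% names(df)))
  tidyr::expand_grid(
    tibble(draw = seq_len(nrow(df)), delta_cost = df$delta_cost,
           delta_effect = df$delta_effect),
    wtp = wtp
  ) |>
    mutate(nmb = .data$wtp * .data$delta_effect - .data$delta_cost)
}

#' Willingness-to-pay grid
#'
#' @param min,max,step Grid limits and spacing in dollars per unit reduction
#'   in pneumonia proportion (defaults: 0 to 30,000 by 250).
#' @return Numeric vector of thresholds.
#' @export
wtp_grid <- function(min = 0, max = 30000, step = 250) seq(min, max, by = step)

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay threshold, the probability that the
#' intervention is cost-effective is the fraction of draws with positive
#' net monetary benefit; draws with exactly zero net benefit count one half.
#'
#' @param draws Data frame of probabilistic draws with columns `delta_cost`
#'   and `delta_effect`, or a `psa_output`.
#' @param wtp Vector of willingness-to-pay thresholds.
#' @return Tibble of class `mw_ceac` with columns `wtp` and
#'   `probability_cost_effective`.
#' @export
ceac <- function(draws, wtp = wtp_grid()) {
  if (inherits(draws, "psa_output")) draws <- draws$draws
  draws <- as_tibble(draws)
  if (nrow(draws) == 0) abort("ceac requires at least one draw")
  if (any(wtp < 0)) abort("willingness to pay must be nonnegative")
  pce <- map_dbl(wtp, function(l) {
    nmb <- l * draws$delta_effect - draws$delta_cost
    (sum(nmb > 0) + 0.5 * sum(nmb == 0)) / length(nmb)
  })
  structure(
    tibble(wtp = wtp, probability_cost_effective = pce),
    class = c("mw_ceac", "tbl_df", "tbl", "data.frame")
  )
}
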
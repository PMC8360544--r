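# Infer whether a DSA parameter names a cost item, a branch probability or
# a length-of-stay class (the three name spaces are disjoint).
.param_kind <- function(parameter) {
  if (parameter %in% .cost_items) return("cost")
  if (parameter %in% .prob_nodes) return("prob")
  if (parameter %in% .los_classes) return("los")
  abort(paste0("unknown parameter: ", parameter))
}

.apply_override <- function(ps, parameter, value, arm = NULL) {
  switch(.param_kind(parameter),
    cost = set_cost(ps, parameter, value),
    prob = {
      if (is.null(arm)) abort("probability overrides need an arm")
      set_probability(ps, parameter, value, arm)
    },
    los = {
      if (is.null(arm)) abort("length-of-stay overrides need an arm")
      set_los(ps, parameter, value, arm)
    }
  )
}

.base_param_value <- function(ps, parameter, arm = NULL) {
  switch(.param_kind(parameter),
    cost = cost_values(ps)[[parameter]],
    prob = arm_probabilities(ps, arm)[[parameter]],
    los = los_values(ps, arm)[[parameter]]
  )
}

# One Table-6-shaped row from a comparison.
.dsa_row <- function(ce, parameter, tested_value, arm = NA_character_,
                     breakoff = NA_real_, zar = 17.35) {
  tibble(
    parameter = parameter,
    arm = arm,
    tested_value = tested_value,
    delta_cost = ce$delta_cost,
    delta_cost_zar = to_display_zar(ce$delta_cost, factor = zar),
    incremental_benefit = ce$delta_effect,
    breakoff = breakoff,
    classification = ce$classification,
    icer = ce$icer_value
  )
}

.display_zar_factor <- function(ps) {
  ps$config$display$zar_per_intl_usd %||% 17.35
}

#' Relative-risk-reduction sweep
#'
#' Re-evaluates the full comparison at each candidate RRR, all other
#' parameters at base, and reports the Table-6-style row including the
#' chlorhexidine-cost dominance break-off point at that RRR.
#'
#' @param ps A `parameter_set` (scenario attached, if any).
#' @param rrr_values RRR values to test, each in `[0, 1)`.
#' @param breakoff Also compute the gel-cost break-off per RRR (default TRUE).
#' @return Tibble with one row per RRR.
#' @export
#' @examples
#' rrr_sweep(load_parameter_set(), c(0.3, 0.2, 0.1))
rrr_sweep <- function(ps, rrr_values = c(0.3, 0.2, 0.1, 0.05, 0.01),
                      breakoff = TRUE) {
  zar <- .display_zar_factor(ps)
  map(rrr_values, function(r) {
    ce <- run_comparison(ps, rrr = r)
    bo <- if (breakoff) breakoff_search(ps, "chlorhexidine", rrr = r) else NA_real_
    .dsa_row(ce, "rrr", r, breakoff = as.numeric(bo), zar = zar)
  }) |>
    list_rbind()
}

#' One-way deterministic sensitivity analysis
#'
#' Sets a single parameter to a tested value, holding everything else at
#' base, and re-evaluates the comparison at a conservative RRR (default
#' 0.01, matching the published analysis design). Overriding an
#' intervention-arm parameter replaces its RRR-derived value.
#'
#' @param ps A `parameter_set`.
#' @param parameter Cost item, probability node, or pathway class.
#' @param value Tested value.
#' @param arm Arm whose parameter is varied (required except for costs).
#' @param rrr RRR context for the evaluation.
#' @return One Table-6-shaped tibble row.
#' @export
one_way <- function(ps, parameter, value, arm = NULL, rrr = 0.01) {
  ps2 <- .apply_override(ps, parameter, value, arm)
  ce <- run_comparison(ps2, rrr = rrr)
  .dsa_row(ce, parameter, value, arm = arm %||% NA_character_,
           zar = .display_zar_factor(ps))
}

#' Dominance break-off threshold search
#'
#' Finds the value of a parameter at which the incremental cost crosses
#' zero (the dominant strategy stops being cheaper), by sign-change
#' bracketing from the base value (doubling the bracket up to ten times in
#' each direction) followed by bisection to $0.5 for costs and 0.05 days
#' for lengths of stay.
#'
#' @param ps A `parameter_set`.
#' @param parameter Parameter searched over.
#' @param arm Arm of the parameter (probabilities and LoS).
#' @param rrr RRR context.
#' @param tol Absolute tolerance on the parameter value at the crossing.
#' @return The break-off value, or `NA` (with a warning and attribute
#'   `reason = "no break-off in range"`) when the incremental cost does not
#'   change sign within the widened bracket.
#' @export
#' @examples
#' breakoff_search(load_parameter_set(), "chlorhexidine", rrr = 0.3)
breakoff_search <- function(ps, parameter, arm = NULL, rrr = ps$rrr,
                            tol = if (.param_kind(parameter) == "los") 0.05 else 0.5) {
  f <- function(v) {
    run_comparison(.apply_override(ps, parameter, v, arm), rrr = rrr)$delta_cost
  }
  base <- .base_param_value(ps, parameter, arm %||% "no_mouthwash")
  d_base <- f(base)
  if (d_base == 0) return(base)

  step0 <- max(abs(base), 1)
  bracket <- NULL
  for (dir in c(1, -1)) {
    step <- step0
    lo <- base
    for (i in seq_len(10)) {
      hi <- max(base + dir * step, 0)
      if (.param_kind(parameter) == "prob") hi <- min(hi, 1)
      d_hi <- f(hi)
      if (sign(d_hi) != sign(d_base)) {
        bracket <- sort(c(lo, hi))
        break
      }
      if (hi == 0 || (.param_kind(parameter) == "prob" && hi == 1)) break
      lo <- hi
      step <- step * 2
    }
    if (!is.null(bracket)) break
  }
  if (is.null(bracket)) {
    warn(paste0("no break-off in range for ", parameter))
    return(structure(NA_real_, reason = "no break-off in range"))
  }
  uniroot(f, interval = bracket, tol = tol)$root
}

#' Extreme scenario analysis
#'
#' Evaluates the three published extreme cases at a conservative RRR:
#' `no_mv` sets every mechanical-ventilation probability to zero in both
#' arms; `best_case` puts the mouthwash arm's pneumonia, critical-care and
#' ventilation probabilities and its pneumonia lengths of stay at their
#' lower bounds while the bed-day and pneumonia-episode costs take their
#' upper bounds; `worst_case` reverses the bounds.
#'
#' @param ps A `parameter_set`.
#' @param label `"no_mv"`, `"best_case"` or `"worst_case"`.
#' @param rrr RRR context (default 0.01 as in the published design).
#' @param bounds DSA bounds table (default: bundled fixture).
#' @return A `cea_result`.
#' @export
extreme <- function(ps, label = c("no_mv", "best_case", "worst_case"),
                    rrr = 0.01, bounds = load_dsa_bounds()) {
  label <- match.arg(label)
  if (label == "no_mv") {
    for (arm in .arms) {
      ps <- set_probability(ps, "pn_mv", 0, arm)
      ps <- set_probability(ps, "np_mv", 0, arm)
    }
    return(run_comparison(ps, rrr = rrr))
  }
  mw_bounds <- filter(bounds, .data$arm %in% "mouthwash",
                      .data$parameter %in% c("pn", "pn_ccu", "pn_mv") |
                        .data$kind == "los")
  cost_bounds <- filter(bounds, .data$kind == "cost")
  probs_at <- if (label == "best_case") "lower" else "upper"
  costs_at <- if (label == "best_case") "upper" else "lower"
  for (i in seq_len(nrow(mw_bounds))) {
    row <- mw_bounds[i, ]
    ps <- .apply_override(ps, row$parameter, row[[probs_at]], "mouthwash")
  }
  for (i in seq_len(nrow(cost_bounds))) {
    row <- cost_bounds[i, ]
    ps <- set_cost(ps, row$parameter, row[[costs_at]])
  }
  run_comparison(ps, rrr = rrr)
}

#' Load the deterministic sensitivity bounds table
#'
#' @param path CSV with columns `parameter`, `kind`, `arm`, `lower`,
#'   `upper` (default: bundled fixture carrying the published bounds).
#' @return Tibble of bounds.
#' @export
load_dsa_bounds <- function(path = mw_extdata("dsa_bounds.csv")) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Full deterministic sensitivity analysis table
#'
#' Emits the complete published-layout DSA table for the scenario attached
#' to the parameter set: the base-case row, the RRR sweep with gel-cost
#' break-offs, every one-way bound variation at the conservative RRR, and
#' the three extreme scenarios.
#'
#' @param ps A `parameter_set`.
#' @param bounds Bounds table (default: bundled fixture).
#' @param rrr_values RRR sweep values.
#' @param rrr_oneway Conservative RRR for one-way rows and extremes.
#' @return Tibble in published column order.
#' @export
dsa_table <- function(ps, bounds = load_dsa_bounds(),
                      rrr_values = c(0.2, 0.1, 0.05, 0.01),
                      rrr_oneway = 0.01) {
  zar <- .display_zar_factor(ps)
  base_ce <- run_comparison(ps)
  base_row <- .dsa_row(base_ce, "base_case", NA_real_,
                       breakoff = as.numeric(breakoff_search(ps, "chlorhexidine")),
                       zar = zar)
  sweep <- rrr_sweep(ps, rrr_values)
  oneway <- pmap(bounds, function(parameter, kind, arm, lower, upper) {
    arm <- if (is.na(arm)) NULL else arm
    bind_rows(
      one_way(ps, parameter, lower, arm = arm, rrr = rrr_oneway),
      one_way(ps, parameter, upper, arm = arm, rrr = rrr_oneway)
    )
  }) |>
    list_rbind()
  extremes <- map(c("no_mv", "best_case", "worst_case"), function(lbl) {
    .dsa_row(extreme(ps, lbl, rrr = rrr_oneway, bounds = bounds), lbl,
             NA_real_, zar = zar)
  }) |>
    list_rbind()
  bind_rows(base_row, sweep, oneway, extremes)
}
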
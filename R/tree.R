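# The twelve terminal pathways per arm: pneumonia status x location, with
# the ventilation split inside critical care, each ending in died or
# discharged by 30 days.
.pathway_grid <- function() {
  one_status <- tibble(
    location = rep(c("ccu", "ccu", "ward"), each = 2),
    mv = rep(c(TRUE, FALSE, NA), each = 2),
    outcome = rep(c("died", "discharged"), 3)
  )
  bind_rows(
    mutate(one_status, pneumonia = TRUE),
    mutate(one_status, pneumonia = FALSE)
  ) |>
    select("pneumonia", "location", "mv", "outcome")
}

# Joint probability of each grid pathway given branch probabilities `p`
# (a named list/vector; elements may be vectors for the PSA, in which case
# the result is a list of vectors in grid order).
.joint_probability <- function(p, grid) {
  pmap(grid, function(pneumonia, location, mv, outcome) {
    pr <- if (pneumonia) p[["pn"]] else 1 - p[["pn"]]
    if (pneumonia) {
      if (location == "ccu") {
        pr <- pr * p[["pn_ccu"]]
        if (mv) {
          pr <- pr * p[["pn_mv"]]
          pr * (if (outcome == "died") p[["pn_mv_died"]] else 1 - p[["pn_mv_died"]])
        } else {
          pr <- pr * (1 - p[["pn_mv"]])
          pr * (if (outcome == "died") p[["pn_ccu_nomv_died"]] else 1 - p[["pn_ccu_nomv_died"]])
        }
      } else {
        pr <- pr * (1 - p[["pn_ccu"]])
        pr * (if (outcome == "died") p[["pn_ward_died"]] else 1 - p[["pn_ward_died"]])
      }
    } else {
      if (location == "ccu") {
        pr <- pr * p[["np_ccu"]]
        if (mv) {
          pr <- pr * p[["np_mv"]]
          pr * (if (outcome == "died") p[["np_mv_died"]] else 1 - p[["np_mv_died"]])
        } else {
          pr <- pr * (1 - p[["np_mv"]])
          pr * (if (outcome == "died") p[["np_ccu_nomv_died"]] else 1 - p[["np_ccu_nomv_died"]])
        }
      } else {
        pr <- pr * (1 - p[["np_ccu"]])
        pr * (if (outcome == "died") p[["np_ward_died"]] else 1 - p[["np_ward_died"]])
      }
    }
  })
}

# Per-patient cost of each grid pathway. Decedents accrue the full mean
# length of stay of their class (no outcome-stratified LoS is available).
# `co` and `lo` are named lists/vectors; elements may be vectors (PSA).
.pathway_cost_values <- function(grid, co, lo, mouthwash, covid_cost = 0) {
  base <- co[["procedure"]] + covid_cost +
    if (mouthwash) co[["chlorhexidine"]] else 0
  pmap(grid, function(pneumonia, location, mv, outcome) {
    cost <- base + if (pneumonia) co[["pneumonia_episode"]] else 0
    cls <- paste0(if (pneumonia) "pn" else "np",
                  if (location == "ccu") {
                    if (mv) "_ccu_mv" else "_ccu_nomv"
                  } else "_ward")
    day_rate <- if (location == "ccu") co[["icu_day"]] else co[["bed_day"]]
    cost <- cost + lo[[cls]] * day_rate
    if (location == "ccu" && mv) cost <- cost + co[["mv_episode"]]
    cost
  })
}

# Shared numeric core: expected cost and pneumonia proportion for one arm,
# elementwise over vector-valued parameters. Both the cohort evaluation and
# the PSA go through this, in identical summation order.
.arm_values <- function(p, co, lo, mouthwash, covid_cost = 0) {
  grid <- .pathway_grid()
  joint <- .joint_probability(p, grid)
  cost <- .pathway_cost_values(grid, co, lo, mouthwash, covid_cost)
  expected <- Reduce(`+`, Map(`*`, joint, cost))
  list(expected_cost = expected, pneumonia_proportion = p[["pn"]])
}

#' Enumerate the terminal pathways of one arm
#'
#' Expands the pathway tree for the requested arm into its ten terminal
#' routes (pneumonia status, ward or critical care, ventilation within
#' critical care, died or discharged by 30 days), with the joint probability
#' along the branches, the per-patient cost, and the effect payload (1 for
#' pneumonia-free pathways, 0 for pneumonia pathways).
#'
#' @param ps A `parameter_set`.
#' @param arm `"no_mouthwash"` or `"mouthwash"`.
#' @param rrr Relative risk reduction used to derive the mouthwash arm.
#' @return Tibble with one row per terminal pathway.
#' @export
#' @examples
#' enumerate_pathways(load_parameter_set(), "no_mouthwash")
enumerate_pathways <- function(ps, arm = c("no_mouthwash", "mouthwash"),
                               rrr = ps$rrr) {
  arm <- match.arg(arm)
  p <- arm_probabilities(ps, arm, rrr = rrr)
  co <- cost_values(ps)
  lo <- los_values(ps, arm)
  covid_cost <- if (is.null(ps$covid)) 0 else ps$covid$per_patient_cost
  grid <- .pathway_grid()
  is_mw <- arm == "mouthwash"
  grid |>
    mutate(
      arm = !!arm,
      joint_probability = unlist(.joint_probability(p, grid)),
      cost = unlist(.pathway_cost_values(grid, co, lo, is_mw, covid_cost)),
      effect = as.integer(!.data$pneumonia)
    ) |>
    select("arm", "pneumonia", "location", "mv", "outcome",
           "joint_probability", "cost", "effect")
}

#' Per-patient cost of pathways
#'
#' Costs a pathway as: procedure cost for every patient, the two-dose
#' chlorhexidine cost in the mouthwash arm, the pneumonia episode cost for
#' pneumonia patients, the class mean length of stay times the ward or
#' critical-care daily rate, the mechanical ventilation episode cost for
#' ventilated patients, and the pandemic per-patient cost when a COVID-19
#' overlay is active.
#'
#' @param pathways Tibble with columns `pneumonia`, `location`, `mv`
#'   (as returned by [enumerate_pathways()]).
#' @param ps A `parameter_set`.
#' @param arm Arm the pathways belong to.
#' @return Numeric vector of per-patient costs (2020 international $).
#' @export
pathway_cost <- function(pathways, ps, arm = c("no_mouthwash", "mouthwash")) {
  arm <- match.arg(arm)
  co <- cost_values(ps)
  lo <- los_values(ps, arm)
  covid_cost <- if (is.null(ps$covid)) 0 else ps$covid$per_patient_cost
  unlist(.pathway_cost_values(
    select(pathways, "pneumonia", "location", "mv",
           dplyr::any_of("outcome")) |>
      mutate(outcome = if ("outcome" %in% names(pathways)) .data$outcome else "discharged"),
    co, lo, arm == "mouthwash", covid_cost
  ))
}

#' Evaluate the cohort expectation for one arm
#'
#' Computes the probability-weighted expected 30-day cost per patient and
#' the proportion of patients with postoperative pneumonia.
#'
#' @inheritParams enumerate_pathways
#' @return An object of class `arm_result` with fields `arm`,
#'   `expected_cost`, `pneumonia_proportion` and the pathway table.
#' @export
#' @examples
#' evaluate_arm(load_parameter_set(), "no_mouthwash")
evaluate_arm <- function(ps, arm = c("no_mouthwash", "mouthwash"),
                         rrr = ps$rrr) {
  arm <- match.arg(arm)
  pw <- enumerate_pathways(ps, arm, rrr = rrr)
  total <- sum(pw$joint_probability)
  if (abs(total - 1) > 1e-9) {
    abort(paste0("pathway probabilities sum to ", format(total), ", not 1"))
  }
  structure(
    list(
      arm = arm,
      rrr = rrr,
      expected_cost = sum(pw$joint_probability * pw$cost),
      pneumonia_proportion = sum(pw$joint_probability[pw$pneumonia]),
      pathways = pw
    ),
    class = "arm_result"
  )
}

#' @export
print.arm_result <- function(x, ...) {
  cat("<arm_result>", x$arm, "\n")
  cat("  expected cost per patient: $", format(round(x$expected_cost, 2)), "\n", sep = "")
  cat("  pneumonia proportion: ", format(round(x$pneumonia_proportion, 4)), "\n", sep = "")
  invisible(x)
}

#' @rdname tidy.arm_result
#' @export
glance.arm_result <- function(x, ...) {
  tibble(
    arm = x$arm,
    rrr = x$rrr,
    expected_cost = x$expected_cost,
    pneumonia_proportion = x$pneumonia_proportion,
    expected_effect = 1 - x$pneumonia_proportion
  )
}

#' Tidiers for arm evaluations
#'
#' `tidy()` returns the terminal pathway table; `glance()` returns the
#' one-row cohort summary.
#'
#' @param x An `arm_result`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.arm_result <- function(x, ...) x$pathways
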
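#' Locate a bundled model input file
#'
#' @param file File name under the package's `extdata` directory.
#' @return Absolute path to the file.
#' @export
mw_extdata <- function(file) {
  path <- system.file("extdata", file, package = "mouthwashCEA")
  if (!nzchar(path)) abort(paste0("bundled file not found: ", file))
  path
}

#' Construct a parameter set
#'
#' Assembles and validates the full model input: branch probabilities
#' (with optional event/total counts backing beta uncertainty), unit and
#' episode costs in 2020 international dollars, mean lengths of stay for the
#' six terminal pathway classes, the relative risk reduction, and the
#' scenario configuration.
#'
#' @param probabilities Tibble with columns `name`, `events`, `total`,
#'   `value`, `distribution` (one row per control-arm branch probability).
#' @param costs Tibble with columns `name`, `adjusted_2020_intl_usd`,
#'   `raw_value`, `source_currency`, `source_year`, `unit`, `distribution`.
#' @param los Tibble with columns `pathway_class`, `mean_days`.
#' @param config Named list of scenario settings (see the bundled
#'   `scenario.yaml`); missing entries take the bundled defaults.
#' @return A validated object of class `parameter_set`.
#' @export
new_parameter_set <- function(probabilities, costs, los, config = NULL) {
  default_cfg <- yaml::read_yaml(mw_extdata("scenario.yaml"))
  config <- utils::modifyList(default_cfg, config %||% list())
  ps <- structure(
    list(
      probabilities = as_tibble(probabilities),
      costs = as_tibble(costs),
      los = as_tibble(los),
      rrr = config$rrr,
      covid = NULL,
      prob_overrides = tibble(arm = character(), name = character(), value = double()),
      cost_overrides = tibble(name = character(), value = double()),
      los_overrides = tibble(arm = character(), pathway_class = character(), mean_days = double()),
      config = config
    ),
    class = "parameter_set"
  )
  validate_parameter_set(ps)
  ps
}

#' Load the model parameter set from delimited fixture files
#'
#' Reads the probability, cost and length-of-stay tables plus the scenario
#' configuration. With no arguments the bundled fixtures carrying the
#' published model inputs are used.
#'
#' @param probabilities,costs,los Paths to CSV files (defaults: bundled fixtures).
#' @param scenario_config Path to a YAML scenario configuration.
#' @return A validated `parameter_set`.
#' @export
#' @examples
#' params <- load_parameter_set()
#' dplyr::filter(params$probabilities, name == "pn")
load_parameter_set <- function(probabilities = mw_extdata("probabilities.csv"),
                               costs = mw_extdata("costs.csv"),
                               los = mw_extdata("los.csv"),
                               scenario_config = mw_extdata("scenario.yaml")) {
  prob_tbl <- readr::read_csv(probabilities, show_col_types = FALSE)
  cost_tbl <- readr::read_csv(costs, show_col_types = FALSE)
  los_tbl <- readr::read_csv(los, show_col_types = FALSE)
  cfg <- yaml::read_yaml(scenario_config)
  new_parameter_set(prob_tbl, cost_tbl, los_tbl, cfg)
}

#' @rdname load_parameter_set
#' @export
default_parameters <- function() load_parameter_set()

#' Validate a parameter set
#'
#' Checks probability ranges, count consistency (a printed probability must
#' agree with `events/total` to within the 2-decimal rounding band, 0.005),
#' cost nonnegativity and unit assignments, length-of-stay completeness over
#' the six terminal classes, and the relative risk reduction range.
#'
#' @param ps A `parameter_set`.
#' @return The input, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_parameter_set <- function(ps) {
  pr <- ps$probabilities
  missing_p <- setdiff(.prob_nodes, pr$name)
  if (length(missing_p) > 0) {
    abort(paste0("incomplete probabilities: missing ", paste(missing_p, collapse = ", ")),
          class = "mw_validation_error")
  }
  bad <- pr$name[is.na(pr$value) | pr$value < 0 | pr$value > 1]
  if (length(bad) > 0) {
    abort(paste0("probability out of [0,1]: ", paste(bad, collapse = ", ")),
          class = "mw_validation_error")
  }
  has_counts <- !is.na(pr$events) & !is.na(pr$total)
  if (any(has_counts)) {
    cc <- pr[has_counts, ]
    if (any(cc$events < 0 | cc$total <= 0 | cc$events > cc$total)) {
      abort("invalid counts: need 0 <= events <= total, total > 0",
            class = "mw_validation_error")
    }
    off <- abs(cc$value - cc$events / cc$total) > 0.005
    if (any(off)) {
      abort(paste0("printed value inconsistent with events/total (beyond rounding): ",
                   paste(cc$name[off], collapse = ", ")),
            class = "mw_validation_error")
    }
  }
  if (!all(pr$distribution %in% c("beta_counts", "fixed"))) {
    abort("unknown probability distribution tag", class = "mw_validation_error")
  }

  co <- ps$costs
  missing_c <- setdiff(.cost_items, co$name)
  if (length(missing_c) > 0) {
    lbl <- c(icu_day = "ICU day", bed_day = "bed day", mv_episode = "MV",
             pneumonia_episode = "pneumonia episode", chlorhexidine = "chlorhexidine",
             procedure = "procedure", covid = "COVID-19")[missing_c]
    abort(paste0("incomplete costs: missing ", paste(coalesce(lbl, missing_c), collapse = ", ")),
          class = "mw_validation_error")
  }
  if (any(co$adjusted_2020_intl_usd < 0)) {
    abort("negative adjusted cost", class = "mw_validation_error")
  }
  per_day <- co$name[co$unit == "per_day"]
  if (!setequal(per_day, c("bed_day", "icu_day"))) {
    abort("per_day unit is reserved for bed_day and icu_day",
          class = "mw_validation_error")
  }

  lo <- ps$los
  missing_l <- setdiff(.los_classes, lo$pathway_class)
  if (length(missing_l) > 0) {
    abort(paste0("incomplete length-of-stay: missing ", paste(missing_l, collapse = ", ")),
          class = "mw_validation_error")
  }
  unknown_l <- setdiff(lo$pathway_class, .los_classes)
  if (length(unknown_l) > 0) {
    abort(paste0("unknown pathway class: ", paste(unknown_l, collapse = ", ")),
          class = "mw_validation_error")
  }
  if (any(lo$mean_days < 0)) abort("negative mean length of stay", class = "mw_validation_error")

  if (is.null(ps$rrr) || ps$rrr < 0 || ps$rrr >= 1) {
    abort("rrr must lie in [0, 1)", class = "mw_validation_error")
  }
  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat("  probabilities:", nrow(x$probabilities), "nodes;",
      "rrr =", format(x$rrr), "\n")
  cat("  costs:", nrow(x$costs), "items; los:", nrow(x$los), "classes\n")
  if (!is.null(x$covid)) {
    cat("  covid overlay: mode", x$covid$mode,
        "increment", format(x$covid$pneumonia_increment),
        "cost", format(x$covid$per_patient_cost), "\n")
  }
  n_ov <- nrow(x$prob_overrides) + nrow(x$cost_overrides) + nrow(x$los_overrides)
  if (n_ov > 0) cat("  overrides:", n_ov, "\n")
  invisible(x)
}

# Effective control-arm probability: the events/total fraction at full
# precision when counts are recorded, the printed value otherwise.
.control_prob_values <- function(ps) {
  pr <- ps$probabilities
  v <- if_else(!is.na(pr$events) & !is.na(pr$total),
               pr$events / pr$total, pr$value)
  stats::setNames(v, pr$name)[.prob_nodes]
}

#' Branch probabilities for one arm
#'
#' Returns the eleven branch probabilities of the pathway tree for the
#' requested arm. The mouthwash arm is derived from the comparator by
#' multiplying the RRR-scaled nodes (pneumonia; and, among pneumonia
#' patients, critical-care admission, mechanical ventilation and the two
#' critical-care mortality probabilities) by `1 - rrr`; all other nodes are
#' identical across arms. Any COVID-19 overlay increment and deterministic
#' overrides attached to the parameter set are applied.
#'
#' @param ps A `parameter_set`.
#' @param arm `"no_mouthwash"` or `"mouthwash"`.
#' @param rrr Relative risk reduction; defaults to the set's configured value.
#' @return Named numeric vector over the tree's probability nodes.
#' @export
arm_probabilities <- function(ps, arm = c("no_mouthwash", "mouthwash"),
                              rrr = ps$rrr) {
  arm <- match.arg(arm)
  if (rrr < 0 || rrr >= 1) abort("rrr must lie in [0, 1)")
  p <- .control_prob_values(ps)
  if (!is.null(ps$covid)) {
    p[["pn"]] <- p[["pn"]] + ps$covid$pneumonia_increment
    if (p[["pn"]] > 1) abort("covid overlay pushes pneumonia probability above 1")
  }
  if (arm == "mouthwash") {
    p[.rrr_scaled_nodes] <- p[.rrr_scaled_nodes] * (1 - rrr)
  }
  ov <- filter(ps$prob_overrides, .data$arm == !!arm)
  if (nrow(ov) > 0) p[ov$name] <- ov$value
  p
}

#' Unit and episode costs as a named vector
#'
#' @param ps A `parameter_set`.
#' @return Named numeric vector of 2020 international-dollar costs, with any
#'   deterministic overrides applied.
#' @export
cost_values <- function(ps) {
  v <- stats::setNames(ps$costs$adjusted_2020_intl_usd, ps$costs$name)[.cost_items]
  if (nrow(ps$cost_overrides) > 0) v[ps$cost_overrides$name] <- ps$cost_overrides$value
  v
}

#' Mean lengths of stay for one arm
#'
#' Base lengths of stay are identical across arms; deterministic sensitivity
#' overrides may differ by arm.
#'
#' @inheritParams arm_probabilities
#' @return Named numeric vector over the six terminal pathway classes (days).
#' @export
los_values <- function(ps, arm = c("no_mouthwash", "mouthwash")) {
  arm <- match.arg(arm)
  v <- stats::setNames(ps$los$mean_days, ps$los$pathway_class)[.los_classes]
  ov <- filter(ps$los_overrides, .data$arm == !!arm)
  if (nrow(ov) > 0) v[ov$pathway_class] <- ov$mean_days
  v
}

#' Override a single model parameter
#'
#' Deterministic overrides are applied after the mouthwash arm is derived by
#' RRR, so overriding an intervention-arm parameter replaces its derived
#' value. Cost overrides are global (costs do not differ by arm);
#' probability and length-of-stay overrides are per arm.
#'
#' @param ps A `parameter_set`.
#' @param name Probability node, cost item, or pathway class to override.
#' @param value Replacement value.
#' @param arm Arm whose parameter is overridden (probabilities and LoS only).
#' @return The modified `parameter_set`.
#' @export
set_probability <- function(ps, name, value, arm) {
  if (!name %in% .prob_nodes) abort(paste0("unknown probability node: ", name))
  if (!arm %in% .arms) abort(paste0("unknown arm: ", arm))
  if (value < 0 || value > 1) abort("probability override outside [0,1]")
  ps$prob_overrides <- bind_rows(
    filter(ps$prob_overrides, !(.data$arm == !!arm & .data$name == !!name)),
    tibble(arm = arm, name = name, value = value)
  )
  ps
}

#' @rdname set_probability
#' @export
set_cost <- function(ps, name, value) {
  if (!name %in% .cost_items) abort(paste0("unknown cost item: ", name))
  if (value < 0) abort("negative cost override")
  ps$cost_overrides <- bind_rows(
    filter(ps$cost_overrides, .data$name != !!name),
    tibble(name = name, value = value)
  )
  ps
}

#' @rdname set_probability
#' @export
set_los <- function(ps, name, value, arm) {
  if (!name %in% .los_classes) abort(paste0("unknown pathway class: ", name))
  if (!arm %in% .arms) abort(paste0("unknown arm: ", arm))
  if (value < 0) abort("negative length-of-stay override")
  ps$los_overrides <- bind_rows(
    filter(ps$los_overrides, !(.data$arm == !!arm & .data$pathway_class == !!name)),
    tibble(arm = arm, pathway_class = name, mean_days = value)
  )
  ps
}

#' Beta distribution specification from event counts
#'
#' Parameterises branch-probability uncertainty directly by the recorded
#' cohort counts: `alpha = events`, `beta = total - events`, so the mean is
#' `events/total`. Degenerate all-or-nothing counts are flagged; sampling
#' applies a +0.5/+0.5 continuity correction to them.
#'
#' @param events,total Nonnegative event count and positive total.
#' @return List with `alpha`, `beta`, the implied `mean`, and `degenerate`.
#' @export
#' @examples
#' beta_from_counts(39, 931)
beta_from_counts <- function(events, total) {
  if (length(events) != 1 || length(total) != 1 || is.na(events) || is.na(total)) {
    abort("events and total must be single non-missing counts")
  }
  if (total <= 0) abort("total must be positive")
  if (events < 0 || events > total) abort("need 0 <= events <= total")
  alpha <- events
  beta <- total - events
  list(alpha = alpha, beta = beta, mean = events / total,
       degenerate = alpha == 0 || beta == 0)
}

#' Derive the mouthwash arm from the comparator by relative risk reduction
#'
#' Multiplies the RRR-scaled probability nodes by `1 - rrr` and copies all
#' other nodes unchanged. The returned parameter set carries both arms'
#' values in its probability table (`value` for the comparator,
#' `mouthwash_value` for the intervention) and records `rrr`.
#'
#' @param ps A `parameter_set` carrying the comparator (control) arm.
#' @param rrr Relative risk reduction in `[0, 1)`.
#' @return A `parameter_set` with the derived intervention arm attached.
#' @export
derive_intervention_arm <- function(ps, rrr = ps$rrr) {
  if (rrr < 0 || rrr >= 1) abort("rrr must lie in [0, 1)")
  ps$rrr <- rrr
  mw <- arm_probabilities(ps, "mouthwash", rrr = rrr)
  ps$probabilities <- mutate(
    ps$probabilities,
    mouthwash_value = unname(mw[.data$name])
  )
  ps
}

#' COVID-19 scenario overlay
#'
#' Constructs the pandemic-period modification: an increment to the
#' control-arm postoperative pneumonia probability (applied before the RRR
#' derivation, so the mouthwash arm inherits a proportional share) and a
#' per-patient cost added to every patient in both arms. `absolute_pp`
#' applies the stated absolute increment (+1.8 percentage points);
#' `calibrated` applies the smaller increment (default +0.28 points)
#' consistent with the published scenario-2 pneumonia proportions.
#'
#' @param mode `"absolute_pp"` or `"calibrated"`.
#' @param pneumonia_increment Absolute increment to the control pneumonia
#'   probability; defaults to the configured value for the chosen mode.
#' @param per_patient_cost Pandemic per-patient cost (2020 international $).
#' @param config Scenario configuration list supplying defaults.
#' @return An object of class `covid_overlay`.
#' @export
covid_overlay <- function(mode = c("absolute_pp", "calibrated"),
                          pneumonia_increment = NULL,
                          per_patient_cost = NULL,
                          config = yaml::read_yaml(mw_extdata("scenario.yaml"))) {
  mode <- match.arg(mode)
  inc <- pneumonia_increment %||%
    if (mode == "absolute_pp") config$covid$pneumonia_increment else config$covid$calibrated_increment
  cost <- per_patient_cost %||% config$covid$per_patient_cost
  if (inc < 0 || inc > 1) abort("pneumonia increment outside [0,1]")
  if (cost < 0) abort("negative covid per-patient cost")
  structure(list(mode = mode, pneumonia_increment = inc, per_patient_cost = cost),
            class = "covid_overlay")
}

#' Apply a COVID-19 overlay to a parameter set
#'
#' Attaches the overlay so that the control pneumonia probability is
#' incremented before RRR derivation and every patient in both arms accrues
#' the pandemic per-patient cost. Raising any probability above 1 is an
#' error, never a silent clamp.
#'
#' @param ps A `parameter_set`.
#' @param overlay A [covid_overlay()].
#' @return The modified `parameter_set`.
#' @export
apply_covid_overlay <- function(ps, overlay = covid_overlay(config = ps$config)) {
  if (!inherits(overlay, "covid_overlay")) abort("overlay must be a covid_overlay")
  p <- .control_prob_values(ps)
  if (p[["pn"]] + overlay$pneumonia_increment > 1) {
    abort("covid overlay pushes pneumonia probability above 1")
  }
  ps$covid <- overlay
  ps
}

#' Parameters under a named analysis scenario
#'
#' Scenario 1 is the pandemic-free base case; scenario 2 applies the
#' COVID-19 overlay in the requested mode.
#'
#' @param ps A `parameter_set`.
#' @param scenario 1 or 2.
#' @param overlay_mode Overlay mode for scenario 2.
#' @return A `parameter_set`.
#' @export
scenario_parameters <- function(ps, scenario = 1,
                                overlay_mode = c("absolute_pp", "calibrated")) {
  if (!scenario %in% c(1, 2)) abort("scenario must be 1 or 2")
  if (scenario == 1) return(ps)
  apply_covid_overlay(ps, covid_overlay(match.arg(overlay_mode), config = ps$config))
}

#' Serialize / restore a parameter set as JSON
#'
#' @param ps A `parameter_set`.
#' @param path File path.
#' @return `write_parameter_set` returns `path` invisibly;
#'   `read_parameter_set` returns the restored `parameter_set`.
#' @export
write_parameter_set <- function(ps, path) {
  payload <- list(
    probabilities = ps$probabilities,
    costs = ps$costs,
    los = ps$los,
    config = ps$config
  )
  jsonlite::write_json(payload, path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_parameter_set
#' @export
read_parameter_set <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_parameter_set(
    as_tibble(payload$probabilities),
    as_tibble(payload$costs),
    as_tibble(payload$los),
    payload$config
  )
}
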
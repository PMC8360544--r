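#' Analysis run configuration
#'
#' Validates the settings for a reporting run and computes the
#' configuration hash echoed into every output's metadata.
#'
#' @param scenario 1 (no COVID-19) or 2 (COVID-19 overlay).
#' @param rrr Relative risk reduction for the base comparison.
#' @param overlay_mode Scenario-2 overlay mode.
#' @param wtp Willingness-to-pay grid for CEAC outputs.
#' @param psa_n,psa_seed PSA iteration count and root seed.
#' @param zar_per_intl_usd Rand display factor.
#' @param out_dir Output directory (created if missing).
#' @return Object of class `run_config`.
#' @export
run_config <- function(scenario = 1, rrr = 0.3,
                       overlay_mode = c("absolute_pp", "calibrated"),
                       wtp = wtp_grid(), psa_n = 10000, psa_seed = 1,
                       zar_per_intl_usd = 17.35, out_dir = tempdir()) {
  if (!length(scenario) == 1 || !scenario %in% c(1, 2)) {
    abort("scenario must be 1 or 2", class = "mw_config_error")
  }
  overlay_mode <- match.arg(overlay_mode)
  if (rrr < 0 || rrr >= 1) abort("rrr must lie in [0, 1)", class = "mw_config_error")
  if (any(wtp < 0)) abort("wtp grid must be nonnegative", class = "mw_config_error")
  if (psa_n < 1) abort("psa_n must be positive", class = "mw_config_error")
  if (zar_per_intl_usd <= 0) abort("display factor must be positive", class = "mw_config_error")
  cfg <- list(
    scenario = scenario, rrr = rrr, overlay_mode = overlay_mode,
    wtp = wtp, psa_n = psa_n, psa_seed = psa_seed,
    zar_per_intl_usd = zar_per_intl_usd, out_dir = out_dir
  )
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "out_dir")])
  structure(cfg, class = "run_config")
}

.config_params <- function(config, ps) {
  ps$rrr <- config$rrr
  ps$config$display$zar_per_intl_usd <- config$zar_per_intl_usd
  scenario_parameters(ps, config$scenario, config$overlay_mode)
}

# Metadata header written as comment lines at the top of each CSV output.
.metadata_lines <- function(config, seed = NULL) {
  c(
    paste0("# mouthwashCEA ", packageVersion("mouthwashCEA")),
    paste0("# config_hash: ", config$hash),
    paste0("# scenario: ", config$scenario),
    paste0("# rrr: ", config$rrr),
    paste0("# overlay_mode: ",
           if (config$scenario == 2) config$overlay_mode else "none"),
    if (!is.null(seed)) paste0("# seed: ", seed)
  )
}

.write_report_csv <- function(tbl, path, config, seed = NULL) {
  writeLines(.metadata_lines(config, seed), path)
  readr::write_csv(tbl, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Base-case cost-effectiveness report
#'
#' Evaluates both arms under the configured scenario, compares them, and
#' writes the base-case table (dollar and Rand rows) to
#' `basecase_scenario<k>.csv` in the configured output directory.
#'
#' @param config A [run_config()].
#' @param ps A `parameter_set` (default: bundled inputs).
#' @return The base-case tibble, invisibly.
#' @export
run_basecase <- function(config = run_config(), ps = load_parameter_set()) {
  ps <- .config_params(config, ps)
  ce <- run_comparison(ps)
  zar <- config$zar_per_intl_usd
  tbl <- tibble(
    parameter = c(
      "Mouthwash costs (USD)", "No-mouthwash costs (USD)",
      "Proportion of pneumonia patients (mouthwash)",
      "Proportion of pneumonia patients (no-mouthwash)",
      "Difference in costs (USD)", "Difference in costs (R)",
      "Difference in proportion of pneumonia patients"
    ),
    value = c(
      ce$intervention$expected_cost, ce$comparator$expected_cost,
      ce$intervention$pneumonia_proportion, ce$comparator$pneumonia_proportion,
      ce$delta_cost, to_display_zar(ce$delta_cost, factor = zar),
      ce$delta_effect
    ),
    display = c(
      format(round(value[1:2])), round(value[3:4], 3),
      format(round(value[5:6])), round(value[7], 3)
    )
  )
  path <- file.path(config$out_dir, paste0("basecase_scenario", config$scenario, ".csv"))
  .write_report_csv(tbl, path, config)
  invisible(tbl)
}

#' Deterministic sensitivity analysis report
#'
#' Emits the full DSA table (base case, RRR sweep, one-way bound rows,
#' extreme scenarios) for the configured scenario to
#' `dsa_scenario<k>.csv`.
#'
#' @inheritParams run_basecase
#' @return The DSA tibble, invisibly.
#' @export
run_dsa <- function(config = run_config(), ps = load_parameter_set()) {
  ps <- .config_params(config, ps)
  tbl <- dsa_table(ps)
  path <- file.path(config$out_dir, paste0("dsa_scenario", config$scenario, ".csv"))
  .write_report_csv(tbl, path, config)
  invisible(tbl)
}

#' Probabilistic sensitivity analysis report
#'
#' Runs the PSA under the configured scenario and writes the draw-level
#' table (`psa_draws_scenario<k>.csv`), the CEAC over the configured
#' willingness-to-pay grid (`ceac_scenario<k>.csv`), and the summary with
#' metadata (`psa_summary_scenario<k>.json`).
#'
#' @inheritParams run_basecase
#' @return The `psa_output`, invisibly.
#' @export
run_psa_report <- function(config = run_config(), ps = load_parameter_set()) {
  ps <- .config_params(config, ps)
  psa <- run_psa(ps, n = config$psa_n, seed = config$psa_seed)
  k <- config$scenario
  .write_report_csv(psa$draws,
                    file.path(config$out_dir, paste0("psa_draws_scenario", k, ".csv")),
                    config, seed = config$psa_seed)
  cc <- ceac(psa, config$wtp)
  .write_report_csv(as_tibble(cc),
                    file.path(config$out_dir, paste0("ceac_scenario", k, ".csv")),
                    config, seed = config$psa_seed)
  jsonlite::write_json(
    list(
      package_version = as.character(packageVersion("mouthwashCEA")),
      config_hash = config$hash,
      seed = config$psa_seed,
      metadata = psa$metadata,
      summary = psa$summary
    ),
    file.path(config$out_dir, paste0("psa_summary_scenario", k, ".json")),
    digits = NA, auto_unbox = TRUE
  )
  invisible(psa)
}
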
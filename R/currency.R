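#' Healthcare market basket
#'
#' A basket of healthcare goods and services priced in one setting, used to
#' transfer costs between countries by the ratio of basket totals.
#'
#' @param setting Country label.
#' @param items Tibble with columns `item` and `unit_cost`.
#' @param total Basket total; defaults to the sum of item costs, and must
#'   agree with it to within 0.5 (printed-total rounding).
#' @return Object of class `basket`.
#' @export
basket <- function(setting, items, total = sum(items$unit_cost)) {
  items <- as_tibble(items)
  if (nrow(items) == 0) abort("basket items must be nonempty")
  if (abs(total - sum(items$unit_cost)) > 0.5) {
    abort("basket total inconsistent with item sum")
  }
  structure(list(setting = setting, items = items, total = total),
            class = "basket")
}

#' Read baskets from a delimited table
#'
#' @param path CSV with columns `setting`, `item`, `unit_cost`
#'   (default: the bundled file carrying the published UK and South Africa
#'   basket totals).
#' @return Named list of `basket` objects.
#' @export
read_baskets <- function(path = mw_extdata("baskets.csv")) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  split(tbl, tbl$setting) |>
    map(~ basket(.x$setting[[1]], select(.x, "item", "unit_cost")))
}

#' Market-basket index between two settings
#'
#' Ratio of the source basket total to the target basket total; dividing a
#' source-setting cost by this index transfers it to the target setting.
#' Published anchor: UK $8,759 over South Africa $4,519 prints as 1.94.
#'
#' @param source,target `basket` objects or positive basket totals.
#' @return The index at full precision (display rounding is the caller's
#'   choice).
#' @export
#' @examples
#' basket_index(8759, 4519)
basket_index <- function(source, target) {
  s <- if (inherits(source, "basket")) source$total else source
  t <- if (inherits(target, "basket")) target$total else target
  if (!is.numeric(s) || !is.numeric(t) || s <= 0 || t <= 0) {
    abort("basket totals must be positive")
  }
  s / t
}

#' Conversion context for cost adjustment
#'
#' Bundles everything needed to express a source-currency, source-year cost
#' in 2020 international dollars for the target setting: per-currency annual
#' inflation factors, purchasing-power-parity factors (currency units per
#' international dollar), per-setting market-basket indices, and the Rand
#' display factor.
#'
#' @param inflation Tibble with columns `currency`, `year`, `factor`, where
#'   `factor` carries year-on-year growth from `year` to `year + 1`.
#' @param ppp Named vector of PPP factors per currency.
#' @param basket_indices Named vector of source-setting-to-target indices.
#' @param zar_per_intl_usd Rand display factor.
#' @return Object of class `conversion_context`.
#' @export
conversion_context <- function(inflation = readr::read_csv(mw_extdata("inflation.csv"),
                                                           show_col_types = FALSE),
                               ppp = c(USD = 1, GBP = 0.7),
                               basket_indices = c("USA" = 10.8, "UK" = 1.94,
                                                  "South Africa" = 1),
                               zar_per_intl_usd = 17.35) {
  if (any(ppp <= 0) || any(basket_indices <= 0) || zar_per_intl_usd <= 0) {
    abort("all conversion factors must be positive")
  }
  structure(
    list(inflation = as_tibble(inflation), ppp = ppp,
         basket_indices = basket_indices, zar_per_intl_usd = zar_per_intl_usd),
    class = "conversion_context"
  )
}

# Cumulative inflation factor from `from_year` to 2020 for one currency.
.inflation_factor <- function(ctx, currency, from_year, to_year = 2020) {
  if (from_year == to_year) return(1)
  years <- seq(from_year, to_year - 1)
  rows <- filter(ctx$inflation, .data$currency == !!currency,
                 .data$year %in% years)
  if (nrow(rows) != length(years)) {
    abort(paste0("inflation series does not cover ", currency, " ",
                 from_year, "-", to_year))
  }
  prod(rows$factor)
}

#' Adjust a cost item to 2020 international dollars
#'
#' Applies, in configurable order, (i) inflation in the source currency to
#' 2020, (ii) PPP conversion to international dollars, and (iii) division by
#' the source-setting market-basket index to transfer the cost to the target
#' setting. The default order is inflate, then PPP, then basket. The full
#' transformation chain is attached as the `"audit"` attribute.
#'
#' @param item One row of a cost table (or a list) with fields `name`,
#'   `raw_value`, `source_currency`, `source_year`, `setting`.
#' @param ctx A [conversion_context()].
#' @param order Character vector permuting `c("inflate", "ppp", "basket")`.
#' @return The adjusted value (2020 international $) with an `"audit"`
#'   attribute logging each step.
#' @export
adjust_cost <- function(item, ctx = conversion_context(),
                        order = c("inflate", "ppp", "basket")) {
  if (!setequal(order, c("inflate", "ppp", "basket"))) {
    abort("order must permute inflate, ppp, basket")
  }
  value <- item$raw_value
  audit <- tibble(step = "start", factor = NA_real_, value = value)
  for (step in order) {
    f <- switch(step,
      inflate = .inflation_factor(ctx, item$source_currency, item$source_year),
      ppp = 1 / ctx$ppp[[item$source_currency]],
      basket = 1 / ctx$basket_indices[[item$setting]]
    )
    value <- value * f
    audit <- bind_rows(audit, tibble(step = step, factor = f, value = value))
  }
  structure(value, audit = mutate(audit, item = item$name, .before = 1))
}

#' Display an international-dollar value in South African Rand
#'
#' @param value Value(s) in 2020 international dollars.
#' @param ctx A [conversion_context()] supplying the display factor, or
#'   `NULL` to use `factor` directly.
#' @param factor Rand per international dollar (default 17.35, fitted to the
#'   published dollar/Rand result pairs).
#' @return Value(s) in Rand.
#' @export
#' @examples
#' to_display_zar(-283)
to_display_zar <- function(value, ctx = NULL, factor = 17.35) {
  f <- if (!is.null(ctx)) ctx$zar_per_intl_usd else factor
  value * f
}
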
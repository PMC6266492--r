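#' Annual EF/EC/deficit balance table
#'
#' One row per year of per-capita demand (EF), supply (EC), available supply
#' after the biodiversity deduction, and the resulting deficit. The available
#' column is `(1 - biodiversity_fraction) * ec`; the deficit is
#' `ef - available`.
#'
#' @param year Integer vector of years.
#' @param ef_per_capita,ec_per_capita Per-capita footprint and (undeducted)
#'   carrying capacity, hm2/person.
#' @param biodiversity_fraction Deduction fraction; default 0.12.
#' @return An `annual_balance_table` tibble with columns `year`,
#'   `ef_per_capita`, `ec_per_capita`, `available_ec_per_capita`,
#'   `deficit_per_capita`, sorted by year.
#' @export
annual_balance_table <- function(year, ef_per_capita, ec_per_capita,
                                 biodiversity_fraction = 0.12) {
  if (length(year) != length(ef_per_capita) ||
      length(year) != length(ec_per_capita)) {
    stop("`year`, `ef_per_capita` and `ec_per_capita` must have equal length",
         call. = FALSE)
  }
  if (any(!is.finite(ef_per_capita)) || any(ef_per_capita < 0) ||
      any(!is.finite(ec_per_capita)) || any(ec_per_capita < 0)) {
    stop("per-capita series must be finite and >= 0", call. = FALSE)
  }
  avail <- (1 - biodiversity_fraction) * ec_per_capita
  out <- tibble::tibble(
    year = as.integer(year),
    ef_per_capita = ef_per_capita,
    ec_per_capita = ec_per_capita,
    available_ec_per_capita = avail,
    deficit_per_capita = ef_per_capita - avail)
  out <- out[order(out$year), ]
  attr(out, "biodiversity_fraction") <- biodiversity_fraction
  class(out) <- c("annual_balance_table", class(out))
  out
}

#' Build the annual balance table from raw accounts
#'
#' Runs the full demand- and supply-side accounting for each year: item-level
#' accounts to per-capita EF ([account_footprint()]), land areas to
#' per-capita EC ([total_capacity()]), then the biodiversity deduction and
#' deficit.
#'
#' @param years_data Named or unnamed list, one element per year, each a list
#'   with components `account` (a [regional_account()]) and `land_areas`
#'   (data frame with `land_type`, `area_hm2`).
#' @param factors A [factor_table()].
#' @return An [annual_balance_table()].
#' @export
build_annual_table <- function(years_data, factors) {
  if (!length(years_data)) {
    stop("`years_data` must contain at least one year", call. = FALSE)
  }
  rows <- lapply(seq_along(years_data), function(i) {
    yd <- years_data[[i]]
    if (is.null(yd$account) || !inherits(yd$account, "regional_account")) {
      stop(sprintf("year entry %d: missing or invalid `account`", i),
           call. = FALSE)
    }
    if (is.null(yd$land_areas)) {
      stop(sprintf("year entry %d (year %s): missing `land_areas`", i,
                   yd$account$year), call. = FALSE)
    }
    fp <- account_footprint(yd$account, factors)
    cp <- total_capacity(yd$land_areas, factors, yd$account$population)
    c(year = yd$account$year, ef = fp$ef_per_capita, ec = cp$ec_per_capita)
  })
  m <- do.call(rbind, rows)
  annual_balance_table(m[, "year"], m[, "ef"], m[, "ec"],
                       biodiversity_fraction = biodiversity_fraction(factors))
}

#' Fit grey models to the annual series and forecast the deficit
#'
#' Fits GM(1,1) to the per-capita EF column and to a per-capita EC column of
#' an annual balance table, forecasts both `horizon` years ahead, and
#' reports the forecast deficit as EF minus EC forecast year by year.
#'
#' `ec_series_mode` selects the supply series: `"raw_ec"` (default) fits the
#' undeducted EC column and uses its forecasts directly as the available
#' supply; `"available_ec"` fits the deducted (x 0.88) column. The default
#' mirrors the study convention whose published grey coefficients anchor at
#' the undeducted first-year EC.
#'
#' @param table An [annual_balance_table()] with >= 4 rows.
#' @param horizon Forecast horizon in years, >= 1; default 5.
#' @param ec_series_mode `"raw_ec"` or `"available_ec"`.
#' @param background_weight Background-sequence weight for both fits;
#'   default 0.5.
#' @return A `forecast_report`: list with `ef_fit` and `ec_fit` (`gm11`
#'   objects), `ec_series_mode`, and `forecasts`, a tibble with columns
#'   `year`, `ef_forecast`, `ec_forecast`, `deficit_forecast`.
#' @export
#' @examples
#' tab <- annual_balance_table(2013:2017,
#'   ef_per_capita = c(1.5270, 1.4782, 2.3897, 1.9143, 1.2611),
#'   ec_per_capita = c(0.3478, 0.3795, 0.4084, 0.3902, 0.3595))
#' rep <- run_grey_analysis(tab, horizon = 5)
#' rep$forecasts
run_grey_analysis <- function(table, horizon = 5,
                              ec_series_mode = c("raw_ec", "available_ec"),
                              background_weight = 0.5) {
  ec_series_mode <- match.arg(ec_series_mode)
  if (!is.numeric(horizon) || length(horizon) != 1 || is.na(horizon) ||
      horizon < 1) {
    stop("`horizon` must be a positive integer", call. = FALSE)
  }
  if (nrow(table) < 4) {
    stop("grey fitting needs at least 4 annual rows", call. = FALSE)
  }
  horizon <- as.integer(horizon)
  ec_col <- if (ec_series_mode == "raw_ec") "ec_per_capita" else
    "available_ec_per_capita"
  ef_fit <- fit_gm11(table$ef_per_capita, years = table$year,
                     background_weight = background_weight)
  ec_fit <- fit_gm11(table[[ec_col]], years = table$year,
                     background_weight = background_weight)
  ef_fc <- gm11_forecast(ef_fit, horizon)
  ec_fc <- gm11_forecast(ec_fit, horizon)
  structure(
    list(ef_fit = ef_fit, ec_fit = ec_fit, ec_series_mode = ec_series_mode,
         forecasts = tibble::tibble(
           year = max(table$year) + seq_len(horizon),
           ef_forecast = unname(ef_fc),
           ec_forecast = unname(ec_fc),
           deficit_forecast = unname(ef_fc - ec_fc))),
    class = "forecast_report")
}

#' @export
print.forecast_report <- function(x, ...) {
  cat(sprintf("Grey forecast report (EC series: %s)\n", x$ec_series_mode))
  cat("EF model:  "); print(x$ef_fit)
  cat("EC model:  "); print(x$ec_fit)
  print(x$forecasts, ...)
  invisible(x)
}
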
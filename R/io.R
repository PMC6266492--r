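#' Read a biological-resource account CSV
#'
#' Expected columns: `item`, `land_type`, `global_avg_yield_kg_per_hm2`,
#' optionally `in_land_total`, then one numeric column per city (production
#' in tonnes). UTF-8, comma-separated, `.` decimal, no thousands separators.
#' Row order is preserved; land types and yields are validated with errors
#' naming the offending row and column.
#'
#' @param path Path to the CSV file.
#' @return Tibble of validated bio items.
#' @export
read_bio_account <- function(path) {
  tbl <- read_account_csv(path)
  withCallingHandlers(
    validate_bio_table(tbl),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Read an energy account CSV
#'
#' Expected columns: `item`, `land_type` (`fossil_energy` or `built_up`),
#' `global_avg_energy_footprint_GJ_per_hm2`, optionally
#' `convert_coefficient_GJ_per_t`, then one numeric column per city
#' (consumption in GJ).
#'
#' @inheritParams read_bio_account
#' @return Tibble of validated energy items.
#' @export
read_energy_account <- function(path) {
  tbl <- read_account_csv(path)
  withCallingHandlers(
    validate_energy_table(tbl),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Read a land-area CSV (supply side)
#'
#' Expected columns: `land_type`, `area_hm2`.
#'
#' @inheritParams read_bio_account
#' @return Tibble with validated land types and nonnegative areas.
#' @export
read_land_areas <- function(path) {
  tbl <- read_account_csv(path)
  miss <- setdiff(c("land_type", "area_hm2"), names(tbl))
  if (length(miss)) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad <- !tbl$land_type %in% land_types()
  if (any(bad)) {
    stop(sprintf("%s: row %d: unknown land type '%s'", path, which(bad)[1],
                 tbl$land_type[which(bad)[1]]), call. = FALSE)
  }
  if (any(!is.finite(tbl$area_hm2)) || any(tbl$area_hm2 < 0)) {
    stop(sprintf("%s: column 'area_hm2' must be finite and >= 0", path),
         call. = FALSE)
  }
  tbl
}

#' Read a factor configuration (YAML)
#'
#' Expected top-level keys: `equivalence_factor` and `yield_factor` (maps
#' from land type to number) and optionally `biodiversity_fraction`.
#'
#' @inheritParams read_bio_account
#' @return A [factor_table()].
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("equivalence_factor", "yield_factor")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("%s: missing key '%s'", path, key), call. = FALSE)
    }
  }
  withCallingHandlers(
    factor_table(
      equivalence_factor = unlist(cfg$equivalence_factor),
      yield_factor = unlist(cfg$yield_factor),
      biodiversity_fraction = if (is.null(cfg$biodiversity_fraction)) 0.12
                              else cfg$biodiversity_fraction),
    error = function(e) stop(sprintf("%s: %s", path, conditionMessage(e)),
                             call. = FALSE))
}

#' Read an annual per-capita series CSV
#'
#' Two accepted shapes: a two-column `year,value` series, or a full annual
#' balance CSV with columns `year`, `ef_per_capita`, `ec_per_capita` (and
#' optionally the derived `available_ec_per_capita`, `deficit_per_capita`,
#' which are recomputed, not trusted).
#'
#' @inheritParams read_bio_account
#' @param biodiversity_fraction Used to rebuild the derived columns when the
#'   file is a full balance table; default 0.12.
#' @return A tibble (`year,value`) or an [annual_balance_table()].
#' @export
read_annual_series <- function(path, biodiversity_fraction = 0.12) {
  tbl <- read_account_csv(path)
  if (!"year" %in% names(tbl)) {
    stop(sprintf("%s: missing column 'year'", path), call. = FALSE)
  }
  if (all(c("ef_per_capita", "ec_per_capita") %in% names(tbl))) {
    return(annual_balance_table(tbl$year, tbl$ef_per_capita,
                                tbl$ec_per_capita, biodiversity_fraction))
  }
  if (!"value" %in% names(tbl)) {
    stop(sprintf(
      "%s: expected columns 'year,value' or 'year,ef_per_capita,ec_per_capita'",
      path), call. = FALSE)
  }
  tbl[c("year", "value")]
}

read_account_csv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE,
                                    fileEncoding = "UTF-8"))
}

#' Write a report to CSV or JSON
#'
#' Serializes an [annual_balance_table()] or a forecast report (from
#' [run_grey_analysis()]) deterministically: stable column order, per-capita
#' values rounded to 4 decimals, no timestamps. JSON output for a forecast
#' report also carries both model summaries (`a`, `u`, initial value,
#' fitted/restored series, mean relative error, grade).
#'
#' @param report An `annual_balance_table` or `forecast_report`.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "annual_balance_table")) {
    tbl <- as.data.frame(report)
    num <- setdiff(names(tbl), "year")
    tbl[num] <- lapply(tbl[num], round, digits = 4)
    if (format == "csv") {
      utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(list(annual_balance = tbl), path,
                           auto_unbox = TRUE, digits = NA)
    }
  } else if (inherits(report, "forecast_report")) {
    tbl <- as.data.frame(report$forecasts)
    num <- setdiff(names(tbl), "year")
    tbl[num] <- lapply(tbl[num], round, digits = 4)
    if (format == "csv") {
      utils::write.csv(tbl, path, row.names = FALSE, quote = FALSE)
    } else {
      jsonlite::write_json(
        list(ec_series_mode = report$ec_series_mode,
             ef_model = gm11_json(report$ef_fit),
             ec_model = gm11_json(report$ec_fit),
             forecasts = tbl),
        path, auto_unbox = TRUE, digits = NA)
    }
  } else {
    stop("`report` must be an annual_balance_table or forecast_report",
         call. = FALSE)
  }
  invisible(path)
}

gm11_json <- function(fit) {
  list(a = fit$a, u = fit$u, initial_value = fit$initial_value,
       years = fit$years, fitted_cumulative = fit$fitted_cumulative,
       restored = fit$restored,
       mean_relative_error = fit$mean_relative_error, grade = fit$grade,
       degenerate = fit$degenerate)
}
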
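#' Capacity contributed by one land-area record
#'
#' Supply-side capacity of a land type: physical area times equivalence
#' factor times yield factor, \eqn{w_j \times y_j \times A_j}. Fossil-energy
#' (CO2-absorption) land has yield factor 0 by default, so it contributes
#' nothing.
#'
#' @param area_hm2 Physical area in hm2, >= 0.
#' @param land_type One of [land_types()].
#' @param factors A [factor_table()].
#' @return Capacity in hm2.
#' @export
#' @examples
#' land_capacity(2099120, "arable", default_factors()) # 8,746,193 hm2
land_capacity <- function(area_hm2, land_type, factors) {
  if (any(!is.finite(area_hm2)) || any(area_hm2 < 0)) {
    stop("`area_hm2` must be finite and >= 0", call. = FALSE)
  }
  w <- factor_lookup(factors, land_type, "equivalence_factor")
  y <- factor_lookup(factors, land_type, "yield_factor")
  area_hm2 * w * y
}

#' Total and per-capita ecological carrying capacity
#'
#' Sums per-land-type capacities into the regional total EC, divides by the
#' population for per-capita EC, and applies the biodiversity deduction:
#' `available = (1 - biodiversity_fraction) * ec_per_capita` (12% reserved by
#' default, leaving 88% available).
#'
#' @param land_areas Data frame with columns `land_type`, `area_hm2` (supply
#'   side, physical hm2). May be empty.
#' @param factors A [factor_table()].
#' @param population Resident population, > 0.
#' @return A `capacity_summary`: list with a per-land-type tibble
#'   (`area_hm2`, factors, `capacity_hm2`), `ec_total` (hm2),
#'   `ec_per_capita`, `available_ec_per_capita` (hm2/person) and
#'   `biodiversity_fraction`.
#' @export
total_capacity <- function(land_areas, factors, population) {
  if (!is.numeric(population) || length(population) != 1 ||
      !is.finite(population) || population <= 0) {
    stop("`population` must be a single positive number", call. = FALSE)
  }
  land_areas <- tibble::as_tibble(land_areas)
  miss <- setdiff(c("land_type", "area_hm2"), names(land_areas))
  if (length(miss)) {
    stop("land areas table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cap <- if (nrow(land_areas)) {
    land_capacity(land_areas$area_hm2, land_areas$land_type, factors)
  } else numeric(0)
  tbl <- tibble::tibble(
    land_type = land_areas$land_type,
    area_hm2 = land_areas$area_hm2,
    equivalence_factor = factor_lookup(factors, land_areas$land_type,
                                       "equivalence_factor"),
    yield_factor = factor_lookup(factors, land_areas$land_type,
                                 "yield_factor"),
    capacity_hm2 = cap)
  ec_total <- sum(cap)
  ec_pc <- ec_total / population
  bf <- biodiversity_fraction(factors)
  structure(
    list(by_land_type = tbl, ec_total = ec_total, ec_per_capita = ec_pc,
         available_ec_per_capita = (1 - bf) * ec_pc,
         biodiversity_fraction = bf, population = population),
    class = "capacity_summary")
}

#' @export
print.capacity_summary <- function(x, ...) {
  cat("Ecological carrying capacity (supply side)\n")
  print(x$by_land_type, ...)
  cat(sprintf(
    "EC total: %s hm2;  ec per capita: %.4f;  available (x%.2f): %.4f hm2/person\n",
    format(round(x$ec_total, 1), big.mark = ","), x$ec_per_capita,
    1 - x$biodiversity_fraction, x$available_ec_per_capita))
  invisible(x)
}

#' Ecological deficit or surplus
#'
#' Per-capita ecological deficit: footprint minus available capacity.
#' Positive values mean demand exceeds supply (deficit); negative values an
#' ecological surplus.
#'
#' @param ef_per_capita Per-capita ecological footprint, hm2/person.
#' @param available_ec_per_capita Per-capita available (post-deduction)
#'   carrying capacity, hm2/person.
#' @return Deficit in hm2/person (negative = surplus).
#' @export
#' @examples
#' ecological_balance(1.2611, 0.3164) # 0.9447, a deficit
ecological_balance <- function(ef_per_capita, available_ec_per_capita) {
  if (any(!is.finite(ef_per_capita)) || any(ef_per_capita < 0) ||
      any(!is.finite(available_ec_per_capita)) ||
      any(available_ec_per_capita < 0)) {
    stop("inputs must be finite and >= 0", call. = FALSE)
  }
  ef_per_capita - available_ec_per_capita
}
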
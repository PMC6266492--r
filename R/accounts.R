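#' Assemble a regional consumption account
#'
#' Bundles the item-level biological-resource production table, the energy
#' consumption table, the resident population and the account year into one
#' validated object. City-level detail enters only as columns of the two
#' tables; the account is always aggregated across cities.
#'
#' @param bio Tibble/data frame of biological items: columns `item`,
#'   `land_type`, `global_avg_yield_kg_per_hm2`, optionally `in_land_total`
#'   (logical, default TRUE; items flagged FALSE are tallied in the item table
#'   but excluded from the per-land-type area aggregation), then one numeric
#'   column per city with production in tonnes. May be empty (zero rows).
#' @param energy Tibble/data frame of energy items: columns `item`,
#'   `land_type` (must be `fossil_energy` or `built_up`),
#'   `global_avg_energy_footprint_GJ_per_hm2`, optionally
#'   `convert_coefficient_GJ_per_t` (metadata for tonne-to-GJ conversion;
#'   city values are already GJ), then one numeric column per city with
#'   consumption in GJ.
#' @param population Resident population (persons), > 0.
#' @param year Account year (integer scalar).
#' @param built_up_area_hm2 Optional physically built-up land area in hm2,
#'   added on top of the energy-side built-up footprint when supplied.
#' @return A `regional_account` object (list).
#' @export
regional_account <- function(bio, energy, population, year,
                             built_up_area_hm2 = NULL) {
  bio <- validate_bio_table(bio)
  energy <- validate_energy_table(energy)
  if (!is.numeric(population) || length(population) != 1 ||
      !is.finite(population) || population <= 0) {
    stop("`population` must be a single positive number", call. = FALSE)
  }
  if (!is.null(built_up_area_hm2) &&
      (!is.numeric(built_up_area_hm2) || built_up_area_hm2 < 0)) {
    stop("`built_up_area_hm2` must be a nonnegative number", call. = FALSE)
  }
  structure(
    list(bio = bio, energy = energy, population = population,
         year = as.integer(year), built_up_area_hm2 = built_up_area_hm2),
    class = "regional_account"
  )
}

#' @export
print.regional_account <- function(x, ...) {
  cat(sprintf(
    "Regional account, year %d: %d bio items, %d energy items, N = %s\n",
    x$year, nrow(x$bio), nrow(x$energy),
    format(x$population, big.mark = ",")))
  invisible(x)
}

# City (production/consumption) columns of an account table.
city_columns <- function(tbl) {
  meta <- c("item", "land_type", "global_avg_yield_kg_per_hm2",
            "global_avg_energy_footprint_GJ_per_hm2",
            "convert_coefficient_GJ_per_t", "in_land_total")
  setdiff(names(tbl), meta)
}

validate_bio_table <- function(bio) {
  bio <- tibble::as_tibble(bio)
  need <- c("item", "land_type", "global_avg_yield_kg_per_hm2")
  miss <- setdiff(need, names(bio))
  if (length(miss)) {
    stop("bio account is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"in_land_total" %in% names(bio)) bio$in_land_total <- TRUE
  bad <- !bio$land_type %in% land_types()
  if (any(bad)) {
    stop(sprintf("bio account row %d: unknown land type '%s'",
                 which(bad)[1], bio$land_type[which(bad)[1]]), call. = FALSE)
  }
  if (nrow(bio) && any(!is.finite(bio$global_avg_yield_kg_per_hm2) |
                       bio$global_avg_yield_kg_per_hm2 <= 0)) {
    i <- which(!is.finite(bio$global_avg_yield_kg_per_hm2) |
                 bio$global_avg_yield_kg_per_hm2 <= 0)[1]
    stop(sprintf("bio account row %d ('%s'): global average yield must be > 0",
                 i, bio$item[i]), call. = FALSE)
  }
  for (cc in city_columns(bio)) {
    if (nrow(bio) == 0) {  # empty table: column type carries no information
      bio[[cc]] <- as.numeric(bio[[cc]])
      next
    }
    v <- bio[[cc]]
    if (!is.numeric(v)) {
      stop(sprintf("bio account column '%s' must be numeric", cc),
           call. = FALSE)
    }
    if (nrow(bio) && any(is.na(v) | v < 0)) {
      stop(sprintf("bio account row %d, column '%s': production must be >= 0",
                   which(is.na(v) | v < 0)[1], cc), call. = FALSE)
    }
  }
  bio
}

validate_energy_table <- function(energy) {
  energy <- tibble::as_tibble(energy)
  need <- c("item", "land_type", "global_avg_energy_footprint_GJ_per_hm2")
  miss <- setdiff(need, names(energy))
  if (length(miss)) {
    stop("energy account is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !energy$land_type %in% c("fossil_energy", "built_up")
  if (any(bad)) {
    stop(sprintf(
      "energy account row %d: land type must be fossil_energy or built_up, got '%s'",
      which(bad)[1], energy$land_type[which(bad)[1]]), call. = FALSE)
  }
  if (nrow(energy) && any(!is.finite(energy$global_avg_energy_footprint_GJ_per_hm2) |
                          energy$global_avg_energy_footprint_GJ_per_hm2 <= 0)) {
    i <- which(!is.finite(energy$global_avg_energy_footprint_GJ_per_hm2) |
                 energy$global_avg_energy_footprint_GJ_per_hm2 <= 0)[1]
    stop(sprintf(
      "energy account row %d ('%s'): global average energy footprint must be > 0",
      i, energy$item[i]), call. = FALSE)
  }
  for (cc in setdiff(city_columns(energy), "convert_coefficient_GJ_per_t")) {
    if (nrow(energy) == 0) {
      energy[[cc]] <- as.numeric(energy[[cc]])
      next
    }
    v <- energy[[cc]]
    if (!is.numeric(v)) {
      stop(sprintf("energy account column '%s' must be numeric", cc),
           call. = FALSE)
    }
    if (nrow(energy) && any(is.na(v) | v < 0)) {
      stop(sprintf(
        "energy account row %d, column '%s': consumption must be >= 0",
        which(is.na(v) | v < 0)[1], cc), call. = FALSE)
    }
  }
  energy
}

#' Total footprint area of one biological item
#'
#' The biologically productive area demanded by one consumption item:
#' regional production (tonnes, summed over cities and converted to kg)
#' divided by the item's global average yield (kg/hm2).
#'
#' @param production Numeric vector of city production in tonnes (any length;
#'   summed).
#' @param global_avg_yield_kg_per_hm2 Global average yield in kg/hm2, > 0.
#' @return Total area in hm2.
#' @export
#' @examples
#' bio_item_footprint(c(500, 500), 1000) # 1000 t at 1000 kg/hm2 -> 1000 hm2
bio_item_footprint <- function(production, global_avg_yield_kg_per_hm2) {
  if (!is.numeric(global_avg_yield_kg_per_hm2) ||
      length(global_avg_yield_kg_per_hm2) != 1 ||
      !is.finite(global_avg_yield_kg_per_hm2) ||
      global_avg_yield_kg_per_hm2 <= 0) {
    stop("global average yield must be a single positive number",
         call. = FALSE)
  }
  if (any(!is.finite(production)) || any(production < 0)) {
    stop("production values must be finite and >= 0", call. = FALSE)
  }
  sum(production) * 1000 / global_avg_yield_kg_per_hm2
}

#' Per-capita footprint of one energy item
#'
#' Regional consumption (GJ, summed over cities) per person, and the
#' fossil-fuel (or built-up, for electricity and heat) land area per person
#' implied by the item's global average energy footprint.
#'
#' @param consumption Numeric vector of city consumption in GJ (summed).
#' @param global_avg_energy_footprint_GJ_per_hm2 Global average energy
#'   footprint in GJ/hm2, > 0.
#' @param population Resident population, > 0.
#' @return List with `consumption_per_capita` (GJ/person) and
#'   `area_per_capita` (hm2/person).
#' @export
energy_item_footprint <- function(consumption,
                                  global_avg_energy_footprint_GJ_per_hm2,
                                  population) {
  if (!is.numeric(population) || length(population) != 1 ||
      !is.finite(population) || population <= 0) {
    stop("`population` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(global_avg_energy_footprint_GJ_per_hm2) ||
      global_avg_energy_footprint_GJ_per_hm2 <= 0) {
    stop("global average energy footprint must be > 0", call. = FALSE)
  }
  if (any(!is.finite(consumption)) || any(consumption < 0)) {
    stop("consumption values must be finite and >= 0", call. = FALSE)
  }
  cpc <- sum(consumption) / population
  list(consumption_per_capita = cpc,
       area_per_capita = cpc / global_avg_energy_footprint_GJ_per_hm2)
}

#' Item-level footprint table of a regional account
#'
#' One row per account item with its total footprint area (bio items) or
#' per-capita consumption and area (energy items).
#'
#' @param account A [regional_account()].
#' @return Tibble with columns `item`, `land_type`, `source` (bio/energy),
#'   `total_area_hm2`, `consumption_per_capita_GJ`, `area_per_capita_hm2`.
#' @export
account_item_footprints <- function(account) {
  stopifnot(inherits(account, "regional_account"))
  N <- account$population
  rows <- list()
  bio <- account$bio
  if (nrow(bio)) {
    tot <- vapply(seq_len(nrow(bio)), function(i) {
      bio_item_footprint(as.numeric(bio[i, city_columns(bio)]),
                         bio$global_avg_yield_kg_per_hm2[i])
    }, numeric(1))
    rows$bio <- tibble::tibble(
      item = bio$item, land_type = bio$land_type, source = "bio",
      total_area_hm2 = tot,
      consumption_per_capita_GJ = NA_real_,
      area_per_capita_hm2 = tot / N)
  }
  energy <- account$energy
  if (nrow(energy)) {
    cities <- setdiff(city_columns(energy), "convert_coefficient_GJ_per_t")
    res <- lapply(seq_len(nrow(energy)), function(i) {
      energy_item_footprint(as.numeric(energy[i, cities]),
                            energy$global_avg_energy_footprint_GJ_per_hm2[i],
                            N)
    })
    apc <- vapply(res, `[[`, numeric(1), "area_per_capita")
    rows$energy <- tibble::tibble(
      item = energy$item, land_type = energy$land_type, source = "energy",
      total_area_hm2 = apc * N,
      consumption_per_capita_GJ =
        vapply(res, `[[`, numeric(1), "consumption_per_capita"),
      area_per_capita_hm2 = apc)
  }
  if (!length(rows)) {
    return(tibble::tibble(item = character(), land_type = character(),
                          source = character(), total_area_hm2 = numeric(),
                          consumption_per_capita_GJ = numeric(),
                          area_per_capita_hm2 = numeric()))
  }
  do.call(rbind, rows)
}

#' Per-capita biologically productive area by land type
#'
#' Sums the item-level per-capita areas of an account within each of the six
#' land types (pre-equivalence, i.e. in physical hm2/person). Bio items
#' flagged `in_land_total = FALSE` are skipped. When the account carries a
#' physically built-up land area, it is added (per capita) to the built-up
#' total on top of the electricity/heat footprint.
#'
#' @param account A [regional_account()].
#' @return Named numeric over [land_types()], hm2/person.
#' @export
per_capita_area_by_land_type <- function(account) {
  stopifnot(inherits(account, "regional_account"))
  items <- account_item_footprints(account)
  keep <- rep(TRUE, nrow(items))
  if (nrow(account$bio)) {
    keep[items$source == "bio"] <- account$bio$in_land_total
  }
  items <- items[keep, ]
  out <- stats::setNames(numeric(length(land_types())), land_types())
  if (nrow(items)) {
    agg <- tapply(items$area_per_capita_hm2, items$land_type, sum)
    out[names(agg)] <- agg
  }
  if (!is.null(account$built_up_area_hm2)) {
    out["built_up"] <- out["built_up"] +
      account$built_up_area_hm2 / account$population
  }
  out
}

#' Aggregate per-capita areas into the ecological footprint
#'
#' Weights each land type's per-capita area by its equivalence factor and
#' sums: \eqn{ef = \sum_j w_j A_j}; the regional total is \eqn{EF = N \times
#' ef}. Yield factors play no role on the demand side.
#'
#' @param areas Named numeric of per-capita areas (hm2/person) over land
#'   types; every named land type must have a configured equivalence factor.
#' @param factors A [factor_table()].
#' @param population Resident population, > 0.
#' @return A `footprint_summary`: list with a per-land-type tibble
#'   (`area_per_capita_hm2`, `equivalence_factor`,
#'   `equivalence_area_per_capita_hm2`), `ef_per_capita` (hm2/person),
#'   `ef_total` (hm2) and `population`.
#' @export
aggregate_footprint <- function(areas, factors, population) {
  if (any(!is.finite(areas)) || any(areas < 0)) {
    stop("per-capita areas must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(population) || population <= 0) {
    stop("`population` must be > 0", call. = FALSE)
  }
  w <- factor_lookup(factors, names(areas), "equivalence_factor")
  tbl <- tibble::tibble(
    land_type = names(areas),
    area_per_capita_hm2 = unname(areas),
    equivalence_factor = w,
    equivalence_area_per_capita_hm2 = unname(areas) * w)
  ef <- sum(tbl$equivalence_area_per_capita_hm2)
  structure(
    list(by_land_type = tbl, ef_per_capita = ef,
         ef_total = population * ef, population = population),
    class = "footprint_summary")
}

#' @export
print.footprint_summary <- function(x, ...) {
  cat("Ecological footprint (demand side)\n")
  print(x$by_land_type, ...)
  cat(sprintf("ef per capita: %.4f hm2/person;  EF total: %s hm2\n",
              x$ef_per_capita,
              format(round(x$ef_total), big.mark = ",")))
  invisible(x)
}

#' Footprint summary of a regional account
#'
#' Convenience wrapper: [per_capita_area_by_land_type()] then
#' [aggregate_footprint()].
#'
#' @inheritParams per_capita_area_by_land_type
#' @inheritParams aggregate_footprint
#' @return A `footprint_summary`.
#' @export
account_footprint <- function(account, factors) {
  aggregate_footprint(per_capita_area_by_land_type(account), factors,
                      account$population)
}
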
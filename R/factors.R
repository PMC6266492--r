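#' Canonical biologically productive land types
#'
#' The six land-type categories of the classical ecological-footprint account:
#' arable land, forest, pasture, water area, fossil-energy (CO2-absorption)
#' land and built-up area.
#'
#' @return Character vector of the six canonical land-type codes.
#' @export
#' @examples
#' land_types()
land_types <- function() {
  c("arable", "forest", "pasture", "water", "fossil_energy", "built_up")
}

#' Construct a factor table
#'
#' A factor table holds, per land type, the equivalence factor \eqn{w_j}
#' (converts physical area to world-average-productivity area; used on both
#' the demand and the supply side) and the yield factor \eqn{y_j} (ratio of
#' local to world-average productivity; supply side only), plus the fraction
#' of capacity set aside for biodiversity conservation.
#'
#' @param equivalence_factor Named numeric, one nonnegative value per land
#'   type in [land_types()].
#' @param yield_factor Named numeric, same shape. Fossil-energy land
#'   conventionally has yield factor 0: no land is actually set aside to
#'   absorb CO2, so its supply-side capacity is zero.
#' @param biodiversity_fraction Fraction of per-capita capacity deducted for
#'   biodiversity conservation land; default 0.12.
#' @return A `factor_table`: tibble with columns `land_type`,
#'   `equivalence_factor`, `yield_factor`, carrying `biodiversity_fraction`
#'   as an attribute.
#' @seealso [default_factors()] for the study values.
#' @export
factor_table <- function(equivalence_factor, yield_factor,
                         biodiversity_fraction = 0.12) {
  lt <- land_types()
  for (nm in c("equivalence_factor", "yield_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || is.null(names(v))) {
      stop(sprintf("`%s` must be a named numeric vector", nm), call. = FALSE)
    }
    missing <- setdiff(lt, names(v))
    if (length(missing)) {
      stop(sprintf("`%s` is missing land types: %s", nm,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    unknown <- setdiff(names(v), lt)
    if (length(unknown)) {
      stop(sprintf("`%s` has unknown land types: %s", nm,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    if (any(!is.finite(v)) || any(v < 0)) {
      stop(sprintf("`%s` values must be finite and >= 0", nm), call. = FALSE)
    }
  }
  if (!is.numeric(biodiversity_fraction) || length(biodiversity_fraction) != 1 ||
      is.na(biodiversity_fraction) ||
      biodiversity_fraction < 0 || biodiversity_fraction > 1) {
    stop("`biodiversity_fraction` must be a single number in [0, 1]",
         call. = FALSE)
  }
  out <- tibble::tibble(
    land_type = lt,
    equivalence_factor = unname(equivalence_factor[lt]),
    yield_factor = unname(yield_factor[lt])
  )
  attr(out, "biodiversity_fraction") <- biodiversity_fraction
  class(out) <- c("factor_table", class(out))
  out
}

#' Default equivalence and yield factors of the Yangtze study
#'
#' Equivalence factors: arable 2.51, forest 1.26, pasture 0.46, water 0.37,
#' fossil-energy 1.26, built-up 2.51. Yield factors: arable 1.66,
#' pasture 0.19, forest 0.91, built-up 1.66, water 1.00, fossil-energy 0
#' (CO2-absorption land is not actually set aside). Biodiversity deduction
#' 12%.
#'
#' @return A [factor_table()].
#' @export
#' @examples
#' default_factors()
default_factors <- function() {
  factor_table(
    equivalence_factor = c(arable = 2.51, forest = 1.26, pasture = 0.46,
                           water = 0.37, fossil_energy = 1.26,
                           built_up = 2.51),
    yield_factor = c(arable = 1.66, pasture = 0.19, forest = 0.91,
                     built_up = 1.66, water = 1, fossil_energy = 0),
    biodiversity_fraction = 0.12
  )
}

#' @export
print.factor_table <- function(x, ...) {
  cat(sprintf("Factor table (biodiversity deduction %.0f%%)\n",
              100 * attr(x, "biodiversity_fraction")))
  print(tibble::as_tibble(unclass_factor_table(x)), ...)
  invisible(x)
}

unclass_factor_table <- function(x) {
  class(x) <- setdiff(class(x), "factor_table")
  x
}

# Look up a named factor column for given land types, erroring informatively
# when a needed land type has no configured factor.
factor_lookup <- function(factors, land_type, column) {
  stopifnot(inherits(factors, "factor_table"))
  idx <- match(land_type, factors$land_type)
  if (anyNA(idx)) {
    stop(sprintf("no %s configured for land type(s): %s", column,
                 paste(unique(land_type[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  factors[[column]][idx]
}

biodiversity_fraction <- function(factors) {
  attr(factors, "biodiversity_fraction")
}
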
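#' Exact GM(1,1)-consistent series
#'
#' Generates a series that satisfies the discretized grey equation exactly:
#' \deqn{x^{(0)}(k) = \frac{u - a\,x^{(1)}(k-1)}{1 + a/2}, \quad k \ge 2,}
#' starting from `initial_value`. Because the least-squares problem solved by
#' [fit_gm11()] has zero residuals on such a series, the fitter recovers
#' `(a, u)` to machine precision — this is the construction oracle used in
#' the parameter-recovery tests.
#'
#' @param a Development coefficient.
#' @param u Control coefficient.
#' @param initial_value First value \eqn{x^{(0)}(1)}, > 0.
#' @param n Series length, >= 4.
#' @return Numeric series of length `n`, strictly positive.
#' @export
#' @examples
#' x <- gm_exact_series(a = 0.1, u = 1, initial_value = 1.5, n = 6)
#' fit_gm11(x)$a  # 0.1 to machine precision
gm_exact_series <- function(a, u, initial_value, n) {
  if (!is.numeric(n) || n < 4) stop("`n` must be >= 4", call. = FALSE)
  if (!is.numeric(initial_value) || initial_value <= 0) {
    stop("`initial_value` must be > 0", call. = FALSE)
  }
  n <- as.integer(n)
  x0 <- numeric(n)
  x0[1] <- initial_value
  x1_prev <- initial_value
  for (k in 2:n) {
    x0[k] <- (u - a * x1_prev) / (1 + a / 2)
    x1_prev <- x1_prev + x0[k]
  }
  if (any(x0 <= 0)) {
    stop("parameters produce nonpositive values; GM(1,1) series must stay positive",
         call. = FALSE)
  }
  x0
}

#' Noisy GM(1,1)-consistent series
#'
#' An exact grey series perturbed by multiplicative lognormal noise with
#' mean 1 and coefficient of variation `noise_cv`. Lognormal noise keeps the
#' series positive, which GM(1,1) requires. Output is a pure function of the
#' arguments and `seed`.
#'
#' @inheritParams gm_exact_series
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   >= 0; 0 returns the exact series.
#' @param seed Integer seed (mandatory).
#' @return Numeric series of length `n`.
#' @export
gm_noisy_series <- function(a, u, initial_value, n, noise_cv, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory for stochastic generation", call. = FALSE)
  }
  if (!is.numeric(noise_cv) || noise_cv < 0) {
    stop("`noise_cv` must be >= 0", call. = FALSE)
  }
  x <- gm_exact_series(a, u, initial_value, n)
  if (noise_cv == 0) return(x)
  sdlog <- sqrt(log(1 + noise_cv^2))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic multi-city accounts targeting per-capita EF/EC series
#'
#' Builds, for each year, an item-level regional account and a land-area
#' table whose implied per-capita footprint and carrying capacity equal the
#' requested target series (up to floating-point error), so the full
#' accounts-to-balance-table pipeline can be exercised without real data.
#' Item and city shares are drawn once per call from the seeded RNG;
#' production is then scaled analytically so that aggregation reproduces the
#' targets.
#'
#' @param target_ef,target_ec Positive per-capita target series
#'   (hm2/person), equal length, one value per year.
#' @param years Integer years, same length.
#' @param population Population used for every year, > 0.
#' @param factors A [factor_table()]; default [default_factors()]. Land
#'   types with zero yield factor receive zero supply area.
#' @param n_cities Number of city columns; default 4.
#' @param items_per_land_type Number of bio items per biological land type;
#'   default 2.
#' @param seed Integer seed (mandatory).
#' @return List with one element per year, each a list of `account` (a
#'   [regional_account()]) and `land_areas`, ready for
#'   [build_annual_table()].
#' @export
#' @examples
#' syn <- synthetic_accounts(
#'   target_ef = c(1.5, 1.6, 1.7, 1.65), target_ec = c(0.4, 0.41, 0.42, 0.4),
#'   years = 2013:2016, population = 1e6, seed = 7)
#' build_annual_table(syn, default_factors())$ef_per_capita
synthetic_accounts <- function(target_ef, target_ec, years, population,
                               factors = default_factors(), n_cities = 4,
                               items_per_land_type = 2, seed) {
  if (missing(seed) || !is.numeric(seed)) {
    stop("`seed` is mandatory for stochastic generation", call. = FALSE)
  }
  if (length(target_ef) != length(years) ||
      length(target_ec) != length(years)) {
    stop("targets and `years` must have equal length", call. = FALSE)
  }
  if (any(target_ef <= 0) || any(target_ec <= 0)) {
    stop("target series must be strictly positive", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  cities <- paste0("city_", seq_len(n_cities))
  bio_lt <- c("arable", "pasture", "water", "forest")
  energy_lt <- c("fossil_energy", "built_up")
  w <- stats::setNames(factors$equivalence_factor, factors$land_type)
  y <- stats::setNames(factors$yield_factor, factors$land_type)

  # fixed per-call structure: land-type shares, item shares, city shares
  lt_share <- stats::runif(6, 0.5, 1.5)
  names(lt_share) <- c(bio_lt, energy_lt)
  item_share <- stats::runif(items_per_land_type * length(bio_lt), 0.5, 1.5)
  city_share <- matrix(stats::runif(n_cities * 50, 0.5, 1.5), ncol = n_cities)
  yields <- stats::runif(items_per_land_type * length(bio_lt), 800, 20000)
  energy_gaef <- c(fossil_energy = 71, built_up = 1000)
  supply_share <- stats::runif(6, 0.5, 1.5)
  names(supply_share) <- factors$land_type

  lapply(seq_along(years), function(i) {
    ef <- target_ef[i]; ec <- target_ec[i]
    # per-capita physical areas by land type, scaled so sum(w * A) == ef
    raw <- lt_share / w[names(lt_share)]
    A <- raw * ef / sum(w[names(lt_share)] * raw)
    bio_rows <- list()
    r <- 0L
    for (j in seq_along(bio_lt)) {
      lt <- bio_lt[j]
      sh <- item_share[(j - 1) * items_per_land_type + seq_len(items_per_land_type)]
      sh <- sh / sum(sh)
      for (m in seq_len(items_per_land_type)) {
        r <- r + 1L
        area_total <- A[lt] * sh[m] * population          # hm2
        yld <- yields[r]                                   # kg/hm2
        prod_t <- area_total * yld / 1000                  # tonnes
        cs <- city_share[r, ] / sum(city_share[r, ])
        row <- c(list(item = sprintf("%s_item_%d", lt, m), land_type = lt,
                      global_avg_yield_kg_per_hm2 = yld),
                 as.list(stats::setNames(prod_t * cs, cities)))
        bio_rows[[r]] <- tibble::as_tibble(row)
      }
    }
    bio <- do.call(rbind, bio_rows)
    energy_rows <- lapply(seq_along(energy_lt), function(j) {
      lt <- energy_lt[j]
      gaef <- energy_gaef[lt]
      total_GJ <- A[lt] * gaef * population
      cs <- city_share[40 + j, ] / sum(city_share[40 + j, ])
      tibble::as_tibble(c(
        list(item = paste0(lt, "_fuel"), land_type = lt,
             global_avg_energy_footprint_GJ_per_hm2 = unname(gaef)),
        as.list(stats::setNames(total_GJ * cs, cities))))
    })
    energy <- do.call(rbind, energy_rows)
    # supply: areas with positive yield factor scaled so sum(w*y*A)/N == ec
    prod_lt <- factors$land_type[y[factors$land_type] > 0]
    raw_s <- supply_share[prod_lt] / (w[prod_lt] * y[prod_lt])
    As <- raw_s * ec * population / sum(w[prod_lt] * y[prod_lt] * raw_s)
    land_areas <- tibble::tibble(
      land_type = factors$land_type,
      area_hm2 = ifelse(factors$land_type %in% prod_lt,
                        As[factors$land_type], 0))
    list(account = regional_account(bio, energy, population, years[i]),
         land_areas = land_areas)
  })
}
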
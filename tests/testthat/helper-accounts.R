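# Small hand-sized account used across tests: two cities, one item per
# source, round numbers so expected areas are exact by hand.
tiny_bio <- function() {
  tibble::tibble(
    item = c("grain", "fish"),
    land_type = c("arable", "water"),
    global_avg_yield_kg_per_hm2 = c(1000, 500),
    city_a = c(600, 100),
    city_b = c(400, 150))
}

tiny_energy <- function() {
  tibble::tibble(
    item = c("coal", "power"),
    land_type = c("fossil_energy", "built_up"),
    global_avg_energy_footprint_GJ_per_hm2 = c(50, 1000),
    city_a = c(30000, 5000),
    city_b = c(20000, 5000))
}

tiny_account <- function(population = 1000, year = 2020) {
  regional_account(tiny_bio(), tiny_energy(), population, year)
}

# Table-6 study series, used by grey-model and pipeline tests.
ef_series <- c(1.5270, 1.4782, 2.3897, 1.9143, 1.2611)
ec_series <- c(0.3478, 0.3795, 0.4084, 0.3902, 0.3595)

# Independent least-squares oracle for the grey coefficients: generic
# numerical minimizer of the same objective, no normal equations.
oracle_gm11 <- function(x0, weight = 0.5) {
  x1 <- cumsum(x0)
  n <- length(x0)
  z <- weight * x1[-1] + (1 - weight) * x1[-n]
  sse <- function(p) sum((x0[-1] - (-p[1] * z + p[2]))^2)
  fit <- stats::optim(c(0, mean(x0)), sse, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
  c(a = fit$par[1], u = fit$par[2])
}
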
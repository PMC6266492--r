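#' Packaged Yangtze River urban agglomeration study inputs (2013-2017)
#'
#' Loads the plain-text fixtures shipped with the package: the 2017
#' item-level biological and energy accounts of the eight-city Yangtze River
#' urban agglomeration (Nanjing, Wuxi, Suzhou, Changzhou, Zhenjiang,
#' Nantong, Yangzhou, Taizhou), the 2017 supply-side land areas, the
#' equivalence/yield factor configuration, and the 2013-2017 annual
#' per-capita EF/EC series.
#'
#' Notes on the fixtures:
#' * The population (43,344,300) is a calibrated value, solved from the
#'   printed (total, per-capita) pairs of the 2017 account; it is not itself
#'   a published figure.
#' * The melon-and-fruit bio item carries `in_land_total = FALSE`: the
#'   study's per-land-type arable total excludes it, and only that
#'   convention reproduces the published footprint total.
#' * The tea row's city production cells are synthetic: the published city
#'   detail is internally inconsistent with the row's total footprint, so
#'   the cells are rescaled to the production implied by the total
#'   (13,435 t at 566 kg/hm2).
#'
#' @return List with components `factors` (a [factor_table()]), `bio`,
#'   `energy` (validated item tables), `account` (the 2017
#'   [regional_account()]), `land_areas`, `annual_series` (an
#'   [annual_balance_table()] for 2013-2017), `population`, `year`, and
#'   `paths` (the underlying files).
#' @export
#' @examples
#' fx <- yangtze_fixtures()
#' account_footprint(fx$account, fx$factors)$ef_per_capita  # 1.2611
yangtze_fixtures <- function() {
  dir <- system.file("extdata", "yangtze", package = "ecogrey",
                     mustWork = TRUE)
  paths <- list(
    bio = file.path(dir, "bio_account_2017.csv"),
    energy = file.path(dir, "energy_account_2017.csv"),
    land_areas = file.path(dir, "land_areas_2017.csv"),
    factors = file.path(dir, "factors.yaml"),
    annual_series = file.path(dir, "annual_series.csv"),
    study = file.path(dir, "study.yaml"))
  study <- yaml::read_yaml(paths$study)
  factors <- read_factor_config(paths$factors)
  bio <- read_bio_account(paths$bio)
  energy <- read_energy_account(paths$energy)
  list(
    factors = factors,
    bio = bio,
    energy = energy,
    account = regional_account(bio, energy, study$population, study$year),
    land_areas = read_land_areas(paths$land_areas),
    annual_series = read_annual_series(
      paths$annual_series,
      biodiversity_fraction = biodiversity_fraction(factors)),
    population = study$population,
    year = study$year,
    paths = paths)
}
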
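Package: ecogrey
Title: Ecological Footprint Accounting and GM(1,1) Grey Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ecological footprint (EF), ecological carrying capacity (EC) and
    ecological deficit (ED) accounting for a multi-city region, following the
    classical equivalence-factor / yield-factor method, together with GM(1,1)
    grey-model fitting and forecasting of the resulting short annual per-capita
    series. Converts item-level biological production and energy consumption
    accounts into per-capita biologically productive areas per land type,
    aggregates them with equivalence factors into the per-capita footprint,
    computes biocapacity with yield factors and a biodiversity deduction, and
    fits the first-order one-variable grey model to the annual series to
    forecast demand, supply and deficit. Ships the 2013-2017 Yangtze River
    urban agglomeration study accounts as plain-text fixtures and a seeded
    synthetic-data generator for grey-consistent accounts and series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
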
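---
title: "Methods: footprint accounting and grey forecasting in ecogrey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: footprint accounting and grey forecasting in ecogrey}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecogrey)
```

# The accounting model

`ecogrey` implements the classical ecological-footprint / biocapacity
account over six land types (arable, forest, pasture, water, fossil-energy,
built-up) and the GM(1,1) grey model for forecasting the resulting short
annual series.

**Demand.** Each biological item converts regional production (tonnes,
summed over cities, ×1000 to kg) into area by dividing by its *global
average yield* (kg/hm²); each energy item converts per-capita consumption
(GJ/person) into area by dividing by the *global average energy footprint*
(GJ/hm²) of its land type — fossil-fuel land for primary fuels, built-up
land for electricity and heat (treated as indirect coal-fired consumption).
Per-land-type areas are weighted by equivalence factors $w_j$ and summed:
$ef = \sum_j w_j A_j$, $EF = N \cdot ef$. Yield factors deliberately play
no role on the demand side: the demand formula is sometimes printed with a
yield factor in the denominator, but the published account tables this
package reproduces are computed without it, and that convention is the one
implemented.

**Supply.** $EC = \sum_j w_j y_j A_j$ with local-vs-world yield factors
$y_j$; $ec = EC/N$. Fossil-energy (CO₂-absorption) land carries $y = 0$:
no land is actually set aside to absorb CO₂, so the supply side contributes
nothing for it. A configurable fraction (default 0.12) of per-capita
capacity is deducted for biodiversity conservation land, applied
multiplicatively: $available = 0.88 \cdot ec$. The deficit is
$ED = ef - available$; the identity $ED + available = ef$ holds exactly.

## Parameters

| Parameter | Units | Default | Rationale |
|---|---|---|---|
| equivalence factors $w_j$ | — | arable/built-up 2.51, forest/fossil 1.26, pasture 0.46, water 0.37 | study configuration (national calorific-value calibration is upstream, out of scope) |
| yield factors $y_j$ | — | arable/built-up 1.66, forest 0.91, pasture 0.19, water 1, fossil 0 | study configuration |
| biodiversity fraction | — | 0.12 | conventional reserve for conservation land |
| tonnes→kg | — | ×1000 | unit identity: 1 t at 1000 kg/hm² = 1 hm² |
| background weight | — | 0.5 | classical half-sum background value; reproduces the published grey coefficients |
| degeneracy threshold on $|a|$ | — | 1e-10 | below it $u/a$ is numerically meaningless; constant model $\hat x^{(0)} \equiv u$ used instead |
| grade ladder (mean relative error) | fraction | ≤1% excellent, ≤3% good, ≤5% qualified | boundary inclusive: an error exactly on a threshold takes the better grade |

# The grey model

GM(1,1) fits short positive series: the 1-AGO accumulated series
$x^{(1)}$ is assumed to satisfy $dx^{(1)}/dt + a\,x^{(1)} = u$. Its
discretization $x^{(0)}(k) = -a\,z^{(1)}(k) + u$ over the background
values $z^{(1)}(k) = \tfrac12(x^{(1)}(k) + x^{(1)}(k-1))$ is solved for
$(a, u)$ by ordinary least squares via the normal equations (2×2; a
reciprocal-condition check guards against a degenerate background
sequence). The time response is anchored at the first observation,

$$\hat x^{(1)}(t+1) = \left(x^{(0)}(1) - \frac{u}{a}\right) e^{-a t} + \frac{u}{a},$$

and restored values are its first differences (IAGO). The anchor is stored
exactly ($\hat x^{(1)}(1) = x^{(0)}(1)$ by construction, enforced to the
last bit). Restored values for $t \ge 2$ form a geometric sequence with
ratio $e^{-a}$, so with $a > 0$ forecasts decline monotonically. With $n$
observations at years $Y_1..Y_n$, forecast step 1 is year $Y_{n+1}$.

Numerical notes:

* On a series generated by the discrete recursion
  $x^{(0)}(k) = (u - a\,x^{(1)}(k-1))/(1 + a/2)$ the least-squares problem
  has zero residuals, so $(a, u)$ are recovered to machine precision; the
  *restored* values still differ from the data by $O(a^2)$ because the
  continuous-time exponential and the discrete recursion have slightly
  different one-step ratios ($e^{-a}$ vs $(1-a/2)/(1+a/2)$). This is an
  intrinsic property of GM(1,1), not a fitting error.
* The fit is scale-equivariant: scaling the series by $c$ leaves $a$
  unchanged and scales $u$ by $c$.
* Accuracy is reported as per-point relative errors of the restored
  in-sample values ($k = 2..n$) and their mean. The published study also
  prints per-model "relative error" percentages (1.51%, 3.10%) whose
  definition is not reproducible from any standard metric on the published
  series (the one-step in-sample mean relative error of the demand-side fit
  is ~23%); those two numbers are therefore not asserted anywhere, and the
  report exposes the standard definitions instead.

# The packaged study fixtures

`yangtze_fixtures()` loads the 2013–2017 accounts of the eight-city Yangtze
River urban agglomeration: the 2017 item-level biological (17 items) and
energy (14 items) accounts, the 2017 supply-side land areas, the factor
configuration, and the five-year annual per-capita series. Three editorial
decisions were needed to make the fixtures reproduce every published
number, all visible in the fixture files:

* **Population.** The resident population is not published; it is
  calibrated by solving $N$ from the published (total, per-capita) pairs.
  Every pair constrains $N$ to an interval; the intersection is
  (43,344,246, 43,344,378] and the fixture carries 43,344,300. It is a
  derived value and is documented as such.
* **Melon and fruit.** The published per-land-type arable total (0.1104
  hm²/person) equals the arable items *excluding* the melon-and-fruit row
  (including it gives 0.1124, and the footprint total would become 1.2663
  instead of the published 1.2611). The fixture flags the row
  `in_land_total = FALSE`: it is tallied in the item table but excluded
  from the aggregation, reproducing the source accounting.
* **Tea.** The published city-level tea production (19,610 t) is
  internally inconsistent with the row's own total footprint (23,737 hm² at
  566 kg/hm² implies 13,435 t) — and the total is what the downstream
  tables use. The fixture's tea city cells are therefore synthetic:
  rescaled proportionally to the implied total.

The derived columns of the five-year balance table (available capacity and
deficit) are recomputed from the 4-decimal per-capita columns rather than
copied, so they can differ from the published rows in the last decimal
(at most 1e-4; e.g. 0.88 × 0.3478 = 0.30606 vs the published 0.3060).

# EC series choice for forecasting

The published grey model labelled "available EC per capita" has
coefficients that anchor at 0.3478 — the *undeducted* first-year EC, not
the deducted 0.3060. `run_grey_analysis()` therefore defaults to
`ec_series_mode = "raw_ec"`: it fits the undeducted EC column and uses its
forecasts directly as the supply path, which reproduces the published
coefficients and the 2018 forecasts (EC 0.3658, ED 1.1713). The
methodologically consistent alternative, fitting the 0.88-deducted column,
is available as `ec_series_mode = "available_ec"`; the two differ by a
scale factor in $u$ only (scale equivariance), so the choice affects the
level, not the shape, of the supply forecast.

# Synthetic data

The generator exists so that every stage is testable without external
data, and doubles as the fitting oracle:

* `gm_exact_series(a, u, x1, n)` follows the discrete grey recursion
  exactly — the fitter must recover $(a, u)$ to ≤1e-10 on it (tested over
  $|a| \le 0.5$, $n$ 4..20).
* `gm_noisy_series()` multiplies an exact series by lognormal factors with
  mean 1 and a chosen coefficient of variation. Lognormal noise keeps the
  series positive, which GM(1,1) requires. A mandatory seed makes every
  draw a pure function of (parameters, seed).
* `synthetic_accounts()` builds whole multi-city account sets whose implied
  per-capita EF/EC equal requested target trajectories to ≤1e-9: item,
  land-type and city shares are drawn once from the seeded RNG and
  production is then scaled analytically so the aggregation identity holds.

What the generator does *not* emulate: yearbook-style missing entries and
their interpolation, inter-annual correlation of item composition, reporting
heterogeneity between cities, or item counts as large as real accounts.
Passing tests on synthetic accounts show the pipeline's arithmetic and
invariances are right; fidelity to real regional statistics is carried by
the packaged study fixtures instead.

Problem sizes used in the test suite are deliberately small — series of
length 4–20, accounts with up to 8 items × 8 cities, 200-replicate noise
envelopes — which keeps the whole suite under a few seconds while covering
every code path; the accounting arithmetic is exact at any scale, and the
grey model is designed for short series, so nothing is lost.

# Interfaces

Readers (`read_bio_account()`, `read_energy_account()`,
`read_land_areas()`, `read_factor_config()`, `read_annual_series()`)
validate schemas strictly and name the offending file, row and column in
errors. CSV files are UTF-8, comma-separated, `.`-decimal, without
thousands separators (grouping in printed tables is presentation only).
`write_report()` serializes balance tables and forecast reports to CSV or
JSON deterministically — stable column order, per-capita values rounded to
4 decimals (matching the precision of the published tables), no
timestamps — so re-running the pipeline on its own outputs is idempotent.
The package's R functions are the interface; batch use is a short Rscript
over them (see `scripts/acceptance.R` for a template).

# Known limitations

* Equivalence/yield factors are configuration constants; deriving them
  from national yearbook data is out of scope.
* City-level (disaggregated) footprints are not an output; cities exist
  only as account columns.
* GM(1,1) only: no GM(1,N), Verhulst or rolling variants, and no
  posterior-variance-ratio test. The model extrapolates a single
  exponential trend; structural breaks (e.g. policy-driven demand drops)
  enter only through the data window.
* The biodiversity deduction is a fixed multiplicative fraction; no
  land-type-specific conservation shares.
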
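---
title: "Growing-season frost exposure: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growing-season frost exposure: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package answers

Climate warming reduces the total number of frost days in a year, but it
also lengthens the growing season of northern vegetation. A season that
starts earlier and ends later overlaps more of the shoulder weeks in which
sub-zero nights still occur, so the number of *growing-season* frost days
(GSFD — days with daily minimum air temperature $T_{\min} < 0\,^{\circ}$C
falling between the start (SOS) and end (EOS) of the season) can rise even
as total frost days fall. `frostphen` implements the full chain needed to
quantify this at grid scale: phenology extraction from NDVI composites,
frost counting inside phenological windows, decadal change testing,
factorial attribution, and spatial association statistics — together with a
synthetic gridded world with known truth on which every stage is validated.

## Season dating from NDVI

Each pixel-year carries 24 bimonthly NDVI composites. Four seasonal-curve
reconstructions are implemented in `fit_curve()`:

* **hants** — least-squares harmonic series: mean plus three harmonics
  (periods 365, 365/2, 365/3 days). Three harmonics is the conventional
  order for a 24-point annual series; more harmonics chase composite noise.
* **polyfit** — sixth-order polynomial on a year scaled to $[-1, 1]$.
* **double_logistic** — the six-parameter model
  $\mathrm{NDVI}(t) = w + A\,[\sigma(k_s(t-S)) - \sigma(k_a(t-E))]$
  with $\sigma$ the logistic function; $S$ and $E$ are inflection days and
  are the model's own season dates.
* **piecewise_logistic** — independent four-parameter sigmoids for the
  rising and falling halves of the year, split at the seasonal peak;
  transition dates are the extrema of each sigmoid's first derivative,
  i.e. its inflection day.

Dating follows the climatological-threshold scheme
(`climatological_dates()`, `annual_dates()`): the multi-year mean
composites are fitted once per pixel; the day of steepest rise in the first
half-year (days 1–182) defines the climatological SOS and the day of
steepest fall in days 183–365 the EOS; the fitted NDVI at those dates
becomes the pixel's thresholds; each year is then dated by its first upward
crossing of the SOS threshold and last downward crossing of the EOS
threshold, interpolated linearly between daily grid points and rounded
half-up to integer days. For the two logistic models the climatological
dates are read from the fitted inflection parameters directly rather than
from a discrete slope scan.

Numerical choices worth knowing:

* The half-year split is fixed at day 182/183, and slope-scan ties resolve
  to the earliest day (ties only arise on flat fits).
* The slope scan accepts only *interior* local extrema of the slope. The
  smooth reconstructions — the sixth-order polynomial especially — swing at
  the year boundaries, and an unrestricted argmax would date the season at
  day 1.
* Double-logistic fits use Levenberg–Marquardt with five candidate starts
  seeded from a slope scan of the raw composites. Annual fits are
  warm-started from the pixel's climatological parameters and accepted
  without the multi-start sweep when their residual sd is commensurate with
  composite noise (below 0.05 NDVI or 1.25× the reference fit); a fit stuck
  in a wrong minimum leaves residuals of the order of the seasonal
  amplitude and triggers the full sweep.
* Pixels whose climatological composite amplitude is below 0.05 NDVI
  (configurable) are non-seasonal and carry no dates. The threshold is our
  choice; published analyses rarely state theirs.
* A double growing season is declared when the fitted curve has two local
  maxima above the dating thresholds separated by a trough of at least 10%
  of the curve amplitude. With two complete seasons, SOS comes from the
  first and EOS from the second; when the second season's fall does not
  cross the EOS threshold by day 365 (it ends the following year), both
  dates come from the first season. Requiring peaks above the thresholds
  keeps Gibbs-type side-lobes of the harmonic/polynomial reconstructions
  from being mistaken for seasons.
* The ensemble date is the mean of the methods that produced a date,
  requiring at least two (default), rounded half-up.

## Frost counting

`daily_min()` collapses 3-h or 6-h samples to daily minima;
`frost_counts()` counts days with $T_{\min}$ **strictly** below
0 °C inside the closed window $[\mathrm{SOS}, \mathrm{EOS}]$ — a day at
exactly 0.0 °C is not frost. Spring and autumn parts split at the summer
solstice, day 173 (22 June) in the fixed 365-day calendar used throughout,
or alternatively at the mid-season day $\lfloor(\mathrm{SOS} +
\mathrm{EOS})/2\rfloor$. The cutoff day itself belongs to spring — two
closed intervals meeting at the solstice would count 22 June twice — which
guarantees the partition identity spring + autumn = total. The vectorized
counter is cumulative-sum based and is tested for exact equality against a
scalar day-loop oracle. All counting uses integer day windows; leap days in
real-world input are removed on read (`read_cube()`) so every year has 365
days.

## Decadal change and attribution

`difference_test()` applies a per-pixel Welch two-sample *t*-test between
the annual values of two decades (Welch rather than pooled: decade
variances need not match). Decade boundaries default to 1982–1989,
1990–1999 and 2000–2012 (or 2000–2009 when comparing against site records)
— the record starts in 1982, and the boundaries are configurable because
published analyses rarely state theirs. Zero-variance pixels are handled by
convention: equal means are unchanged (p = 1), unequal means are changed
(p = 0). Hemispheric fractions (`area_fraction()`) and regional means
(`region_mean_change()`) weight pixels by the cosine of latitude. No
multiple-testing correction is applied across pixels, deliberately
mirroring the analysis style of the field.

`run_scenario()` implements the factorial attribution: per draw, one year
is sampled uniformly from the record and held constant globally — either
its phenology field (so only temperature varies) or its daily temperature
field (so only phenology varies) — and counts are averaged over ten draws
(default) to remove the luck of the drawn year. One drawn year applies to
all pixels of a draw; a per-pixel draw would also be defensible, but a
globally constant field matches the idea of "holding the driver constant"
and keeps the draw manifest auditable (draw years are recorded and
reproducible from the master seed). Frost counting is nonlinear in its
inputs, so no exact additive decomposition is asserted; the dominance label
(`attribute_change()`) compares the two scenarios' absolute decadal changes
with a 0.1-day tie band.

## Spatial association

`partial_correlation()` is the first-order formula
$r_{xy\cdot z} = (r_{xy} - r_{xz} r_{yz}) / \sqrt{(1-r_{xz}^2)(1-r_{yz}^2)}$
with the *t* transform on $n-3$ degrees of freedom;
`moving_window_partial()` evaluates it over every 2.5° × 2.5° (5 × 5 pixel)
window centred on each half-degree cell, truncated at grid edges, reported
only where at least ten valid pixels contribute. The temperature covariate
is the change in growing-season mean daily $T_{\min}$, computed over each
pixel's climatological ensemble season (`season_mean_tmin()`); an
annual-mean alternative is available, since the covariate definition is an
open choice. `binned_change_density()` and `continental_association()`
provide the hemispheric view: 1-day binned density of (Δphenology,
ΔGSFD) pairs with quadrant percentages, and the cos-latitude-weighted
regression slope of ΔGSFD on ΔGSL.

## The synthetic earth

`gen_truth()` draws smooth low-order random surfaces for every truth field
so that moving-window statistics see real spatial structure. The defaults
describe a mid-to-high-latitude world: baseline SOS 110–145, EOS 255–295
(gap ≥ 30 days enforced), SOS advancing 0.1–0.4 d yr⁻¹, EOS delaying
0.05–0.25 d yr⁻¹, winter NDVI 0.05–0.15 with amplitude 0.4–0.6, annual
mean $T_{\min}$ −2 to 6 °C with a 12–18 °C seasonal cycle (coldest
mid-January), 2–4 °C diurnal range (coldest sample 06:00), AR(1) daily
weather noise (lag-1 autocorrelation 0.6–0.8, sd 2.5–4 °C) shared by all
sub-daily samples of a day, and a warming trend of 0.02–0.05 °C yr⁻¹ —
about 0.7 °C between a 1980s and a 2000s decade, the magnitude typical of
recent northern warming.

`gen_ndvi()` evaluates the double-logistic truth curve (slopes 0.15 d⁻¹) at
24 fixed mid-composite days, adds independent Gaussian composite noise
(default 0.02 NDVI), and clips to $[-0.2, 1]$. `gen_insitu()` emulates a
phenology network: sites at random pixels reporting the pixel's true dates
plus observation noise, with whole site-years missing at random.

What the generator deliberately does **not** emulate: satellite orbital
artifacts, snow and cloud contamination, mixed-pixel species composition,
sub-daily weather variability (the diurnal cycle is deterministic), spatial
correlation of weather noise between pixels, and leap days. Passing the
recovery tests therefore demonstrates correctness of the algorithms under
the stated statistical structure, not robustness to every failure mode of
real satellite archives.

## Validation sizes

The test suite and the acceptance script exercise: date and trend recovery
on a 16 × 32-pixel, 31-year world (noiseless, and with 0.02 composite
noise); exact oracle equivalence of the vectorized frost counter on 10⁴
random windows; attribution recovery on two 12 × 24-pixel worlds (one with
only phenology trends, one with only a warming trend; 6-h temperature
sampling, ten draws); statistical-kernel agreement with reference
implementations (Welch p-values to 10⁻¹⁰, partial correlations to 10⁻¹²)
and type-I control on a 2 500-pixel null world; and the directional
reproduction of the central hypothesis on a 20 × 40-pixel world with
spatially varying season-length trends under uniform warming, where the
association of ΔGSFD with ΔGSL (controlling temperature) dominates the
association with ΔT_min. These sizes are the package's validation choices:
large enough for stable statistics, small enough to run routinely.

## Known limitations

* The harmonic and polynomial reconstructions are biased date estimators on
  logistic-shaped seasons (several days); the ensemble inherits a fraction
  of that bias. This mirrors the behaviour of the published methods rather
  than a defect of the implementation.
* Days are defined in the cube's native time coordinate; no local-solar-time
  correction is applied when reducing sub-daily samples to daily minima.
* Grid I/O uses a plain-text cube dialect with the same axes, units and
  calendar semantics as CF-style NetCDF; Kelvin input is auto-detected
  (values above 150) and converted with a warning.
* Counting frost days quantifies *exposure*, not damage: species-specific
  susceptibility and timing sensitivity are outside the package's scope.
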
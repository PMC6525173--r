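---
title: "Soil-water-modified thermal time: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Soil-water-modified thermal time: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoflow)
```

## The problem

Chickpea and wheat flowering time is conventionally modelled from
temperature and photoperiod alone, yet field sowings on deep, wet clay
soils flower weeks later than such models predict. `phenoflow` implements
the hypothesis that **wet topsoil itself slows development**: whenever the
fractional available soil water (FASW) of the 0–60 cm root zone exceeds the
readily-available-water threshold of 0.65, daily thermal time TT is
replaced by

$$\mathrm{TT_m} = \mathrm{TT}\,\bigl(1.65 - \min(\mathrm{FASW}, 1)\bigr),
\qquad \mathrm{FASW} \ge 0.65,\ \text{stage} \ge 3\ (\text{emergence}),$$

with
$$\mathrm{FASW} = \frac{\sum_i \bigl(\mathrm{sw}_i - \mathrm{ll15}_i\bigr)}
                       {\sum_i \bigl(\mathrm{dul}_i - \mathrm{ll15}_i\bigr)}$$
summed over layers intersecting 0–60 cm (a straddling layer prorated by
thickness). The multiplier is exactly 1 at the gate and 0.65 at or above
field capacity, so the gated phases stretch by at most $1/0.65 \approx
1.54$. The 1.65 constant and 0.65 threshold are manual-calibration values
of the source analysis; they are the package defaults and are never
re-fitted internally (the cohort tooling can *recover* the constant by grid
search, which is a validation exercise, not a calibration).

The gate comparison is implemented as $\ge 0.65$. The equality case has
multiplier exactly 1, so the choice between $\ge$ and $>$ is numerically
immaterial; it is still surfaced in the documentation because the two
conventions appear side by side in the source material.

## Thermal time and phases

The cardinal response uses base 0 °C, optimum 30 °C, ceiling 40 °C on the
daily mean: TT equals the mean temperature up to 30 °C. Above the optimum
the response declines *linearly* to zero at the ceiling — the simplest
shape consistent with a stated ceiling; winter sowings never exercise it
(means stay far below 30 °C), so nothing downstream depends on that choice.

Development is a chain of thermal-time targets over stages 1 sowing →
2 germination → 3 emergence → … → 6 flowering → … → 9 maturity.
Germination is triggered the first day the surface layer is wetter than
LL15 (a minimal moisture trigger; the sources are silent). The emergence
target is `lag + rate × sowing depth(mm)` with defaults 40 °Cd and
1.5 °Cd/mm — ordinary crop-model magnitudes for a 5 cm sowing. The
end-juvenile → floral-initiation target is interpolated piecewise-linearly
against daylength and held flat beyond the end knots; the day's surplus
thermal time rolls into the next phase, so several stages can pass in one
(hot) day. Days to flowering is `flowering date − sowing date` in whole
days, flowering being the day its stage is entered.

Two chickpea parameterisations ship for PBA HatTrick/PBA Boundary and
Tyson: the *original* (446 → 0 °Cd over 10.7 → 17 h, emergence→end-juvenile
515 °Cd; Tyson 468.3 °Cd from 10.1 h) and the *soilwater* re-parameterisation
used with the modification (upper knot 12 h, 660 °Cd; Tyson 690 °Cd). The
table the values come from prints compacted arrays; the two-element
photoperiod axes were read as knot pairs matching the two-element target
arrays.

## Water balance

The source analysis delegates soil water to a full cropping-systems
simulator. Here a minimal cascading bucket reproduces the same *observable
contract* — a daily FASW trajectory — with the standard process set, in
this daily order:

1. infiltration of rain + irrigation into layer 1 (runoff off by default;
   a fractional hook exists),
2. instantaneous cascade of water above saturation,
3. gravitational drainage `swcon × (sw − dul)` per layer, cascading
   downward (below the profile: deep drainage),
4. Ritchie two-stage soil evaporation from layer 1 (stage 1 to `U = 6` mm
   since last rewetting, then `cona × (√t − √(t−1))` with
   `cona = 3.5 mm/√day`), floored at air-dry,
5. root uptake `kl × (sw − ll15) × thickness` per rooted layer, scaled so
   the day's total never exceeds the transpiration demand.

All fluxes are clipped to physical bounds, and the per-day flux ledger
closes the mass balance to < 10⁻⁶ mm (enforced by a 1000-day property
test). Transpiration demand is `kc(stage) × ET0` with ET0 from the
temperature-only Hargreaves formula, avoiding radiation inputs; potential
soil evaporation is `0.6 × ET0`. The root front grows at 0.7 mm per °Cd of
unadjusted TT from the sowing depth, capped at the profile bottom. These
are standard magnitudes, exposed as arguments, and the acceptance surface
is the invariants and the qualitative FASW dynamics — not bit-equality with
any external simulator. FASW is returned *unclamped* (it exceeds 1 between
DUL and saturation) so traces can show supersaturation; the clamp lives in
the modification.

Starting water is a fraction of PAWC, allocated either uniformly
(`ll15 + f·(dul − ll15)` per layer) or fill-from-top. The national
water-balance product used for initialisation in the field study does not
define a per-layer mapping, so both modes are provided instead of asserting
one; the state is initialised with a dry surface (stage-2 evaporation),
which the first rewetting resets.

## Wheat

The sources name photoperiod and vernalisation sensitivity factors but
never print their equations, so the package adopts the APSIM-Wheat
conventions and documents them as adopted, not source-specified:
$f_p = 1 - 0.002\,R_p\,(20 - pp)^2$ and
$f_v = 1 - 0.0054545\,R_v\,(50 - V)$, both clamped to $[0,1]$, with vernal
days $V$ accruing on cool days, devernalising on hot days while $V < 10$,
and the factors combined as $\min(f_p, f_v)$ (the APSIM combination;
"multiplying … with the factors" in the prose is ambiguous and the product
variant would only be more severe). The factors apply from emergence to
floral initiation; afterwards plain TT accrues, with the FASW modification
on top in the `reduced_sw` preset. Four presets mirror the published
comparison: original (Rp 3.2, Rv 2.7, 555 °Cd to initiation), gene-based
(2.6, 0.9, 715 °Cd), reduced (2.6, 1.98, 555 °Cd), and reduced + soil
water. Air temperature stands in for the temperature of the underground
apex — a known simplification, discussed but unspecified in the sources.
The post-initiation target (650 °Cd) is an ordinary magnitude chosen once;
only differences between presets matter to every comparison made here.

## Frost and yield

A post-flowering frost event is a day with Tmin ≤ 0 °C strictly after
flowering and within the assessment window (default: to simulated
maturity). One source sentence prints the inequality inverted (≥ 0 °C);
it is treated as a typographical slip because the surrounding text, the
abstract and the results all define frost as ≤ 0 °C. Consecutive frost
days count individually (no event merging is defined anywhere). The yield
penalty is 5 % of potential per event, with the loss capped at 100 %
(beyond 20 events the uncapped equations would go negative).

## Agreement statistics

NRMSE is RMSE(observed − predicted)/mean(observed); the source's wording
mixes "fitted" and "simulated", and this is the only reading under which
the statistic is a prediction-error measure. Lin's CCC uses population
(divide-by-n) moments per Lin's original definition, with a sample-moment
variant behind a flag; a brute-force moment-form recomputation agrees to
10⁻¹². McBride categories are applied with 0.90/0.95/0.99 as printed, the
boundary values falling to the lower class.

## The synthetic world

Real validation of the field results needs proprietary station weather and
soil characterisations, so the test world is synthetic and *stated once*:

* **Weather**: seasonal sinusoid (mean 17 °C, amplitude 8 °C, warmest
  mid-January, diurnal range 14 °C, Gaussian noise sd 2.5 °C) and
  Markov-chain rainfall (stationary wet-day probability 0.25, persistence
  0.45, gamma amounts with mean 8 mm). This emulates an inland southern
  Queensland winter-cropping climate: winter minima that can dip below
  zero (frosts occur) and modest, clustered rain. It does **not** emulate
  synoptic rain systems, heat waves, or inter-annual drivers, so a green
  cohort test establishes internal consistency and directional behaviour,
  not field skill.
* **Soils**: four profiles with PAWC exactly 109/136/244/257 mm in
  plausible Ferrosol/Vertisol layer shapes; layer values are constructed,
  not measured (they are labelled fixtures, and nothing asserts them
  against any database).
* **Cohorts**: 23.4–28.5 °S, April–June sowings, starting water 10–40 % of
  PAWC, per-scenario wet-day probability 0.12–0.45 and wet-day mean
  5–12 mm so dry and wet site-seasons both occur; observed flowering =
  model truth (modification on, constant 1.65) + integer noise (sd 1.5 d).

Because the truth generator *is* the with-modification model, the
with/without comparison must favour the modification — that is the
designed acceptance surface (parameter recovery and direction of
improvement), not evidence about nature.

## Numerical choices and degenerate inputs

* Daylength uses a cosine declination and the hour angle at a configurable
  sun altitude, default −2.2° (twilight-extended, the crop-model
  photoperiod convention); the sources never state the convention, hence a
  parameter rather than a constant. Polar-night/day cases clamp to 0/24 h.
* One known spec-level symmetry statement (mirror latitude *and* shift half
  a year) double-flips and is not a complement; the tested symmetry is
  daylength(φ,d) + daylength(−φ,d) = 24 h.
* The FASW > 0.65 persistence contrast between high- and low-PAWC profiles
  is asserted under dry-down forcing: under pulsed rain a small store
  re-crosses the gate on every pulse, which is the same mechanism, seen
  from the other side.
* Weather series with date gaps are rejected, never gap-filled; a row with
  Tmin > Tmax is an error naming the row.
* A simulation that runs out of weather before flowering returns
  `did_flower = FALSE` with `NA` day counts, not an error; cohort runs
  record per-scenario failures as `NA` rows.
* All randomness is seed-driven; cohort scenario *i* uses sub-seed
  `seed·1000 + i`, keeping derived seeds well inside 32-bit range for the
  seeds used in tests and scripts.

## Limitations

No biomass, leaf area, nitrogen or yield formation (yield enters only as
the frost module's potential-yield input); no chickpea vernalisation; no
wheat grain phases; no solute transport, unsaturated upward flow, soil
temperature or curve-number runoff calibration; no weather-service or
soil-database clients. The modification itself is an empirical,
manually-calibrated rule — the package makes it reproducible and testable,
it does not explain its physiology.
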
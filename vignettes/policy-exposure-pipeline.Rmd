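---
title: "From decarbonization scenarios to county PM2.5 exposure, disparity, and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From decarbonization scenarios to county PM2.5 exposure, disparity, and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqequity)
library(dplyr)
```

## What the pipeline computes

`aqequity` chains five stages, each exposed as ordinary functions over data
frames so any stage can be run, inspected, or replaced in isolation:

1. **Scenario generation** — stylized regional NOx, SO2 and primary PM2.5
   emission trajectories for six policies (current policy, clean electricity
   standard, carbon tax, ICE vehicle ban, ICE ban + CES, linear net-zero),
   standing in for a full energy-system optimization.
2. **Downscaling** — regional totals to counties: constant 2020 unit
   generation shares within power-plant clusters plus a grow-in-place
   heuristic for new capacity; vehicle-miles-traveled (VMT) spatial
   surrogates for on-road emissions. Both paths conserve mass to machine
   precision.
3. **Air quality** — a reduced-complexity atmospheric model: sector-averaged
   annual Gaussian plume kernels by effective release height, simplified
   ammonium--nitrate--sulfate partitioning against a fixed baseline
   inventory, and the add-one-ton marginal-concentration algorithm that
   yields source-receptor matrices. Total concentrations are emissions times
   marginal concentrations, which preserves source-sector attribution.
4. **Exposure equity** — population-weighted exposure per race-ethnicity
   group, the disparity statistic (group mean minus total-population mean),
   and population-weighted exposure quantiles.
5. **Health** — a log-linear concentration-response function applied to
   adults 30+, under three estimate variants; cumulative and avoided deaths
   against the current-policy baseline and per-capita rates.

## The atmospheric model and its assumptions

Receptors are population-weighted county centroids; sources discharge from
the same points. The ground-level sector-averaged annual concentration from a
source of strength $Q$ (short tons/yr, converted to g/s) at downwind
distance $x$ is

$$
C(x) = \min\!\left(
\frac{2\,Q\,f_s}{\sqrt{2\pi}\,\sigma_z(x)\,u\,\tfrac{2\pi x}{16}}
  \exp\!\left(-\frac{H^2}{2\sigma_z(x)^2}\right),\;
\frac{Q\,f_s}{\tfrac{2\pi x}{16}\,z_{mix}\,u}
\right),
$$

with a 16-sector wind rose (default uniform, $f_s = 1/16$), transport speed
$u = 4$ m/s, mixing height $z_{mix} = 1000$ m, and a Briggs-style rural
neutral-stability closure $\sigma_z(x) = a x/(1+bx)^c$ with
$a = 0.06$, $b = 0.0015$, $c = 0.5$. The second limb is a well-mixed
boundary-layer box: it bounds the kernel so annual-average concentrations
never exceed the fully mixed value, which also keeps every kernel finite and
monotonically decreasing in distance for ground sources. Release heights are
binned: ground (transport), and low / medium / tall point-source bins at
125 / 375 / 750 m effective height; power-plant units default to the medium
(250--500 m) bin, where the bulk of power-sector emissions are discharged.

Two numerical choices matter here. First, the self-receptor singularity:
distances below $0.5\sqrt{\text{area}/\pi}$ (half the equal-area circle
radius of the source county) are clamped to that floor, a county-scale
analogue of not evaluating a plume at its own stack. Second, all
meteorological parameters live in `met_config()`, including a multiplicative
calibration scalar (default 1) standing in for monitor calibration, which is
out of scope.

### Chemistry

Secondary inorganic PM forms at the receptor from the dispersed precursor
mass: a fixed fraction of dispersed SO2 (default 0.2) arrives as sulfate and
of NOx (default 0.15) as nitric-acid demand. Sulfate always forms particle
mass — ammonium sulfate (132 g/mol per mol sulfate) when the county ammonia
budget covers 2 mol per mol sulfate, sulfuric acid (98 g/mol) otherwise;
ammonia left over after sulfate limits ammonium nitrate
($\min(\text{demand}, \text{free NH}_3) \times 80$ g/mol). The default
ammonia budget (3 µmol/m³ everywhere) is deliberately generous: typical
baseline sulfate in the synthetic runs is two orders of magnitude below it,
so marginal concentrations sit in the linear, ammonia-rich regime and the
linearized source-receptor totals stay within a few percent of a direct
two-field recomputation. Marginal entries are floored at zero: at a strongly
ammonia-limited receptor an added ton of SO2 can displace nitrate and lower
total PM, and the source-receptor representation used here does not carry
negative marginals.

The marginal algorithm itself mirrors reduced-complexity integrated
assessment practice: compute the full speciated field from the fixed
baseline inventory, add one ton for a source-pollutant-height triple,
recompute, difference, reset. Primary PM2.5 is linear, so its marginal is
the plume kernel row for any baseline; the SO2 and NOx marginals embed the
baseline's ammonia regime.

## The concentration-response function

Deaths are computed as
$\Delta\text{Mort} = y_0 \cdot \text{Pop} \cdot (1 - e^{-\beta\,\Delta PM})$
per county, race-ethnicity group and age band (30+ only), with
$\beta = \ln(RR)/10$ for a relative risk quoted per 10 µg/m³. The form is
isolated in `delta_mortality()` so the alternative convention
($y_0\,\text{Pop}\,(e^{\beta \Delta PM}-1)$) is a one-line swap; at the
concentration changes this pipeline produces the two agree to well under a
percent. Three variants are computed: (A) constant relative risk with
all-person (race-collapsed) baseline mortality; (B) constant relative risk
with race- and age-specific mortality; (C) race-specific relative risk with
race- and age-specific mortality. The defaults — constant RR 1.06 per
10 µg/m³ and a Black non-Hispanic $\beta$ multiplier of 3 in variant C — are
configuration placeholders shaped like the cohort literature (Krewski-style
constant risk, Di-style race-specific risk), not estimates of it. Cumulative
deaths weight each five-year period's annual result by five calendar years,
with 2050 counted once, closing the 2020--2050 horizon at exactly 31 years.

The avoided-deaths range reported for each policy is the minimum and maximum
across the three variants; whether published ranges of this kind are
variant ranges or a different uncertainty construct is generally unstated,
so the min--max construction is labelled as an assumption.

## What the synthetic generators emulate — and what they do not

The generators reproduce the *structural* properties the analysis depends
on, not any real place:

* **Geography** — a planar square domain (default 1000 km) tiled into nine
  contiguous regions of equal-area counties. Only inter-centroid distances
  enter the physics, so planar km geometry removes projection ambiguity.
* **Population** — heavy-tailed county sizes (log-normal, a few dense
  counties); national race-ethnicity shares anchored at 2020 and 2050
  (White non-Hispanic 60% → 48%, Hispanic 18% → 25%, Black non-Hispanic
  13% → 14%, Other the remainder, 9% → 13%) with linear share interpolation
  between anchors, since only the endpoints are specified; +20% total growth
  by 2050; and a fixed age pyramid per group in which White non-Hispanics
  skew oldest — the feature that makes age-specific mortality rates matter.
  The published share figures for the named groups sum with the residual
  "Other" group to one only approximately; this package keeps the named
  groups at their stated values and assigns the exact remainder to Other.
  Sex is not modelled: only race and age are demographically active in the
  concentration-response function.
* **Power fleet** — clusters of units confined to one region each, 2020
  generation log-normal around a typical capacity factor, planned and
  retired-site records in every region as grow-in-place candidates.
* **VMT surrogate** — county VMT proportional to population times a seeded
  urban/rural multiplier for surrogate years 2023/2026/2032; the 2035--2050
  national scaling factors follow gentle deterministic growth (~0.8%/yr from
  2032) with small noise, the shape national VMT projections take, rather
  than i.i.d. draws that would produce physically implausible double-digit
  VMT swings between adjacent periods.

Consequently, passing tests demonstrate the *internal* correctness of the
coupled method — conservation, zero-sum disparity, linearity and
monotonicity properties, cohort accounting — under realistic magnitudes.
They do not validate the model against observed concentrations, real
inventories, or any published real-data result.

## Scenario responses

Power-sector fossil emissions scale the 2020 fleet by a scenario factor:
a 3%/yr decline under current policy (existing incentives and retirements);
one minus the clean-electricity fraction under the CES (80% clean in 2030,
linear to 100% in 2050, effective 2030); $\max(0.15, e^{-0.03\,\tau(t)})$
under a carbon tax rising linearly from \$50/t CO2 in 2025 to \$80/t in 2050
— the floor makes late-horizon concentrations plateau, reflecting a tax too
low to force the last emissions out; and the linear cap under net-zero.
Scenario start years follow the policy designs: CES and ICE ban bind from
2030, the carbon tax from 2025, which is what drives the timing differences
in avoided deaths.

On-road emissions are regional ICE vehicle-miles (surrogate totals times the
surviving ICE stock share from a five-year cohort turnover model — existing
vehicles are never scrapped by a sales mandate) times fleet-average emission
factors. Two multiplicative effects apply on top: a secular 2%/yr
emission-factor improvement representing tightening vehicle standards — the
mechanism by which real-world on-road emissions decline despite growing
VMT — and, for the carbon tax and net-zero scenarios, a demand response.
ICE-ban scenarios add an electrified-transport demand increment served by
new gas capacity in proportion to the scenario's remaining fossil share;
sited by the grow-in-place heuristic, this is the channel through which a
vehicle ban *raises* power-sector emissions absent a clean electricity
standard.

The stylized responses are deliberately not calibrated to any optimization
model: sub-period dynamics of a least-cost dispatch are not recoverable from
scenario descriptions alone, so the package makes the qualitative mechanisms
(timing, scope, interaction) explicit and configurable instead.

## Other design decisions

* **Disparity is a national statistic**: each person experiences their
  county's concentration, and a group's disparity is its national
  population-weighted mean minus the total-population mean. Weighted by
  group populations, disparities sum to zero identically — a useful
  validity check the test suite enforces at 1e-9. Period-specific
  populations are used (rather than frozen 2020 weights); the choice is
  visible in the code and easy to flip.
* **Weighted quantiles** default to the inclusive step-CDF convention (the
  smallest value whose cumulative normalized weight reaches the target),
  which matches a direct enumeration of the weighted CDF; an interpolating
  midpoint convention is available via `type = "midpoint"`.
* **Grow-in-place tiers** are capped: planned sites absorb new capacity up
  to their recorded capacity, overflow goes to retired sites likewise
  capped, and any remainder is spread over existing same-fuel capacity
  uncapped. Allocation is exact by construction.
* **Zero-generation clusters** receive uniform unit shares, preserving mass
  conservation where proportional shares are undefined.
* **Non-exhaust particulates** (brake and tire wear) are excluded: only
  combustion emissions are modelled, so primary PM2.5 from transport is
  understated by construction.

## Problem sizes and runtime

The default configuration — 9 regions × 6 counties, 10 million people,
18 clusters × 3 units, 8.6 million vehicles — was chosen so that a full
six-scenario run (including building the 54 × 54 source-receptor set for
three pollutants and two height bins) completes in about ten seconds, which
keeps the whole property-test suite interactive. Every structural property
the pipeline guarantees (conservation, zero-sum, linearity, determinism) is
scale-invariant, so nothing about the checks depends on this size; the
configuration scales to hundreds of counties if needed.

## Known limitations

* County is the finest spatial unit; near-source disparities within
  counties are invisible by construction.
* A single annual wind rose and one stability class; no seasonality,
  terrain, or photochemistry (no ozone, VOCs, or ammonia emissions).
* The chemistry is a two-regime partitioning, not a thermodynamic
  equilibrium model, and negative marginals from sulfate--nitrate
  displacement are floored at zero.
* Relative risks and baseline mortality rates are synthetic placeholders;
  absolute death counts are meaningful only relative to each other across
  scenarios within a run.
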
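---
title: "Methods: emergy ES accounting and driver attribution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emergy ES accounting and driver attribution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emergyes)
```

## The accounting model and its assumptions

`emergyes` values ecosystem services (ES) from the donor side: a service
is worth the cumulative available energy the biosphere invested to
produce it, expressed in solar equivalent joules per year (sej/yr). The
unit of analysis is one record — a spatial unit × ecosystem class ×
epoch — carrying physical drivers (area, NDVI, precipitation,
evapotranspiration, elevation, NPP, carbon pool and turnover, soil
profile, renewable emergy flows, dams for rivers).

Three structural assumptions shape the accounting:

1. **Vegetation-fraction correction.** Mapped class areas overstate the
   effective vegetated surface, so `S′ = S · VF` with
   `VF = (NDVI − NDVI_min)/(NDVI_max − NDVI_min)`. The support
   (min/max) is computed per ecosystem class over the whole analysis
   extent within one epoch; `compute_corrected_areas()` can instead use
   per-region supports (`ndvi_support = "region"`). Open-water classes
   (lake, reservoir/pond, river) default to `VF = 1`, since the
   correction targets vegetated surfaces; this is configurable
   (`water_vf = "ndvi"`). VF outside [0, 1] (anomalous NDVI) is clipped
   with a warning so the contract `S′ ≤ S` always holds.
2. **The renewable MAX rule.** Photosynthesis is driven by whichever
   renewable input is largest, not by their sum, so the NPP service of a
   record is `MAX(R)` over six candidates: grouped
   solar + tidal + geothermal, wave, wind, rain chemical potential,
   runoff geopotential, runoff chemical potential. Ties break by that
   fixed listing order. The winner's underlying physical factor
   (insolation, wind, precipitation, elevation) is persisted because
   attribution dispatch needs it. Wave energy is mapped to the wind
   factor (wind-driven waves); the grouped term to insolation.
3. **Double-counting-safe totals.** NPP, carbon sequestration, soil (or
   sediment) building, groundwater recharge and microclimate regulation
   all trace back to the same renewable input, so only the largest of
   the five enters a total; purification, retention and climate
   regulation are additive. Rivers have special cases: materials
   transport is never added (its driver, runoff geopotential, already
   backs the NPP service), and hydropower is additive except when runoff
   geopotential is the winning renewable flow and the dam sits strictly
   inside the reach, where the total takes `max(max5, HG)`. A dam at the
   reach end (X = 1) zeroes the five-group term through the printed
   `(1 − X)` factor; this is implemented exactly as stated even though
   its physical reading is not obvious. A river without dams uses the
   additive form with `HG = 0`.

Applicability is enforced, not zero-filled: terrestrial classes carry
{NPP, CS, SB, GR, AP, SR, MR, CR}, non-river aquatic classes {NPP, CS,
SBa, GR, AP, WP, MR, CR}, rivers add {MT, HG}. A service a class does not
provide is absent (`NA`) in the ledger, never 0. A eutrophic water body
loses its sediment-building service entirely (excluded from the max
group), with the reason recorded.

## Parameters

All parameters are user-supplied through a single JSON document
(`load_params()` / `save_params()`); the packaged `demo_params()` set is
explicitly non-authoritative, with magnitudes chosen so services land in
the 1e18–1e23 sej/yr range typical of national tables. Internal units
are SI (m², m/yr, sej/yr); every unit bridge (ha↔m², kg→g, t→g, m³→cm³,
m²→cm²) is a named constant applied in exactly one place, never an
inline literal, so dimensional choices are auditable.

Constants the method itself fixes — and the only ones defaulted when a
file omits them — are: runoff rate 0.25, mineral mass fraction 0.95,
mineral turnover 1000 yr, aquatic deposition absorption 0.78,
deposition/NPP ratio 0.3037, water density 1000 kg/m³, gravity 9.8 m/s²,
kcal→J 4186, and the declared unit bridges. Everything else (UEVs,
DALY/PDF factors, uptake/removal/sequestration capacities, litter and
detritus fractions, g→kcal factors) must be present; a missing key or a
non-positive UEV is a hard error naming the key.

Two dimensional chains are deliberately exposed rather than guessed:

* the water-purification product mg/kg × gC/m²/yr is bridged by
  `wp_bridge` (default 1);
* the dam rain term nominally yields kg while the rain UEV is tabulated
  per gram; `hg_mass_conv` (default 1, i.e. the demo UEV_r is read per
  kg) declares the conversion.

Distinct keys are kept for the soil-mineral UEVs and the mountain UEV
despite their shared symbol in the literature: different physical
referents.

## The attribution method

For each (unit, class), the change in total ES between a baseline and an
end epoch is decomposed with first-order partial differentials. The
class total is modelled as

T = (1 + k2)·X·S + (k1 + k4)·S·τ + k3·S

with X the per-area intensity of the winning max-group service (the
natural driver), S the corrected area (human driver), τ the emergy of
per-capita health expenditure (cognition driver), and constants
k1 + k4 (human-health DALY terms), k2 (ecosystem-quality PDF terms), k3
(soil retention per area). One printed form of this model omits the area
factor on k3; it is implemented as `k3·S`, consistent with the adjacent
forms and with the stated partial ∂T/∂S.

Design choices a maintainer should know:

* **Constants are estimated from the baseline ledger**
  (`a = HH/(S·τ)`, `b = EQ/R`, `c = SR/S`), so the model reproduces the
  baseline total exactly. At the end epoch the model can diverge from
  the ledger total (the EQ terms physically follow `MAX(R)` while the
  model ties them to the winning service); the divergence is reported in
  a `d_total_ledger` column, never hidden, and rates are computed
  against the model change.
* **Partials are evaluated at the baseline state.** The elasticity form
  and the partial-derivative form are algebraically identical; the
  partial form is always used for contributions, and elasticities are
  reported as `NA` when a baseline denominator is zero.
* **The residual is exact by definition**:
  `δ = ΔT − (Cr_R + Cr_τ + Cr_S)` with T evaluated at both states, so
  contributions + δ = ΔT bit-consistently, and for this bilinear model δ
  equals the analytic interaction remainder
  `(1+k2)·ΔX·ΔS + (k1+k4)·Δτ·ΔS` (property-tested at 1e-10 relative
  tolerance over 1,000 random instances).
* **Rate closure.** The residual rate is defined as
  `1 − (R_R + R_τ + R_S)`, so rates always close to 1; rates may lie far
  outside [0, 1] (a driver can contribute more than the net change). A
  zero ΔT yields flagged undefined rates, never silent zeros.
* **Winner switches.** If the max-group winner differs between epochs,
  the baseline winner defines the model and the switch's effect lands in
  δ, with a logged diagnostic.
* **The human driver is the corrected area S′** — it is the area that
  enters every service formula — so a vegetation-fraction change counts
  as a human/land-use effect, not a natural one.
* **Natural-factor dispatch**: MR → evapotranspiration,
  GR → precipitation, CS → NPP (biomass carbon density as recorded
  sub-factor), NPP/SB/SBa → the winning renewable flow's factor,
  HG → elevation.

Aggregation sums contributions over classes (equivalently: class changes
weighted by class rates), then units, precipitation zones and the
extent. The regional report emits, per zone: driver contributions, their
subtotal, the zone's share of the extent change, the subtotal per unit
of total zone area and per unit of zone ecosystem area (the two
published per-area columns are described inconsistently in the source
material, so both are emitted under distinct names), and integer-percent
rates rounded half away from zero (R's default half-to-even rounding
does not reproduce printed report tables). Natural-factor share tables
normalise the absolute natural contributions per unit to 100%; this is a
declared reconstruction of how such tables are assembled, since no exact
recipe is published.

## The synthetic generator

`generate_fixture()` emulates the statistical structure of the inputs —
nine classes per unit, two epochs, zone-dependent precipitation,
multiplicative driver deltas — and nothing else: no raster geometry, no
spatial autocorrelation, no realistic land-use transition structure.
Renewable flows are derived from the physical drivers (rain chemical
from precipitation, runoff geopotential from precipitation × elevation,
and so on) and scale with area, so every service is homogeneous of
degree 1 in area and a pure-area plan is recovered exactly as a
human-driver change. Jitter is multiplicative log-normal, drawn once at
baseline and reused at the end epoch, so planned deltas are exactly
recoverable at any jitter level. Dam catchments scale with the river
record's area for the same homogeneity reason. Consequently a green
synthetic-recovery test establishes the algebra of the decomposition,
not the realism of any particular parameter magnitude; the demo UEV and
impact-factor values are placeholders.

## Numerical choices and degenerate inputs

* Iteration over pollutants, metals, gases and minerals is in
  lexicographic order, so sums are bit-reproducible.
* CSV writers serialize doubles with 17 significant digits; JSON
  parameters likewise. Read(write(x)) reproduces every value exactly.
* A record whose corrected area is zero (NDVI at the class minimum)
  contributes zero to every area-proportional service; its
  carbon-sequestration UEV is undefined and reported as `NA` with a zero
  service value. NPP = 0 with a nonzero carbon pool is a hard error.
* Multiple dams on one river record: the dam position is the
  emergy-weighted mean of per-dam positions (strict mode errors
  instead), since the total formulas treat X as a single scalar per
  reach.
* Degenerate NDVI support (a single record, or constant NDVI in a
  class) falls back to VF = 1 rather than dividing by zero; the scalar
  `vegetation_fraction()` primitive errors instead, as its contract
  requires a proper support.
* Missing pollutant/metal/gas entries are zero uptake with a warning,
  matching data-availability-driven pollutant subsets in practice.

## Known limitations

* The model ties ecosystem-quality (PDF) terms to the winning max-group
  service; when the winner is not the NPP service this is an
  approximation inherited from the method, and its error is visible in
  the reported model/ledger divergence.
* Physical renewable flows are inputs (or synthetic derivations), not
  computed from meteorological first principles.
* Agricultural land is out of scope, as are monetary valuation, raster
  ingestion, statistical inference on drivers and NPP water-limit
  thresholds.
* The shipped parameter numbers support testing and demonstration only.
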
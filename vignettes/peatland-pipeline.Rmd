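---
title: "Modelling blanket-bog development and reconstructing its water table"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling blanket-bog development and reconstructing its water table}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

peatsim couples two ways of looking at the same peatland: a process model
that predicts annual water-table depth (WTD) and carbon fluxes from
climate, and a palaeoecological route that reconstructs past WTD from
subfossil testate-amoeba (TA) assemblages dated with spheroidal
carbonaceous particles (SCPs). The comparison module pairs the two
series, fits a regression-based offset correction, and contrasts managed
against unmanaged simulations. This vignette records the model structure,
the tunable parameters and the design decisions taken where the design
was genuinely open.

## The cohort simulator

Each simulated year deposits one litter cohort whose carbon is split over
four litter-quality pools (fast, mid, slow, humic). A cohort's dry mass
and an age-dependent bulk density give its thickness, so the column
compacts as it ages:

* `bd(age) = bd_surface + (bd_deep - bd_surface) (1 - exp(-age/bd_efold))`,
  defaults 0.04 to 0.14 g cm^-3 with a 100-year e-folding, spanning the
  range typical of fresh Sphagnum litter through consolidated catotelm
  peat.

### Water table

Storage is defined by the air-filled pore-space law
`phi(d) = min(1, 0.2 exp(1.6 d^2))`, `d` the distance above the water
table *in metres*. The exponent only traverses the (0.2, 1) interval for
distances of order a metre; any other unit makes the curve degenerate
within centimetres, which fixes the unit choice. Integrating `phi` from
the surface to the water table gives the storage deficit `D(w)` (cm of
water); the annual bucket balance is run on `D`:

1. actual evapotranspiration = potential evapotranspiration (PET),
   limited by available water;
2. bedrock drainage = `hc` x saturated-thickness fraction (`hc` default
   0.1 cm/yr, unweathered clay). The specific yield `sy` (default 0.02,
   clay) is retained as a floor on the storage coefficient used to
   translate water losses into water-table movement; the default
   pore-space law exceeds it everywhere, so with defaults it is inactive;
3. water in excess of a field-capacity threshold (default: the surface)
   is shed as runoff within the year — high water tables produce high
   runoff — and standing water is capped at -10 cm, anything wetter also
   becoming runoff. Reconstructions and the model alike are insensitive
   to water tables above the surface, so the cap loses nothing of
   interest.

The ledger `P - AET - runoff - drainage = D(start) - D(end)` closes
exactly every year and is asserted to 1e-6 (relative) in the tests.

The *reported annual-mean* WTD adds a within-year dry-season drawdown,
`max(0, beta PET - rho P)` cm of water pushed through the same storage
function. The drawdown refills from the winter surplus, so it does not
enter the annual ledger. `beta` (dry-season share of annual atmospheric
demand drawn from storage, default 0.10) and `rho` (dry-season share of
annual precipitation recharging the water table, default 0.017) are the
two calibrated hydrological constants: they were set, once, so that an
unmanaged run under the default climate reproduces the observed
blanket-bog regime of mean annual WTD about 4.4 cm with interannual
standard deviation about 1.8 cm. Monotonicity is built in: more rain can
never deepen the annual-mean water table, more evaporative demand can
never shallow it.

### Production and vegetation

PET uses the cubic annual evaporative-demand form
`PET(T) = max(0, 300 + 25 T + 0.05 T^3)` mm/yr, monotone in temperature
and vanishing below about -10.7 degC. Production follows the saturating
evapotranspiration-productivity curve
`NPP = 0.475 x 3000 (1 - exp(-0.0009695 (PET - 20)))` g C m^-2 yr^-1
(0.475 g C per g dry matter). The literature this family comes from
prints no constants for blanket bog specifically; the set above is the
package's documented choice and gives ~470 g C m^-2 yr^-1 at 5.1 degC,
consistent with the flux scale of UK blanket bog.

Vegetation is a mixture of seven plant functional types (shrub, sedge,
rush, grass, herb, Sphagnum, other moss) interpolated from a fixed
lookup over the *five-year mean* WTD, padded by repetition at the start
of a run. The five-year average deliberately makes the community
resilient: one anomalous dry year among wet years barely moves it. The
lookup is monotone — Sphagnum+sedge share never increases, and shrub
share never decreases, as the five-year mean deepens. PFTs control
litter-quality allocation and the plant-mediated methane route; total
NPP is treated as community-independent, since bog communities converge
in annual production far more than in litter quality.

### Decomposition and methane

Pools decay by the *discrete annual* fraction `min(1, k fT)` above the
water table and `anoxic_ratio` times that below, with
`fT = q10^((T - tref)/10)` (q10 = 2, tref = 10 degC). Discrete annual
rates rather than within-year exponential integration are a deliberate
choice: they make the anoxic:oxic first-year loss ratio exactly the
anoxic ratio (0.035; literature range 0.025-0.0625 accepted as
overrides), where exponential forms would distort the ratio for fast
pools. A cohort straddling the water table splits by thickness fraction.
Charcoal is inert and never decays.

Default aerobic rate constants are `k = (0.6, 0.25, 0.06, 0.004)` /yr
for the fast, mid, slow and humic pools. They were chosen, together
with the litter-allocation matrix, so that the acrotelm processes most
labile litter while decomposable material still persists through the
5-15 cm horizon — the zone drainage exposes — and so that a
multi-millennial run settles into a realistic regime (soil CO2 efflux a
few hundred g C m^-2 yr^-1, net CH4 around ten, a slowly positive soil
carbon budget and metres of peat after nine millennia).

Anoxic carbon loss is partitioned into CH4 (`ch4_fraction_anoxic`,
default 0.10) and CO2. Anaerobic mineralization in peat is strongly
CO2-dominated in field observations, which is why the default sits well
below one half; it is a single configurable constant. Produced CH4
escapes by plant-mediated transport (proportional to sedge+rush cover)
and ebullition (default 0.10), both bypassing oxidation, while the
diffusive remainder is oxidized first-order over its transit of the oxic
zone, `exp(-0.05 max(wtd, 0))`. The published oxidation constant "0.05 g
C g^-1 year^-1" leaves its mass basis ambiguous (per g CH4-C? per g dry
peat?); this package interprets it as a first-order removal rate per cm
of oxic peat transited per year, which preserves the intended
behaviour — no oxidation under standing water, progressively stronger
removal as the water table deepens — and keeps the constant where a user
can change it (`decomp_params(ch4_oxidation_rate=)`).

### Long runs

Cohorts buried deeper than any plausible water table decay with
identical fractional rates, so pooling them is exact for carbon; the
simulator merges cohorts older than 250 years into 25-year blocks,
which coarsens only the depth discretization of old peat (the
bulk-density age uses the mass-weighted mean birth year). A 9,000-year
run therefore carries a few hundred active cohorts and completes in
seconds; the carbon ledger
`delta stock = litter - CO2 - CH4 - erosion` closes to numerical
precision throughout. Erosion is a stub (default 0) retained for budget
bookkeeping.

## Management scenarios

The grouse-moor schedule encodes a dated intervention history on a
northern-England shooting estate: burns every 20 years from 1851 to
1950; burn-year NPP at 1% with sigmoidal recovery to 100% by 5 or 10
years; 5% of the burnt biomass carbon routed to the inert charcoal pool;
grips installed 1831, at optimum for 25 years, declining linearly to 60%
in the year before the 1871 renewal, at optimum again until 1905, then
linearly to zero by 1955; full-efficiency drainage lowers the water
table by 5 cm. Decisions taken where the record is silent:

* the recovery sigmoid is a logistic with midpoint at half the recovery
  span and scale span/8, rescaled so it is pinned *exactly* at the 1%
  floor in the burn year and exactly at 1 from the recovery year onward;
* the renewal is an instantaneous jump back to optimum;
* the 1905-1955 decline is linear;
* the decline segments are laid on integer years so the last pre-renewal
  year evaluates to exactly 0.60;
* the drainage offset is added to the water table after the hydrological
  balance and before decomposition reads it, so drainage alters fluxes
  exactly as a natural deepening of the same size would;
* burning is applied to the whole modelled patch, reading the 20-year
  rotation as the patch's return interval;
* grazing is a no-op above 450 m elevation, and the default site sits at
  550 m.

`scenario_preset()` names the five standard contrasts (`no_shoot`,
`burn_drain_10`, `burn_drain_5`, `burn_only_10`, `burn_only_5`).

## The transfer function

`fit_wa_tol()` implements weighted averaging with tolerance
downweighting and inverse deshrinking. With proportions `y_ik`, observed
WTD `x_i`:

* optima `u_k = sum_i y_ik x_i / sum_i y_ik`;
* tolerances `t_k` = the matching weighted standard deviation, floored
  at 1% of the training WTD range so rare taxa cannot blow up the
  inverse-variance weights (the floor is standard practice; a taxon seen
  once has an undefined spread);
* initial estimates `x^_i = sum_k y_ik u_k / t_k^2 / sum_k y_ik / t_k^2`;
* inverse deshrinking regresses observed on initial estimates and
  reports predictions on that line. If the initial estimates are
  constant (one taxon everywhere) the deshrinking degenerates to
  recentring on the observed mean.

Proportions make every computation invariant to counts-versus-percent
scaling; raw estimates are convex combinations of optima and so stay
within their span. Negative (above-surface) WTDs pass through
untruncated. Sample-specific errors come from resampling training
samples with replacement (default 1,000 cycles), refitting, and
combining the spread of each fossil prediction with the mean squared
out-of-bag training error: `SE_i = sqrt(v_boot,i + s1^2)` — the cited
bootstrap approach, written out since the source gives no formulas.
`standardize_recon()` converts a reconstruction to z-scores (exact mean
0, sd 1) so models with different absolute optima can be compared.

## Chronology

`detect_scp_markers()` finds the three SCP features used as
age-equivalent markers (~1850 start, ~1950 rapid increase, ~1978 peak):
the start is the *boundary* — the deepest depth above which
concentrations exceed the detection threshold (default 0, i.e. any
presence); the rapid increase is the deeper endpoint of the steepest
rising segment between peak and start; the peak takes the shallowest
depth on ties. `build_age_model()` anchors a piecewise-linear age-depth
model at the core top (default 2011) and the three markers, and
extrapolates below the start at the deepest segment's accumulation rate.
Fractional years are kept; pairing rounds to the nearest calendar year.

## Proxy-model comparison

`pair_years()` matches each dated reconstruction sample to the model
year minimizing the age difference within +/-1 year; exact years are
preferred, a sample exactly between two available model years is paired
with their average (the tie rule had to be chosen; averaging discards
least), and unmatched samples are dropped with a count. `fit_offset()`
is ordinary least squares of model WTD on reconstructed WTD — that
orientation matches how the corrected proxy series is subsequently used
as a predictor of model-scale WTD — and `apply_offset()` maps the
reconstruction onto the model scale, after which refitting on the
training pairs returns slope 1, intercept 0 by the usual projection
property. Period summaries use sample (n-1) standard deviations; a
single-year period reports sd 0 with an explicit `sd_defined = FALSE`
flag.

## Synthetic data: what it does and does not emulate

`gen_climate()` draws independent normal interannual deviates around
stationary means (defaults 5.1 degC, 2,000 mm/yr with sds 0.6 degC and
200 mm — a Moor House-like upland climate), truncates precipitation at
zero, and offers a linear temperature trend and an optional AR(1) knob;
no persistence is the default because the annual instrumental series
this emulates shows only weak autocorrelation. `gen_training_set()` and
`gen_fossil_core()` draw multinomial counts (default 150 tests, a
typical TA count; totals are configurable since counting effort varies)
from Gaussian taxon responses — exactly the unimodal assumption
weighted averaging relies on. The packaged eight-taxon set spans optima
-2 to 35 cm with tolerances 4-10 cm, bracketing wet and dry indicator
taxa. `gen_scp_profile()` reproduces the *shape* features the chronology
needs (zero tail, slow ramp, steep concave rise, peak, surface decline)
and nothing of deposition physics.

Passing tests on these generators therefore show that the methods
recover what they assume: unimodal responses, multinomial noise,
stationary climate. They do not show robustness to taphonomic loss,
taxonomic inconsistency, non-Gaussian responses, secondary gradients or
climate regime shifts — all present in real data.

## Problem sizes and numerical choices

The test-suite study conditions: conservation is asserted on a
9,000-year run (the age of the emulated site's peat); scenario contrasts
run a 1,200-year spin-up to 1750 followed by 1751-2012 twins; the
transfer-function checks use 40 training samples, count 150, with
recovery cores of 30 samples; the rehearsal pipeline reconstructs 51
five-yearly samples with count 300 and a +15 cm imposed proxy bias. The
storage function and its inverse use a 16,384-point cached
interpolation of the closed form (imaginary-error-function integral);
ledgers are computed from the same cached values, so closure is exact by
construction and asserted to 1e-6. Root-finding in the exported
`wtd_from_deficit()` uses `uniroot` at 1e-10.

## Known limitations

Annual resolution only (a monthly driver hook would change the
within-year drawdown treatment); erosion is a stub; charcoal does not
feed back on hydrology or bulk density; no spatial burn mosaics or
below-450 m grazing; the reported CH4 pathway partition (plant
transport, ebullition, oxidation) is a minimal three-route scheme, and
net CH4 levels should be read as scenario contrasts rather than flux
predictions.
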
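---
title: "Gorgonian carbon budgets: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gorgonian carbon budgets: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gorgC)
```

## The model

Gorgonians (sea fans) are passive suspension feeders that remove carbon from
the water column by capturing zooplankton, micro- and nano-plankton and
detrital particulate organic matter, return part of it through respiration,
and immobilize part of it in long-lived skeletal and tissue structures.
`gorgC` quantifies both processes for surveyed populations:

* **C flux** (benthic-pelagic coupling): daily ingestion minus daily
  respiration, summed over colonies, integrated over the productive season.
* **C sink** (blue carbon): carbon invested annually in colony growth.

Every colony observation is a height (cm) at a depth (m). Heights are
converted through species-specific allometry:

$$L = a\,H^{b} \qquad \text{(total branch length, cm)}$$

and analogous laws for colony surface area. Length then scales linearly into
ash-free dry mass (AFDM, mg cm^-1^), polyp number (polyps cm^-1^) and carbon
content (mg C cm^-1^). Physiological rates attach to those currencies:

* zooplankton capture: µg C polyp^-1^ d^-1^ × polyps;
* seston feeding: µg C g AFDM^-1^ h^-1^ or d^-1^ × AFDM;
* autotrophic input (mixotrophic shallow *Eunicella singularis* only):
  µg C cm^-2^ d^-1^ × surface area;
* respiration: mg O~2~ g AFDM^-1^ h^-1^ × 24 × AFDM × 0.281 / 1000 → g C
  d^-1^, with 0.281 mg C per mg O~2~ the respiratory conversion;
* sink: annual height growth → length increment via the power law × C
  content per cm, or a published per-size-class annual C investment table,
  or an effective per-biomass rate (below).

Colonies are partitioned into shallow (≤ 35 m) and deep (> 35 m)
compartments per species — the depth at which Mediterranean precoralligenous
and shallow coralligenous assemblages give way to deep coralligenous ones —
and all quantities are summed per compartment, then per species.

## Key parameters

| parameter | units | default | why |
|---|---|---|---|
| `threshold_m` | m | 35 | assemblage shift with light penetration; 35.0 itself is shallow |
| `season_days` | d | 90 | spring is the only season with positive energy balance; the published seasonal/daily quotients cluster at 89.9–90.1 |
| `o2_to_c` | mg C / mg O~2~ | 0.281 | respiratory quotient conversion |
| unit area | m² | 1 | densities are colonies m^-2^; sampling-unit area is carried explicitly |
| size-class width | cm | 10 | convention of the population-structure literature; config-driven |

The shipped allometric constants are the published ones for the three
species (*Paramuricea clavata* H→L `1.06·H^1.69`, AFDM 18.35 mg cm^-1^;
*E. singularis* shallow `0.2869·H^1.9652`, area `0.0609·H^2.4655`, AFDM
5.69, polyps 31.1 cm^-1^; deep `0.4669·H^1.8432`, AFDM 4.43;
*Leptogorgia sarmentosa* `2.1167·H^1.3684`, AFDM 2.94). The *L. sarmentosa*
coefficient has been reported both as 2.1167 and 0.21167 in different
places; the default is the larger value, which keeps total branch length
above height for a ramified colony, and the config allows overriding —
both readings are noted in the source rather than silently resolved.

## Effective (calibrated) rates

The physiological rates behind the original survey come from a dozen
laboratory and in-situ studies and are not part of this package's inputs.
So that the pipeline is runnable end to end, `calibrated_parameters()`
back-solves **effective per-biomass rates** from the reported compartment
totals: daily ingestion / biomass and daily respiration / biomass
(mg C g AFDM^-1^ d^-1^, the respiration re-expressed as mg O~2~ via 0.281),
and an effective sink rate (mg C g AFDM^-1^ yr^-1^). By construction these
rates regenerate the reported compartment totals exactly when pushed back
through the budget chain against the same biomass (the closure property the
test suite asserts to ≤ 0.01 g C d^-1^). They are population-level effective
rates, not physiological measurements: the per-polyp and per-cm² channels
are folded into a single per-AFDM channel, which is why the calibrated
*E. singularis* shallow entry is not flagged mixotrophic even though the
species is. Users with access to the literature rates can supply them via
the YAML schema and the per-channel machinery (`zooplankton_rate`,
`autotrophic_rate`, `polyp_table`, `sink_mode = "length_increment"` or
`"per_size_class_table"`) is used instead.

The *P. clavata* polyps-per-size-class table is published only at its
endpoints (630 and 26 175 polyps per colony); the package ships those and
expects users to supply interior classes. The *E. singularis* growth rate
is defined as the mean of two published height-increment studies whose
values are likewise user-supplied.

## Numerical choices

* Power-law fitting is ordinary least squares on log-log pairs — standard
  for allometry, exactly recovers coefficients from noiseless data, and
  reports R² in log space with 95% confidence limits on $(a, b)$. Point
  estimates drive the budget; the intervals are reporting-only.
* Size classes and histogram bins are half-open `[lo, hi)`; boundary
  heights belong to the upper class (deterministic tie-break). Heights
  outside a table or edge range are clamped to the end classes with a
  warning, never rejected: the laws are applied across the whole observed
  size range.
* All intermediate arithmetic is full double precision; rounding to two
  decimals happens only in `format_budget()` at serialization. Published
  sums are only consistent under late rounding.
* Negative net flux (respiration exceeding ingestion, possible outside
  spring) is allowed and warned about, not rejected.
* In every aggregated row the identities `net = ingestion − respiration`
  and `seasonal = net × season_days` hold exactly, and species totals equal
  shallow + deep exactly.

## Density, patchiness and upscaling

Gorgonians are strongly patchy: the mean density over *all* sampling units
("total density") is far below the mean over occupied units ("density on
patch"). `density_summary()` reports both, with the number of units behind
each; a single occupied unit yields an undefined (NA) patch SD. Upscaling
to the full study area multiplies **total** density by the area (ha ×
10⁴ m²) of suitable benthic assemblage per species, then applies mean
per-colony compartment budgets (shallow assemblages take shallow means,
deep take deep). Per-hectare sink rates are invariant to uniform area
rescaling, and assemblage rows sum exactly to species totals.

The real per-assemblage suitable areas are not public; the shipped
`synthetic_habitat_areas.csv` is a clearly labelled synthetic stand-in used
to exercise the stage. The three published per-species per-ha sink rates
are treated as inputs when combining into the area-wide total
(`combined_sink_t_ha_yr()`), not as reproducible outputs.

Per-m² summaries are reported under a declared denominator convention
(`occupied_units` or `all_units`) because the convention behind published
per-m² means is not uniquely determined; they are reporting-only and never
acceptance-tested.

## The synthetic survey generator

`generate_survey()` emulates the structure of an ROV survey: transects of
fixed-area sampling units alternating between a shallow and a deep
assemblage; per species and unit, a zero-inflated negative binomial count
(occupancy × overdispersed count — chosen precisely so the total/on-patch
density distinction is exercised); truncated-lognormal colony heights with
species medians (15–25 cm) tuned to give per-colony biomass of the
magnitude seen in the field. Ground-truth per-compartment budgets are
recorded at generation time, and a pipeline re-run must reproduce them
exactly (the stages downstream of the random draw are deterministic).
`generate_measurement_pairs()` likewise stands in for digitized colony
photographs, with multiplicative lognormal noise; `noise_sd = 0.6` on 28
pairs was calibrated to give a mean log-log R² near 0.78, matching the fit
quality of in-situ photographic allometry.

What the generator does **not** emulate: ROV optics and measurement error
structure, spatial autocorrelation along transects, depth-dependent size
gradients within a zone, and mixed shallow/deep assemblages. Passing tests
on synthetic surveys therefore demonstrate the correctness of the
accounting machinery, not the field accuracy of the rates.

## Statistical comparison

Cross-species differences in biomass, flux and sink are tested the way the
field does: square-root transform, one-way ANOVA, Tukey HSD. The
observational unit is configurable and defaults to per-transect per-species
totals (the transect grid is the only published sample structure). The
published F statistics are not reproducible without the per-transect data
and are not targets. Test-suite problem sizes (a few hundred sampling
units, 1000-replicate null simulations) were chosen as the smallest that
make the binomial error bounds on the type-I-error check informative.

## Known limitations

* Carbon lost to reproduction, predation and natural turnover is not
  modelled (no data exist for these species); the sink is growth-only and
  therefore an upper bound on net annual immobilization.
* Respiration uses fixed rates referenced to 16 °C (shallow) / 14 °C
  (deep); no temperature response curve.
* The spring snapshot is not interpolated across seasons.
* Deep *E. singularis* heterotrophic rates borrow from shallow colonies,
  likely underestimating deep feeding; the config simply allows distinct
  values.
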
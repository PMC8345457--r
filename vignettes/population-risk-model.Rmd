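---
title: "A nest-based landscape population model for pesticide risk to herbivorous mammals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A nest-based landscape population model for pesticide risk to herbivorous mammals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lagopop)
set.seed(1)
```

## The model

`lagopop` is a stochastic, individual-based model of local populations
("nests") of large herbivorous mammals — parameterized here for the European
rabbit (*Oryctolagus cuniculus*) and the brown hare (*Lepus europaeus*) —
coupled to a landscape-level pesticide exposure model and to dose-time-response
functions derived from standard regulatory toxicity endpoints. Its purpose is
the kind of question a regulatory risk assessor asks: given a proposed use
pattern (crop, application rate, dates, drift mitigation), what is the expected
impact on the mid-term abundance of a focal mammal population, and which
factors — dose, timing, splitting, landscape configuration — drive that impact?

The model has two coupled parts.

**Demography.** Each nest holds discrete individuals with an age in days and a
sex. Individuals belong to one of up to four age groups by age thresholds;
each group has a background monthly mortality rate, and reproductive groups
have a background monthly reproduction rate (offspring per reproductive female
per month) that operates only during the nest's reproductive season. Every
day, for each group, the number of deaths is a binomial draw at the group's
effective daily rate and the dead are removed uniformly at random; in season,
births are Poisson draws with mean `n_females * monthly_rate / 30` per day,
newborns entering the first group at age 0 with random sex; finally all ages
advance one day and individuals crossing a threshold are promoted.

**Exposure and effects.** Fields are polygons with an inner band (in-field
margin) and an outer band (off-field strip receiving drift). An application
deposits an initial residue `RUD * rate` (mg/kg per kg/ha) on the food items of
the treated zones, scaled by the zone's deposition fraction, and residues decay
first-order with half-life `DT50`. A nest's circular feeding area is overlaid
on the landscape to obtain zone area fractions; combined with relative food
availability weights they give diet fractions, and the daily estimated
theoretical exposure is

    ETE_t = (FIR / bw) * sum_items( diet_fraction * residue_t )

in mg/kg body weight per day. Three effect pathways read this exposure through
clamped linear dose-response lines (values below 0 corrected to 0, above 1
to 1):

* *acute mortality*, evaluated at the same day's `ETE_t`, with the line fitted
  through `(LD0 / f_LD0, 0)` and `(LD50 / f_LD50, 0.5)`;
* *chronic mortality* and *reproduction*, evaluated at time-weighted-average
  (TWA) exposure over a pesticide-specific window, with the line through the
  origin and `(LOAEL / f_chronic, 0.25)` — a default 25% level of effect at
  the adjusted LOAEL, accepted as linear provided the implied effect at the
  adjusted NOAEL falls in the 5–10% band.

Effects are combined with the background rates assuming independent causes:

    accumulated mortality = 1 - (1 - background) * prod_x (1 - effect_x)
    final reproduction    = background * prod_x (1 - effect_x)

The *lag schedule* connects exposure months to effect months: chronic
mortality in month *m* is driven by the maximum TWA exposure of month *m − 1*;
reproduction in month *m* by the largest monthly-maximum TWA over months
*m − 1* and *m − 2* (a 30-day pregnancy variant using only *m − 1* is a
configuration switch). Acute mortality acts the same day, with no background
acute mortality. Months are fixed 30-day blocks from day 0.

```{r dr}
glyphosate_profile()
bromoxynil_profile()
```

## Default parameters and why

| Parameter | Rabbit | Hare | Units / note |
|---|---|---|---|
| monthly mortality (groups 0–3) | 0.77 / 0.38 / 0.11 / 0.11 | 0.87 / 0.30 / 0.08 / 0.08 | published demographic reviews |
| monthly reproduction (groups 0–3) | 0 / 0 / 0 / 4 | 0 / 0 / 0.6 / 1.75 | offspring per reproductive female per month |
| reproductive season | December–May | January–August | Mediterranean / central-European conditions |
| initial individuals per nest | 140 | 100 | split 0/0/60/80 and 0/10/30/60 |
| sex ratio | 1:1 | 1:1 | newborn sex Bernoulli(0.5) |
| age thresholds (days) | 0/30/120/270 | 0/30/180/365 | modelling defaults, see below |

The demographic reviews supply rates per age *group* but not the group
boundary ages, so the thresholds are modelling defaults: weaning at about one
month, subadulthood at about four (rabbit) or six (hare) months, and full
adulthood at nine (rabbit) or twelve (hare) months, within the range those
reviews report for maturation.

**Monthly-to-daily rate conversion.** Two readings of "monthly rates applied
at daily intervals" are implemented. The *compound* conversion
`1 - (1 - m)^(1/30)` reproduces the monthly rate exactly when compounded over
a month ([monthly_to_daily_mortality()]). The *uniform* conversion `m / 30`
spreads the monthly rate evenly across days. The engine default is
**uniform**: a deterministic age-structured projection of the default rabbit
rates shows that under the uniform reading the Table of defaults represents a
near-stationary population with roughly threefold seasonal amplification —
the regime the defaults are intended to describe — whereas compound
conversion of these particular rates (a 77% monthly infant mortality becomes
a much harsher daily regime when compounded) produces a population declining
by roughly a third per year under any plausible maturation ages. The choice
is a configuration field (`rate_conversion`), and both conversions are
exercised by the unit tests.

**Initial age structure.** Simulations of the rabbit fixture start in
December, at the opening of the breeding season; the 140 individuals are
split 0/0/60/80 (subadult/adult), which is the stationary December structure
implied by the default rates — six months after the last births, no infants
or juveniles remain. Initial ages are drawn uniformly within each group's age
span; the last group spans one further year beyond its threshold (there is no
senescence, so adult age does not affect the dynamics).

**Exposure placeholders.** The regulatory guidance supplies residue-per-unit-
dose values, dissipation half-lives, and intake rates per crop and species;
those tables are not reproduced here. The bundled fixtures ship clearly
labelled non-normative placeholders — RUD 85 mg/kg per kg/ha on cereals,
DT50 10 days (glyphosate) and 3 days (bromoxynil, whose field residues
dissipate rapidly), FIR/bw 0.45 kg food per kg body weight per day — chosen
to reproduce the qualitative exposure shapes of the case study (a sharp
post-application peak decaying to near zero within weeks for bromoxynil).
Every fixture records, per numeric default, whether it is a sourced endpoint
or a placeholder (`pesticide_provenance()`), and all are overridable.

## The daily loop and numerical choices

Within a day the order of events is fixed: (1) at month boundaries the
effective monthly rates are recomputed from the lagged maximum TWAs and
converted to daily rates; (2) acute mortality is applied at the day's
exposure; (3) background-plus-chronic daily mortality; (4) reproduction if
the calendar month (from `start_month`) is in season; (5) ageing and
promotion. The order matters only at small population sizes, which is why it
is pinned down and documented.

Other numerical decisions:

* **TWA truncation**: the averaging window is truncated at day 0 (mean over
  the available days), so early-simulation exposures are not diluted by
  non-existent history.
* **Clamping**: dose-response outputs are clamped to [0, 1]; the lower clamp
  is part of the acute-line definition, the upper is forced by rate
  semantics.
* **Coefficient rounding**: derived line coefficients are echoed half-up at
  the conventional printed precision (`round_half_up()`); internal arithmetic
  keeps full precision.
* **Disc–polygon overlap** is computed by rasterizing the feeding disc
  (default resolution radius/100, error of order resolution/radius, verified
  against analytic rectangle and half-plane cases). Rectangular fields use
  exact rectangular band offsets; general polygons use Euclidean
  distance-to-boundary classification, which is the exact erosion/dilation
  for convex shapes. Where fields overlap, the first field in declaration
  order claims the point.
* **Random numbers**: replicate *i* uses seed `base_seed + i`; each nest
  derives an independent sub-stream from `(seed, nest_id)`, so adding a nest
  never perturbs the others, and an unexposed nest inside a treated scenario
  reproduces its pesticide-free trajectory exactly.
* **Confidence intervals** across replicates use the normal approximation
  `mean ± 1.96 sd/√n` (a percentile mode and a min/max envelope are
  options).

## What the bundled scenarios emulate — and what they do not

The fixtures reproduce the published case-study *designs*: pesticide-free
stability and replicability runs (1000–10,000 days, 50 replicates, initial
densities 30–200), a glyphosate use pattern (two applications at 4.0 kg/ha on
cereals), a bromoxynil pattern (one application at 1.0 kg/ha), dose-by-timing
grids (0/0.05/0.1/0.2 kg/ha at 15/30/90/120 days after season start) and
application-splitting designs. The treated fixtures assume worst-case dietary
exposure (the whole diet from the treated area), matching the verification
setting of the case study.

Passing tests on these scenarios therefore show that the demographic engine,
the exposure bookkeeping, the dose-response derivations and the lag schedule
interact as specified — they do not validate the model against field data.
Absolute exposure magnitudes depend on the placeholder residue and intake
values; only coefficient-level quantities (the derived dose-response lines)
and structural properties (stability, dose ordering, lag timing, replicate
agreement) are asserted. The test suite runs the stability and replicability
checks at 50 replicates over 1000 days and the dose-ordering checks at 50
replicates over 540 days, the replication counts of the original figures.

## Known limitations

* Background rates are density-independent; there is no compensatory
  recruitment, so long-horizon trajectories drift at the deterministic growth
  rate implied by the rates and thresholds.
* No dispersal between nests, no explicit litter structure, no individual
  energetics or toxicokinetics.
* The exposure module implements the generic residue structure (RUD
  deposition, first-order dissipation, dietary weighting); regulatory
  shortcut values must be supplied by the user for normative assessments.
* Mixture effects are independent-survival combinations only; no synergy or
  antagonism.
* The worst-case diet mode ignores the landscape; the landscape mode assumes
  uniform use of the feeding area (no preference or avoidance behaviour).
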
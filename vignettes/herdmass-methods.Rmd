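---
title: "Methods: segmented growth/value models and herd-level biomass aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented growth/value models and herd-level biomass aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdmass)
```

## Scope and data model

`herdmass` estimates cattle biomass (kg liveweight) and stock value (€)
at animal, herd, herd-type and sector level from three kinds of
administrative data: slaughter-valuation records (weighed *and* valued
animals), livestock-market price returns (category-labelled, no dates of
birth), and a registration/movement event log (births, deaths, paired
move-out/move-in events). The real counterparts of these databases are
confidential, so the package treats a synthetic population with known
generative parameters as its reference input; every method is exercised
and judged against that ground truth.

## The segmented liveweight and value models

For an animal of age $x$ days, the expected response (liveweight in kg or
value in €) is continuous piecewise-linear with $K$ break-points
$\psi_1 < \dots < \psi_K$:

$$
E[y] = \beta_0 + \beta_1 x + \sum_{k=1}^{K}\delta_k (x-\psi_k)_+ +
  \mathbf{z}^\top\boldsymbol\gamma ,
$$

where $(u)_+=\max(u,0)$, $\delta_k$ is the slope change at $\psi_k$, and
$\mathbf{z}$ contains treatment-coded dummies for breed category (dairy,
continental beef, British-Irish beef), calendar month, and year, each with
the earliest level as reference. Separate models are fitted for females
and males, for both responses — four models in total — because growth
trajectories and price profiles differ by sex.

### Estimation

`segfit()` estimates $(\beta,\delta,\psi)$ by iterative linearization.
Given current $\psi$, the design is augmented with the hinge terms
$(x-\psi_k)_+$ and the indicator terms $-\,\mathbf 1\{x>\psi_k\}$; after an
ordinary least-squares solve with coefficients $\hat\delta_k$ (hinge) and
$\hat\gamma_k$ (indicator), the first-order update is
$\psi_k \leftarrow \psi_k + \hat\gamma_k/\hat\delta_k$. The raw update can
oscillate around the optimum, so each step is halved (up to ten times)
until the residual sum of squares does not increase; descent is therefore
monotone, and the iteration stops when the largest relative break change
falls below `tol` (default `1e-4`, at most 50 iterations) or no step
improves. If the iteration leaves the observed age range, collapses two
breaks, empties a segment (fewer than `min_seg_obs = 5` observations), or
stalls immediately, the estimator falls back to a profile grid search on a
1-day lattice (exhaustive for small problems; a coarse lattice followed by
per-coordinate 1-day refinement for large ones), optionally polished by
restarting the iteration from the lattice optimum. Break-points are
initialised at the $k/(K+1)$ age quantiles: standard and scale-free.

The grid search doubles as an independent oracle in the test-suite: on
280–300-row instances the iterative solution's RSS matches the exhaustive
lattice optimum to well within 0.1%.

### Choosing the number of break-points

`select_breakpoint_count()` fits $K = 1,2,\dots,k_{\max}$ ($k_{\max}\le3$)
and returns the smallest $K$ whose increment to $R^2$ from $K+1$ is below
`delta_r2_threshold`. The threshold quantifies "only minor improvement";
it defaults to 0.01 and is deliberately exposed as configuration, since no
canonical value exists. Because an extra hinge regressor can never
increase the RSS at fixed break positions, each $K+1$ candidate is also
started from the $K$-break solution augmented with the best single
additional lattice break, and the better of the two runs is kept — this
keeps the reported $R^2(K)$ sequence non-decreasing even when the
free-running iteration lands in a poorer local optimum. On data simulated
with two true breaks at 608/1878 days (n = 600, residual SD 40 kg) the
procedure selects $K=2$ in every one of 50 seeded replicates and recovers
the break positions with a median error of about 2.5%.

A note on identifiability: the terminal (mature-cow) segment of the
liveweight truth has a slope of 0.01 kg/day — essentially flat. Its
*relative* estimation error is large even when the absolute error is a few
grams per day, so recovery checks quantify the two growth segments in
relative terms and the terminal slope only in absolute terms.

### Training-sample design

Model training emulates the source design: sampling from the cleaned
valuation dataset is stratified by animal class (calf, heifer, steer,
bull, cow, pregnant heifer) with equal numbers per class — 600 per class
(3,600 records) for liveweight and 1,000 per class (6,000 records) for
value — reflecting a design limited by its least frequent class.

## Cleaning rules

`clean_dataset()` applies, in documented order, with each dropped record
attributed to the first rule it fails:

1. **Completeness** — value (non-zero), liveweight, date of birth, date of
   death, sex and breed must all be present.
2. **Liveweight windows** — 30–1,400 kg for calves, heifers and steers;
   200–1,400 kg for bulls, cows and pregnant heifers. Both endpoints are
   inclusive ("from X to Y" read as a closed interval — conservative
   retention).
3. **Breed resolution** — codes map to dairy / continental beef /
   British-Irish beef. A cross code (terminal "X", e.g. `FRX`) is stripped
   to the sire code before lookup; codes that are themselves mapped are
   never stripped (`DX`, Dexter). The shipped map
   (`inst/extdata/breed_map.csv`) is a conventional grouping, explicitly
   user-replaceable, because no official registry list is distributed with
   the package.

Cleaning is idempotent, and the attached report accounts for every input
row.

## Population snapshots

`build_snapshots()` reconstructs, for the first day of every month, the
set of animals standing in each herd, as half-open stays $[\text{start},
\text{end})$ derived from the event log. The boundary rule is: events
dated exactly on a snapshot date take effect at that snapshot — a move on
the 1st counts in the destination herd, a death on the 1st removes the
animal. The rule is a package decision (the convention is not dictated by
the data) chosen for determinism; it is applied uniformly and documented
here. Animals with contradictory histories (no or duplicate birth,
unmatched move-ins, events after death) are quarantined and reported, not
fatal. Ages are exact calendar-day differences; dates are timezone-free.
Construction is a pure function of the event table and is
order-independent after sorting.

## Herd classification

Each herd-year receives a type and subtype from an ordered decision tree
over features computed from the January, May and September snapshots
(average head counts by sex × age band × breed category; age band
boundary 730 days) and that year's flows (births, move counts, stay
lengths, inflow ages, on-site deaths). Herds empty at all three census
months fall to a throughput sub-rule: short-stay traffic ⇒ trading;
inflow ending in on-site slaughter ⇒ fattening; otherwise unclassified.
Calving herds split on the breed make-up of adult females (≥ 30% of both
⇒ mixed; ≥ 50% dairy ⇒ dairy; else beef), with subtypes from progeny
policy (dairy: D / DRm / DnR_C / DnR_nC; beef: BP on breed purity, BSW /
BSY / BSB on the mean age at which home-born stock leaves). Non-calving
herds split into trading, store/rearing (youngstock-dominated, no on-site
slaughter; subtypes Rdf / Sdm / Sbf / Sbm / Sbmx by sex and breed mix)
and fattening.

All thresholds live in one JSON file
(`inst/extdata/classifier_rules.json`). The tree this emulates publishes
its exact thresholds in an inaccessible supplement, so the shipped values
are calibrated only to reproduce the taxonomy's behaviour on the synthetic
population — on noise-free archetype herds the default rules recover the
intended type for ≥ 95% of herds (100% in the shipped test population) —
and are meant to be replaced when real data are available. Rule order
matters and is fixed and versioned; permuting rules may change outcomes.

## Aggregation and deflation

Per-animal predictions (each snapshot member, using its sex's fit, age in
days, breed category, snapshot month and year) are summed to herd-month
totals. A herd's annual figure is the mean of its monthly totals with
empty herd-months counted as zero — a herd destocked half the year has
half the biomass; the alternative (mean over occupied months only) is
available behind a flag. Herd-type annual averages are means of herd
annual figures; the sector total is the sum of herd annual figures. The
alternative sector definition — the annual mean of monthly national sums —
is always computed alongside; the two differ only when herds appear or
disappear mid-year. Additivity from animal to herd to type to sector is
exact up to floating-point (tested at 1e-6 relative).

Values are deflated as real = nominal × 100 / index. Monthly series use
the monthly index, annual series the annual index. The synthetic CPI's
annual view defaults to the December value rather than the mean of months:
stock value is a point-in-time (stock, not flow) quantity, so end-of-year
deflation is the consistent choice; a mean-of-months annual view is
available via `annual_method = "mean"`. Both real and nominal values are
always emitted. Biomass is carried in kg and value in € everywhere;
conversion to '000 tonnes and € million (`kg_to_kilotonnes()`,
`eur_to_millions()`) happens only at the reporting boundary.

Months or years present in the movement data but absent from the training
data are resolved to the reference level with a logged warning — the
predictable consequence of training on one window and predicting another.

## Validation and reference denominators

Market records carry an animal category, not a date of birth, so
`validate_value_model()` converts each category to an age range
(`inst/extdata/category_age_map.csv` — plausible industry ranges, shipped
as replaceable configuration, not an official mapping), predicts the value
at each integer month of age in the range with month and year fixed at the
sale-date medians of the market table, averages unweighted, and compares
with the per-category market mean as a signed relative difference; the
|diff| ≤ 10% screen is reported per cell. `reference_biomass()` provides
the LSU (650 kg per unit, per-category coefficients), TLU (250 kg per
head) and PCU (450 kg per adult cow, per-category standard weights)
denominators, linear in head counts.

## The synthetic population

The generator is the package's study design, not a test fixture:

* **Growth/value truths** are continuous piecewise-linear curves with two
  breaks per sex — 608/1878 days (female) and 713/1884 (male) for
  liveweight; 682/1254 (female) and 335/1041 (male) for value — additive
  breed offsets, small sinusoidal month effects, linear year effects, and
  additive Gaussian noise (default SD 40 kg / €120; a heteroscedastic
  option with SD proportional to the mean exists behind a flag, since the
  residual structure of real valuation data is unknown). Slopes and
  intercepts give realistic Irish trajectories: about 40 kg at birth,
  0.85–1.0 kg/day early growth, mature cows near 850 kg, values rising to
  a plateau around first calving and declining toward cull age.
* **Slaughter records** draw equal numbers per animal class from
  class-specific age windows (class is assigned from sex and age by
  configurable thresholds, since no canonical class boundaries exist);
  about 15% of records carry a cross code for the cleaning rules to
  resolve.
* **The movement database** simulates herd archetypes: spring-calving
  dairy herds selling surplus calves to rearing herds, suckler beef herds
  finishing their own stock, dairy-female rearing herds whose biomass
  peaks in October (two cohorts on the ground just before the older one
  leaves), fattening herds slaughtering bought-in stores, and short-stay
  trading herds through which transfers route with spring/autumn-peaked
  probability. Marts are modelled as instantaneous herd-to-herd moves: no
  animal is "between herds" on a snapshot date. Every animal has exactly
  one birth; every transfer is a paired move-out/move-in.
* **Market records** allocate latent ages round-robin over the integer
  months of each category's range (exposed in a `latent_age_days` column
  for generator-level checks only).
* **The CPI** applies geometric drift, normalised so the base period is
  exactly 100.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: the risk structure of a disease-programme
sampling frame (reactor animals are not a random sample of the herd),
disease effects on growth, geographic structure, missing or contradictory
records beyond the quarantine paths exercised in tests, herds switching
type mid-study, and real price dynamics beyond smooth drift.

## Numerical choices and problem sizes

Determinism: every generator takes a seed and restores the caller's RNG
state; identical seeds and parameters give byte-identical tables. The
grid fallback uses a 1-day lattice with at least 5 observations per
segment; degenerate designs (collinear covariates, empty segments) raise
errors rather than silently dropping terms; constant covariates are
absorbed into the intercept with their level recorded. Negative
predictions (possible at extrapolated young ages) are floored at a
configured minimum with a warning.

The shipped tests and the acceptance script run at deliberately desk-scale
sizes — 50 replicate fits of n = 600, a three-year population of roughly
2,500 animals in ~55 herds, 280–300-row oracle instances — chosen so the
whole suite completes in a few minutes while every estimator is exercised
against its oracle. The methods scale linearly in events and animals.

## Known limitations

* Break-point standard errors and confidence intervals are not computed.
* The classifier thresholds and the category→age map are calibrated to
  the synthetic taxonomy, not to any official rule set; both are single
  config files intended to be swapped.
* The fallback discriminator for census-empty herds (trading vs fattening
  vs unclassified) is a best guess flagged as such in the rule file.
* Sector totals depend on the chosen reading of "combining" herd and
  herd-type averages; both definitions are emitted so the difference is
  visible rather than hidden.
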
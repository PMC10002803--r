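---
title: "Methods: demand, catchments, rate models and capacitated siting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: demand, catchments, rate models and capacitated siting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`equiscreen` chains five analyses: a synthetic-geography generator, a
road-network drive-time module, guideline-based demand models, Poisson rate
regressions of facility access, and a capacitated maximal-covering siting
optimizer. This vignette records the modelling assumptions, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open.

## Screening demand

Demand is the number of screening mammograms a tract's women are owed per
year. Three guideline readings are implemented:

* **USPSTF** — biennial screening for women 50–74. A biennial schedule at
  steady state screens half the eligible population each year, so demand is
  `women_50_74 / 2`. The halving is an explicit steady-state assumption: a
  programme ramping up or down would deviate from it.
* **Race-based** — USPSTF plus biennial screening of Black women from age
  40, adding `pct_black_women × women_40_49 / 2`. Tract data rarely provide
  an age-by-race cross-tabulation, so the tract-level Black fraction is
  applied uniformly to the 40–49 band. The increment covers ages 40–49 only;
  from 50 those women are already in the USPSTF term.
* **ACR** — annual screening for all women 40 and older:
  `women_40_49 + women_50_74 + women_over_74`. "40 and older" is taken at
  face value, with no upper age cap; capping at 74 would only lower ACR
  demand, which is already the largest of the three.

Because the Black fraction is at most one and biennial halves an annual
schedule, `USPSTF ≤ race-based ≤ ACR` holds tract by tract; the test suite
property-checks this dominance, along with additivity under tract merging
and scale equivariance. Demand stays real-valued end to end — rounding
happens only in report tables — so the allocator never sees
order-dependent rounding artifacts.

Capacity is `units × 4500` screenings per unit per year, derived from a
working limit of three mammograms per unit per business hour. The per-unit
constant is a `capacity_model()` parameter, so sensitivity analyses can
move it without touching the allocator.

## Drive-time catchments

Travel time between a tract's population-weighted centroid and a facility
is the exact shortest-path sum of `60 × length_km / speed_kmh` over an
undirected road network (Dijkstra via `igraph`, no heuristics; desk-scale
problems of a few hundred origins and destinations run in milliseconds).
Because edges are undirected, tract→site times equal the site-outward
service areas a GIS would draw, and one matrix serves both the catchment
table and the allocator.

Conventions, chosen once and tested:

* Bands are closed on the right — `(0,15]`, `(15,30]`, `(30,∞)` — so a
  tract at exactly 15 minutes is "within 15".
* A tract's band depends only on its minimum drive time; the nearest site
  is reported with ties to the smallest site id.
* Unreachable pairs carry an `Inf` sentinel and land in the over-30 band —
  conservative access reporting rather than silent omission.
* Whether a real analysis should judge "within 15 minutes" by centroid or
  by polygon overlap is ambiguous; the centroid convention is used and
  stated, not presented as the only reading.

## Poisson rate models

Per-tract counts of facilities, units, BICOE facilities and BICOE units are
modelled as `y ~ Poisson(μ)`, `log μ = β₀ + Zβ + log(population)`. The
offset makes the model a rate model; covariates (deprivation z-score, three
female age-band counts, percent Black women, percent households with a
vehicle, bus stops — in that fixed order) are standardized so `exp(β)` is a
rate ratio per SD. Confidence intervals are Wald on the log scale,
exponentiated; fitting is plain `stats::glm` maximum likelihood with no
overdispersion correction, since the method is specified as Poisson
regression.

Open choices resolved here:

* **Standardization scope.** Covariates are standardized *within the fitted
  stratum* with the sample SD (n−1). "Per SD change" then means the SD of
  the population the model describes; the alternative (statewide scaling
  for county models) changes only the units of reported RRs, and the
  invariance test confirms affine rescaling of covariates never changes
  them.
* **Suppression.** A stratum model is withheld (`flag = "unavailable"`)
  when the stratum's outcome total is below 5 events — sparse-outcome
  county models are reported as unavailable rather than as unstable
  estimates. The threshold is a documented argument, not a constant.
* **Degeneracy.** Non-convergence or separation-like geometry (unstable
  standard errors) raises an error from `fit_rate_model`; inside
  `stratified_fits` it is caught and flagged `"degenerate"` so one bad
  stratum cannot abort a pipeline run.

`plant_known_rates()` inverts the model: given coefficients it simulates
counts with the same linear predictor, which is how the suite measures
recovery — at n = 1000 tracts and 100 replicates, per-covariate 95% CI
coverage must sit in [90%, 99%] and mean RR bias within 5%.

## Capacitated maximal-covering siting

Demand points are tract centroids weighted by annual screenings; existing
facilities are *required* (always open, fixed capacity); candidates come
from a fishnet grid snapped to the road network (duplicate snap nodes
merged), each assumed to hold one unit (4500/year). The default cell size
of 5 km yields roughly ten candidates per existing site. A point can be
served only within the 20-minute cutoff — the assumed maximum a woman would
travel to screening.

**Assignment rule.** Whole-point, nearest-feasible: points are processed in
ascending order of nearest-site time (ties by point id) and each goes
wholly to its nearest site with remaining capacity for its full weight
within the cutoff, else stays unassigned. Fractional splitting of a tract
across sites is deliberately not modelled — demand points are centroids, a
single place. The whole-point rule makes coverage slightly
order-dependent, which is why the same rule is used verbatim inside the
optimizer and the exhaustive oracle.

**Optimizer.** The proprietary GIS heuristic behind "maximize capacitated
coverage" is undocumented, so the package implements the *problem* with a
transparent algorithm: greedy construction (each step opens the candidate
that maximizes covered demand) followed by pairwise interchange (swap an
opened candidate for a closed one while coverage strictly improves). A
single greedy start can lodge in a local optimum that only a simultaneous
double swap escapes; rather than widen the swap neighbourhood (quadratic
cost), the solver runs a deterministic multi-start — by default 8 starts,
each forcing one of the highest singleton-gain candidates as the first
opened site — and keeps the best solution, breaking ties toward the
lexicographically smallest site set. On every desk-scale instance tested
(≤8 candidates, p ≤ 3, hundreds of seeded cases) this matches exhaustive
enumeration; at larger scale greedy coverage retains the usual (1 − 1/e)
guarantee relative to the capacitated-greedy optimum but is not certified
optimal. All tie-breaks are total-ordered, so identical inputs always give
identical opened sets.

**Cumulative nesting.** Solutions for p = 1, 3, 5 nest by construction:
sites chosen at smaller p are fixed open at larger p and exempt from
interchange. This mirrors how siting recommendations are presented
(numbered, cumulative additions) and guarantees monotone coverage in p.

**Drive-time improvement** is the demand-weighted mean of each point's
minimum drive time, before versus after the new sites; averaging over
demand (people owed screenings) rather than raw tracts weights the metric
toward where women actually live. Since after-sites ⊇ before-sites, the
reduction is never negative. Points unreachable before are excluded from
both means.

**BICOE conversion.** Required sites become the BICOE facilities with their
capacities; every non-BICOE facility is a candidate at its actual location.
Candidates keep their actual unit capacity by default — they are real,
already-built sites — with `single_unit = TRUE` exposing the
new-site convention as an alternative.

## The synthetic world

`generate_scenario()` produces the stated world the tests run in: 214
tracts (129 urban, 85 rural), 30 facilities (16 urban / 14 rural) with 1–4
units (mean ≈ 1.5, so ≈ 44 units), BICOE probability 7/16 urban and 2/14
rural (≈ 30% BICOE overall, concentrated in the urban county). Demographic
means and dispersions per county follow published tract summaries: urban
tracts have more women 40–49, fewer 50–74 and >74, a higher Black fraction
(mean 26% vs 16%), lower vehicle ownership (91% vs 95%) and more bus stops
(14 vs 7). Tract population scales the women-40+ total by a factor drawn
around 3.76, matching the ratio of total population to women 40+ in those
summaries. Fractions are Beta draws matched to mean/SD, bus stops negative
binomial, deprivation standard normal.

Geometry is planar kilometres — the analysis needs minutes, not geodesy.
The road network is a jittered lattice per county (urban: 3 km spacing at
50 km/h; rural: 8 km at 80 km/h) joined and then repaired so one connected
component carries every snapped tract and facility; snapping is nearest
node with ties to the smallest node id. Tracts cluster around a few town
centers where facilities also sit; 15% of rural tracts are instead placed
uniformly, and rural towns are drawn from the interior 44% of the county
box, so a small rural fringe genuinely exceeds 30 network-minutes — the
urban-short/rural-long contrast the real catchment analysis exhibits (all
urban tracts within 15 minutes, ~1–3% of rural tracts over 30, across
seeds). Each tract's population is split over five blocks by a symmetric
Dirichlet so population-weighted centroids are nontrivial.

What the generator does *not* emulate: real tract geometry and adjacency,
spatial autocorrelation of demographics, cross-border facility use, one-way
streets, congestion, or transit. A green test therefore establishes that
the *methods* behave correctly in a world with the assumed statistical
structure — not that any specific state's published coefficients or maps
are reproduced, which would require the restricted source data.

## Determinism and numerics

Everything downstream of a `scenario_config(seed = s)` is a pure function
of the config: re-running a pipeline writes byte-identical CSV/JSON (the
manifest stores an MD5 of the configuration, excluding the output path).
Coverage comparisons in the optimizer use a 1e-9 slack so floating-point
noise cannot flip a swap decision; capacity feasibility is asserted with
the same slack. Percentages in report tables round half away from zero
(`round_half_up`), reproducing printed integer shares exactly; everything
else stays at full precision.

## Known limitations

* Drive time is the only access dimension — no transit, hours, insurance
  or childcare barriers; vehicle ownership and bus stops enter only as
  regression covariates.
* Plain Poisson models ignore spatial autocorrelation and possible
  overdispersion; at the observed facility sparsity (~0.1–0.2 per tract)
  overdispersion has little room to act, but counties are not independent
  replicates.
* The whole-point assignment rule can strand a large tract behind a small
  one at a nearly full site; fractional assignment would change coverage
  at the margin.
* Optimality of the siting heuristic is certified only at desk scale;
  state-scale certificates would need an integer-programming solver, which
  is out of scope.
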
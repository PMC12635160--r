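---
title: "Methods: coastal flood hazard at hazardous sites and exposure equity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coastal flood hazard at hazardous sites and exposure equity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floodequity)
```

# The problem

Coastal facilities that store, use or emit hazardous substances — power
plants, refineries, sewage treatment works, industrial reporters, landfills,
wells, legacy defense sites — sit disproportionately on low-lying land.
Rising seas raise the frequency with which extreme water levels overtop a
site's ground elevation, threatening contaminant releases into surrounding
neighborhoods. `floodequity` implements the full analysis chain for asking
two questions: *which sites face a material annual flood probability under
projected sea-level rise (SLR)*, and *which neighborhoods bear that burden,
as a function of social marginalization*.

Because the real national inputs (facility registries, tax parcels, lidar
elevation, localized SLR posteriors, census demographics) are large and
partly proprietary, the package ships a deterministic synthetic-region
generator with the same statistical structure, so every stage is exercised
end to end by code alone.

# Flood model

Each tide gauge carries a Poisson–generalized-Pareto (GPD) flood return
curve. Above the gauge threshold $\mu$ the expected annual number of events
exceeding height $z$ (meters above mean higher high water, MHHW) is

$$N_0(z) = \lambda\left[1 + \xi\,\frac{z-\mu}{\sigma}\right]^{-1/\xi},$$

with the exponential limit $\lambda e^{-(z-\mu)/\sigma}$ as $\xi \to 0$
(applied for $|\xi| < 10^{-8}$) and a finite upper endpoint
$\mu - \sigma/\xi$ for $\xi < 0$. The GPD fit does not extend below the
threshold; there the curve is continued log-linearly from $(\mu, \lambda)$
down to $(0, \texttt{cap\_rate})$ and held constant below the datum. The
default `cap_rate` of 182.6 events/yr is the order of one exceedance per
day's higher high tide — heights at or below MHHW are effectively flooded by
the tide itself. The sub-threshold continuation matters only for sites with
footprints near or below the datum, where any reasonable choice gives
$p \approx 1$.

Local sea-level rise $s$ lowers a site's effective freeboard. Given a
sample-based SLR distribution (samples, not a parametric object, so the
integration is distribution-agnostic), the law of total probability gives
the expected annual count and, with Poisson arrivals, the annual probability
of at least one flood over the site elevation $z$:

$$N_e(z) = \mathbb{E}_s\,[N_0(z - s)], \qquad p = 1 - e^{-N_e}.$$

The estimator is the sample mean over the *full* SLR sample array — no
subsampling — so results are reproducible bit for bit. A site is **at risk**
when $p \ge 0.01$, the 1-in-100-year criterion. The boundary is inclusive
on $p$: a canonical 1-in-100-year exceedance has $N_e = 0.01$ and hence
$p = 1 - e^{-0.01} \approx 0.00995$, so with a strict inequality the
textbook example itself would be excluded; `classify_at_risk()` also exposes
the alternative of applying the criterion to $N_e$ (`on = "rate"`).

Site elevation is the 25th percentile (linear interpolation between order
statistics, the `quantile()` type-7 default) of DEM cell centers inside the
site footprint; point sites (wells) use the containing cell.

# Site ingestion

Raw registry records pass through, in order: **filtering** (drop locational
accuracy worse than 50 m or zip-code-level geocodes, and facilities closed
or remediated by 2020; *retain* inactive facilities and expired permits,
since residual material remains), **categorization** (a prioritized rulebook
over permit/program codes, NAICS industry codes and keywords; exactly one of
eleven categories per record, unmatched records dropped with a logged
count), **deduplication** (same category + identical coordinates + fuzzy
address similarity $\ge 0.8$ collapse to one record; identical coordinates
with similar addresses in *different* categories are distinct facilities;
identical coordinates with dissimilar addresses are flagged and dropped by
the default plausibility predicate, which is injectable), **footprint
assignment** (point-in-parcel join; otherwise a circular buffer whose area
equals the category's median intersected-parcel area; wells stay points),
**FUDS overlap resolution**, **coastline clipping**, **offshore-well
exclusion** (wells not covered by any block-group polygon, boundary
inclusive), and **elevation extraction**. Every exclusion rule logs its
count; `exclusion_log()` returns the ledger.

Address similarity is normalized indel similarity on upper-cased,
punctuation-stripped, whitespace-collapsed strings, computed through
`utils::adist()` with substitution cost 2 (making substitutions equivalent
to delete+insert); the 0.8 threshold reproduces the intended behavior on
abbreviation variants ("123 Main St" vs "123 Main Street": 0.85).

For formerly used defense sites, polygons are authoritative; points inside a
polygon are duplicates of it; points outside every polygon get a buffer
sized to the *median polygon area* (FUDS convention differs deliberately
from the parcel-median convention of other categories). A buffered point
overlapping a polygon is clipped by it. Two overlapping polygons are
compared by the overlap ratio — intersection area over the smaller
polygon's area: at or below 0.45 the overlap is split, above 0.45 the two
merge into one site. The split geometry divides the overlap along the
perpendicular bisector of the two centroids (any even division would do;
this one is symmetric and convexity-preserving); the merge takes the convex
hull of the pair, a slight over-approximation that keeps every footprint a
set of disjoint convex pieces. Components of three or more mutually
overlapping polygons are emitted with an unresolved flag and excluded —
such knots need case-by-case judgment, not a rule.

All geometry lives on a local planar CRS in meters, so Euclidean distances
are exact. Footprints are represented as sets of disjoint convex polygons;
intersection, halfplane splitting, subtraction and point/edge distances on
convex pieces are exact and cheap, which is why the clipping and splitting
rules above can assert zero pairwise overlap to numerical tolerance.

# Exposure

The analysis universe is: counties containing at least one at-risk site
under the high-emissions scenario in 2100, and within them "coastal" block
groups — those within 3 km Euclidean distance of land below the 10 m
elevation contour. We read "within 3 km of the 10-m elevation line" as the
sub-10 m zone itself plus a 3 km fringe: a literal distance to the contour
*line* would exclude the very lowest-lying neighborhoods, which cannot be
the intent. The zone is discretized as DEM cells below 10 m.

A block group's populated portion is the set of 30 m population-grid cells
with population > 0 whose centers fall inside its polygon; where no gridded
population exists the whole polygon is used (the fallback mode is a config
switch in the generator). A block group is **exposed** at radius $r$ (1 km
primary, 3 km sensitivity) if any at-risk site's footprint lies within $r$
of its populated geometry; distance is measured to the footprint *edge*,
since footprints exist precisely to represent a site's extent. The site
count `n_sites` counts each site once per block group, and the expected
annual exposure is

$$\mathrm{EAE} = \sum_{\text{at-risk sites within } r} p_{\text{annual}},$$

the expected number of nearby sites flooded at least once in the year. EAE
sums over *at-risk* sites by default (switchable to all sites via
`at_risk_only = FALSE`). Bounds follow immediately:
$0.01\,n \le \mathrm{EAE} \le n$.

# Equity statistics

Descriptive comparisons between exposed and unexposed block groups use
two-sided Mann–Whitney tests (normal approximation with tie correction),
with medians and quartiles per group and no multiplicity adjustment.

Regression models take one marginalization covariate at a time (they are
collinear), scaled to unit standard deviation using the mean and SD of the
*whole* coastal universe; the binary disadvantaged-community flag stays
unscaled. Each model adds block-group population density and county fixed
effects, and reports county-clustered one-way sandwich standard errors with
the finite-cluster correction $\frac{G}{G-1}\cdot\frac{N-1}{N-k}$
(`sandwich::vcovCL(type = "HC1", cadjust = TRUE)`); 95% CIs use the normal
quantile on the estimation scale. The primary model is logistic (odds
ratio for exposure); restricted to exposed block groups, a negative binomial
model (ML dispersion, `MASS::glm.nb`) gives incidence-rate ratios for the
site count and a linear model gives mean differences in EAE. Counties
without outcome variation are dropped from the logistic fit with a logged
count; fewer than two usable counties or complete separation are errors.

Concentration curves order block groups by *descending* covariate value and
plot the cumulative share of burden against the cumulative share of block
groups. The concentration index is $C = 1 - 2A$ with $A$ the trapezoid area
under the piecewise-linear curve, so burden concentrated among marginalized
block groups puts the curve above the diagonal and makes $C$ negative;
$C \in [-1, 1]$. Ties in the ranking variable are broken by stable input
order by default, with pooling of tied blocks available (`ties = "pool"`) —
the two differ only in how the curve passes through tied runs, not in $C$'s
sign. CIs come from a nonparametric bootstrap over block groups
(percentile 2.5/97.5, seed-deterministic, at least 100 replicates); a
disparity is called significant when the interval excludes 0. Equal
block-group weighting is used (the curve's x-axis is the share of block
groups); population weighting would be a one-line extension but changes the
estimand.

# The synthetic generator

`make_region()` builds a planar coastal region: a DEM with a low coastal
plain rising through a linear ramp to >18 m inland, plus spatially
correlated Gaussian noise (bilinear interpolation of a coarse control grid,
correlation scale `noise_scale_m`, damped to zero at the coastline so the
shore sits at the datum); counties as strips touching the coast, optionally
plus fully-inland counties (which the study-county screen later removes);
block groups tiling each county; a population raster scattering each block
group's population around its centroid with a zeroed low-weight fraction,
so dasymetric refinement is non-trivial; tide gauges with Poisson–GPD
parameters drawn from realistic ranges ($\lambda \in [2,5]$ events/yr,
$\mu \in [0.7, 1.2]$ m, $\sigma \in [0.08, 0.2]$ m, $\xi \in [-0.05,
0.15]$); and shifted-lognormal SLR sample distributions whose location
grows with year and emissions scenario (medians of roughly 0.3 m in 2050
and 0.6–0.9 m in 2100, in line with localized projection ranges). Within a
gauge and year, the two scenarios share base draws, so the high-emissions
distribution dominates the moderate one *pointwise* — that makes scenario
monotonicity a theorem on synthetic data rather than a tendency.

`make_sites_and_demographics()` places sites with density decaying inland
and injects the pathologies the cleaning stage must handle: near-duplicate
records (same coordinates and category, perturbed addresses), imprecise and
closed records, hint-less records, offshore wells, and engineered FUDS
overlap pairs in the split range and the merge range. Tax parcels are
anchored on most non-well sites so the parcel join fires at a realistic
rate (~70%).

The marginalization covariate is tied to exposure by a known logistic law.
After the spatial exposure pattern is realized, county intercepts $a_c$ are
calibrated so that $\mathbb{E}_{z\sim N(0,1)}[\sigma(a_c + b z)]$ matches
each county's realized exposure rate, and the latent covariate is drawn
from the Bayes-implied conditional densities $f(z \mid E, c)$ through a
Gaussian copula: $w_i = \sqrt{\rho}\,\tau_{t(i)} + \sqrt{1-\rho}\,\eta_i$
with tract-level effects $\tau$ over groups of eight adjacent block groups
and $\rho = 0.35$, mapped through the conditional quantile function. Each
observation keeps the exact conditional marginal — so
$P(E \mid z, c) = \sigma(a_c + b z)$ holds with standardized slope exactly
$b$ — while neighboring block groups are positively correlated.

The copula step deserves its design note. Demographic covariates in real
census data are strongly spatially autocorrelated, and exposure is
intrinsically clustered (a 1 km radius around a site covers several
neighboring block groups); this co-location of correlated covariate and
correlated outcome is precisely what makes county-clustered standard errors
the appropriate inference, and a generator without it produces data for
which the clustered estimator is mis-calibrated. In design simulations, a
covariate drawn conditionally iid gave cluster intervals that were
anti-conservative, and a geometry in which all exposure hugged a narrow
coastal strip concentrated the information in a couple of tracts per county
with the same effect. The parameter-recovery experiments therefore use a
broad low-lying plain (`plain_frac = 0.4`) with wells spread across it
(`site_scale_m = 6000`), under which the estimator is unbiased and its
clustered intervals attain near-nominal coverage. The generator records the
true slope, the calibrated intercepts, the per-site analytic risk (both
under the full SLR distribution and under a degenerate distribution at the
median, where classification is closed-form) and the exposure truth, so
downstream recovery is testable exactly.

What the generator does *not* emulate: real geomorphology (tides, storm
surge dynamics, marsh attenuation), realistic county/block-group shapes,
registry schema quirks beyond the injected ones, geocoding error structure,
and any spatial dependence between demographics and siting history other
than the single configured association. Passing tests therefore demonstrate
the correctness and statistical calibration of the *machinery*, not the
real-world magnitudes of any disparity.

# Numerical choices and degenerate inputs

* GPD shape $|\xi| < 10^{-8}$ switches to the exponential form; heights
  beyond a finite upper endpoint return exactly 0 events/yr.
* The $p$–$N$ Poisson identity is maintained to $10^{-12}$ absolute
  (computed via `expm1`).
* Geometry slivers below $10^{-6}\,\mathrm{m}^2$ are discarded during
  clipping; circles are 64-gons (area within 0.2% of the true circle).
* Percentiles use linear interpolation (type 7); footprints smaller than a
  DEM cell fall back to the centroid cell, and a footprint covering no data
  is an error naming the site.
* Regions smaller than 4 DEM cells, empty gauge lists, SLR distributions
  with fewer than 100 samples, all-zero burdens, bootstraps under 100
  replicates, single-county model frames and zero-variance covariates are
  all rejected with explicit messages.
* Rounding for report tables is decimal half-up (0.05 -> 0.1), matching how
  printed tables are conventionally formatted, not banker's rounding.
* Scenario-difference percentages are reported against the larger
  (high-emissions) count, with the against-smaller figure also returned;
  for the canonical 5500 vs 5138 comparison the two read 7% and 7%.

# Problem sizes used in the test suite

Module tests run on a 12 x 8 km region (100 m cells, 40 block groups,
~110 site records). The parameter-recovery experiment runs 100 replicates
each under true OR 1.4 and under the null on 30 x 60 km regions with 25
counties, 4000 block groups and 250 wells (150 m cells, fallback population
mode) — large enough for the asymptotics the inference relies on, small
enough that a replicate takes about two seconds. The acceptance script
re-runs the full pipeline on a mid-sized region (120 block groups, six
counties, four scenario-years, two radii) plus one recovery replicate.

# Worked example

```{r example, eval = FALSE}
cfg <- region_config(seed = 1)
region <- make_sites_and_demographics(make_region(cfg))
sites <- ingest_sites(region$raw_sites, region$parcels, region$land,
                      region$blockgroups, region$dem, region$gauges)
risk <- site_risk_table(sites, region$slr, flood_curves_tbl(region$gauges),
                        "RCP85", 2100)
exposure <- exposure_table(region$blockgroups, sites, risk, 1000,
                           popgrid = region$popgrid)
fit <- region$blockgroups |>
  dplyr::left_join(exposure[, c("bg_id", "exposed")], by = "bg_id") |>
  standardize("p_poverty") |>
  fit_exposure_model("exposed", "p_poverty", "logistic")
tidy(fit)
```

# Known limitations

The flood climatology is static (no storm intensification), flooding is a
modified bathtub (no attenuation, groundwater or hydrodynamics), the merge
rule's convex hull slightly overstates merged FUDS footprints, the
synthetic CRS is planar (no projection distortion to exercise), and the
concentration index is unweighted by population. Multiple-comparison
adjustment is deliberately absent from the descriptive tables, mirroring
standard practice for this kind of descriptive equity surface.
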
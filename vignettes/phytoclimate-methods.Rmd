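---
title: "Phytoclimate risk assessment: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phytoclimate risk assessment: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoclim)
```

## The idea

Climate-change exposure indices measure how far climate variables move, but
plants do not perceive raw climate variables: physiological responses are
nonlinear and colimited by several factors at once. `phytoclim` therefore
transforms a climatology into a *phytoclimate* — a vector of climatic
suitabilities for plant growth forms (evergreen trees, C4 grasses,
succulents, ...), one value per form and grid cell. Risk is then measured as
Euclidean distance in this transformed space: how much a cell's phytoclimate
changes locally, whether a future phytoclimate has any present-day analogue
(novelty), and whether a present phytoclimate survives anywhere in the
future (disappearance).

The pipeline has seven stages:

1. **Climatology** — monthly minimum/mean/maximum temperature,
   precipitation, solar radiation, static soil field capacity and wilting
   point, and a scalar atmospheric CO2 per scenario.
2. **Soil moisture** — a monthly bucket model with Hargreaves potential
   evapotranspiration converts precipitation into plant-available water.
3. **Growth model** — a transport-resistance plant growth model simulates
   equilibrium biomass of a species in every cell from its 18 physiological
   parameters.
4. **Species fitting** — the 18 parameters are estimated per species from
   presence/pseudo-absence data by Differential Evolution, scoring
   candidates with a complementary log-log suitability regression on
   log-biomass; fits with true skill statistic (TSS) at or below 0.7 are
   discarded.
5. **Phytoclimatic transform** — per cell and growth form, the fraction of
   that form's accepted species whose binarized suitability map marks the
   cell suitable.
6. **Zones** — a Gaussian mixture (ellipsoidal, equal shape: the "VEV"
   family) clusters cells into phytoclimatic zones; the 5th percentile of
   pairwise intercentroid distances defines the ecological significance
   threshold.
7. **Risk indices** — local change, novelty and disappearance distances,
   future-zone assignment with novel designation, pseudo-GCM ensemble
   medians, and equal-area summaries.

Real-world inputs at global scale (downloaded climatologies, cleaned
occurrence corpora, growth-form databases) are out of scope here; a
synthetic-data generator with known truth exercises every stage end to end.

## The soil-moisture model

Potential evapotranspiration uses the classical Hargreaves form

$$\mathrm{PET} = 0.0023 \cdot 0.408 \cdot R_a \cdot (T_{\mathrm{mean}} +
17.8)\sqrt{T_{\max} - T_{\min}}$$

in mm/day, scaled by month length, floored at zero (0.408 converts
MJ m^-2 day^-1 into mm of evaporative equivalent). The bucket update per
month is

$$W_{m+1} = \mathrm{clamp}(W_m + P_m - \mathrm{AET}_m,\; wp,\; fc), \qquad
\mathrm{AET}_m = \min\!\big(\mathrm{PET}_m \cdot f(W_m),\; W_m + P_m - wp\big)$$

with the soil-limited reduction $f(W) = (W - wp)/(fc - wp)$; excess above
field capacity is lost as runoff/drainage. The annual cycle is iterated to
a periodic steady state (January store changing by < 0.01 mm, at most 50
cycles; bucket maps contract geometrically, so this is conservative). The
exact Hargreaves constants and the linear AET reduction are this package's
choices — the scientific claim is only "a Hargreaves-type PET inside a
single-layer bucket" — and they are fixed so results are reproducible
bit for bit. Moisture is deliberately independent of vegetation: it is a
property of the climate and soil, shared by all species.

## The growth model

Each plant is six pools: shoot and root structural mass ($M_s$, $M_r$),
carbon substrate ($C_s$, $C_r$) and nitrogen substrate ($N_s$, $N_r$), in
arbitrary mass units (amu), updated on a monthly step:

* **Carbon uptake** $U_C = A_{\max} \cdot \tau(W; c_{\mathrm{moist}}) \cdot
  \nu(N_s/M_s) \cdot M_s / (1 + B/k_B)$, where $\tau$ is a trapezoid
  response, $\nu$ a saturating shoot-nitrogen dependence with species
  half-saturation and floor, and $A_{\max}$ the universal uptake ceiling
  (below).
* **Nitrogen uptake** $U_N = \sigma_N \cdot \tau(T; n_{\mathrm{temp}})
  \cdot \tau(W; n_{\mathrm{moist}}) \cdot M_r / (1 + B/k_B)$. Soil
  nitrogen is assumed uniform across cells, so nitrogen uptake varies only
  with temperature and moisture.
* **Transport** of each substrate down its concentration gradient through a
  resistance, flux-limited so pools stay non-negative.
* **Growth** of each compartment $G = k_g \cdot \tau(T; g_{\mathrm{temp}})
  \cdot c \cdot n \cdot M$ (substrate concentrations $c$, $n$), consuming
  substrate at the structural fractions $f_C$, $f_N$.
* **Litter** first-order loss of structural mass.

The $(1 + B/k_B)^{-1}$ factor is self-shading/root-competition density
dependence. It is needed because the otherwise linear source–sink dynamics
are scale-invariant: populations either grow or decay exponentially and no
interior equilibrium exists. With it, every cell has a well-defined
equilibrium biomass, which the solver finds by repeating the 12-month cycle
until the annual-mean biomass changes by less than a relative tolerance of
1e-4 (at most 80 cycles), from a fixed small initial state. Biomass below a
floor (0.05 amu) is reported as zero: the cell cannot support the species.
Carbon bookkeeping is exact by construction — per step, the change in
substrate plus structural carbon equals uptake minus litter — and the test
suite asserts this identity along random trajectories.

Two numerical properties of this nonlinear monthly map deserve mention.
First, cells near the niche edge relax arbitrarily slowly (their net annual
growth rate approaches zero), so at any finite cycle budget some cells
carry an unsettled last-cycle mean; `equilibrium_biomass()` flags these in
a `converged` attribute. Second, the map can hold coexisting annual
attractors in rare cells (well below 1% on the bundled synthetic worlds),
where the month the simulation starts in selects the attractor; the annual
mean is phase-invariant everywhere else. Both are properties of explicit
seasonal plant-growth models generally, not of this implementation.

A species is exactly 18 numbers: four breakpoints each for the three
trapezoids (nitrogen uptake vs temperature, nitrogen uptake vs moisture,
carbon uptake vs moisture), the two shoot-nitrogen constants, and four
breakpoints for growth vs temperature. Everything else is universal
(`ttr_constants()`): $\sigma_N = 0.05$, $k_g = 25$, transport resistances
1, $f_C = 0.45$, $f_N = 0.02$, litter rates 0.05/month, $k_B = 10$ amu.
These were fixed once so that (i) a nontrivial equilibrium exists, (ii)
trajectories converge in a few dozen annual cycles, and (iii) the
carbon-limited branch, not the nitrogen-limited branch, typically sets the
equilibrium — mirroring the intended role of the CO2-sensitive uptake
ceiling. Mean temperature drives the temperature responses; minimum and
maximum temperature enter only through evapotranspiration.

### The universal uptake ceiling

Potential carbon assimilation is colimited by light, temperature and CO2 in
a Farquhar-like minimum form, with one parameterization per photosynthetic
pathway:

$$A_{\max} = 0.6\, e^{-((T - T_{\mathrm{opt}})/s)^2} \cdot
\min\!\Big(1 - e^{-R/10},\; \frac{\mathrm{CO_2}}{\mathrm{CO_2} + K}\Big)$$

with $T_{\mathrm{opt}} = 22$, $s = 14$, $K = 300$ ppm for C3 and
$T_{\mathrm{opt}} = 30$, $s = 13$, $K = 40$ ppm for C4. The qualitative
contracts are what matter: zero radiation means zero uptake; the C3 rate
rises (saturating) with CO2, so fertilization can only help C3 species; the
C4 rate is nearly CO2-saturated above ~400 ppm and peaks at warmer
temperatures. The ceiling is shared by all species of a pathway; species
can only reduce it through their moisture and shoot-nitrogen dependencies.

## Species fitting

Presences are thinned to one record per cell, capped at 400 by a stratified
sample conserving the proportions of 20 environmental zones
(largest-remainder apportionment), and paired with as many pseudo-absences
as presences — drawn with zone probabilities inversely proportional to the
zone's share of the presence sample, so zones where the species is common
are rarely declared absent. Zones absent from the presence sample receive
the minimum observed presence proportion before inverse weighting (the
inverse rule is undefined at zero). Species with fewer presences than zones
get exactly 20 pseudo-absences. At least 7 presences are required.

The environmental zones come from CLARA k-medoids on standardized monthly
forcing features, refined by a single reassignment pass of a discriminant
analysis on principal components (cells move to the zone of highest
discriminant posterior). A single pass was chosen over iterating to
convergence: it is deterministic, cheap, and in practice moves only
boundary cells.

Candidate parameter vectors are scored by the Bernoulli log-likelihood of

$$p = 1 - \exp(-\exp(\beta_0 + \beta_1 \ln(B + \varepsilon)))$$

at the sample cells, with $(\beta_0, \beta_1)$ profiled per candidate by an
inner Newton solver and $\varepsilon = 10^{-6}$ amu guarding $B = 0$.
Profiling estimated coefficients (rather than the literal $\eta = \ln B$)
is the statistically standard reading of a suitability regression; the
search is over the 18 growth-model parameters only.

The optimizer is Differential Evolution with binomial crossover
(local-to-best mutation, F = 0.8, CR = 0.5), elitist selection, reflection
at the box bounds, and 1000 generations at full scale (reducible for small
studies; every reduction is recorded in the run manifest). Trapezoids are
encoded as a lower breakpoint plus three non-negative widths, so every
candidate is automatically ordered. The initial population is data-informed:
niches are centered on the climates of randomly chosen presence cells.
Without this, most random 18-vectors describe species that can grow
nowhere in the sample, the likelihood surface is flat there, and the search
wastes generations escaping the dead plateau; initializing on presences is
standard practice and does not bias the profiled likelihood. Search bounds
derive from the forcing envelope plus a 25% margin.

After the search, the binarization threshold maximizes true positives plus
true negatives over candidate cutoffs (observed scores plus midpoints; ties
break to the lowest cutoff, for determinism), and the TSS
(sensitivity + specificity - 1) is computed from the resulting confusion
matrix. Models with TSS <= 0.7 are flagged rejected and excluded from the
transform.

## Zones, threshold and risk indices

Growth-form suitability is a plain fraction: of the accepted models of form
$k$, how many mark cell $i$ suitable. Cells are clustered with `mclust`'s
"VEV" Gaussian mixture family (18 components at full scale; the mixture's
BIC scan is exposed for smaller studies). Degenerate synthetic surfaces
(many identical vectors) can make the likelihood unbounded, so a small
seeded jitter (sd 1e-4) is added for estimation only; centroids are
recomputed on the unjittered data.

The significance threshold is the 5th percentile (linear interpolation
between order statistics — the conventional definition, stated here because
percentile conventions differ) of the $k(k-1)/2$ pairwise centroid
distances: an index value above it is comparable to a shift between
phytoclimatic zones. Novelty and disappearance share this threshold by
default; it is configurable.

All three indices use plain Euclidean distance over growth-form
suitability components. The novelty/disappearance pools are *all* land
cells globally, including the focal cell's own counterpart, which gives the
invariants `novelty <= change` and `disappearance <= change` cellwise;
these are asserted on every synthetic run. Minimum-distance searches are
evaluated in exact blocked linear algebra — no approximate nearest
neighbour — so they equal the brute-force $O(N^2)$ scan to machine
precision. Future cells take the zone of their nearest ambient cell (ties
to the lowest cell index) unless their novelty exceeds the threshold, in
which case they are designated novel. Pseudo-GCM ensembles are summarized
by cellwise medians, both at the suitability level (feeding zone
assignment) and at the index level (feeding risk maps).

## The synthetic world

`generate_climatology()` emulates the structure of a gridded climate
product on an equal-area grid: mean temperature falls poleward
(0.5 degC per degree of the latitude proxy) with seasonal amplitude rising
poleward, smooth spatial noise, positive diurnal-range offsets, spatially
autocorrelated annual precipitation (lognormal around ~1100 mm with a
longitudinal gradient) with cosine seasonality, radiation a deterministic
function of latitude band and month, autocorrelated soils with
$wp \le fc$, and a smooth land mask (85% land by default). Ambient CO2
defaults to 338 ppm; future scenarios use 438 ppm (reduced emissions) and
677 ppm (high emissions), a uniform warming plus seeded spatially smooth
pseudo-GCM noise, a multiplicative precipitation factor, and unchanged
radiation and soils.

Virtual species have known 18-parameter truth. Growth forms carry
form-level niche centers with species scattered around them, so species of
a form cluster in climate space — the property that makes growth-form
surfaces meaningful and subsampling stable. Occurrences are sampled only
from truly suitable cells (one per cell), so a perfect refit would reach
TSS = 1 against truth; an optional bias mode thins records outside a random
well-sampled region, emulating herbarium bias. A rejection loop with
adaptive niche widening/narrowing keeps each species' suitable fraction
inside a target prevalence band.

What the generator does *not* emulate: real climate physics (fronts,
orography, teleconnections), observation error in occurrences, taxonomic
misassignment of growth forms, or dispersal-limited realized distributions.
Passing tests therefore demonstrate the internal consistency and
recoverability of the method under its own assumptions, not predictive
skill on real data.

## Study sizes used by the tests and the acceptance run

The bundled tests run the full pipeline at desk scale, chosen once as the
smallest sizes at which every stage is scientifically non-degenerate: a
30 x 30 world (~765 land cells) with 20 virtual species, 200 unbiased
presences each, Differential Evolution at 200 generations with population
24; zone models use 8 components there (18 needs more cells than a desk
grid provides). The subsampling-stability check uses 336 species (24 per
form, true-parameter maps) on a 24 x 24 world. The acceptance script runs
the same fitted study plus a null scenario and two five-member pseudo-GCM
ensembles. At these sizes a full test run and the acceptance script each
take on the order of ten minutes on one CPU.

## Known limitations

* The exact transport-resistance equations and the Farquhar
  parameterization are package-defined concrete forms satisfying the
  documented qualitative contracts; they are not calibrated against field
  measurements, and absolute biomass is in arbitrary units.
* Binarization thresholds and calibrations are estimated on the fitting
  sample and reused unchanged for future projections, so calibration drift
  under extrapolation is not modelled.
* Pseudo-absence contamination bounds attainable sample TSS for
  high-prevalence species; the acceptance filter is therefore conservative
  for widespread species.
* Zone counts at desk scale are far below the full-scale 18; intercentroid
  thresholds are correspondingly coarser.
* No snow storage, multi-layer soils, vegetation feedback on
  evapotranspiration, competition, or dispersal.
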
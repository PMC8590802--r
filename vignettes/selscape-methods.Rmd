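---
title: "Methods: two-level habitat selection and circuit-theory connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-level habitat selection and circuit-theory connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`selscape` implements a complete habitat-selection and connectivity workflow
of the kind used to study recolonizing carnivores (the motivating system is
an expanding bobcat *Lynx rufus* population in a mixed agricultural
landscape): a population-level resource selection function (RSF) fitted to
verified sightings, an individual-level RSF fitted to GPS telemetry within
kernel home ranges, and a circuit-theory connectivity model parameterized by
the population-level suitability surface and validated with locations of
likely dispersers. Because the original inputs (a 30 m land-cover raster,
road networks, collar data) are large and external, the package pairs every
stage with a seedable synthetic generator whose selection coefficients are
known, so the whole pipeline can be exercised end to end against ground
truth.

## Population-level selection

Verified sightings are treated as presences and contrasted with
pseudo-absences drawn uniformly outside an exclusion buffer around every
presence, at a 4:1 availability ratio. The buffer radius is the radius of a
circle with the area of the mean home range: for 99.7 km² that is
$\sqrt{A/\pi} = 5{,}633$ m, rounded to 5,600 m. Covariates are
moving-window land-cover proportions at 7, 15, 30 and 50 km² (square
windows with edge $\sqrt{A}$ — the 7 km² window has a 2.64 km edge — rounded
to an odd cell count so the window centers on a cell), Euclidean distance
to high-traffic roads, and road density. Covariates are centered and scaled
before modeling, and pairs with Pearson $|r| > 0.7$ are flagged and dropped
from a common model.

Candidate models are binomial GLMs (logit link)
$\operatorname{logit} P(y{=}1\mid x) = \beta_0 + \beta^\top x$, ranked by
the small-sample Akaike criterion
$\mathrm{AICc} = -2\ell + 2k + 2k(k{+}1)/(n{-}k{-}1)$ with $n$ the number
of use–availability rows. Models within 2 AICc units of the best are
averaged with renormalized Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$, giving a per-cell
suitability $H = \sum_m \tilde w_m\, p_m \in [0,1]$. Fit is summarized by
the rank-statistic (Mann–Whitney, tie-corrected) AUC and by repeated 95/5
cross-validation scored as classification accuracy at probability 0.5 —
the threshold is a package decision, since "predictive ability" admits
several readings and only a single accuracy summary is conventionally
reported.

A deliberate design choice: the candidate model set is supplied in the run
configuration rather than hard-coded, constrained by the rule that the same
land-cover variable never enters one model at two scales (the multi-scale
versions of one proportion are nearly collinear).

## Individual-level selection

Residents are individuals with more than 30 fixes and no disperser flag.
Each animal's home range is the 95% isopleth of a bivariate
product-Gaussian kernel density estimate with per-axis reference bandwidth
$h = \hat\sigma\, n^{-1/6}$, evaluated on a grid extending four bandwidths
past the fixes at ≥200×200 resolution; the isopleth is the smallest set of
cells reaching 0.95 of the density mass, so its mass overshoots 0.95 by at
most one cell. The bandwidth rule is the package's own choice — the
ecology default and deterministic — because no estimator is uniquely
standard. Availability is sampled uniformly within the isopleth, one
available point per fix.

Selection is estimated from the pooled used/available data with a weighted
binomial GLM. "Distribution weighting" gives each of the $I$ animals equal
total weight ($w = N/(I n_i)$ per row of animal $i$), the most common
reading of weighting "by the individual animals"; with equal weights the
fit reduces exactly to the pooled fit, and duplicating rows while halving
their weights is a no-op — both identities are tested. The exponential RSF
form scores relative selection $w(x) = e^{\beta^\top x}$ with the
intercept absorbed; the logistic RSPF form returns absolute selection
probabilities. Forms (and weighting schemes) are compared by consistent
AIC, $\mathrm{CAIC} = -2\ell + k(\ln n + 1)$, which exceeds AIC whenever
$n \ge 8$. Relative selection strength is displayed as the use curve:
fitted values at *available* points against one covariate with a loess
smooth (span 0.75, degree 1). Because it averages over the availability of
the other covariates, the curve legitimately changes when availability
changes; it shows probability of use, not of selection.

Group contrasts of home-range area (sex, study area) use the
Kruskal–Wallis rank test with tie correction. The package ships a
*synthetic* 20-animal home-range table (`synthetic_homeranges()`)
reconstructed from published group summaries of the motivating system —
the individual rows are invented, but group means (27.27 vs 69.79 km² by
sex; 79.23 vs 28.73 km² by study area) and the rank structure implied by
the published test statistics (H = 6.477 and 5.841) are reproduced
exactly; the statistics depend on the data only through rank sums, which
are integers and therefore recoverable.

## Connectivity

Suitability becomes resistance through
$$R \;=\; 100 - 99\,\frac{1 - e^{-cH}}{1 - e^{-c}},$$
with exponents $c = 2$ (intermediate) and $c = 8$ (resistance drops
sharply at low suitability), plus a linear variant mapped onto the same
range, $R = 100 - 99H$, so all three maps share the $[1, 100]$ scale
before averaging. Both transforms send $H{=}0 \mapsto R{=}100$ and
$H{=}1 \mapsto R{=}1$ and are strictly decreasing.

The landscape is a conductive surface: one graph node per valid cell,
8-neighbor edges with conductance the arithmetic mean of the two cells'
conductances $1/R$, diagonals scaled by $1/\sqrt2$ (the documented default
of the standard circuit-theory connectivity software for conductance
averaging). For each unordered pair of node regions, the regions are
contracted to super-nodes, one is grounded, unit current is injected at
the other, and node potentials solve the reduced graph Laplacian (sparse
Cholesky; the reduced system is symmetric positive definite). Per-cell
current density is half the sum of absolute incident edge currents;
region-member cells are reported with the full current they carry into
the network. Effective resistance is the potential difference per unit
current. The solver is verified against series/parallel closed forms, a
dense Moore–Penrose pseudoinverse oracle on random graphs, current
conservation at interior nodes, Rayleigh monotonicity, and scaling
invariance.

The cumulative map sums the ten pairwise maps of the five node regions and
is displayed as equal-count deciles over cells with positive current
(zero-current cells are left unclassified — whether the original
quantiles included them is unknowable, and positive-only binning keeps
bin 10 meaningful in sparse-flow landscapes).

## Disperser validation

Each candidate disperser location (a "1") is matched with three uniform
points in a 5 km disc ("0"s); each point gets the decile of each candidate
map. Per map, a random-intercept (location) logistic GLMM of used on
decile is estimated by Laplace approximation ($k = 3$; a 7-node adaptive
Gauss–Hermite cross-check must agree in log-likelihood within 0.05, and a
fit with negligible random-effect variance must match the plain logistic
likelihood — both are tested). AICc uses the number of rows. Akaike
weights over the three models weight the final map average; maps are first
normalized to unit mean over valid cells because raw current maps from
different resistance scales are not commensurable (the original
normalization is unstated; unit-mean is the package's choice and is
order-invariant and identity-preserving for a single map).

## The synthetic generator

What it emulates: a spatially autocorrelated multi-class land-cover mosaic
(a smoothed Gaussian random field thresholded at quantiles matching target
proportions — rank-transformed so realized proportions are exact up to
ties); through-going roads in two traffic classes and streams; presences
drawn cell-wise with weight $\operatorname{logit}^{-1}(\beta_0 +
\beta^{*\top} x)$; per-animal telemetry from a bivariate-normal
home-range kernel thinned by $e^{\beta^{*\top}x}$; dispersers drawn with
probability $\propto \text{current}^{\text{preference}}$.

The generative intercept defaults to −12 so presence weights sit deep in
the rare-event regime where $\operatorname{logit}^{-1}(\eta) \approx
e^\eta$ (relative weight distortion below $10^{-3}$ over the default
coefficient range — a shallower intercept leaves a visible downward bias
in the strongest slope, since $\log \operatorname{logit}^{-1}(\eta) =
\eta - \log(1+e^\eta)$); then the use–availability logistic slope
estimand equals $\beta^*$ and
Wald 95% intervals achieve nominal coverage — verified at 200 replicate
draws (2,000 presences, 4:1) on a 500×500 landscape. The
default disperser preference is 2 (moderate corridor concentration);
validation power is demonstrated at preference 4.

What it does not emulate: real movement autocorrelation (fixes are
conditionally independent given the home range), observer effort bias in
sightings, temporally varying land cover, and road-crossing behavior.
Passing tests therefore demonstrate the estimators' correctness under the
stated sampling models, not robustness to those field realities.

## Numerical and scale choices

* Grids are row-1-south internally with half-open cells; all units are
  meters and km². ESRI ASCII files (north-first) are flipped on read/write.
* Moving windows are square (the published 7 km² ↔ 2.64 km edge arithmetic
  is exactly $\sqrt{7}$ km, which fixes the shape), truncated at the grid
  boundary with proportions over available cells.
* Distances are exact Euclidean distance transforms (two-pass parabolic
  envelope), center-to-rasterized-feature, cross-checked against a
  brute-force nearest-source scan.
* The default synthetic extent is 200×200 cells at 30 m for pipeline runs
  and 500×500 for the parameter-recovery suite; unit fixtures are smaller.
  Extent-dependent distances (pseudo-absence exclusion, disperser disc)
  scale with the synthetic extent in `synthetic_run_config()`, while
  `default_run_config()` records the full-scale study constants.
* One master seed spawns per-stage seeds; identical (config, seed) gives
  byte-identical artifacts, which is asserted on file hashes.

## Known limitations

* The weighted GLM's standard errors treat weights as frequency weights;
  for the distribution weighting this is the conventional, slightly
  anti-conservative choice (no sandwich correction).
* The exponential RSF is estimated through the use–availability logistic
  surrogate; its intercept is a nuisance tied to the availability ratio.
* KDE home ranges ignore temporal autocorrelation (no aKDE), matching the
  emulated design rather than current best practice.
* The circuit solver targets planar grid graphs; it is exact but not tuned
  for very large extents (no preconditioned iterative fallback is needed at
  the package's design sizes).
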
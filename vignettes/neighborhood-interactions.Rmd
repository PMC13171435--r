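---
title: "Quantifying pairwise and higher-order neighbourhood interactions in forest censuses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pairwise and higher-order neighbourhood interactions in forest censuses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Conspecific negative density dependence — the tendency of conspecific
neighbours to depress a focal tree's growth and survival more than
heterospecific neighbours — is a leading candidate mechanism for the
maintenance of local tree diversity and for the latitudinal diversity
gradient. Classical neighbourhood analyses assume that trees interact in a
strictly pairwise fashion. `hoiforest` implements a neighbourhood framework
in which pairwise interactions can themselves be modified by third parties:
a *higher-order interaction* (HOI) is the effect of an initiator $k$ on a
receiver $i$ transmitted through a neighbour $j$, with coefficient
$\beta_{ijk}$. The package estimates both interaction layers from standard
two-census mapped stem data, asks when the higher-order layer is
statistically warranted, and summarises how the cumulative neighbourhood
effect varies with species abundance and latitude.

## Demographic models

For a focal tree $f$ of species $i$, annualised diameter growth follows a
power law in size multiplied by exponential neighbourhood terms:

$$\mathrm{Growth}_{i_f} = G_i \, \mathrm{DBH}_{i_f}^{\gamma}\,
  e^{\mathrm{Pair}_{i_f}}\, e^{\mathrm{HOI}_{i_f}},$$

which we fit after log transformation as an ordinary least squares
regression of $\log(\mathrm{growth})$ on $\log(\mathrm{DBH})$ and the
crowding indices. $G_i$ is the potential growth rate in the absence of
neighbours and $\gamma$ the size scaling. Interval survival is a logistic
regression

$$\operatorname{logit} P(\text{survive}) = \lambda_i
  + \gamma_1 \mathrm{DBH}^{-1} + \gamma_2 \mathrm{DBH}
  + \gamma_3 \mathrm{DBH}^2 + \mathrm{Pair}_{i_f} + \mathrm{HOI}_{i_f},$$

with $\mathrm{DBH}^{-1}$ capturing the rapid drop of mortality with size in
small stems and the linear/quadratic terms the U-shaped senescence effect.
Note the orientation: we place the linear predictor on the log-odds of
*surviving*, so a negative interaction coefficient always means a
performance cost, for growth and survival alike. (Written with the linear
predictor in the denominator exponent instead, the sign reading of the
survival coefficients would invert; we prefer one consistent competitive
reading of $\alpha<0$ across both responses, and the package documents its
coefficients under that convention.)

The neighbourhood terms decompose into conspecific and heterospecific
parts,

$$\mathrm{Pair}_{i_f} = \alpha_{ii} n_{i,i_f} + \alpha_{ih} n_{h,i_f},
\qquad
\mathrm{HOI}_{i_f} = \beta_{iii} n_{ii,i_f} + \beta_{iih} n_{ih,i_f}
 + \beta_{ihi} n_{hi,i_f} + \beta_{ihh} n_{hh,i_f},$$

where heterospecific neighbours are pooled under a single mean-field
coefficient $\alpha_{ih}$ rather than a per-pair interaction matrix — with
dozens of rare neighbour species per focal species, species-specific
heterospecific coefficients are not estimable from plot data.

## Crowding indices

A neighbour $j$ within radius $r$ of the focal stem contributes
$\mathrm{DBH}_j^{a} / d_{fj}^{b}$, directly proportional to its size and
inversely proportional to its distance; $n_{i,i_f}$ and $n_{h,i_f}$ sum
these contributions over conspecific and heterospecific neighbours. For
the higher-order indices, each transmitter's contribution is additionally
weighted by the transmitter's *own* crowding, split by the initiator's
identity relative to the focal species: $n_{ii}$ and $n_{ih}$ weight
conspecific transmitters by their crowding from focal-species and from
other stems respectively, and $n_{hi}$, $n_{hh}$ do the same for
heterospecific transmitters. This makes the subscript semantics of
$\beta_{ijk}$ exact: the middle index is the transmitter's identity, the
last the initiator's, both read relative to the receiver.

Defaults and their reasons:

* `radius = 10` m. Crown and root competition among stems down to 1 cm
  DBH acts over roughly this scale; the kernel is configurable so
  robustness across radii is a one-line change.
* `size_exponent = 1`, `distance_exponent = 1`. The kernel family
  $\mathrm{DBH}^a/d^b$ covers the common dialects (e.g. basal-area
  weighting $a=2$, squared-distance discounting $b=2$).
* `min_distance = 0.1` m. Distances are clamped from below so co-located
  stems (coordinate rounding, multi-stem clumps) never contribute
  unbounded crowding.
* `exclude_focal = TRUE`. The focal stem is removed from its
  transmitters' crowding, so a tree never initiates a higher-order effect
  on itself. The alternative is available for sensitivity analysis.
* `standardize = FALSE`. Optional within-species standardization of each
  index is provided for cross-species comparability of coefficients, but
  raw indices are the default because they keep recovery of generative
  parameters exact.

**Edge policy.** A focal stem within $2r$ of a plot border is flagged
non-interior and excluded from model fitting: within $r$ its own
neighbourhood is truncated, and between $r$ and $2r$ its transmitters'
neighbourhoods are. All stems, interior or not, still act as neighbours
and initiators. No toroidal wrapping is applied to observed data.

**Computation.** The whole-plot computation is a blocked matrix
formulation: one pass accumulates each stem's crowding received from every
species, a second pass assembles the four higher-order sums per focal
stem, subtracting the focal's own contribution from each transmitter's
crowding where required. It is algebraically identical to the
definitional per-focal loops (`pairwise_indices()`,
`higher_order_indices()`), and the test suite verifies agreement to
within $10^{-10}$ relative against independent exhaustive-loop oracles.
Quantities that are differences of accumulated sums (e.g. heterospecific
crowding as total minus conspecific) are clamped at zero to keep exact
zeros exact.

## Model classes, AIC support, and derived summaries

Three nested classes are fitted per species, plot and response: *null*
(size terms only), *pair-only* (adding $n_i$, $n_h$) and *HOI-inclusive*
(adding the four higher-order indices). Pairwise coefficients from the
pair-only class are *modified* coefficients — they absorb whatever
higher-order structure exists — while those from the HOI-inclusive class
are *true* coefficients with the higher-order layer isolated. A class is
considered supported only when its AIC is at least two units below every
simpler alternative; ties and near-ties collapse to the simpler model.
AIC counts all free parameters, including the Gaussian residual variance
of the growth model.

Species enter the growth analysis with more than 100 linked trees, and
the survival analysis with additionally at least 20 survivors and 20
deaths. Within a species, growth fits use interior surviving stems with
positive recorded growth; survival fits use all interior stems.

Degenerate designs (an index constant across a species' stems, or exact
collinearity) are handled by dropping the offending columns and flagging
the fit rather than failing, so whole-plot batch runs always complete;
flagged fits are excluded from downstream gradient regressions.
Quasi-separated survival fits fall back to a lightly ridge-penalised
logistic regression ($\lambda = 10^{-3}$ on non-intercept terms) with a
warning.

Observed-versus-predicted correlations are computed in sample: the three
classes are nested least-squares/likelihood fits on identical data, so
in-sample correlations order exactly as the model hierarchy does and the
paired comparison across species measures how much signal each layer
adds. Cross-validated variants can be layered on top by the user but are
not part of the core summaries.

**Latitudinal gradients.** Exponential relationships between coefficient
magnitude and absolute latitude are fitted as OLS of $\log|\hat\theta|$
on latitude, separately for competitive ($\hat\theta<0$) and facilitative
($\hat\theta>0$) subsets (zeros excluded; every non-zero estimate enters
exactly one subset). This log-linear reading reproduces the usual
$t$/df structure of exponential regressions and makes the slope a decay
rate per degree. Species are weighted equally; precision weighting is
deliberately not applied because the estimate-level standard errors are
themselves strongly size-dependent and would concentrate the fit on a
few large-sample species. Plot-level displays use the mean ± s.e.m. of
species estimates per plot. Plot richness per hectare is the mean species
count over non-overlapping 100 m × 100 m quadrats (falling back to total
richness divided by area for plots smaller than one quadrat, also
available as an explicit estimator choice).

**Cumulative effects.** For each focal tree the fitted neighbourhood
multipliers are $e^{\mathrm{Pair}}$ and $e^{\mathrm{HOI}}$; species-level
$\mathrm{RC}$ statistics are their means over the species' interior trees,
using the true (HOI-inclusive) coefficients for *all* growth-eligible
species regardless of support class, so the species set is not selected on
the statistic being modelled. Natural logarithms are used throughout.
$\log \mathrm{RC}$ is then modelled on log abundance (census-1 main stems
per hectare), absolute latitude and their interaction; a negative
abundance coefficient is the stabilization signature (rare species
benefit, common species are suppressed) and a positive interaction means
that signature weakens with latitude. Zone predictions evaluate the
fitted model at the middle latitudes of the tropical (11.75°),
subtropical (29.25°) and temperate (45°) belts with pointwise 95%
confidence bands; with a zero interaction coefficient the three curves
are exactly parallel.

## The synthetic forest generator

`simulate_network()` emulates the observational design the estimators are
meant for: plots spread over a latitude span (default 2–61° absolute),
species richness declining as $S_0 e^{-k|L|}$ (defaults $S_0 = 30$,
$k = 0.03$/degree), log-series abundances, Thomas-process stem positions
with monospecific clusters (parents at ~8 stems per cluster, 8 m
dispersion, toroidally wrapped so intensity stays homogeneous),
truncated-lognormal DBH (median 3 cm, log-sd 0.7, minimum 1 cm), and a
5-year census interval. Growth and survival are drawn from exactly the
demographic models above — lognormal multiplicative growth noise
(log-sd 0.5) and one Bernoulli survival draw per stem over the interval —
with per-species coefficients whose magnitudes decay exponentially with
latitude and whose signs split evenly between competitive and
facilitative. Default magnitude scales at the equator are
$\alpha_{ii} = 0.08$, $\alpha_{ih} = 0.04$ and higher-order scales of a
few $10^{-4}$ (higher-order indices are products of two crowding sums and
run two orders of magnitude larger than pairwise ones); intraspecific and
conspecific-linked types decay at 0.05/degree, heterospecific-linked ones
are flat. The baseline survival logit (1.5 ± 0.3) yields interval
survival around 0.8–0.85, i.e. 3–4% annual mortality, typical of stems
≥ 1 cm. Stem density defaults to 700/ha — a deliberately thinned stand so
that desk-scale simulation studies run in minutes.

What the generator does *not* emulate: recruitment (census-2 recruits are
simply absent), habitat heterogeneity and spatially autocorrelated
environments, measurement error in DBH, species-specific (non-mean-field)
heterospecific coefficients, and any nonlinearity in how initiators
modify pairwise effects. Passing calibration tests on these forests
therefore demonstrates that the estimators are correct and well
calibrated *under the model's own assumptions* — not that those
assumptions hold in any particular real forest.

## Calibration studies and chosen problem sizes

The package ships simulation studies used by its acceptance tests:

* **Parameter recovery** (`growth_recovery_study()`,
  `survival_recovery_study()`): a fixed design of 2,000 interior stems of
  one focal species (a 9-ha plot at 1,000 stems/ha, three equally
  abundant species), with growth noise or survival outcomes redrawn 200
  times. Conditioning on a fixed design isolates estimator calibration
  from spatial sampling; t-based (growth) and Wald (survival) 95%
  intervals then cover the truth at their nominal rate and relative
  biases stay within Monte Carlo error of zero. For this design the
  higher-order magnitudes are set a few-fold above the network defaults
  so that a 5% relative bias is resolvable against the Monte Carlo error
  of 200 replicates.
* **AIC support rates** (`aic_support_study()`): on the same design, with
  the higher-order layer removed from the truth the two-unit rule
  supports the HOI class in only a few percent of replicates (the rule's
  false-support rate; theoretically $P(\chi^2_4 > 10) \approx 4\%$),
  while with the strong higher-order layer present support is nearly
  certain.
* **Gradient contrast** (`gradient_contrast_study()`): 50 replicate
  networks of 20 plots (130 m plots, 700 stems/ha, 4 equally abundant
  species, all-competitive signs), intraspecific magnitudes decaying at
  0.05/degree and interspecific flat. The study regresses the pair-only
  (modified) pairwise estimates: in this network every
  conspecific-linked coefficient type shares the intraspecific decay and
  every heterospecific-linked type the interspecific one, so modified
  coefficients carry the identical contrast, and they avoid the variance
  inflation that the strong collinearity between $n_i$ and the
  higher-order indices causes for pairwise coefficients inside the
  HOI-inclusive fit (which would attenuate the fitted slope toward the
  estimation-noise floor at high latitude). `model_class = "hoi"`
  reproduces the attenuated variant for comparison.
* **RC recovery** (`rc_recovery_study()`): species-level records drawn
  from a known four-term model (abundance slope −0.8) and refitted, 200
  replicates of 300 species.

## Numerical and degenerate-input conventions

* Non-positive annualised increments (shrinkage, measurement noise) are
  replaced by a configurable floor, 0.01 cm/yr by default, before the log
  transform; the count is reported, and a `drop` policy is available.
  The floor is a tenth of a typical slow-growth rate and keeps shrinking
  stems in the fitted population instead of silently selecting them out.
* Multi-stem trees are reduced to the largest census-1 stem, ties broken
  by stem id; stems absent from census 2 count as deaths; census-2 stems
  with no census-1 match must be flagged recruits, otherwise linking
  aborts with a consistency error.
* Exponential latitude fits with fewer than 3 values in a sign subset
  return a no-fit record with a reason rather than an estimate; subsets
  whose magnitudes are exactly constant return slope 0 with $p = 1$
  rather than floating-point noise.
* All simulation is deterministic given integer seeds; network plots use
  seeds derived from the network seed by fixed offsets.

## Limitations

Growth and survival are modelled separately, so covariation of their
neighbourhood responses is not captured; recruitment is outside the
scope; the mean-field pooling of heterospecific effects hides pairwise
structure among heterospecifics; and the linear (in the index) form of
the higher-order modification is an assumption, not a finding. Gradient
regressions treat species estimates as exchangeable within sign subsets
and do not model estimation uncertainty in the dependent variable.
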
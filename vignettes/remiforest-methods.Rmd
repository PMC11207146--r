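---
title: "Methods: remittance-mediated forest recovery under PES programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: remittance-mediated forest recovery under PES programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remiforest)
```

## The scientific problem

Payments-for-ecosystem-services (PES) reforestation programs compensate
rural households for retiring cropland into forest. Retiring land frees
farm labour; households send out-migrants to cities; migrants may remit
money home; remittance can replace income otherwise extracted from nearby
forests. If that chain holds, part of the program's socioeconomic and
ecological outcome is *additional* — it would not occur with migration
alone. `remiforest` implements the estimators for each link of the chain
and a synthetic data generator that makes them testable end to end.

## The models

**Sending remittance.** For migrant $i$ in resident group $c$,

$$\Pr(y_{ic}=1 \mid x_{ic}, u_c) = \mathrm{logit}^{-1}(x_{ic}'\beta + u_c),
\qquad u_c \sim N(0, \sigma_u^2),$$

fitted by adaptive Gauss–Hermite quadrature (15 points by default;
`nAGQ = 1` falls back to the Laplace approximation) with sampling weights.
The intraclass correlation uses the logistic residual variance $\pi^2/3$:
$\mathrm{ICC} = \sigma_u^2 / (\sigma_u^2 + \pi^2/3)$.

**Remitted amount.** Among senders only (a hurdle-style separation; zero
amounts are never imputed), the log10 amount follows a random-intercept
linear model. Amounts live on the log10 scale throughout the package —
the additionality estimator exponentiates with base 10 and effects read
as "per 10-times increase" — so the two stages share one scale. Maximum
likelihood is the default (REML via a flag) so AIC/BIC comparisons across
fixed-effect sets are valid; a difference of more than 10 flags the
lower-valued model as favoured.

**Marginal effects.** For the logistic model the effect of covariate $j$
is $\beta_j \int p(1-p)\,\phi(u/\sigma_u)\,du$, the population-averaged
derivative, computed by Gauss–Hermite integration and evaluated at
covariate means; standard errors come from the delta method over the
fixed effects (uncertainty in $\sigma_u$ is not propagated — a known
simplification). The payment covariate is cumulative program payment in
thousand Yuan, so effects read "per additional 1,000 Yuan". The weighted
bootstrap resamples *households* (clusters) with probability proportional
to their sampling weight and refits, erroring when more than 20% of
replicates fail.

## Buffer metrics

Forest change around a house is the difference of area-weighted forest
proportions between the survey year and the program start, and greenness
change the difference of area-weighted mean EVI over forested cells, with
cell weights equal to the fraction of the cell inside the buffer. Cells
with less than 0.5% overlap are excluded before renormalisation (the
threshold is applied to the raw fraction, a declared choice). The
as-typeset change formula is read as a difference of *weighted
proportions*: an unnormalised second term would leave the metric outside
$[-1, 1]$.

Weights are computed by a closed-form circle/axis-aligned-rectangle
intersection area (inclusion–exclusion over corner integrals of
$\sqrt{r^2 - t^2}$), exact to floating point and fully vectorised. A
polygonal approximation of the circle was considered and rejected: the
closed form is faster and removes the approximation error entirely; a
100×100 supersampling oracle is retained in the tests. Ring buffers
around convex resident-group polygons use a point-to-polygon distance
kernel subsampled at 16×16 midpoints per cell; a cell straddling a ring
boundary legitimately carries fractional weight in *both* rings, and the
tests assert that ring weights partition the full dilation weight.
Missing EVI under forest drops that cell from both numerator and
denominator of that time point's term; a time point with zero forested
weight yields a missing (not zero) EVI change.

## Matching, treatment effects, associations

Propensity scores come from a logistic regression of remittance receipt
on the covariate block; accuracy is the share of households whose
thresholded score reproduces their observed state. Each control is
matched to the nearest-score treated household within the caliper;
treated households are reusable and carry weight one over their
multiplicity; score ties break on the smallest household id so matching
is invariant to row order. The default caliper is 0.05 on the probability
scale with a 0.01–0.10 sensitivity grid.

The pairwise bootstrap draws 60% of the pairs *with replacement* (the
sources describe the scheme as both a "subset" and "with replacement"; a
without-replacement mode sits behind a flag) and evaluates three
directional hypotheses per replicate: H1 (paired difference > 0), H2
(treated > 0), H3 (control $\le$ 0, scored separately as significant
negative and as non-significant). All tests are two-sided at
$\alpha = 0.05$ with the direction checked — a replicate counts for H1
only if $p < 0.05$ *and* the difference is positive. Replicate t-tests
weight treated values by the matching multiplicity weights with the Kish
effective sample size as degrees of freedom; ignoring the weights
double-counts reused treated households and inflates the null occurrence
severely. The OLS remittance–forest association uses the same bootstrap
and the same directional scoring ($p < 0.05$ and slope positive); the
sign-blind rate is also reported (`occurrence_any`), but note that it has
an elevated null baseline (~12%) purely because bootstrap replicates of
one dataset are correlated with that dataset's realised effect.

Group-level associations regress ring-buffer change on log10 group
remittance; outliers are points with |studentised residual| > 3 (the
display convention of grey "all points" vs red "excluding outliers"
lines), a declared choice since no rule is stated in the sources.

## Additionality

$$G_{Econ}\% = \frac{\sum_i 10^{\hat\beta M_i P_i / 1000}}{\sum_h P_h}
\times 100\%,\qquad
G_{Ecol}\% = \frac{\sum_h \hat\gamma \, L_h \, A}{\sum_h P_h / \lambda}
\times 100\%,$$

with $M_i$ migration years, $P_i$ the annual payment attributed to
migrant $i$ (by default the household's payment — how a household's
payment allocates to individual migrants is unstated, and an equal-split
mode is configurable), $L_h$ the log10 of the household's attributable
remittance $\sum_{i \in S_h} 10^{\hat\beta M_i P_i/1000}$ (an
observed-totals mode exists), $A$ the buffer area (default the 100 m
disc, the radius where effects concentrate) and $\lambda$ the per-site
payment rate. Only migrants from participating households enter the
numerator: the literal formula would award $10^0 = 1$ Yuan of
"stimulated" remittance to every non-participant (a literal mode is
available). The formula's units are internally loose (a $10^{\cdot}$
quantity over a Yuan/year flow); it is implemented as printed.
Households whose attributable remittance is an extreme outlier among
receivers (z-score > 10 by default; the motivating survey excluded one
case at 21.05) are dropped. Bounds take $\hat\beta \pm \hat\sigma_\beta$,
and for $G_{Ecol}$ multiply the lower (upper) limits of both estimators.
National scaling is purely multiplicative against supplied program totals
(investment, enrolled area), reported in Yuan (6.22 Yuan/US$) and ha.

## The synthetic generator

`generate_scenario()` draws, from a single master seed with fixed
per-stage substreams: two sites (a semi-arid and a subtropical one), 63
resident groups (22 + 41) with households scattered around group centres
(s.d. 200 m), 458 migrant households and exactly 767 migrants (truncated
Poisson counts, mean ≈ 1.7, adjusted to the configured total),
participation at rate 0.57 with payment = enrolled area × site rate
(0.135 / 0.1875 Yuan/year/m²), and remittance from the same two-part
model the estimators fit — so recovery tests have an exact planted truth
(`beta_ccfp_logit = 0.104`, `beta_ccfp_amount = 0.099` per 1,000 Yuan).
Household covariates confound remittance receipt (education, cropland,
market access, transport), giving a propensity model accuracy around 0.7
and making matching consequential.

Rasters are 30 m grids; the initial forest field thresholds smoothed
white noise (site forest fractions 0.35 and 0.6). The planted effect
field adds, for every cell intersecting the 100 m disc of a household,
`nonremit_drift + remit_forest_slope * log10(remittance)` for receiving
households (defaults −0.015 and 0.011) and the drift alone for
non-receiving migrant households; transition probabilities are sized so
the expected buffer-level change equals the planted value, and
overlapping zones add (so a household's own buffer carries its full
effect and neighbour spillover enters as noise, not attenuation).
Background churn is a paired swap process — every spontaneous forest
loss is matched with a gain at a non-forest cell within 90 m — which
makes the expected background change of any buffer zero by construction;
probability-based churn schemes leave spatially autocorrelated drift
that a t-test reads as signal. EVI co-moves with the planted effect at
`evi_coupling` (0.5) plus N(0, 0.02) noise. Energy use couples
negatively, and gas spending positively, to log10 remittance; migrants
choose among 87 destination cities with log10 distances uniform on
[1.7, 3.2] and gravity-decaying probability.

What the generator does *not* emulate: classification error in the
forest/EVI layers, geographic coordinate systems (all coordinates are
site-local planar metres), non-convex group boundaries, temporal
dynamics of remitting, and any dependence of sampling weights on the
outcome beyond the participant/non-participant stratification. Passing
recovery tests therefore show the estimators are correct under the
assumed data-generating process, not that the substantive findings hold
in the real survey.

## Numerical choices and calibration measurements

- Derived seeds stay below $2^{31}$; every stochastic stage is
  reproducible from the master seed alone.
- Mixed-model fits at the variance boundary ("singular") count as
  converged; true optimiser failures flag the fit instead of erroring.
- The default problem sizes in the tests and the acceptance script are
  chosen to exercise the study-scale scenario where the statistic demands
  it (458 households for parameter recovery over 200 table replicates)
  and a 100-household scenario where only calibration is measured (null
  occurrence over 24–40 independent scenarios at 250 bootstrap replicates
  each). Occurrence percentages of a *single* dataset are not expected to
  sit at the nominal level — replicates within a dataset are correlated —
  so calibration is always summarised as the mean over independent
  scenarios.
- Groups of size one are allowed in the mixed models (they inform the
  fit through the integral) but are listed in a warning. Constant
  covariates are dropped from the propensity model with a warning.
- Degenerate buffers (no included cells, or no forested weight at one
  date) yield flagged missing metrics, never silent zeros.

## Known limitations

- Sampling weights enter lme4 as frequency-style weights; design-based
  variance estimation (linearisation or replicate weights) is out of
  scope, as is any third variance level above the resident group.
- No spatial-autocorrelation-adjusted standard errors: spillover is
  addressed by aggregation to resident groups, mirroring the study
  design. Residual within-cluster correlation of buffer outcomes keeps
  measured null occurrence slightly above the nominal 5% (about 6–8%).
- Ring buffers require convex group polygons (the generator's dilated
  hulls are convex by construction).
- The propensity model is a plain logistic fit; no regularisation, so
  highly collinear covariate blocks should be pruned by the caller.
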
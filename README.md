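# remiforest

Payments-for-ecosystem-services (PES) reforestation programs such as
China's Conversion of Cropland to Forest Program (CCFP) pay rural
households to retire sloped cropland into forest. A household that sends
out-migrants to distant cities may receive remittances, and that money can
substitute for income otherwise extracted from nearby forests (fuelwood,
fodder, timber). `remiforest` implements the full inference chain for
testing whether remittance mediates additional forest recovery around rural
households:

1. **Remittance models** — two-level mixed-effects models with resident
   groups `c` as the clustering level and sampling weights:
   a logistic model for whether migrant `i` in group `c` sends remittance,
   `Pr(y_ic = 1) = logit^-1(x_ic' beta + u_c)`, `u_c ~ N(0, sigma_u^2)`,
   and a linear model for the log10 remitted amount among senders. The
   payment covariate is the cumulative program payment in thousand Yuan, so
   coefficients read "per additional 1,000 Yuan". Marginal effects are
   population-averaged over the random intercept by Gauss–Hermite
   integration; a weighted household bootstrap gives margin distributions.
2. **Buffer change metrics** — for circular buffers of radius 25–200 m
   around each house and for rings dilated 0–100 m and 100–200 m around
   resident-group polygons:
   `dForest = sum(w_i K_i1)/sum(w_i) - sum(w_i K_i0)/sum(w_i)` and
   `dEVI = sum(w_i K_i1 eta_i1)/sum(w_i K_i1) - sum(w_i K_i0 eta_i0)/sum(w_i K_i0)`,
   where `K` is the 0/1 forest indicator, `eta` the Enhanced Vegetation
   Index, and `w_i` the *exact* fraction of cell `i` inside the buffer
   (cells below 0.5% overlap are excluded).
3. **Matching and treatment effects** — logistic propensity scores for
   receiving remittance, one-to-one nearest-score matching of each
   no-remittance control to a treated household (treated reusable, weighted
   by inverse multiplicity), balance diagnostics, caliper sensitivity, and
   a pairwise bootstrap (1,000 draws of 60% of the pairs, with replacement)
   testing H1: treated − control > 0, H2: treated > 0, H3: control <= 0,
   recording the occurrence of p < 0.05 across replicates.
4. **Mechanism tests** — fuelwood share of energy spending, energy-ladder
   stages, livestock and extraction inputs, compared between remittance
   groups with weighted t and chi-squared tests.
5. **Additionality** — the socioeconomic share
   `G_Econ% = sum_i 10^(beta * M_i * P_i / 1000) / sum_h P_h * 100` and the
   ecological share
   `G_Ecol% = sum_h gamma * L_h * A / sum_h (P_h / lambda) * 100`
   (with `M_i` migration years, `P_i`, `P_h` program payments, `L_h` the
   log10 attributable household remittance, `A` the buffer area and
   `lambda` the per-site payment rate), with uncertainty propagated from
   both coefficients and scaling to program-level totals.
6. **Flows** — migration/remittance flow tables by destination city and
   province, log10-distance bins (short 1.7–2.2, medium 2.2–2.7, long
   2.7–3.2) and one-way ANOVA across bins.

Because the original survey microdata are confidential, the package ships a
first-class synthetic generator (`generate_scenario()`) that emulates the
two-site study structure — 458 migrant households with 767 migrants in 63
resident groups, payment rates 0.135 and 0.1875 Yuan/year/m², ~36%
remittance senders — and plants known effect sizes, so every estimator can
be validated by parameter recovery.

## Worked example

```r
library(remiforest)

res <- run_pipeline(scenario_config(seed = 7), out_dir = "results/run7",
                    n_reps = 500)
res
#> <remiforest_results>
#>   households 458, migrants 767, matched pairs 221
#>   ATE on forest change @100 m: +0.0406 (boot sd 0.0078, H1 occ 100%)
#>   additionality: econ 1.06%, ecol 6.82%
```

The summary reads: among 221 matched treated/control pairs, forest cover
within 100 m of remittance-receiving households grew about 4.1 percentage
points more than around migrant households without remittance (the planted
truth for this seed is 4.4 points, within one bootstrap s.d.), the
difference was significant in essentially every bootstrap replicate, and
the estimated remittance-mediated additionality is ~1% of program payments
and ~7% of the enrolled-area baseline under the synthetic conditions.

Individual stages are ordinary functions over data frames:

```r
scn <- generate_scenario(scenario_config(seed = 7))
fit <- fit_remit_logit(scn$migrants,
                       sent_remittance ~ payment_k + age + education +
                         (1 | group_id))
tidy(fit)      # coefficient table
glance(fit)    # ICC, AIC/BIC, convergence
marginal_effects(fit)$effects
```

`autoplot()`/`plot_*()` helpers draw the ATE-by-radius, predictive-margin,
group-association and flow-bin figures.

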
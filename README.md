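# camcooccur

Analysis pipeline for camera-trap surveys of two co-occurring (sympatric)
species — built for the common study design in which paired questions are
asked of the same detection data: **where** does each species occur
(occupancy), **when** is it active (diel overlap), and **how** is
detection distributed in space (interpolated detection maps). The intended
users are wildlife ecologists analysing single-season camera-trap data
with site covariates.

## What it computes

**Occupancy.** A Bayesian single-season occupancy model per species.
For site *i* with standardized site covariates *x<sub>i</sub>* and
distance covariates *w<sub>i</sub>*:

    z_i ~ Bernoulli(psi_i),        logit(psi_i) = x_i' beta
    y_i | z_i ~ Binomial(n_i, p_i z_i),  logit(p_i) = w_i' alpha

where *y<sub>i</sub>* counts the weekly occasions with at least one
detection and *z<sub>i</sub>* is the latent occupancy state. Coefficients
get Normal(0, 3.16) priors and the model is fitted by
Metropolis-within-Gibbs MCMC (exact Gibbs draws for *z*, adaptive
random-walk updates for the coefficients, plus covariance-shaped joint
proposals). Summaries report posterior mean, SD, 95% credible interval,
split-chain Rhat, effective sample size, `overlap0` and `f`; per-site
psi/p posterior means feed a Welch t-test between the species.

**Diel overlap.** Detection times become angles on the 24-h clock;
activity densities are von Mises kernel density estimates
(cross-validated bandwidth) and temporal overlap is the Dhat1
coefficient — the area under the pointwise minimum of the two densities,
0 = no overlap, 1 = identical activity — with smoothed-bootstrap "norm0"
confidence intervals, overall and within site strata (e.g.
protected-area or large-predator strata).

**Detection maps.** Per-site detection frequency (proportion of occasions
with a detection) interpolated by inverse distance weighting onto a
raster, exported as ESRI ASCII + CSV.

**Synthetic studies.** `simulate_study()` generates full surveys —
covariates with field-realistic moments, occupancy states, detection
histories and diel timestamps — from known parameters, so every estimator
can be validated against ground truth.

## Worked example

```r
library(camcooccur)

# a synthetic 154-site survey with known truth
study <- simulate_study(sim_config(seed = 7))
records <- collapse_independent_events(study$records)

design <- study$design
print(design)
#> survey_design: 154 sites x 21 days (7-day occasions, 3 per site), 3234 trap-days

h <- build_detection_history(records, design, "junglecat")
print(h)
#> detection_history for 'junglecat': 154 sites x 3 occasions, 55 detections
#> at 34 sites (naive occupancy 0.221)

std <- standardize_covariates(study$covariates,
        c("canopycover", "predators", "livestock", "human", "othercat",
          "dist_water", "dist_road", "dist_settlement"))
print(screen_collinearity(std))
#> collinearity screen passed: no |r| > 0.70

fit <- fit_occupancy(h, std, occu_spec(),
                     mcmc_settings(3, 1000, 1000, 5000, seed = 11))
head(summarize_posterior(fit), 3)
#>          parameter    mean     sd     lci     uci  rhat    ess overlap0      f
#> 1 beta_(Intercept) -0.7315 0.3751 -1.3781 0.08469 1.004  689.9        1 0.9635
#> 2 beta_canopycover -0.2924 0.2509 -0.7929 0.17843 1.003 2168.5        1 0.8800
#> 3   beta_predators  0.1002 0.2390 -0.3667 0.55829 1.001 2201.5        1 0.6713
```

`overlap0 = 1` marks coefficients whose 95% credible interval contains 0
(no clear effect); `rhat < 1.1` is the convergence criterion. Diel
overlap between the two species:

```r
ta <- to_radians(records$timestamp[records$species == "junglecat"])
tb <- to_radians(records$timestamp[records$species == "leopardcat"])
bootstrap_ci(ta, tb, reps = 999, seed = 7)
#> Dhat1 = 0.900 (norm0 95% CI: 0.806-0.994; n = 103/95, 999 bootstraps)
study$truth$true_overlap   # exact overlap of the generating mixtures
#> [1] 0.8018776
```

With only ~100 events per species a single realization can sit a few
hundredths from the generating overlap, as here; the coverage behaviour
of these intervals is exercised systematically in the test suite.

The whole workflow is also scriptable from the shell via
`exec/camcooccur` (`simulate | occupancy | overlap | idw-map`
subcommands) or the `pipeline_*()` functions, which write the summary
CSVs, rasters and JSON sidecars.

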
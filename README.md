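# pgmknot

Bayesian piecewise growth models with a freely estimated knot location,
for longitudinal researchers who need to ask not just *how* an outcome
changes over time but *when* the change of phase happens — and how much
that answer depends on the prior placed on the changepoint and on
attrition in the data.

## The model

The linear–linear piecewise growth model (PGM) is a latent growth curve
model whose mean trajectory has two linear segments joined at a knot
γ on the study's time-code scale:

```
y_i  = Λ(γ) η_i + ε_i,    ε_i ~ N(0, diag(σ²_ε1 … σ²_εJ))
η_i  = α + ζ_i,           ζ_i ~ N(0, Ω_η)
```

with J repeated measures per subject and three growth factors
(intercept, pre-knot slope, post-knot slope). Row *j* of the J×3
loading matrix is

```
Λ_j(γ) = [ 1,  min(t_j, γ),  max(t_j − γ, 0) ]
```

so the knot enters the likelihood nonlinearly through the loadings.
Estimation is by Markov chain Monte Carlo: conjugate Gibbs updates for
η, α (normal), Ω_η (inverse Wishart), and the residual variances
(inverse gamma); a Metropolis step for γ on its truncated support
(Gaussian random walk, adapted during burn-in, mixed with occasional
independence draws from the prior so chains can cross between separated
knot modes); and data augmentation for outcomes that are missing at
random — missing y_ij are resampled each iteration from their normal
full conditionals, so incomplete subjects contribute exactly their
observed information.

Seven knot-prior regimes are built in, crossing informativeness with
placement: a diffuse uniform over the study window (`DIF`) and
truncated normals `I-ATK`, `WI-ATK`, `I-PRK`, `WI-PRK`, `I-PSK`,
`WI-PSK` (informative variance 0.146 on the default 0–6 grid, weakly
informative = 5×, centers at the presumed knot, before it, after it).
On other time grids the presets rescale by the documented 10%-overlap
rule. A MAR attrition generator produces the study's missingness
patterns (constant / start-concentrated / end-concentrated rise to 30%
or 70% at the last wave) by logistic dropout on the standardized
first-occasion outcome (slope b₁ = 1.48), with intercepts solved by
quadrature so the marginal missingness hits the target schedule.

A study runner reproduces the full 3 × 7 × 7 Monte Carlo design
(sample sizes 50/150/500 × seven missingness levels × seven knot
priors, 500 replications per cell by default) and scores each cell by
convergence rate, coverage of the 95% credible interval for γ, average
bias, and RMSE.

## Worked example

Generate data from the documented default population (knot at coded
time 3), impose start-concentrated 30% attrition, and fit under the
weakly informative prior at the true knot:

```r
library(pgmknot)

pop <- default_population()
d   <- generate_complete(pop, n = 150, seed = 11)
dm  <- apply_mar(d, missing_level_spec("Concen-S-30%"), seed = 12)
dm
#> <longitudinal_dataset> n = 150 subjects, J = 7 occasions, 19.6% missing overall

fit <- fit_pgm(dm, default_nuisance_priors(knot_prior_preset("WI-ATK")),
               mcmc_config(seed = 13))
fit
#> <pgm_fit> 4 chains x 2500 retained draws, n = 150 subjects
#>   knot: mean 2.755, 95% CI [1.731, 3.816], R-hat 1.023
#>   converged: TRUE (max R-hat 1.023 < 1.10), knot acceptance 0.34
```

The knot posterior centers near the true changepoint (3) with an
interval that reflects how little a single n = 150 dataset says about
it; the `converged` flag applies the R̂ < 1.1 screen to every monitored
parameter. `summary(fit)` gives the full posterior table:

```r
s <- summary(fit)
s[s$parameter %in% c("alpha[1]", "alpha[2]", "alpha[3]", "gamma"), ]
#>    parameter   mean median    sd ci_lower ci_upper rhat
#> 1   alpha[1] 50.516 50.512 0.673   49.193    51.86 1.01
#> 2   alpha[2]  0.669  0.692 0.410   -0.201     1.41 1.01
#> 3   alpha[3]  2.223  2.200 0.362    1.565     2.99 1.01
#> 17     gamma  2.755  2.741 0.532    1.731     3.82 1.02
```

For your own wide-format CSV (header of time codes, one row per
subject, empty cells = missing), `fit_from_csv(path)` fits all seven
presets rescaled to your grid and returns one knot summary row per
prior — the standard prior sensitivity analysis. Simulation cells run
with, e.g.,

```r
design <- study_design(sample_sizes = 50L, missing_levels = "Complete",
                       prior_names = "I-ATK", replications = 100L,
                       mcmc = mcmc_config_reduced(), seed = 1L)
run_cell(1L, design)
#> <cell_metrics> 81/100 converged (0.810); coverage 1.000, bias -0.005, RMSE 0.107
```

## Acceptance script

`scripts/acceptance.R` re-runs the package end to end at desk scale:
it regenerates the n = 50 complete-data cell under the I-ATK and
WI-ATK knot priors (100 replications each, 2 chains), computes coverage
of the true knot over R̂-screened replications, calibrates the
Constant-30% MAR generator at n = 100,000, and writes the results as
JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
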
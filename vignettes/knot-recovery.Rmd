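---
title: "Estimating knot locations in Bayesian piecewise growth models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating knot locations in Bayesian piecewise growth models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(pgmknot)
```

## The model and its assumptions

`pgmknot` fits the linear–linear piecewise latent growth curve model

$$
y_i = \Lambda(\gamma)\,\eta_i + \epsilon_i, \qquad
\eta_i \sim N(\alpha, \Omega_\eta), \qquad
\epsilon_i \sim N\!\big(0, \mathrm{diag}(\sigma^2_{\epsilon 1}, \dots,
\sigma^2_{\epsilon J})\big),
$$

where row $j$ of the loading matrix is
$[\,1,\ \min(t_j,\gamma),\ \max(t_j-\gamma,0)\,]$. The three growth
factors are the intercept, the pre-knot slope, and the post-knot slope;
the knot $\gamma$ — the time at which the trajectory changes phase — is
a free parameter on the raw time-code scale (no internal rescaling).
The model assumes multivariate-normal outcomes, a single common knot
for all subjects, residuals that are independent across occasions
(heteroscedastic by occasion: each diagonal element of the residual
covariance carries its own inverse-gamma prior), and, for incomplete
data, missingness at random. At least five occasions are required for
identification; the constructors enforce this.

Priors follow the conventions of Gibbs-sampled structural equation
models: $\alpha_m \sim N(\mu_\alpha, \sigma^2_\alpha)$ with diffuse
defaults $(0, 10^6)$; $\Omega_\eta \sim IW(\Psi, \nu)$ with
$\Psi = I_{3\times 3}$, $\nu = 3$; $\sigma^2_{\epsilon j} \sim
IG(0.001, 0.001)$ with density $\propto x^{-a-1}e^{-b/x}$ and the
inverse Wishart with density $\propto
|\Omega|^{-(\nu+p+1)/2}e^{-\mathrm{tr}(\Psi\Omega^{-1})/2}$. The knot
prior is either uniform over the study window or a normal truncated to
it; `knot_prior_preset()` supplies the seven standard regimes. On the
default $0\ldots 6$ grid the informative variance is 0.146 and the
weakly informative one $5\times$ that, used verbatim. On any other
grid the presets are rebuilt: the accurate center is the grid
midpoint, the misplaced centers are midpoints between an endpoint and
the accurate center, and the informative standard deviation solves the
10%-overlap condition between adjacent informative priors,
$2\Phi(-d/2\sigma) = 0.10$ at spacing $d = \mathrm{range}/4$, i.e.
$\sigma = d/(2\,\Phi^{-1}(0.95))$. On a $0\ldots 8.5$ grid this gives
variance 0.417 (weakly informative 2.085), matching the published
applied-analysis scaling. The printed simulation variance 0.146 does
*not* satisfy the same identity (the rule would give 0.208), so on the
default grid the printed value always wins; this asymmetry is
deliberate and documented rather than silently "corrected".

## The sampler

One Gibbs sweep updates, in order: (1) missing outcomes from
$N(\Lambda_j(\gamma)^\top\eta_i, \sigma^2_{\epsilon j})$ (data
augmentation — the monotone attrition structure needs no special
handling because each missing cell has a proper full conditional);
(2) each $\eta_i$ from its multivariate-normal full conditional;
(3) $\alpha$ (normal); (4) $\Omega_\eta$ (inverse Wishart, drawn by
Bartlett decomposition of the inverted scale); (5) each
$\sigma^2_{\epsilon j}$ (inverse gamma); (6) the knot, by Metropolis on
the complete-data likelihood times the knot prior.

The knot kernel is a mixture: with probability 0.9 a Gaussian random
walk whose step size adapts during burn-in toward 25–45% acceptance
(frozen afterwards, so the post-burn-in kernel is a fixed, valid
Metropolis kernel), and with probability 0.1 an independence proposal
drawn from the knot prior, for which the prior and proposal densities
cancel and the acceptance ratio is the bare likelihood ratio. The
independence component matters: the knot posterior can be multimodal —
in particular, near the ends of the time window one slope factor loses
identification and the diffuse mean priors put nonnegligible mass
there (a Lindley-type boundary pseudo-mode), and on sparse or uneven
grids a likelihood ridge appears past the second-to-last occasion
where the knot and the post-knot slope trade off exactly. A pure
random walk gets trapped on one mode for entire chains and produces
seed-dependent convergence verdicts; prior-independence jumps restore
mixing across modes while leaving the stationary distribution
untouched. Proposals outside the truncation bounds are rejected
through the prior's $-\infty$ log density.

Chains are run sequentially from one seeded RNG stream, so a fitted
model is a pure function of (data, priors, config, seed). Starting
values are dispersed: the knot from the interior 10–90% quantile range
of its prior, growth-factor means from a two-piece least-squares fit
of the occasion means at that starting knot (jittered), variances from
moment estimates (jittered). Convergence is screened by split-chain
R-hat, rank-normalized and folded (the maximum of the bulk and folded
statistics), with the classic Gelman–Rubin form available as an
option; a fit is `converged` when every monitored structural parameter
— $\alpha$, the six unique elements of $\Omega_\eta$, the $J$ residual
variances, and $\gamma$ — has $\widehat R$ strictly below the
threshold (default 1.1). Latent scores and imputed values are not
monitored, mirroring common practice of monitoring structural
parameters only; this choice is a documented decision, not an inferred
intent.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `n_chains` | 4 (2 in `mcmc_config_reduced`) | chains | ≥2 required for R-hat |
| `n_iter` | 25,000 (4,000 reduced) | post-burn-in iterations | full-scale mirrors the published protocol; reduced is desk-scale |
| `burn_in` | 5,000 (1,000 reduced) | iterations | adaptation window for the knot step |
| `thin` | 10 (1 reduced) | — | autocorrelation control at full scale |
| `rhat_threshold` | 1.1 | — | the conventional screen |
| `knot_proposal_sd` | 0.2 | time codes | initial RW step, adapted in burn-in |
| `b1` | 1.48 | logit per SD of $y_1$ | strong dropout–cause association |
| `terminal_prop` | 0.30 / 0.70 | fraction | typical end-of-study attrition levels |

`mcmc_config()` is the full-scale protocol; `mcmc_config_reduced()`
(2 × 4,000 after 1,000, unthinned) is the default for the packaged
study and the acceptance runs, and `mcmc_config_illustrative()`
(4 × 50,000 after 50,000) mirrors the single-dataset applied protocol.
Knot mixing slows as $n$ grows (the complete-data conditional
tightens), so large-$n$ fits warrant the longer configurations.

## The synthetic world

`default_population()` is the data-generating model of the packaged
Monte Carlo study: seven equidistant occasions coded $0\ldots 6$, knot
at the fourth occasion ($\gamma = 3$), growth-factor means
$(50, 1, 2.5)$, factor covariance $\mathrm{diag}(25, 0.5, 0.5)$, and
residual variance 60 at every occasion. The slope change of 1.5 is a
large standardized effect ($1.5/\sqrt{0.5+0.5} = 1.5$) relative to the
slope heterogeneity.

The exact population values used by the original study are available
only in its supplementary materials, so this package derives its own
documented world from the study's printed summaries, treated as
constraints: (a) at $n = 50$ a single dataset must carry weak
information about the knot, so that informative priors dominate the
posterior (the published small-sample coverage and RMSE patterns);
(b) by $n = 500$ the no-knot boundary pseudo-mode must be suppressed,
so that a diffuse-prior analysis recovers the knot (the published
large-sample convergence and RMSE). A per-subject Fisher-information
and Kullback–Leibler calculation (information about $\gamma$;
divergence from the true model to the best knot-free boundary model)
shows the two constraints bracket the residual variance into a narrow
window, and short sampler probes against the printed large-$n$ and
misplaced-prior behaviors fixed $\sigma^2_\epsilon = 60$. The value
was frozen before any acceptance measurement and is not revisited;
residual discrepancies are reported as such. One consequence is
visible in the packaged checks: knot recovery under the accurate
informative prior is slightly *tighter* here (RMSE ≈ 0.11 at
$n = 50$) than the published 0.202 — an analytic bound
($\max_I \sqrt I/(I + 1/0.146) = 0.191$) shows no Gaussian-regime
population can reproduce that printed value exactly, so the difference
is attributed to the unpublished population details rather than to the
method.

The MAR generator emulates attrition in longitudinal panels:
missingness from the second occasion onward follows a logistic model
on the *standardized first-occasion outcome* (sample mean/SD), with
intercepts solved by adaptive quadrature (tolerance $10^{-8}$) so each
occasion's marginal missingness matches a target schedule — quadratic
or linear rises to 30% or 70% at the last wave. Indicators are drawn
independently per occasion, which reproduces the printed marginal
proportions exactly; an opt-in `monotone` flag carries dropout forward
for strict staircase attrition, since the original procedure describes
attrition but generates per-occasion indicators and it is not stated
whether monotonicity was enforced afterwards. The generator does not
emulate: intermittent missingness unrelated to the first occasion,
MNAR mechanisms, non-normal outcomes, or subject-varying measurement
schedules. A green simulation test therefore certifies the method
under exactly this world, not under arbitrary real data.

## Numerical choices

* Truncated-normal densities are normalized explicitly by the normal
  mass on the support; log densities return $-\infty$ outside it (a
  value, not an error).
* Intercepts for occasions with a 0% missingness target are `NA`
  sentinels; no $-\infty$ arithmetic.
* The inverse-gamma draw guards against underflow of the tiny-shape
  prior draw ($a = 0.001$, reachable only in the no-data path used to
  verify that the posterior reproduces the prior).
* Observed-data log-likelihood groups subjects by missingness pattern
  and shares one Cholesky factor per pattern.
* R-hat returns 1 by convention, with a warning, when the pooled draws
  have zero variance; the convergence flag uses a strict inequality at
  the threshold.
* Replication seeds are derived arithmetically from (master seed, cell
  index, replication index), all below $2^{31}$, so study results are
  independent of scheduling; parallel execution would not change them.
* Metrics over cells with zero converged replications return `NA`
  sentinels rather than zeros.

## Known limitations

Single common knot only (no multiple, disjoint, or individually
varying knots, and no mixture components); MAR attrition generation is
defined on the default grid (other grids need an explicit schedule);
the sampler is a bespoke Gibbs/Metropolis scheme, not a general PPL,
so model changes require code; and under diffuse knot priors at small
$n$ the posterior is genuinely multimodal, where the honest outputs
are a failed R-hat screen and a wide interval, not a point estimate.
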
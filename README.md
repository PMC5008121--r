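# sspopdyn

Bayesian age-structured state-space population models with stochastic
covariate selection, for seabird-style monitoring data: annual breeding-pair
and chick counts with repeated censuses, a short window of mark-recapture
survival estimates, and a panel of candidate environmental and demographic
covariates with missing segments.

## The model

A female-only six-stage demographic process (ages 1-5 pre-recruitment plus
breeding adults) is projected with binomial demographic stochasticity.  The
deterministic skeleton is the Leslie-type matrix

```
R_t = [ 0 0 0 0 0  phi_a (b/2) phi_f
        phi_a 0 0 0 0 0
        0 phi_a 0 0 0 0
        0 0 phi_a 0 0 0
        0 0 0 phi_a 0 0
        0 0 0 0 phi_a phi_a ]
```

with annual vital rates linked to standardized covariates on the logit
scale.  Survival (fledgling / older) carries a shared predation effect, an
extra fledgling predation effect, and a lag-1 SSTa effect:

    logit(phi_f,t) = alpha_f0 + (I1 a1 + I2 a2) P_t + I3 a3 S_{t-1}
    logit(phi_a,t) = alpha_a0 +  I1 a1         P_t + I3 a3 S_{t-1}

Productivity carries ten candidate terms (arrival mass, predation, SSTa and
SAM at two lags each, ENSO at lags 2-3, interspecific competition, and the
model's own latent breeding-female abundance as a density-dependence
auto-covariate):

    logit(b_t) = beta_0 + sum_k J_k beta_k x_{k,t}

Every `I`/`J` is a Bernoulli switch indicator with a Uniform(0,1) inclusion
probability (stochastic search variable selection): the posterior mean of an
indicator is the probability that the covariate operates in the model.
Counts enter through a normal observation model whose variance comes from
the repeated censuses; survival estimates through a hierarchical normal
error model whose variance ceiling is gamma-distributed, moment-matched to
the reported 95% CIs.  Missing covariate segments are imputed inside the
sampler (i.i.d. normal for arrival mass, a backward random walk for the
predation index).  Posterior computation is MCMC via JAGS (`rjags`), with
the unobserved pre-recruitment stages marginalized exactly for speed and
mixing; see the methods vignette (`vignettes/state-space-model.Rmd`).

Downstream analyses: one-breakpoint (broken-stick) trend fitting on log
counts, period summaries (vital-rate means, adult mortality, recruitment
proportion), no-data trajectory validation from marginal posteriors, and
bootstrap covariate-sensitivity ranking between fits with and without a
covariate.

## Worked example

No field data ship with the package; `study_like_fixture()` generates the
packaged 28-season study-like scenario (a colony declining ~7%/yr then
stabilizing, predation index unobserved for the first 16 seasons, arrival
mass for the first 4, survival estimates for the final 8).

```r
library(sspopdyn)

sim <- study_like_fixture()
fit <- sspm(sim$counts, sim$covariates, survival = sim$survival,
            replicates = sim$replicates, control = mcmc_control(seed = 1))
print(fit)
```

```
Age-structured state-space population model fit
  28 years (1985-2012), 16 survival obs, s2 = 350.9
  3 chains x 2000 draws (thin 30), 519 s; max Rhat = 1.010

Coefficients (posterior mean [95% CrI]):
  alpha_f0     -0.025 [ -0.117,   0.083]
  alpha_a0      2.257 [  2.154,   2.368]
  alpha_1      -0.617 [ -0.719,  -0.509]
  alpha_2      -0.305 [ -0.450,  -0.171]
  alpha_3       0.012 [ -2.924,   2.999]
  beta_0        0.374 [  0.279,   0.474]
  beta_1        0.254 [  0.172,   0.341]
  beta_8       -0.248 [ -0.342,  -0.145]
  ...
  sigma_rw      0.552 [  0.327,   0.896]

Inclusion probabilities > 0.5:
  surv.P_shared=1.00, surv.P_fledgling=1.00, prod.A=1.00, prod.E3=1.00
```

The sampler converges (max Rhat 1.01 over all monitored coefficients,
inclusion probabilities, hyperparameters and latent abundances), recovers
the generator's true effects — negative shared and fledgling-specific
predation effects on survival, a positive arrival-mass and negative
ENSO-lag-3 effect on productivity — and decisively excludes the null
covariates (their inclusion probabilities sit near the slab-prior floor
while their credible intervals span the prior).

```r
fit_broken_stick(sim$counts$year, sim$counts$pairs)
#> Broken-stick trend fit
#>   breakpoint: 2004.26 (SE 0.61)
#>   pre-break:  -7.87% per year (SE 0.22)
#>   post-break: 1.84% per year (SE 0.70)

round(period_summaries(fit, split_year = 2000), 3)
#>       n_years phi_f phi_f_sd phi_a phi_a_sd     b  b_sd adult_mortality recruitment
#> early      15 0.398    0.129 0.873    0.038 0.535 0.083           0.127       0.071
#> late       13 0.484    0.208 0.888    0.062 0.634 0.097           0.112       0.107

validate_without_data(fit, n_sim = 250, seed = 21)
#> No-data validation: 100% of observed counts inside the 95% envelope (250 simulations)
```

The period summaries show the decline mechanism: lower early-period
survival and productivity (adult mortality 0.127 against recruitment
0.071) followed by recovery of both.  The no-data validation re-simulates
the trajectory using only the covariates and the marginal posteriors — the
observed series stays inside the ensemble envelope, while shuffling the
covariate years destroys it.

A thin command-line interface wraps the same functions
(`inst/cli/sspopdyn.R`): subcommands `simulate`, `fit`, `changepoint`,
`validate`, `sensitivity`, `report`, each writing delimited-text outputs
plus a reproducibility manifest.

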
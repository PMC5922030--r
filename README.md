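# jmcd4

Bayesian shared-parameter joint modelling of longitudinal CD4 cell-count
change and time to default from antiretroviral therapy (HAART).

## The problem

HIV patients on HAART are followed at scheduled clinic visits; the
visit-to-visit change in CD4 cell count, Δy<sub>ij</sub> =
y<sub>ij</sub> − y<sub>i,j−1</sub>, tracks treatment response, and many
patients default (stop attending) before the study ends.  The same
unobserved patient characteristics plausibly drive both outcomes, so the
package links them through shared random effects:

* **Longitudinal submodel** — an overdispersed count GLMM:
  log μ<sub>ij</sub> = x<sub>ij</sub>ᵀβ₁ + ν<sub>i0</sub> +
  ν<sub>i1</sub>t<sub>ij</sub> + ε<sub>ij</sub>, with
  ε<sub>ij</sub> ~ N(0, b<sub>i</sub>) and patient-specific dispersion
  log b<sub>i</sub> ~ N(0, σ<sub>b</sub>²) (a Poisson–log-normal count,
  the generative form of quasi-Poisson overdispersion).
* **Survival submodel** — Weibull proportional hazards for the number of
  follow-up visits to default:
  h<sub>i</sub>(t) = φρt<sup>ρ−1</sup> exp(x<sub>i2</sub>ᵀβ₂ +
  W<sub>i2</sub>), with shared latent term
  W<sub>i2</sub> = τ₀ν<sub>i0</sub> + τ₁ν<sub>i1</sub> +
  τ<sub>b</sub> log b<sub>i</sub> + u<sub>i</sub> and frailty
  u<sub>i</sub> ~ N(0, σ<sub>ν</sub>²).

Fitting is by Metropolis-within-Gibbs MCMC with conjugate variance
updates and exact interweaving moves for the hierarchy's flat ridges;
model selection uses the DIC over a ladder of random-effect structures.
The package also provides the separate submodel fits (quasi-Poisson-type
vs negative binomial counts, Weibull vs Cox survival), an MCAR
missingness diagnostic, descriptive tables, and a synthetic cohort
generator calibrated to the published 792-patient cohort so that every
stage is verifiable by parameter recovery — the original hospital
records are not public.

It is aimed at biostatisticians analysing longitudinal count biomarkers
with informative dropout, and at anyone wanting a transparent, fully
testable reference implementation of a shared-parameter joint model for
counts.

## Worked example

```r
library(jmcd4)

co <- simulate_cohort(n = 792, seed = 1)
co
#> Synthetic joint cohort: 792 patients
#>   longitudinal records: 7444 (9.1% flagged missing)
#>   defaults observed: 602 of 792

mv <- mean_variance_profile(co$longitudinal)
head(mv, 3)
#>   visit_index   n     mean       sd overdispersed
#> 1           1 699 39.98426 120.6349          TRUE
#> 2           2 557 42.53321 152.5019          TRUE
#> 3           3 508 42.98031 111.3675          TRUE

wf <- fit_parametric_survival(co$survival, co$covariates, terms = "age")
wf
#> weibull proportional-hazards fit (loglik -2097.22)
#>   shape rho = 0.826 (0.771, 0.885) -> decreasing default rate
#>   scale phi = 0.2420
#>   term estimate      se    lower    upper     hr
#> 1  age -0.01702 0.00273 -0.02237 -0.01167 0.9831
```

The per-visit standard deviation exceeding the mean at every visit is
the overdispersion signature that motivates the Poisson–log-normal
family; the fitted shape ρ < 1 says the default rate declines as
patients accumulate follow-up visits; the age hazard ratio 0.983 means
each additional year of age multiplies the default hazard by that
factor in this simulated cohort.  The joint fit and DIC ladder follow
the same pattern:

```r
fit <- fit_joint(co$longitudinal, co$survival, co$covariates)
summary(fit)                 # posterior summaries, hazard ratios, DIC
run_ladder(co$longitudinal, co$survival, co$covariates)
mcar_check(co$longitudinal, co$covariates)
```

See the methods vignette (`vignettes/joint-modelling.Rmd`) for the full
model, priors, sampler design, generator calibration and limitations.

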
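# dietmix

Bayesian mixing models for estimating predator diet composition from
fatty-acid (FA) profiles, stable-isotope (SI) signatures, or both in a
single joint model.

## The problem

Quantitative diet estimates underpin predator–prey studies and
ecosystem-based management. Stable isotopes mix linearly across prey but
rarely provide more than 2–3 dimensions, so multi-prey systems are
under-determined; fatty-acid profiles provide many dimensions but are
*compositional* (proportions of total lipid summing to one) and are
distorted by selective assimilation. `dietmix` treats FA profiles in
log-ratio space with an explicit probabilistic mixing model, propagates
uncertainty in prey distributions, conversion coefficients and fat content
into the diet estimates, and lets both marker types inform one vector of
diet proportions.

## The model

For prey individual $i$ of species $s$, the alr-transformed profile
$y_{i,s} = \mathrm{alr}(\phi_{i,s})$ is multivariate normal,
$y_{i,s} \sim N(\mu_s, \Sigma_s)$. A predator $j$ with diet proportions
$\pi_j$ consuming prey items $\phi_{j,s}$ drawn from those distributions has
expected profile

$$\tau_j = C\Big\{\sum_s (\pi_{j,s} \Phi_s)\,(\kappa_s \odot \phi_{j,s})\Big\},
\qquad t_j \sim N(\mathrm{alr}(\tau_j), \Sigma_\tau),$$

with $\Phi_s$ the relative fat content, $\kappa_s$ per-FA conversion
coefficients (gamma/log-normal priors moment-matched to feeding-trial
means and variances; identified up to scale because of the closure $C$),
and $\Sigma_\tau$ the predator residual covariance. Isotopes mix linearly
with additive fractionation, $t^{SI}_r = \sum_s \pi_{r,s}(y_s + \gamma_s)$,
$\gamma_{s,SI} \sim N(\nu_{SI}, \sigma_{SI})$. Diet proportions can be
population-level (Dirichlet prior), hierarchical per predator, or driven by
covariates through a design matrix. Estimation is by an adaptive
Metropolis-within-Gibbs sampler with split-R̂ and effective-sample-size
diagnostics.

The package also implements ordination-based fatty-acid selection
(contributions to among-species separation on constrained CAP axes, under
a prey-matrix condition-number guard), conversion-coefficient estimation
from feeding trials with known diets, and a simulator that generates
datasets with known truth for validation and sensitivity studies.

## A worked example

```r
library(dietmix)

# a synthetic study with known truth: 3 prey species, 12 FAs, 2 isotopes
sc  <- scenario_spec(n_species = 3, n_fa = 12, n_isotopes = 2,
                     n_samples = 30, n_predators = 10,
                     pi_true = c(0.2, 0.3, 0.5), seed = 1)
sim <- simulate_diet_data(sc)

fit <- fit_diet(sim$data, markers = "both", grouping = "population",
                consumed = "marginal",
                mcmc = mcmc_control(n_chains = 2, n_iter = 2400), seed = 2)
print(fit)
#> Bayesian diet mixing model (both markers, population grouping, marginal-prey mode)
#> Species: prey1, prey2, prey3
#>
#> Posterior mean diet proportions:
#> prey1 prey2 prey3
#> 0.187 0.344 0.469
#>
#> max split-Rhat: 1.011 | min ESS: 274
```

The posterior means sit within a few percentage points of the true diet
(0.2, 0.3, 0.5); `summary(fit)` adds credible intervals and per-parameter
diagnostics, `plot(fit)` draws the posterior densities, and
`combine_sources(fit$draws, c(prey1 = "fish", prey2 = "fish",
prey3 = "crustacean"))` gives posterior draws for post-hoc prey groups.
`consumed = "marginal"` integrates the latent consumed-prey items out of
the predator likelihood (fast and calibrated); the default samples them
explicitly, and `latent_prey = FALSE` gives the crude species-mean
approximation.

Real data enter through data frames or a YAML run configuration:

```r
d   <- read_diet_data("run.yml")    # CSV tables named in the config
sel <- select_fas(d, cum_var_target = 0.75, cond_cap = 20)
d2  <- subset_fas(d, sel$selected)
fit <- fit_diet(d2, markers = "both", grouping = "individual", seed = 1)
```

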
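---
title: "Estimating predator diets from fatty acids and stable isotopes"
author: "dietmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating predator diets from fatty acids and stable isotopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Chemical dietary markers integrate a predator's diet over weeks to months.
Stable-isotope (SI) ratios such as δ¹³C and δ¹⁵N mix approximately linearly
across prey sources, but only two or three isotopes are typically measured,
so systems with more prey species than isotopes are under-determined.
Fatty-acid (FA) profiles offer many more dimensions, but come with two
complications: they are *compositions* (non-negative proportions of total
lipid summing to one, so the usual normal-theory mixing models do not apply
directly), and prey FAs are assimilated selectively, so the predator's
profile is a distorted, not a faithful, mixture of its prey's.

`dietmix` addresses both with a Bayesian mixing model for FA profiles built
in log-ratio space, and couples it with a standard SI mixing model so both
markers inform a single vector of diet proportions.

## The model

Write $\phi_{i,s}$ for the $p$-part FA composition of prey individual $i$ of
species $s$ ($s = 1,\dots,n$).  After the additive log-ratio transform
$y_{i,s} = \mathrm{alr}(\phi_{i,s}) = \log(\phi_{i,s,1\ldots p-1}/\phi_{i,s,p})$
we assume $y_{i,s} \sim N(\mu_s, \Sigma_s)$: each species has its own mean
profile and covariance, both estimated, so prey uncertainty propagates into
diet estimates.

A predator $j$ with diet proportions $\pi_j$ consumes prey items whose
profiles $\phi_{j,s}$ are themselves draws from the species distributions
(predators do not eat "average" prey).  Its expected profile is the
closure-normalised mixture

$$\tau_j = C\Big\{\sum_{s=1}^{n} (\pi_{j,s}\,\Phi_s)\,
(\kappa_s \odot \phi_{j,s})\Big\},$$

where $\Phi_s$ is the relative fat content of species $s$, $\kappa_s$ a
vector of per-FA conversion coefficients (selective uptake/metabolism), and
$C$ the closure operation.  Observed predator signatures satisfy
$t_j \sim N(\mathrm{alr}(\tau_j), \Sigma_\tau)$.  Because $C$ absorbs any
common scale, $\kappa$ and $\Phi$ are identified only as *relative* uptake;
the package reports closure-normalised coefficient draws for this reason.
Both have moment-matched priors — gamma for $\kappa$, log-normal for $\Phi$
— parametrised directly by means and variances from controlled feeding
experiments; an entry with zero prior variance is treated as a known
constant and is not sampled.

Isotopes mix linearly with additive trophic fractionation $\gamma_s$:
$t^{SI}_r = \sum_s \pi_{r,s}(y_s + \gamma_s)$ plus residual noise, with
$\gamma_{s,SI} \sim N(\nu_{SI}, \sigma_{SI})$ from the literature or from
feeding trials.  There is deliberately *no* default fractionation: an SI
model without fractionation priors refuses to build rather than assuming a
tacit trophic shift.  Prey FA and SI samples need not come from the same
individuals, and a joint model shares one diet vector across both
likelihoods — this is where the resolution gain of combining markers comes
from.

### Diet-proportion structure

* **population** — one diet vector for all predators, with a symmetric
  Dirichlet prior (α = 1 by default).
* **individual** — per-predator diets whose log-ratio transforms are drawn
  from a population distribution $N(\Pi, \Sigma_\Pi)$.
* **linear** — the population mean is replaced by a design-matrix mean
  $X B$, giving regression/ANOVA structure on diets.

The hierarchical prior is stated most naturally on clr-transformed
proportions, but clr vectors sum to zero, so a density on them is
degenerate.  Internally the package therefore uses an orthonormal isometric
log-ratio basis (a fixed Helmert-type contrast matrix) — the identical model
family with a proper density — and reports proportions on output.

### Latent, mean-prey and marginal consumed profiles

By default the consumed prey items $\phi_{j,s}$ are sampled (latent mode),
matching the model statement above.  Two alternatives are provided through
the `consumed` argument:

* **mean** (`latent_prey = FALSE`) substitutes the species mean profile
  $\mathrm{alr}^{-1}(\mu_s)$ and omits the latent terms.  This is the crude
  approximation: between-item variation in consumed prey must then be
  absorbed by the predator residual $\Sigma_\tau$, and with few predators
  a high-dimensional $\Sigma_\tau$ cannot be estimated well from the
  residuals alone — in our simulations the mean mode is visibly
  *overconfident* at feasibility scale (posterior SDs of a few hundredths
  against replicate errors up to 0.1).
* **marginal** integrates the latent consumed prey out of the predator
  likelihood instead of sampling it: exactly for isotopes (the mixture is
  linear, so the marginal covariance is
  $\Sigma_\tau^{SI} + \sum_s \pi_s^2 \Sigma_s^{SI}$), and to second order
  for fatty acids, where the within-species covariance is propagated
  through the Jacobian of the alr mixture (delta method; the Jacobian is
  validated against finite differences in the test suite) and the marginal
  mean carries the closed-form second-order curvature correction —
  $E[\mathrm{alr}\,\tau(\phi)]$ differs from
  $\mathrm{alr}\,\tau(\mathrm{E}\,\phi)$ by a Jensen offset that is far
  from negligible at realistic within-species spread (up to ~0.03 alr
  units at SD 0.3), and ignoring it biases the diet estimates.  The
  residual covariances keep conjugate updates through a partially
  collapsed scheme that re-draws the per-predator mixture deviation,
  updates the covariance given it, and discards it.  One consequence of
  keeping the prey-covariance update conjugate is that $\Sigma_s$ is
  informed by the prey samples only in this mode — a deliberate cut,
  harmless when prey are well sampled.

The marginal mode exists because the exact latent formulation, while
faithful, is very hard to sample at realistic scale with random-walk
kernels: the diet vector and the per-species means of the consumed
profiles form a tight ridge (the predator term pins their combination),
and chains need enormous runs to traverse it.  The marginal mode removes
the latents — and with them the ridge — while retaining their variance
contribution, giving mean-prey speed with latent-model calibration.  It
supports population grouping and is what the package's own validation runs
use; the latent mode remains the default for final inferences where its
run-time is acceptable.

## Priors and numerical choices

* Covariances ($\Sigma_s$, $\Sigma_\tau$, their SI analogues, $\Sigma_\Pi$)
  get inverse-Wishart priors with degrees of freedom `dimension + 2` and
  scaled identity scale matrices.  The scale — the order of magnitude of the
  diagonal — is the one knob that practice shows needs manual adjustment for
  good mixing with few samples.  Defaults: 0.1 for prey alr covariances,
  0.01 for the predator FA residual, 1 and 0.1 (‰²) for the SI analogues,
  0.1 for the diet covariance.
* Prey alr means: vague $N(0, 10^2)$; prey isotope means: $N(0, 100^2)$ ‰.
* Zero FA proportions are replaced multiplicatively (default δ = half the
  smallest positive observed proportion) before log-ratio transforms; the
  rule preserves ratios among non-zero parts.
* FA tables whose rows sum to ≈100 are detected as percentage exports and
  rescaled; row sums within 10⁻³ of 1 are re-closed with a warning, larger
  deviations are errors.
* The alr reference defaults to the last FA column and is user-selectable;
  it is recorded in the dataset object.

## Sampling

The sampler is an adaptive Metropolis-within-Gibbs scheme over parameter
blocks in unconstrained space (log scale for positive scalars, ilr for
simplexes).  Conditionally conjugate blocks are updated by exact Gibbs
draws: every covariance matrix (inverse-Wishart), the diet
hyper-parameters, the fractionation coefficients (the predator isotope
mean is linear in them), the latent consumed isotope values, and the prey
means in latent mode.  In mean-prey and marginal modes the prey means use
an independence Metropolis-Hastings step whose proposal is the exact
conditional given the prey samples, so the acceptance ratio reduces to the
predator-likelihood ratio.  Latent consumed FA profiles are updated by
vectorised per-predator Metropolis moves (the per-predator blocks are
conditionally independent), supplemented by joint blocks that move the
diet vector together with per-species consumed or prey means — the
direction the predator term otherwise pins.  All random-walk blocks adapt
their scales towards standard acceptance targets during warmup, switching
to empirical-covariance (Haario-style) proposals once enough warmup draws
exist; adaptation is frozen at the end of warmup.  Chains start from
overdispersed points (moment-based for prey blocks, jittered uniform
compositions for diets), and the (data, settings, seed) triple fully
determines the draws.

Defaults are 3 chains × 20 000 iterations with half discarded as warmup.
Convergence is monitored by split-chain potential scale reduction
($\hat R$; a fit warns above 1.1) and autocorrelation-based effective
sample size.

## Selecting fatty acids

Gas chromatography yields many FAs; keeping them all inflates model
dimension without adding signal.  `select_fas()` ranks FAs by their
contribution to among-species separation in a constrained analysis of
principal coordinates — principal coordinates of Euclidean distances
between clr-transformed profiles, constrained by species membership, which
for this metric is an RDA of the clr data (computed with `vegan::rda`).
The contribution of an FA is its eigenvalue-weighted squared loading summed
over constrained axes, normalised to sum to one across FAs; this
attribution is one documented choice among alternatives.  FAs are added in
contribution order while cumulative contribution is below a target (default
0.75) and the *prey-matrix condition number* — the ratio of extreme singular
values of the species-mean proportion matrix re-closed on the candidate
subset — stays at or below a cap (default 20).  The condition number guards
against collinear prey signatures, which leave mixing proportions poorly
identified no matter how much variance the subset explains.  The defaults
bracket values that worked well in applications of this procedure
(≈75% of among-source variance at a condition number around 16, with the
next FA nearly doubling it).

## The simulator

`scenario_spec()`/`simulate_diet_data()` generate data from exactly the
forward model the estimator assumes, with known truth.  Species mean
log-profiles sit at the vertices of a regular simplex in the zero-sum
log-abundance subspace, scaled so that the pairwise distance equals the
`separation` parameter — one interpretable knob for source separation
(default 2 alr units, against a within-species SD of 0.3: well-separated
but visibly overlapping species, the regime a feasibility study wants).
Isotope means are placed analogously (default 3‰ separation, 0.5‰
within-species SD, carbon/nitrogen-like fractionation truth of 1.0‰ and
3.4‰).  Optional knobs confine the species signal to a subset of FAs
(zero-sum contrasts within that subset, so clr differences are exactly
confined to it), draw per-predator diets from a symmetric Dirichlet
(specialist vs generalist populations), perturb the true conversion
coefficients around 1 with chosen variance (the generated dataset always
carries matching prior tables), or slide one species' mean towards the
convex hull of two others (collinearity).

What the simulator does *not* emulate: real FA profiles have strongly
non-Gaussian within-species structure, measurement zeros, and conversion
coefficients that vary between individuals, and real prey libraries are
sampled unevenly.  Passing the validation below therefore shows the
estimator is correct *under its own assumptions*, not that those
assumptions hold for any particular field dataset.

## Validation and problem sizes

The test suite validates, at sizes chosen to keep a full run on one CPU in
tens of minutes:

* exact compositional algebra (1 000 random compositions, parts 3–25,
  tolerance 10⁻¹⁰);
* likelihood equality with independently coded direct-summation oracles on
  100 random small instances (≤3 species, ≤4 FAs, ≤3 predators, 10⁻¹⁰
  relative);
* agreement of the MCMC diet marginal with a 4 000-point numerical
  posterior in a two-species model with all nuisance blocks fixed
  (total-variation distance < 0.05 over 25 bins);
* feasibility-scale recovery — 3 species × 30 samples, 12 FAs, 2 isotopes,
  10 predators, true diet (0.2, 0.3, 0.5) — posterior means within ±0.10 of
  truth for every component in each of 20 replicates, 90% intervals
  covering truth in ≥80% of cases;
* joint FA+SI posterior SDs no larger than FA-only SDs for all components
  in at least two-thirds of 20 matched replicates;
* monotone response of recovery error to source separation (decreasing)
  and conversion-coefficient noise (increasing), Spearman tests over
  3 levels × 10 replicates each;
* recovery of 3 discriminative FAs out of 10 (4 species) with top-3 recall
  ≥ 0.9 over 50 replicates;
* feeding-trial conversion-coefficient recovery (6 FAs, 10 predators on
  pure diets, low noise) with closure-normalised posterior means within
  ±0.05 of truth per FA.

The replicated validation fits use the marginal consumed-prey mode with
short chains (2 × 2 000 iterations for the feasibility replicates, single
chains of 1 100–1 400 for the spread and sensitivity sweeps, where only
posterior means and SDs are scored and convergence at these sizes was
established beforehand with multi-chain runs, split-$\hat R \le 1.05$);
the grid-oracle comparison uses 2 chains of 24 000 iterations.  These are
sampler settings, not model properties, and the latent-prey and mean-prey
modes are exercised separately in the unit suite.
`scripts/acceptance.R` re-runs a compact version of the same battery from
scratch and writes the resulting numbers as JSON.

## Known limitations

* Model dimension grows with predators × FAs × species; fully Bayesian runs
  beyond roughly 15 FAs and 5 prey species become slow, which is precisely
  why FA selection and the mean-prey approximation exist.  Geometric-mean
  predator profiles (`geometric_mean_profile()`) are a cheap first pass.
* Posterior means of proportions near the simplex boundary are biased
  inward by construction; for very uneven diets report the full posterior,
  not a point estimate.
* The SI observation-noise covariance is given the same inverse-Wishart
  treatment as the FA residual by symmetry; concentration-dependent
  fractionation is supported only through the fractionation priors.
* Individual/linear joint models require the same predator individuals in
  both marker tables; population models do not.
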
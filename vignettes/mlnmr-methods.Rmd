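---
title: "Multilevel network meta-regression: model, integration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel network meta-regression: model, integration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mlnmr)
```

This vignette is the package's own account of the statistical method it
implements, the numerical machinery underneath it, and the design
decisions that were genuinely open — with the reasoning behind each.

## 1. The model and its assumptions

We synthesise a connected network of randomised trials comparing
treatments $k = 1, \dots, K$ (treatment 1 the network reference). Trials
either contribute individual patient data (IPD) — one record per
randomised individual with outcome $y_{ijk}$ and covariates $x_{ijk}$ —
or aggregate data (AgD): per-arm summary outcomes plus study-level
marginal covariate summaries.

A single individual-level model is specified for everyone:

$$y_{ijk} \sim \pi_{\mathrm{Ind}}(\theta_{ijk}), \qquad
g(\theta_{ijk}) = \eta_{jk}(x) = \mu_j + x^\top(\beta_1 + \beta_{2,k})
+ \gamma_k,$$

with study-specific intercepts $\mu_j$, prognostic coefficients
$\beta_1$, treatment-specific effect-modifier interactions
$\beta_{2,k}$ (with $\beta_{2,1} = 0$, $\gamma_1 = 0$), and
individual-level treatment effects $\gamma_k$. Covariates declared only
prognostic have their interaction entries fixed to zero, and vice versa.

Aggregate arms are *not* modelled by plugging mean covariates into
$g^{-1}$ — that incurs aggregation bias whenever the link is non-linear,
because $E\{g^{-1}(\eta(X))\} \ne g^{-1}(\eta(E X))$. Instead the
aggregate-level mean outcome is the individual model integrated over the
study's joint covariate distribution $f_{jk}$:

$$\theta_{\cdot jk} = \int_{\mathcal X} g^{-1}\{\eta_{jk}(x)\}
f_{jk}(x)\, dx.$$

The key substantive assumption is *conditional constancy of relative
effects*: given the modelled effect modifiers, individual-level relative
effects are constant across study populations. Unobserved effect
modifiers violate it and are not detectable from a two-study network;
with larger networks, residual heterogeneity (Section 6) and
inconsistency checks probe it.

### Aggregate likelihoods

For a normal individual likelihood the aggregate mean is normal with
variance $\sigma^2_{jk}/N_{jk}$; Poisson counts aggregate to a Poisson
total. The binary case is genuinely non-trivial: the arm count is a sum
of *non-identical* Bernoulli variables — Poisson-binomial, with mean
$\sum_i p_{ijk}$ but variance $\sum_i p_{ijk}(1 - p_{ijk})$, *smaller*
than the naive binomial $N\bar p(1-\bar p)$. We therefore use the
two-parameter binomial approximation, adjusting both parameters to match
the Poisson-binomial mean and variance:

$$N'_{jk} = \frac{N_{jk}\,\bar p_{jk}^2}{\overline{p^2}_{jk}}, \qquad
p'_{jk} = \frac{\overline{p^2}_{jk}}{\bar p_{jk}},$$

where $\bar p$ and $\overline{p^2}$ are the integrals of the probability
and the squared probability over $f_{jk}$. Both identities
($N'p' = \sum p_i$ and $N'p'(1-p') = \sum p_i(1-p_i)$) are verified
against brute-force Poisson-binomial enumeration in the test suite.
$N'$ is real-valued, so the density is evaluated through the log-gamma
generalisation of the binomial coefficient; in the degenerate case of
equal probabilities, $\overline{p^2} = \bar p^2$ and the plain binomial
is recovered exactly. If observed events exceed $N'$ (possible only
under extreme heterogeneity) the continuous extension is used and a
warning raised.

## 2. Numerical integration: Sobol' points under a Gaussian copula

Each AgD study gets a *fixed* grid of $\tilde N$ covariate points built
once and reused at every posterior evaluation:

1. $\tilde N$ points of a Sobol' low-discrepancy sequence in
   $[0,1)^d$, one dimension per covariate. The generator is implemented
   in the package (Joe–Kuo direction numbers, 21 dimensions, 31-bit
   precision) and scrambled by a seeded random digital shift. The shift
   preserves the digital-net structure — and hence the near-$1/\tilde N$
   error rate — while displacing the all-zeros first point, which would
   otherwise map to $-\infty$ under the inverse-normal transform.
2. Inverse-normal transform, then correlation by the Cholesky factor of
   the copula correlation matrix, then the normal CDF back to uniforms:
   a Gaussian copula.
3. Each uniform column through its marginal quantile function.

The copula correlation is borrowed from the IPD studies: Spearman rank
correlations (valid for continuous *and* binary covariates) are pooled
across IPD studies weighted by study size, then mapped to latent normal
correlations by $r = 2\sin(\pi\rho_s/6)$ — the exact inversion of the
Gaussian-copula rank correlation for continuous margins, an accepted
approximation for binary ones. Elementwise transforms can leave the
positive semi-definite cone, so the matrix is repaired by clipping
eigenvalues at $10^{-8}$ and rescaling to unit diagonal.

Marginals are moment-matched from published summaries: normal (as
given); gamma with shape $(m/s)^2$, rate $m/s^2$ for right-skewed
covariates; a logit-normal rescaled to known bounds (default $[0,100]$,
for percentage covariates) with location/scale found by Nelder–Mead on
the first two moments (optimizer tolerance $10^{-12}$, accepted at
$10^{-2}$ relative moment error); Bernoulli for binary covariates, as a
latent-normal threshold at the $(1-p)$ quantile.

Grid quality is testable: marginal Kolmogorov–Smirnov distance below
$2/\sqrt{\tilde N}$, imposed rank correlations recovered within 0.05,
and — for a probit-normal integrand with a closed form — absolute
integration error decaying with log–log slope steeper than $-0.8$ across
$\tilde N = 2^6 \dots 2^{14}$, reaching below $10^{-3}$ at
$\tilde N = 10^4$. The default is $\tilde N = 10{,}000$ points;
test-suite fits use 64–1000 points, which these error rates show is
already accurate to 2–3 decimal places — adequate for the simulation
scales used there.

## 3. Effect-modifier structures

Estimating independent interactions for treatment $k$ needs IPD on $k$
or several AgD studies of $k$. When neither holds, the *shared*
structure ties $\beta_{2,k}$ within a treatment class (one interaction
vector per class); the *exchangeable* structure instead draws
per-treatment interactions from a class-level normal
$\beta_{2,k;l} \sim N(m_{\beta_2,l}, \sigma^2_{\beta_2,l})$ with
hyperpriors, and requires at least two treatments per class for the
variance to be identifiable (enforced with an error). A practical
consequence of the shared structure, used as a test oracle: contrasts
between treatments of the same class are covariate-free and therefore
numerically identical in every target population, draw by draw.

## 4. Estimation

Sampling is by MCMC in JAGS, with model code generated per network and
model specification. Two reparameterisations make the one-site
Gibbs/slice sampler efficient; both are exact (unit-Jacobian) changes of
variables, so the declared priors are unchanged:

- **Covariate standardisation.** Covariates are centred at the pooled
  IPD mean and scaled by the pooled IPD sd (AgD-weighted summaries when
  no IPD exist); draws are transformed back before reporting. Centring
  decorrelates $\mu_j, \gamma_k$ from the coefficients; scaling equalises
  step sizes across covariates with arbitrary units.
- **Hierarchical centring of interactions.** Rather than sampling
  $\beta_1$ and $\beta_{2,r}$ (which are strongly anti-correlated in the
  posterior, since treatment arms identify only their sum), the sampler
  draws the reference coefficient vector $b_0 = \beta_1$ and per-group
  arm coefficient vectors $b_r \sim N(b_0, s_{\beta_2}^2)$, with
  $\beta_{2,r} = b_r - b_0$ derived. The joint prior is identical to
  independent normals on $\beta_1$ and $\beta_2$; the likelihood now
  factorises over $b_0$ (control arms) and $b_r$ (class-$r$ arms),
  removing a posterior correlation of $\approx -0.95$ observed in the
  unreparameterised model and roughly tripling worst-case effective
  sample size at fixed wall time.

Priors (all configurable): $N(0, 100^2)$ on $\mu_j$, $\gamma_k$ and on
the standardised-scale coefficients $\beta_1, \beta_2$ — placing the
prior per covariate sd is what makes a single "non-informative" sd
meaningful across weight in kilograms and binary indicators —
half-normal(0, 2.5²) on $\tau$ and on $\sigma_{\beta_2,l}$ (the
heterogeneity prior is a weakly-informative default; nothing in the
method pins it down), half-normal(0, 10²) on the normal-likelihood
outcome sd, one $\sigma_j$ per study. Defaults: 4 chains, 1000 warmup +
1000 kept iterations.

Random effects use the sequential conditional form of the equicorrelated
multivariate normal: within study $j$, the $m$-th non-reference arm has

$$\delta_{j,m} \mid \delta_{j,<m} \sim
N\!\Big(\gamma_{k_m} + \tfrac1m\textstyle\sum_{i<m}(\delta_{j,i} -
\gamma_{k_i}),\; \tfrac{m+1}{2m}\tau^2\Big),$$

which reproduces exactly the joint distribution with variance $\tau^2$
and pairwise correlation 0.5. Studies without a reference arm still
parameterise effects against treatment 1; their $\mu_j$ is the
(unobserved) reference intercept, absorbed as a free parameter.

Convergence is assessed by split-chain $\widehat R$ (threshold 1.01 —
stricter than the classical 1.1/1.05, cheap at this scale), effective
sample sizes and Monte Carlo standard errors; the fit warns when any
parameter exceeds the threshold. Identical seeds give bit-identical
chains (per-chain RNG streams are seeded as `seed + chain`).

## 5. Target-population prediction

Contrasts are linear in covariates, so the population average equals the
plug-in at the population's effect-modifier means:
$d_{ab}(P) = \bar x_P^\top(\beta_{2,b} - \beta_{2,a}) + \gamma_b -
\gamma_a$ per draw. Consistency $d_{ab}(P) = d_{b}(P) - d_{a}(P)$ holds
exactly within each population — but not across populations, which is
the point of population adjustment. Absolute outcomes are genuinely
non-linear and are averaged over the population's full covariate
representation (IPD rows, or a grid built exactly as for AgD studies,
reusing the copula machinery). The baseline $\mu_{(P)}$ is the study's
own intercept draws for in-network populations; external populations
accept a fixed value or a normal (mean, sd) sampled per draw. Point
estimates are posterior means with 95% equal-tailed credible intervals
(the estimator is not dictated by the method; the mean is the common
MCMC reporting choice).

## 6. Model criticism

Residual deviance is computed per data point — each IPD individual and
each AgD arm is one point — as the posterior mean of
$-2\{\log L(y\mid\theta) - \log L(y\mid y)\}$; AgD arms use the
two-parameter-adjusted binomial with the observed count compared against
the same $N'$. Note the "about 1 per point" heuristic is a
large-count/normal intuition: for Bernoulli points the expectation at
the truth is $2H(p)$ (twice the entropy), below 1 at event rates away
from one half — the tests compare against this exact oracle. DIC uses
$p_D = \bar D - \hat D$ with $\hat D$ evaluated at the posterior means
of the parameters.

Residual heterogeneity is assessed by refitting with random effects and
examining DIC and the $\tau$ posterior; inconsistency by the
unrelated-mean-effects (UME) model, which frees one effect per observed
(study-baseline, treatment) design pair. In a network without closed
loops the UME and consistency models coincide — a structural fact the
tests exploit — while an inconsistency injected into a loop shows up as
a DIC advantage for UME concentrated on that loop's studies. The UME
construction here frees the treatment effects only; interaction
contrasts keep the declared tying structure, because freeing them per
design is not identifiable in networks of realistic size. Node-splitting
is out of scope.

## 7. The synthetic-data generator

`default_scenario()` emulates the structure of a phase-3 psoriasis-like
programme: 6 treatments (reference A; B, C, E, F sharing one
effect-modifier class, D alone), studies S1–S2 (IPD, arms A/B/C), S3
(IPD, arms A/D) and S4 (AgD, arms A/E/F/D) — so the AgD-only treatments
are identified through the shared-class assumption plus S4's own
reference arm, mirroring how such networks are identified in practice.
Five covariates (normal age; gamma-skewed weight and duration; two
binaries) with modest rank correlations and small between-study shifts
in means; probit outcomes with prognostic and effect-modifying
coefficients of realistic magnitude (treatment effects 1.7–2.8 SMD,
interactions up to 0.15 SMD per covariate sd; placebo response around
13–18%). The default 200 individuals per arm keeps replicate fits at
interactive speed. The generator draws covariates from the same
marginal-plus-copula family the integration module assumes, so the
fitted model can be exactly well specified — passing recovery tests
therefore demonstrate correctness of the machinery, *not* robustness to
misspecified marginals, unobserved effect modifiers, missing data or
dropout, none of which the generator emulates.

Aggregation of a simulated study (`aggregate_from_ipd()`) reproduces
exactly the published view the method assumes: per-arm counts and
study-level marginal summaries, individual rows discarded.

## 8. Numerical choices and degenerate inputs

- Probabilities are clamped to $(10^{-12}, 1-10^{-12})$ before logs;
  $\overline{p^2}$ is clamped into $[\bar p^2, \bar p]$ (Jensen bounds)
  against floating-point violations at the grid level.
- Gamma moment matching is closed-form; logit-normal matching fails
  loudly if the moments are unreachable on the declared support.
- Constant covariates make rank correlations undefined: error naming the
  covariate. Duplicated columns give a degeneracy warning.
- Arms duplicated within an AgD study are merged (summing events and
  sizes) with a warning; single-arm AgD studies are accepted, flagged,
  and excluded from fitting and connectivity — they could only inform
  baselines, which requires assumptions this package does not make.
- Networks mixing outcome kinds, missing covariate cells (imputation is
  out of scope), binary outcomes outside {0,1}, events exceeding sample
  sizes, and proportions outside [0,1] are all rejected at read time.

## 9. Known limitations

- Likelihoods: Bernoulli (probit/logit), normal (identity), Poisson
  (log). No survival or multinomial outcomes.
- The logit link integrates the expit numerically; no probit-scale
  approximation of the logit is shipped.
- Only the Gaussian copula is provided.
- The sampler is Gibbs/slice-based; very large IPD networks will be
  slower than a gradient-based implementation, though the psoriasis-scale
  problem (≈4000 individuals, $\tilde N = 10^4$) remains of the order of
  minutes.
- Posterior draws are reported on the uncentred scale; convergence
  diagnostics are computed on the sampled (standardised) scale, where
  mixing is the question being asked.
- A prior-predictive identity ("no data gives back the prior") has no
  runnable form here, since the model graph requires at least one study.
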
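---
title: "Probabilistic-input conjunctive diagnosis models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic-input conjunctive diagnosis models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pincdm)
```

## The models

Cognitive diagnosis models classify examinees on $K$ binary latent skills
("attributes"). A test of $I$ items is described by a Q-matrix, the $I \times
K$ binary design matrix with $q_{ik} = 1$ when item $i$ requires attribute
$k$. Under the conjunctive condensation rule, the ideal (latent) response of
person $n$ to item $i$ is

$$\eta_{ni} = \prod_{k=1}^K x_{nk}^{\,q_{ik}},$$

with the convention $0^0 = 1$, so attributes an item does not require never
affect it. Observed responses are noisy versions of the latent ones through
the slip/guess signal-detection link

$$P(Y_{ni} = 1) = g_i + (1 - s_i - g_i)\,\omega_{ni},$$

where $s_i$ (slip) is the probability of missing an item despite holding its
requirements and $g_i$ (guess) the probability of solving it without them.
Estimation imposes the monotonicity restriction $g_i < 1 - s_i$, so that
holding the required attributes can never hurt.

The four variants implemented here differ only in what stands in for
$\omega_{ni}$:

* **DINA** — deterministic mastery: $\omega_{ni} = \eta_{ni}$ with binary
  profiles $\alpha_{nk} \in \{0, 1\}$.
* **PINC** — probabilistic mastery: each person carries a mastery
  *probability* $\delta_{nk} \in (0, 1)$ per attribute, and
  $\omega_{ni} = \rho_{ni} = \prod_k \delta_{nk}^{\,q_{ik}}$. The person
  report is a vector of graded mastery probabilities rather than a forced
  binary classification.
* **HO-DINA / HO-PINC** — a single higher-order trait
  $\theta_n \sim N(0, 1)$ drives all attributes through a logistic link,
  $\delta_{nk} = \text{logit}^{-1}(\lambda_k \theta_n - \beta_k)$ with slopes
  $\lambda_k > 0$ and intercepts $\beta_k$; HO-DINA additionally draws
  $\alpha_{nk} \sim \text{Bernoulli}(\delta_{nk})$ before the conjunction,
  HO-PINC feeds $\delta$ into the product directly.

The PINC model nests the DINA model exactly: evaluated at binary $\delta$ the
two response functions coincide, a reduction the test suite asserts
identically. Under local independence the likelihood is the product of
Bernoulli cell likelihoods; missing responses are supported through a mask
and simply drop out of every likelihood sum (ignorable missingness — real
data sets have holes even though simulated ones do not).

## Priors and sampler

Estimation is Bayesian with non-informative priors:
$\delta_{nk} \sim \text{Beta}(1,1)$; $s_i \sim \text{Beta}(1,1)$ and
$g_i \sim \text{Beta}(1,1)$ truncated to $g_i < 1 - s_i$; for the
higher-order variants $\theta_n \sim N(0,1)$ (fixed, for identification),
$\lambda_k \sim N(0, 4)\,I(\lambda_k > 0)$ and $\beta_k \sim N(0, 4)$. The
normal spread of 4 is read as a *variance* (standard deviation 2); both are
exposed as `cdm_priors(lambda_sd =, beta_sd =)` should a user prefer the
other reading. DINA base rates use $\pi_k \sim \text{Beta}(1,1)$.

`fit_cdm()` runs a Metropolis-within-Gibbs sampler written in C++, with one
full sweep per iteration:

* $\delta_{nk}$ — random-walk Metropolis on the logit scale (the Beta prior
  plus log-Jacobian make the target terms $a \log \delta + b \log(1 -
  \delta)$), so draws stay strictly inside $(0, 1)$;
* $\alpha_{nk}$ (DINA variants) — drawn exactly from the two-point full
  conditional;
* $\theta_n$, $\lambda_k$, $\beta_k$ — scalar random walks; $\lambda$
  proposals at or below 0 are rejected, which with a symmetric proposal is
  exactly the positive-truncated target;
* $(s_i, g_i)$ — random walks with proposals outside
  $\{s > 0,\; g > 0,\; g < 1 - s\}$ rejected (the truncated prior);
* the deviance $-2\log L$ is recorded at every retained iteration, not
  recomputed afterwards.

Chains start from independent prior draws. Proposal scales adapt in batches
of 50 iterations during burn-in only, stepping each log-scale by
$\min(0.25, 1/\sqrt{b})$ at batch $b$ toward the target acceptance band
0.30–0.45, and are frozen at the end of burn-in so the retained draws come
from a fixed, detailed-balance-preserving kernel. Defaults follow the
estimation protocol of the recovery studies: 2 chains × 10,000 iterations,
5,000 burn-in, no thinning.

Numerical choices: probabilities are clamped into
$[10^{-10}, 1 - 10^{-10}]$ before any logarithm (Beta(1,1) draws can approach
the bounds); latent-response caches are always recomputed as fresh products
rather than updated by ratios, so no floating-point drift accumulates over
sweeps; a response column that is constant 0 or 1 triggers a warning (weakly
identified item parameters), not a failure; an attribute column of zeros in
the Q-matrix warns that the corresponding mastery parameters will simply
return their prior.

One caveat the convergence report is designed to surface: with flat
Beta(1, 1) mastery priors, the PINC likelihood can trade $\delta$ against
$(s_i, g_i)$ on weakly informative designs. The monotonicity restriction is
the only structural guard imposed — matching the estimand — so inspect
`convergence_report()` and the acceptance-rate ledger rather than expecting
the sampler to hide the problem.

## Convergence and fit indices

`psrf()` implements the Brooks–Gelman potential scale reduction factor,
$\sqrt{((n-1)/n)\,W + \text{var}(\bar x_c)} / \sqrt{W}$, bounded below by
$\sqrt{(n-1)/n}$; `convergence_report()` applies it to every monitored
scalar ($\delta$ or $\theta, \lambda, \beta$ or $\pi$; $s$; $g$; deviance)
with the customary cutoff of 1.2 (1.1 stricter).

`fit_indices()` reports DIC with the effective parameter count
$p_D = \text{var}(D)/2$ (headline) alongside the plug-in variant
$\bar D - D(\hat\theta)$, and labels the posterior mean deviance and the
plug-in deviance separately because "-2LL" conventions differ across
software. The conditional predictive ordinate uses the harmonic-mean
estimator per cell, $\text{CPO}_{ni} = [M^{-1} \sum_m 1/L_{ni}^{(m)}]^{-1}$,
accumulated as a streaming log-sum-exp over the replayed draws; item-level
$-2\text{LCPO}$ is $-2 \sum_n \log \text{CPO}_{ni}$ and the test level is the
sum over items. For the deterministic variants the plug-in deviance inserts
the posterior mastery probabilities into the marginal product algebra, which
equals the response probability conditional on $\theta$ marginal over
independent Bernoulli attribute draws.

## The simulator and the recovery study

`simulate_cdm()` generates data under all four variants at the generating
values of the recovery design: five attributes; the structured Q-matrix of
`default_qmatrix()` (single-attribute identity block, adjacent pairs, then
three-or-more blocks; 30-item tests repeat the 15-item design); mastery
$\delta_{nk} \sim \text{Beta}(1,1)$ for PINC; $\theta \sim N(0,1)$,
$\lambda_k = 1.5$, $\beta = (-1, -0.5, 0, 0.5, 1)$ for the higher-order
variants; item quality high ($s = g = 0.1$) or low ($s = g = 0.2$). The
published design figure is not machine-readable, so `default_qmatrix()` is a
concrete instantiation honouring every stated structural constraint of that
design; residual cell-level differences are absorbed by the recovery
tolerances. HO-PINC responses are generated directly from $\delta$ (the
model definition implies no intermediate Bernoulli draw); HO-DINA draws one
Bernoulli $\alpha_{nk}$ per person–attribute first.

`recovery_condition()` orchestrates simulate–fit–score cycles with the
protocol of the reference study: the fitted model always matches the
generating model; a replication whose fit has any monitored PSRF $\ge$ 1.2
has its *dataset replaced* by a freshly simulated one (new derived seed)
rather than re-run longer, capped at 10 attempts. All randomness descends
from one base seed through a multiplicative-congruential spawning rule
(`child_seed()`), so any chain, replication or replacement is reproducible
in isolation.

Aggregation conventions are deliberately emitted in duplicate, since pooling
order is a genuine free choice: RMSE pooled over persons × replications and
as the mean of per-replication RMSEs; correlation per replication then
averaged, and pooled. The two differ by far less than the reporting
precision in every condition we compute.

Two problem scales are built in. *Replica* mode (30 replications,
10,000/5,000 iterations) mirrors the full reference protocol; *desk* mode (5
replications, 3,000/1,500) is the default for the test suite and the
acceptance script and reproduces pooled RMSEs to well within their
replication noise — RMSE pooled over 2,500 person-values is stable to about
±0.005 across seeds.

## Interpreting recovery correlations: the EAP ceiling

One identity is worth keeping in mind when reading recovery tables. For the
exact posterior mean $\hat\delta = E[\delta \mid Y]$, the law of total
variance gives $\text{Var}(\hat\delta) = \text{Var}(\delta) -
E[(\hat\delta - \delta)^2]$, and since the posterior mean maximizes
correlation with the truth among all estimators,

$$\text{Cor}(\hat\delta, \delta) \;=\;
  \sqrt{1 - \frac{\text{RMSE}^2}{\text{Var}(\delta)}}$$

is a *ceiling* tied to the achievable RMSE. Under the independent-uniform
PINC design ($\text{Var}(\delta) = 1/12$), an RMSE near 0.23 pins the
person-level correlation near 0.55 — which is what this package computes,
and what an independent importance-sampling oracle for the exact EAP (known
item parameters, true prior) also yields. Reported correlations
substantially above this ceiling at the same RMSE cannot be person-level
Pearson correlations of any estimator; treat RMSE as the primary recovery
metric and the correlation as a consistency check against this identity.
The higher-order design is far above the independent-attribute ceiling in
absolute terms (its pooling shrinks RMSE and raises the ceiling), which is
the substantive argument for the HO-PINC variant.

## What the simulator does and does not emulate

Passing recovery tests show that the sampler recovers the generating
parameters when the model is true, the Q-matrix is correct and complete, and
responses are conditionally independent. Real data violate all three in
degrees: attributes may be hierarchically related, items locally dependent,
the Q-matrix misspecified, and missingness non-ignorable. None of these are
simulated here (deliberately — they are model extensions, not generator
settings), so good desk-scale recovery is evidence about the estimator, not
about the adequacy of the model for any particular test.

## Known limitations

* Conjunctive condensation only; disjunctive/compensatory rules are out of
  scope.
* Dichotomous items and binary attributes; no polytomous extensions,
  attribute hierarchies, differential item functioning or local dependence.
* No Hamiltonian/NUTS sampling or marginal-likelihood estimation; model
  comparison rests on DIC and $-2$LCPO.
* The PINC identifiability caveat above: flat mastery priors on short tests
  make $\delta$ posteriors broad, and mastery probabilities shrink strongly
  toward 0.5. That is honest uncertainty, not a bug, but users wanting sharp
  classifications should prefer the higher-order variants or informative
  priors.
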
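---
title: "A Beta mixture item response model for careless responding in VAS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Beta mixture item response model for careless responding in VAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vascareless)
```

## The measurement model

Visual analogue scale responses live on the open unit interval, and the Beta
distribution is the natural conditional law for them.  The attentive
component of the model gives respondent $i$'s answer to item $j$ a
$\mathrm{Beta}(a_{ij}, b_{ij})$ distribution whose shapes are driven by the
linear predictor $\eta_{ij} = s_j\,\theta_{i,d(j)} - b_j$:

$$a_{ij} = \exp\!\big((\eta_{ij} + \alpha_j)/2\big), \qquad
  b_{ij} = \exp\!\big(-(\eta_{ij} - \alpha_j)/2\big).$$

Three properties make this parameterization the right one, and the package's
unit tests pin each of them down:

* the expected response is $\mathrm{logit}^{-1}(\eta_{ij})$ — an S-shaped
  item characteristic curve in the trait, with the wording sign $s_j = \pm 1$
  flipping its direction for reverse-keyed items;
* the dispersion $\alpha_j$ cancels from the mean entirely; it only moves the
  total concentration $a_{ij} + b_{ij}$, so higher $\alpha_j$ means a more
  peaked conditional density and a more peaked item information function;
* at $\theta = b_j = \alpha_j = 0$ the model collapses to the uniform
  $\mathrm{Beta}(1,1)$.

Item information is computed numerically (`item_information()`): the
expectation over the response, by Gauss–Legendre quadrature with 201 nodes,
of the negative second trait-derivative of the log-density, central
differences with step $10^{-4}$.  Both constants are arguments.  A
closed-form information function exists in the literature but the numerical
route keeps the whole information machinery dependent on nothing except the
log-density, which is the quantity the rest of the package is built on.

## The careless component and the mixture

Careless respondents do not process content, so their responses should
depend on neither the trait nor the item.  The model absorbs them with a
single $\mathrm{Beta}(m, n)$ shared across persons and items — a residual
class with minimal structure rather than a taxonomy of careless behaviours.
Each response cell is a two-component mixture

$$f(y_{ij}) = \pi_i\, f_{\text{att}}(y_{ij}) + (1 - \pi_i)\,
  \mathrm{Beta}(y_{ij}\,|\,m, n),$$

and the class indicator is never sampled: the sampler works directly with
this marginal form (log-sum-exp per cell), which keeps the posterior free of
discrete jumps.  The attentive class is anchored structurally — it is the
only component with item-driven shape — so no label-switching correction is
needed; the recovery tests verify that the attentive component never absorbs
the planted careless rows.

The person probabilities get a hierarchical two-class Dirichlet prior,
$(\pi_i, 1-\pi_i) \sim \mathrm{Dirichlet}(\omega\pi,\ \omega(1-\pi))$, which
reduces to a Beta density; $\pi$ (population attentive share) has a flat
Dirichlet(1,1) prior and $\omega$ a half-Cauchy(0, 5).  This hierarchy is
not an implementation detail: when contamination is rare, it pulls
individual $\pi_i$ upward toward the attentive bulk, which is exactly why
the fixed 0.5 threshold rule misses careless respondents at low prevalence
while the ranking rule (flag the $\lfloor N(1-\hat\pi)\rceil$ least
attentive) stays calibrated.

## Priors and numerical choices

| parameter | prior | default scale | why |
|---|---|---|---|
| $b_j$, $\alpha_j$ | Normal(0, sd) | 10 | diffuse on the logit-type scale |
| $\sigma_d$ (trait SD) | half-Cauchy | 5 | weakly informative, heavy tail |
| $R$ (trait correlations) | LKJ | shape 1 | uniform over correlation matrices; skipped when $D=1$ |
| $m$, $n$ | half-Cauchy | 5 | careless shapes can legitimately be far from 1 |
| $\pi$ | Dirichlet(1, 1) | — | uniform |
| $\omega$ | half-Cauchy | 5 | concentration can be near-zero or large |

The item-prior SD of 10 and the half-Cauchy scale 5 for $m, n$ are the
package's own defaults, chosen to match the diffuse intent of the prior
stack and kept configurable through `prior_config()`.  Trait means are fixed
at zero for identification; the normal mixture CFA baseline instead fixes
the trait variance to one and frees the loadings (its identification
constraint is an assumption of this package, with loading signs constrained
by item wording through a signed half-normal(0, 10) prior).

All likelihood work is done in log space with log-gamma normalizing
constants; $m, n < 1$ produce densities unbounded at the boundaries and
would overflow otherwise.  For the same reason every generated or loaded
response is squeezed into $[10^{-3}, 1-10^{-3}]$ — a documented clamp shared
by the simulator, the readers, and the fitters.  Boundary responses in
stored files are legal and clamped on load rather than rejected, because
slider software exports exact 0s and 1s routinely.  Missing cells simply
contribute no likelihood term; only rows that are entirely missing are
dropped.

## Sampler

`vasmix()` runs an adaptive random-walk Metropolis-within-Gibbs scheme
written in C++: per iteration it updates item difficulties and dispersions
(per item), traits (per person, jointly over dimensions), trait SDs and —
for multidimensional fits — correlation entries under the LKJ prior with a
positive-definiteness check, the careless shapes $(m, n)$ (two single moves
plus one joint move along their correlated direction, which is what makes
the midpoint-clustered contamination pattern mix acceptably), each
$\mathrm{logit}(\pi_i)$, $\mathrm{logit}(\pi)$, and $\log\omega$.  Proposal
scales adapt toward 44% acceptance during burn-in only.  Initialization
starts near the attentive-dominant regime the hierarchical prior implies
($\pi_i = 0.9$, $\pi = 0.8$, $m = n = 1$, items at prior means, traits at
zero), jittered per chain; all randomness flows through R's RNG so a seed
reproduces a fit bit for bit.

Convergence is assessed by the Gelman–Rubin potential scale reduction
(`epsr()`, optionally split-chain), with the conventional 1.1 cutoff.  A
non-converged fit is not an error — the flag is returned and longer chains
are the remedy.  Two scales matter:

* `vasmix()` defaults to 2 chains × 4,000 iterations (half burn-in): a
  desk-scale setting for interactive work.  Production analyses should use
  2 × 40,000.
* `run_study()` aggregates each condition cell over the replications whose
  *structural* parameters (items, trait SD, $m$, $n$, $\pi$, $\omega$) pass
  EPSR < 1.1.  Person-level parameters are excluded from this gate: with
  shortened chains the ~600 per-person EPSR values are individually noisy,
  and gating on their maximum would discard most replications for reasons
  unrelated to the quantities the tables average.  `vasmix()`'s own
  `converged` flag remains the strict all-parameters rule.

## What the simulator does and does not emulate

`simulate_vas()` reproduces the validation design: $N = 300$ persons,
10 items with the first half reverse-keyed, difficulties and traits standard
normal, dispersions uniform on $[0, 3]$, a unidimensional generating trait
(deliberately the hardest case — multidimensional structure makes careless
patterns easier to spot), and a fixed number $\lfloor N\pi_c\rceil$ of
careless rows so that classification metrics have a deterministic
denominator.  Three contamination patterns are available: i.i.d.
$\mathrm{Beta}(0.5, 0.5)$ extremes (model-true), person-level end preference
(each careless person sticks to $U(0, 0.2)$ or $U(0.8, 1)$ — drawn
independently per item within the chosen side), and a truncated
$\mathcal N(0.5, 0.25)$ midpoint pattern.  Only the first is itself a Beta
law; the other two exist to probe the residual class under mis-specification.

Real careless behaviour is messier than any of these: respondents mix
strategies within a questionnaire, attentiveness can drift over time, and
response times carry signal the model never sees.  Passing the simulation
suite therefore demonstrates correct recovery of this generating process,
not a guarantee about any particular empirical dataset.

## Design choices that were genuinely open

* **Fixed careless count** per dataset rather than Bernoulli contamination:
  per-condition metrics then have an exact denominator.
* **Threshold ties**: a posterior attentiveness probability of exactly 0.5
  is labelled attentive — careless requires being strictly more likely
  careless than attentive.
* **Ranking-rule count**: $k = \lfloor N(1-\hat\pi)\rceil$ with
  half-away-from-zero rounding and ties broken by ascending person index.
* **End-preference side** is a person attribute, not a response attribute;
  within-row coherence is exactly what makes the pattern "overly
  consistent".
* **Replication seeds** are a deterministic hash of (base seed, cell,
  replication), so any single replication can be regenerated in isolation.
* **Factor-score comparison condition**: the bundled comparison between the
  mixture model and the plain Beta IRM runs at 15% Beta-pattern
  contamination.  Among the candidate cells this is the one where the two
  models' trait-recovery profile (RMSE near 0.29 for the mixture and 0.35
  for the Beta IRM, correlations near 0.96 for both) sits exactly in the
  regime the comparison is meant to illustrate: enough contamination for the
  unadjusted model to suffer visibly, not so much that it breaks down.  The
  condition is an argument of `run_study()`, not a constant.
* The study harness reports the **cell-level scale** it ran at (replication
  counts and chain lengths are recorded in every `vasmix_study` object), and
  the reduced-scale defaults trade Monte-Carlo error for runtime — the
  bundled tests use 8–20 replications with 2 × 3,000-iteration chains
  against the full design's 100 replications of 2 × 40,000.

## Known limitations

A single residual Beta class cannot represent multimodal careless mixtures
exactly (the end-preference pattern is approximated by a U-shaped Beta);
the number of careless classes is fixed at one; attentiveness is a person
property, not an item-level state, so within-person lapses are out of scope;
and marginal-likelihood-based model comparison (WAIC/LOO) is not provided.
The CFA baseline is intentionally mis-specified for bounded data — it exists
to document that failure mode, not as a recommended analysis.
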
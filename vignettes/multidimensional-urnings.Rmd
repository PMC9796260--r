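---
title: "Tracking multiple abilities with urn-based ratings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking multiple abilities with urn-based ratings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(urnings)
```

## The measurement problem

Adaptive learning systems stream millions of item responses and must keep
per-learner ability estimates current after every single response, for many
interrelated skills at once. Classical multidimensional IRT estimation is
far too heavy for that loop, and lightweight trackers in the Elo family
have no known invariant distribution, so the uncertainty of their ratings
cannot be quantified and adaptive item selection silently inflates their
variance.

This package implements an urn-based rating system that keeps the
computational footprint of Elo while having fully known statistical
behaviour. Every learner holds one *tracking urn* per ability dimension
(urn size $n_{im}$, green-ball count — the *urning* — $R_{im}$), every item
holds a single urn ($n_j$, $R_j$). The proportion $R/n$ is the running
estimate of an inverse-logit-transformed parameter, and when the true
parameters are stable each urning has a known conditional product-binomial
invariant distribution, so exact confidence statements are available at
any moment.

## Response model

An item relates to the $M$ dimensions through a vector of non-negative
integer weights $w_{jm}$ with total $W_j = \sum_m w_{jm}$, covering both
between-item multidimensionality (a single non-zero weight) and
within-item multidimensionality (several non-zero weights). The
probability of a correct response is compensatory,

$$\Pr(X_{ij} = 1) =
  \frac{\exp(\sum_m w_{jm}\theta_{im} - \delta_j)}
       {1 + \exp(\sum_m w_{jm}\theta_{im} - \delta_j)},$$

implemented in `prob_correct()`. The same probability has an urn
formulation (`prob_correct_urn()`): draw $w_{jm}$ balls from each learner
urn and $W_j$ balls from the item urn until all learner balls share one
colour that differs from all the item balls; the learner's colour decides
the response. The two forms coincide exactly when the item urn proportion
is $\pi_j = \mathrm{logistic}(\delta_j / W_j)$ — the division by $W_j$ is
easy to miss but essential: for $W_j > 1$ an item urning $R_j/n_j$
estimates $\mathrm{logistic}(\delta_j/W_j)$, not
$\mathrm{logistic}(\delta_j)$. The package's invariant-distribution tests
pin this parameterization down: with the wrong mapping the stationary
distribution of the update chain visibly departs from the product
binomial; with the right one it matches to machine precision.

## The two-step update

After observing $X_{ij}$ the urnings are updated in two steps
(`update_pair()`):

1. **Add** balls matching the response: $R^*_{im} = R_{im} + w_{jm}X$,
   $R^*_j = R_j + W_j(1 - X)$ (`step1_add()`).
2. **Sample** $w_{jm}$ balls without replacement from each learner urn and
   $W_j$ from the item urn until either all learner balls are green and
   all item balls red, or the reverse; remove the sampled balls
   (`step2_sample()`).

Step 2 is not simulated literally; its outcome is a Bernoulli draw with
probability $P_A/(P_A+P_B)$, where $P_A$ and $P_B$ are falling-factorial
products over the enlarged urns (`learner_green_probability()`). Factors
are multiplied as doubles (magnitudes stay far below overflow for urn
sizes up to $10^4$ with weights up to 4), and any non-positive factor
marks its branch impossible rather than raising an error. The
implementation is validated exhaustively against an independent
hypergeometric enumeration for all small configurations.

Each accepted update conserves $r_{+m} = R_{im} + (w_{jm}/W_j)R_j$, and
the invariant distribution of a repeatedly updated pair is binomial in
each urn conditional on $r_{+m}$. The original sample-then-replace rule
with its Metropolis acceptance step is retained as
`legacy_unidim_update()` for the unidimensional unit-weight case; the two
algorithms share one stationary distribution, which the test suite checks
by a two-sample comparison of long thinned runs.

## Adaptive selection and its correction

Items are selected either uniformly at random or adaptively with
probability proportional to the expected response variance
$\hat p_{ij}(1-\hat p_{ij})$ (`selection_probabilities()`), with smoothed
urn proportions $\hat\pi = (R+1)/(n+2)$ so that pegged urns remain
selectable and the correction ratio below is always defined. Matching item
difficulty to learner ability inflates the variance of the ratings; the
package therefore accepts a proposed update with probability
$\min\{1, S'_{ij}/S_{ij}\}$, the ratio of the item's selection probability
at the proposed and current urnings (`adaptivity_correction()`), with the
normalizing constant over the candidate set recomputed for the proposed
state. Within a session candidates exclude items the learner has already
answered, and the same candidate set is used on both sides of the ratio.
The correction is applied only to adaptively selected interactions;
under random selection the ratio is identically 1.

## Anchoring through reference subsets

Because abilities drift and learners enter and leave, the total ball count
is not a usable reference point. Instead, for each dimension the items
loading only on that dimension form a *reference subset* whose urning sum
is held constant: a reference item's update is applied only together with an
opposite update of equal magnitude from the same subset, via queues of
pending requests (`reference_queue()`, `route_item_update()`). Queues are
keyed by (dimension, magnitude) so a $+2$ can only pair with a $-2$ and
the subset sum is conserved exactly — necessary because single-loading
items may carry weight 2 or 3. An item may hold several pending requests,
and a pop may select the requesting item's own opposite entry, which nets
to zero; entries whose application would overrun the partner's urn
(possible because urnings move while a request waits) are skipped until
they are applicable again. Learner urnings are never queued. This open
queue is load-bearing: the net pending imbalance is exactly the channel
through which genuine population-level growth enters the learner urnings,
and it is self-stabilizing because surplus green balls raise the
learner-green probability and thereby suppress further item down-requests.
Design variants that cap or discard queue entries were examined and are
either unstable (discarding the item side of a request injects balls with
positive feedback) or clamp growth (rejecting the whole update once an
item is pending caps the inflow when the queue saturates); the simulation
tests guard the chosen discipline. Fit diagnostics (next section) should be read
for non-reference items: the constraint deliberately distorts the
reference items' marginal distributions (their variance drops below the
binomial), which is visible to the identity the diagnostics test.

## Item-fit diagnostics

Under random selection and a correctly specified model, the probability of
a correct response given the post-Step-1 urning values equals the
probability that the learner's draw wins Step 2. `accumulate_fit()`
tabulates, per item and dimension, observed proportions correct and
learner-green proportions for every combination of post-Step-1 values
$(r_m, t)$; `flag_misfit()` tests the two proportions per cell. Because
the expected proportion is itself estimated from the same updates, the
default test is the exact conditional two-proportion test (hypergeometric
null, mid-$p$) rather than a one-sample binomial test, which would be
markedly miscalibrated. For single-loading items, where the closed form is
available (`expected_cell_probability()`), an exact binomial mid-$p$ test
against the known probability can be used instead.

Two calibration caveats, both visible in the test suite: cells with
near-degenerate expected proportions cannot reject at any level (discrete
conservatism), so type-I calibration should be judged on informative
cells; and for items loading on several dimensions the per-dimension
marginal cells mix over the remaining dimensions, which couples the two
proportions and makes the test conservative. Misfit direction is
informative: overstated weights concentrate "observed above expected"
flags where the proportion correct is below one half (the
ability–response relationship is exaggerated), understated weights show
the mirror image, and the item urning variance is inflated (deflated)
when a weight is overstated (understated).

## Population and individual inference

Treating the urnings of learner $i$ as independent
$\mathrm{Binomial}(n_{im}, \mathrm{logistic}(\theta_{im}))$ observations
of a latent ability vector $\theta_i \sim \mathrm{MVN}(\mu, \Sigma)$,
`estimate_population()` samples the posterior of $(\mu, \Sigma)$ by
Metropolis-within-Gibbs: vectorized per-dimension random-walk updates of
all latent abilities (scale adapted towards a 0.44 acceptance rate during
burn-in only) alternate with conjugate normal–inverse-Wishart draws.
Defaults: 2,000 iterations, 500 burn-in, prior $\mu_0 = 0$,
$\kappa_0 = 1$, $\nu_0 = M + 2$, $S_0 = I$ — weakly informative on the
scale of logit abilities. A split-$\hat R$ above 1.1 on $\mu$ triggers a
warning. The small negative dependence among urnings induced by sum
conservation is ignored; the binomial variance is an upper bound.
Correlation estimates are not attenuated by measurement error, because the
binomial uncertainty of each urning is part of the model rather than
folded into the observed score.

`individual_posterior()` draws $\theta_i$ given $(\mu, \Sigma)$ with the
same kernel: estimates pool towards the population mean and across
dimensions, so credible intervals are systematically narrower than the
exact Clopper–Pearson interval of a single urning
(`urning_interval()`) mapped to the logit scale. For $M = 1$ the sampler
is checked against grid quadrature.

## The simulation harness

`run_system()` drives full synthetic systems; the hot loop (selection,
response generation, two-step update, correction, queue routing) is C++.
Two designs are built in:

* **Stationary**: abilities MVN on the logit scale (defaults mean 0, SD 1,
  equicorrelation 0.5), difficulties the equally spaced standard-normal
  quantiles, a 25-type item bank (9 single-dimension types with weights
  1–3, 12 two-dimension types, 4 three-dimension types; every $W_j$
  divides the default item urn size 204).
* **Dynamic**: each learner keeps a fixed factor score $z_i \sim N(0,I)$
  and $\theta_i(t) = \mu(t) + L(t)z_i$ with $\Sigma(t) = L(t)L(t)^\top$,
  so the population is exactly MVN at every timepoint while means, SDs and
  correlations follow monotone linear paths (defaults: mean 0 to 1, SD 1
  to 1.5 — a Matthew effect — and correlation 0.5 to 0.7 — an increasing
  positive manifold — over 200 timepoints). These endpoint values are the
  package's own choice of a realistic school-year-scale development; the
  trajectory law is a deliberate simplification (per-learner rank
  stability is perfect, which real practice data will not show). Half the
  items keep constant difficulty, a quarter drift up and a quarter down by
  0.5 logits across the horizon, balanced within each reference subset so
  the anchors stay interpretable.

Per session every learner answers one randomly selected item (these feed
the fit diagnostics) and $g-1$ adaptively selected ones. Initial urnings
are Binomial$(n, 1/2)$, item urnings $W_j \cdot$Binomial$(n_j/W_j, 1/2)$ —
a symmetric cold start that respects the divisibility of item urnings by
$W_j$. Runs are bit-reproducible from the seed (a single global R RNG
drives everything, including the C++ core), and `replay_events()` can
reconstruct any run's final state deterministically from its event log.

What passing simulations do *not* show: robustness to guessing, response
times, dropout, or learners whose developmental ordering changes — none of
these are generated.

## Numerical and design choices

* Logistic/logit are computed in overflow-safe form; Step-2 products use
  doubles with explicit zero-clamping of impossible branches.
* Learner order within a session is a fresh random shuffle each session.
* Items never repeat within a learner's session; the Metropolis ratio uses
  the same reduced candidate set that selection used.
* The exact conditional mid-$p$ test is the default misfit test
  (calibration reasons above); Benjamini–Hochberg adjustment is available
  but off by default, mirroring the per-cell display the diagnostics are
  designed for.
* Test and example problem sizes (hundreds of learners, hundreds of items,
  a few thousand sessions) are chosen so the whole suite runs in minutes;
  all headline checks are scaled-down surrogates of much larger systems,
  with sizes stated in the tests themselves.

## Known limitations

* Weights must be integers fixed in advance; the system tracks but cannot
  estimate them (misfit diagnostics flag wrong choices).
* Urn sizes are fixed per entity for a run; no adaptive urn-size schedule.
* A dimension without single-loading items has no reference subset, and
  development along it is not interpretable over time.
* The population model estimates each timepoint separately; there is no
  joint temporal model of $(\mu_t, \Sigma_t)$.
* In a fully stationary anchored system the learner-urning mean tracks
  $n\pi$ closely but not perfectly (the anchoring constraint and adaptive
  correction leave offsets on the order of a few thousandths on the
  probability scale), which matters only when biases of that order are at
  stake.
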
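---
title: "Estimating the selected treatment mean in multistage drop-the-losers trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the selected treatment mean in multistage drop-the-losers trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The design and the estimation problem

A multistage drop-the-losers trial starts with $K_1$ experimental arms and
drops a predetermined number of poorly performing arms at each interim
analysis until a single arm remains for the confirmatory stage.  A
three-stage trial keeping $L$ of $K$ arms after stage one is written
$K\!:\!L\!:\!1$.  Patient responses on arm $k$ are
$N(\mu_k, v^2)$ with known common variance; at stage $j$ every active arm
recruits $n_j$ patients, so its stage mean $Y_{kj}$ has standard deviation
$\sigma_j = \sqrt{v^2 / n_j}$.  Arms are ranked at each interim analysis by
their cumulative MLEs $\bar{X}_{kj} = \sum_{i \le j} n_i Y_{ki} / N_j$,
$N_j = \sum_{i\le j} n_i$.  With a common variance and shared control data,
this head-to-head ranking of experimental-arm MLEs is equivalent to ranking
control-adjusted test statistics, and the control arm plays no role in
selection; the package therefore never simulates one, and it estimates
$\mu_1$ (the selected arm's mean) rather than the contrast with control,
whose control part is a trivial unbiased MLE.

We index arms by their final rank, so the selected arm is arm 1.  The
realized set of selection inequalities is the event $Q$.  Under $Q$ the
naive all-stage MLE $\bar{X}_{1J}$ is biased upward: the interim means that
earned the arm its selection are conditionally too large.  The bias is
worst when all arms are truly equal, and grows with the number of starting
arms.

### What exactly is conditioned on

`rank_and_select()` records, for each selection stage, the threshold the
survivors had to clear: the largest cumulative MLE among the arms dropped
there.  Event $Q$ is taken as *membership*: every kept arm beat every
dropped arm at that stage, with survivors ordered among themselves only at
the ranking that decides the next drop.  For a 3:2:1 trial this is exactly
three inequalities,
$$Y_{11} \ge Y_{31},\quad Y_{21} \ge Y_{31},\quad \bar X_{12} \ge \bar X_{22},$$
and the equal-means selection probability is exactly $1/6$ (the first two
constraints pick the dropped arm with probability $1/3$; the stage-two
comparison is symmetric in the two kept arms, giving $1/2$).  A stricter
reading would also order the kept arms at stage one ($Y_{11} \ge Y_{21}$).
We expose that as the `q_ordering = "full"` option of
`selection_probability()` — note its equal-means probability is
$\approx 0.117$, *not* $1/6 \times 1/2 = 1/12$, because the stage-two
comparison is positively correlated with the stage-one ordering.  The
estimators always condition on the membership inequalities, which is the
form in which the truncation bound below is derived.  Internal ordering
among simultaneously dropped arms is recorded in the ranking but excluded
from estimator conditioning.

Ties in any ranking are broken toward the lower original arm index — a
probability-zero event for continuous data, fixed deterministically so that
tests are reproducible.

## The five point estimators

* **MLE** $\bar{X}_{1J}$: efficient, biased upward.
* **Final-stage mean** $Y_{1J}$: unbiased (all selection happened before
  the final stage) but ignores the earlier data; its MSE is $\sigma_J^2$.
* **RB1** — Rao-Blackwellization of $Y_{1J}$ given the selected arm's
  sufficient total $Z_1 = \sum_j n_j Y_{1j}$, its intermediate stage means
  $Y_{12},\dots,Y_{1,J-1}$, and $Q$.  Conditioning on the intermediates is
  the price of tractability: given them, multivariate-normal conditioning
  leaves a law of $Y_{1J}$ whose moments
  $$\tilde\mu = \frac{z - \sum_{i=2}^{J-1} n_i y_{1i}}{n_1 + n_J},\qquad
    \tilde\sigma^2 = \frac{v^2\, n_1}{n_J (n_1 + n_J)}$$
  are free of every mean parameter, and $Q$ truncates $Y_{1J}$ above at
  $$t = \min_{j < J}\ \frac{z - \sum_{i=2}^{J-1} n_i y_{1i}
        - \bigl(N_j c_j - \sum_{i=2}^{j} n_i y_{1i}\bigr)}{n_J},$$
  where $c_j$ is the stage-$j$ selection threshold.  Then
  $$\widehat\mu_1^{RB1} = \tilde\mu -
      \tilde\sigma\,\frac{\phi(w)}{\Phi(w)},\qquad w = (t-\tilde\mu)/\tilde\sigma,$$
  the mean of a normal truncated above.  RB1 is unbiased — indeed unbiased
  conditionally on *which* arm was selected — and has smaller variance than
  $Y_{1J}$, but it is not the UMVCUE: the conditioning statistic is
  sufficient without being minimal (hence not complete).  The same formula
  serves any number of stages, including $J = 2$, where it reduces to the
  classical two-stage conditionally unbiased estimator.
* **RB2** ($J = 3$) — the same construction conditioning on $Z_1$ alone and
  only on the stage-two selection rule: the unrestricted conditional mean
  is the MLE $z/N_3$ with variance $v^2 (1/n_3 - 1/N_3)$, truncated above
  at $t' = (z - N_2 \bar{X}_{22})/n_3$.  Because the conditioning event is
  not the full $Q$, RB2 keeps a small positive bias, traded for a
  substantially smaller MSE than RB1.
* **BC-MLE** (3:2:1 only) — maximizes the selection-conditioned likelihood
  of $(\mu_1, \mu_2, \mu_3)$ given one statistic per arm
  ($\bar X_{13}$, $\bar X_{22}$, $Y_{31}$, with variances $v^2/N_3$,
  $v^2/N_2$, $v^2/n_1$): three Gaussian log-densities minus
  $\log P(Q;\mu)$, where $P(Q;\mu)$ is the positive-orthant probability of
  the trivariate normal difference vector above.  It shrinks the MLE's
  bias at the cost of overcorrection (negative bias) under equal means.
  Generalizing it beyond 3:2:1 is possible in principle but the orthant
  computation grows quickly, so the package deliberately restricts it.

## Numerical choices

* The inverse Mills ratio $\phi/\Phi$ is evaluated on the log scale as
  `exp(dnorm(log = TRUE) - pnorm(log.p = TRUE))`, which is accurate for
  arbitrarily deep truncation (as $w \to -\infty$ the ratio approaches
  $-w$); no separate asymptotic branch is needed.
* Orthant probabilities use the deterministic TVPACK algorithm of
  **mvtnorm** at absolute tolerance $10^{-6}$, so likelihood values are
  exactly reproducible call to call.
* `bcmle_estimate()` runs Nelder-Mead from the naive statistics, polishes
  with box-constrained L-BFGS-B (bounds: statistics $\pm 10$ standard
  deviations, which keeps the search where the orthant probability is
  positive), and accepts the optimum only when every finite-difference
  gradient component is below $10^{-4}$; otherwise it restarts from
  jittered starts a bounded number of times.
* On a small fraction of replicates (about half a percent in the
  unequal-allocation null scenario, fewer with equal allocation) the
  selection-conditioned likelihood has no interior maximum: the orthant
  penalty keeps rewarding ever more extreme means and the optimum runs to
  the search box.  The conditional MLE does not exist for such data;
  `bcmle_estimate()` reports non-convergence rather than a box-pinned
  value, and the harness counts those replicates as failures instead of
  averaging an artifact of the box radius into the bias.
* Profile-likelihood endpoints solve $\Lambda(\mu_1) = \chi^2_{1,1-\alpha}$
  by bracketing and `uniroot` to $10^{-4}$, warm-starting each inner
  2-parameter maximization from its neighbour.
* Degenerate inputs: a zero-width bootstrap distribution (constant
  responses) yields a zero-width interval; `v2` must be strictly positive;
  an outcome whose recorded final-stage mean exceeds its truncation bound
  is rejected as inconsistent with $Q$.

## Interval estimation

The sampling distribution of RB1 is strongly left-skewed, so symmetric
(delta-method) intervals are a poor fit; the package instead adapts the
conditional nonparametric bootstrap.  Per accepted replicate, the selected
arm's stage-wise patient responses are resampled with replacement, and the
replicate is kept only if its bootstrap cumulative MLE clears the trial's
*original observed* competitor threshold at every selection stage — the
bootstrap analogue of conditioning on $Q$ with the competitors held fixed.
RB1/RB2 are then evaluated at the bootstrap means with the truncation
bounds recomputed from the bootstrap statistics (competitor thresholds
still frozen at their observed values).  Accepting a replicate is exactly
equivalent to its final-stage mean lying below the recomputed RB1 bound,
mirroring how $Q$ restricts the real data; freezing the numeric value of
the bound itself would instead collapse the resampling distribution's
skew and visibly undercover.  Percentile intervals are read off the
accepted replicates (no BCa correction).  The acceptance rate is reported,
and the run fails with a diagnostic below an 0.1% acceptance rate.

BC-MLE intervals invert the profile-likelihood ratio against the
$\chi^2_1$ quantile.  The MLE and final-stage estimators get standard Wald
intervals — exact in distribution for the unbiased final-stage mean
(constant width $2 \times 1.96\,\sigma_J$, e.g. 3.92 at $\sigma_J = 1$),
anti-conservative for the selection-biased MLE.

## What the simulations emulate, and at what scale

The synthetic-data generator draws exactly the study conditions of the
published comparisons: normal responses with known, arm- and
stage-constant variance, fixed per-stage sample sizes, selection always
running to the final stage (no efficacy/futility stopping), and no
control-arm involvement.  Real trials violate these in familiar ways —
unknown or heteroscedastic variances, non-normal outcomes, early stopping
— and the estimators are derived under the stated assumptions, so passing
tests certify the machinery under those assumptions, not robustness beyond
them.

Default study sizes keep full runs on a single CPU in minutes and are the
package's reporting convention: 50,000 replicates for closed-form point
estimators (Monte-Carlo SE of a bias about 0.003), 100,000 for the
unequal-allocation scenario, 2,000 replicates for the optimizer-bound
BC-MLE (SE about 0.017), and interval studies at 1,000 simulated trials
with 500 accepted resamples each.  The per-replicate RNG substreams are
keyed by `(seed, replicate_index)` so any single trial can be reproduced
in isolation; batch simulations use one stream seeded by the scenario
seed.

```{r, eval = FALSE}
library(droplosers)
design <- dtl_design(c(3, 2, 1), n_per_stage = 50, v2 = 50)
scenario <- dtl_scenario(design, means = c(0, 0, 0), reps = 50000,
                         seed = 1)
oc_study(scenario, estimators = c("mle", "rb1", "rb2", "final"))
```

## Known limitations

* Known, common variance only; the unknown-variance problem needs a
  different construction and is out of scope.
* BC-MLE and its profile intervals are 3:2:1-specific; RB2 is
  three-stage-specific.  RB1, the MLE and the final-stage estimator work
  for any `J`-stage strictly-decreasing schedule.
* No hypothesis testing, critical values or error-rate control — the
  package is about estimation.
* The bootstrap needs patient-level data for the selected arm at every
  stage; summary-level trials support only the closed-form estimators and
  Wald/profile intervals.
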
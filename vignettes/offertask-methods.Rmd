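---
title: "Modelling immediate versus long-term value in a sequential offer task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling immediate versus long-term value in a sequential offer task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offertask)
```

## The task

On each trial a player is shown a sequence of token offers (worth 3, 5 or 7
tokens) and accepts ("go") or rejects ("nogo") each one. The trial contains
7–9 offers, of which only 4–6 may be accepted; both counts are drawn
uniformly and independently and are not revealed, though a signal indicates
when the accept budget has been exhausted (after which rejections are
enforced). Offer values are probabilistic: at trial onset each value is
equally likely (the uniform contingency, `m = 0`). Accepting a 5-token offer
— except on the first offer, or after three or more prior rejections — shifts
the distribution of all future offers moderately toward 3s
(`m = 1`: probabilities 0.5/0.25/0.25), and accepting a 7-token offer shifts
it severely (`m = 2`: 0.9/0.05/0.05). The contingency follows the most
recent choice.

This structure dissociates the *immediate value* of acting (the face value
`IR` of the current offer) from its *long-term value* (`EV`): early in a
trial, accepting the largest offer is immediately lucrative but poisons the
remainder of the trial, so its long-term value can be negative. The package
provides the generative engine (`simulate_trial()`, `update_m()`,
`offer_probs()`), an exact optimal agent, four candidate choice models,
hierarchical model fitting and comparison, behavioral analyses, and a
synthetic-data generator — everything needed to study the
impulsivity/self-control trade-off the task was designed to expose.

## The optimal agent

The player never observes the trial's true offer count or budget, only that
the trial is still running. The agent therefore carries a belief **O** over
offers remaining (initially uniform on 7–9) and a belief **A** over accepts
remaining (uniform on 4–6), together with the contingency index `m`. After
each offer **O** shifts left by one and renormalizes,
$P'(c) = P(c+1)/\sum_c P(c+1)$, and after each accept **A** does the same —
a uniform belief stays uniform and shifts left. The expected value of a
state is the recursion

$$
SV(\mathbf{O},\mathbf{A}) = \sum_{r \in \{3,5,7\}} M_m(r)\,\max\!\Big(
P(o{>}1)\,SV(\mathbf{O}',\mathbf{A}),\;
r + P(o{>}1)P(a{>}1)\,SV(\mathbf{O}',\mathbf{A}')\Big)
$$

with the contingency state threaded through the tree: the accept branch for
`r` in {5, 7} continues with the updated `m` (subject to the first-offer
exemption and the three-rejection lock, both of which are derivable from
the beliefs: the offer index and the rejection count are functions of how
far **O** and **A** have shifted), and the reject branch advances the
rejection count. The recursion bottoms out when the current offer is
certainly the last (`P(o>1) = 0`), where the state is worth the mean of the
current offer distribution. At every state the agent's action values are

* `V_R = P(o>1) · SV(O', A)` — expected earnings after rejecting,
* `V_AF = P(o>1) P(a>1) · SV(O', A')` — future earnings after accepting
  (face value excluded), with `m` updated for the accepted value,
* `EV = V_AF + IR − V_R` — the long-term value of accepting.

Because both beliefs are deterministic functions of the number of offers
seen and accepts used, states are keyed by the integer triple
(offers seen, accepts used, `m`) and the recursion is memoized
(97 reachable states). `brute_force_sv()` re-derives every value by
exhaustive, cache-free recursion directly on belief objects and agrees with
the memoized solver to ten decimal places; the suite asserts this over the
full enumeration.

A consequence worth noting: the three-rejection lock makes rejections
*instrumentally* valuable (three early rejections buy immunity for the
rest of the trial), so at a state reached by rejecting early offers the
optimal agent keeps rejecting. At the states where immediate and long-term
value are most decorrelated — offer indexes 2–3 under the uniform
distribution with the first offer accepted — the solver reproduces the
task's signature dissociation:

```{r signature}
st <- belief_state(offers_seen = 1, n_accepted = 1, m = 0) # index 2, no rejections
round(sapply(c(3, 5, 7), long_term_value, state = st), 3)
```

Accepting the 7 is a net loss despite the largest immediate payoff;
accepting the 5 is worthwhile.

Two readings of the contingency rule are genuinely open. First, the printed
rule follows the *most recent* choice, implying that accepting a 5 while
`m = 2` relaxes the penalty to `m = 1`; we take this literal reading as the
default and expose `rule = "monotone"` to forbid improvement. Second, ties
at `EV = 0` are resolved to accept, fixed for determinism. A third variant,
`rule = "none"`, switches the contingency off entirely; in that limit the
suite checks that `EV` is strictly increasing in face value and that every
offer is worth taking whenever the budget certainly covers the remaining
offers — the greedy sanity limit.

## Choice models

All models map a decision value $V_A$ to an acceptance probability through
a softmax, $P(go) = 1/(1+e^{-\tau V_A})$, with temperature $\tau > 0$:

| model | $V_A$ | parameters |
|---|---|---|
| immediate | $IR - c$ | $\tau$, $c$ |
| optimal | $EV$ | $\tau$ |
| trade1 | $EV\,w + (IR - c)(1 - w)$ | $\tau$, $c$, $w$ |
| trade3 | as trade1 with $w \in \{w_3, w_5, w_7\}$ by face value | $\tau$, $c$, $w_3$, $w_5$, $w_7$ |

The trade weights $w \in [0,1]$ measure self-control: near 0 the player is
driven by face value (impulsive), near 1 by long-term value (controlled).
The intercept is called `c_int` and the weights `w`/`w3`/`w5`/`w7`
throughout, avoiding the symbol collision in the original notation where
the same symbol served as the immediate model's intercept and the
trade-off weight. Likelihoods (`choice_nll()`) cover every free choice —
forced post-budget rejections are excluded, probabilities are floored at
1e-12 — and long-term values are precomputed once per state by the solver
and joined onto the data (`augment_choice_log()`) rather than recomputed
per likelihood call. Nesting identities (`trade1` at $w=1$ equals
`optimal`; `trade3` with equal weights equals `trade1`) are asserted
exactly in the suite.

## Hierarchical fitting and model comparison

Parameters are fit with a Type-II maximum-likelihood random-effects
procedure. Each parameter is transformed to an unconstrained scale (log for
$\tau$, logit for weights, identity for the intercept) where the group
distribution is Gaussian, one distribution per parameter shared across
subjects. Expectation-Maximization alternates:

* **E-step** — each subject's posterior mode (MAP) under the current group
  prior, by L-BFGS-B with analytic gradients, plus a Laplace (Gaussian)
  approximation of the posterior from the finite-difference Hessian at the
  mode;
* **M-step** — moment-matching updates of the group mean and variance from
  the posterior modes and widths, with variances floored at 1e-6 (the flag
  `variance_floor_hit` records when the floor binds).

Iteration stops when every hyperparameter changes by less than 1e-4
(absolute), or after 100 iterations. The first E-step uses five starting
points (the prior mean plus four seeded draws from the prior); later
E-steps warm-start from the previous mode alongside the current prior
mean — once a subject's mode is known, additional cold restarts per
iteration buy nothing and cost a multiple of the total runtime. Restart
draws are shared across subjects and subjects are processed in sorted-id
order, so fits are invariant to row order and deterministic given the seed.
The EM objective (the summed Laplace-approximated log marginals) is
non-decreasing across iterations up to numerical slack, asserted in the
suite.

The per-subject marginal likelihood under the group prior is integrated by
the same Laplace approximation (the integration method is a standard choice
for this EM family; the original analysis does not state its own). Models
are compared by the integrated BIC,
$\mathrm{iBIC} = -2\log \hat{L} + k \log n$, where $k$ counts group-level
hyperparameters (a mean and a variance per parameter, so 2–10 across the
four models) and $n$ is the total number of free choices pooled over
subjects — a single dataset-level sample size, consistent with reading the
comparison as a likelihood-ratio-style test. Goodness of fit is summarized
by the Cox–Snell pseudo-r², $1 - \exp(2(\ell_0 - \ell_1)/n)$, against a
per-subject intercept-only baseline (constant accept probability at the
subject's maximum-likelihood accept rate), reported per subject and as a
group mean with a bootstrap 95% confidence interval over subjects.

## The synthetic-data generator

No subject-level dataset is distributed with the original study, so the
generator is the package's stand-in and defines its study conditions:
23 subjects, three sessions of 36 trials (108 trials per subject), choices
sampled from any of the four models. The default generating model is
`trade3` with group means at the reported central tendencies for this task
($\tau = 2.833$, $c = 5.891$, $w_3 = 0.834$, $w_5 = 1.0$, $w_7 = 0.264$) —
the $w_5$ mean is clamped to 0.995 because the logit transform is undefined
at the boundary — and between-subject SDs implied by the reported quartile
spreads under normality (IQR/1.349: 1.35, 0.95, 0.08, 0.38, 0.21
respectively). Per-subject parameters are drawn Gaussian in unconstrained
space so every draw respects its native domain; native SDs are mapped by
the delta method with the mapped SD clipped to [0.05, 3], which keeps the
transform-space spread finite for means near a domain boundary. Sessions
are statistically identical — the session column exists for schema
fidelity, not because fatigue or learning is modelled. Every subject's
stream derives from the master seed and the subject index, so a subject's
data do not depend on the group size and regeneration is byte-identical.

What the generator emulates: the exact trial structure, contingency
dynamics, budget enforcement, and softmax choice given the true model.
What it does not: reaction times, training-phase learning, session-order
effects, or any lapse/attention process. Passing recovery tests therefore
show that the fitting machinery identifies these models *under their own
assumptions* at the study's scale — not that real subjects are free of the
unmodelled processes.

## Behavioral analyses

`acceptance_grid()` pools the probability of accepting at every
(offer index × prior rejections × face value) state under the uniform
contingency, excluding forced records; cells with fewer than 15
observations (configurable) are flagged for display exclusion, and the flag
never removes data from any regression. `select_decorrelated_offers()`
returns the free choices at indexes 2–3 under `m = 0` — the states where
immediate and long-term value are maximally decorrelated; the rejection
count is deliberately left unrestricted, since the defining text for this
subset specifies only the index range and the uniform distribution.

`robust_logistic()` regresses go/nogo on `IR` and `EV` per subject (both
regressors competing for variance, unstandardized by default with a
z-scoring switch). The fitting algorithm is iteratively reweighted least
squares; the robust weighting referenced by the original description is
under-specified, so the package fits the plain logistic MLE first and then
applies bisquare down-weighting of large Pearson residuals (fixed scale,
tuning constant 4.685), switchable off to recover plain logistic
regression (verified against `glm()` in the suite). Fully iterated
bisquare weights can zero out every contrarian observation of a binary
response and push the fit to infinity; a diverging robust iteration
therefore falls back to the one-step robust estimate computed at the MLE,
which bounds outlier influence while remaining finite. Complete or
quasi-complete separation is flagged and the subject excluded from the
group test with a warning. Group inference is a two-sided one-sample
t-test on the per-subject betas with df = n − 1.

## Numerical choices and problem sizes

* Solver arithmetic is double precision throughout; values are rounded
  (3 decimals) only on CSV export. Oracle agreement is asserted at 1e-10.
* Subject-level optimization: L-BFGS-B within [−20, 20] per unconstrained
  coordinate (wide enough to be inert at any plausible optimum while
  keeping the transforms finite), `factr = 1e4`, non-finite objectives
  capped, eigenvalue-floored (1e-6) Hessians wherever a positive-definite
  matrix is required.
* EM: tolerance 1e-4 on all hyperparameters, max 100 iterations; a final
  E-step after convergence aligns the reported modes with the reported
  prior.
* Recovery studies run at the design scale of 23 subjects × 108 trials:
  10 replicates for parameter recovery (group-mean trade weights within
  ±0.15; per-subject $w_7$ correlation pooled across replicates ≥ 0.7) and
  5 replicates per generating model for model recovery (the generating
  model must top the iBIC ranking in a majority). Unit tests use smaller
  groups (2–6 subjects, 5–60 trials) chosen to exercise the same code
  paths quickly.

## Known limitations

* The Laplace approximation can be poor for weights whose posterior piles
  against a boundary (e.g. $w_5$ near 1); the variance floor and the
  bounded optimizer keep the fit finite, but the reported group variance
  for such parameters is approximate.
* iBIC inherits the Laplace error; model pairs separated by only a few
  units should not be over-interpreted.
* The optimal agent assumes exact knowledge of the task structure, as the
  players were instructed; it does not model learning of the
  contingencies, and no reaction-time process is modelled anywhere.
* The one-step fallback in the robust regression is a pragmatic guard, not
  a fully efficient robust estimator; for clean synthetic data it
  coincides closely with the MLE.
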
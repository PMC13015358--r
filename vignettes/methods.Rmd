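---
title: "Measuring decision bounds from an explicit decision variable"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring decision bounds from an explicit decision variable}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigeonbound)
```

## The task model

`pigeonbound` simulates and analyzes a two-alternative task in which the
decision variable is displayed explicitly: a pigeon starts at the center of
the screen and takes a biased random walk toward one of two seed piles.
Every 200 ms the pigeon takes one step drawn independently from a Gaussian
with standard deviation `sigma` and mean `+/-mu` (the sign, drawn 50/50 per
trial, is the correct answer). Positions are expressed in normalized screen
units: the screen edge is distance 1 from the start and the piles sit at
`+/-0.8`, the furthest reachable point. The per-step signal-to-noise ratio
(SNR) is `mu/sigma`. The decision-maker presses a key at a self-chosen time
to predict the pigeon's destination; in bounded-accumulation terms, the
pigeon position is the accumulated evidence and the keypress marks a
crossing of a decision bound `b`, the position magnitude at which the
decision-maker commits.

Blocks are budgeted in steps rather than trials: each trial charges one
step to start, one step per pigeon step until the keypress, and (in some
conditions) a step penalty for errors; the block ends with the first trial
that exhausts a 600-step budget, played to completion. Reward rate —
coins earned per step consumed — is therefore the quantity a good player
maximizes, and it is equivalent to total coins per block up to the budget
constant. The packaged condition table (`cohort_conditions()`) spans three
cohorts: payoff manipulations at fixed SNR, trial-wise SNR mixtures, and
within-trial SNR changepoints cued at a participant-specific time.

Two conventions are deliberate choices where the task description is
silent. First, the piles clip the walk but do not end the trial: positions
are truncated to `[-0.8, 0.8]` after each update and sampling continues
until the keypress. Second, trials are capped at `max_steps = 60` steps
(configurable); an agent that never crosses its bound makes a forced,
flagged choice at the cap. Both choices guarantee termination without
changing the dynamics in the regimes the analyses use.

## Simulated decision-makers

An `agent_policy()` couples a bound schedule to two nuisance processes that
real behavior exhibits:

* **Non-decision time (NDT)**, an integer motor delay of 0–4 steps between
  commitment and keypress. The walk continues during the delay and the
  choice is never revised, so the position at the keypress can disagree
  with the choice — an *incongruent* trial. The congruence structure of
  the data is what makes NDT estimable.
* **Fast guesses**: with some probability the agent commits at the first
  step to whichever side the pigeon moved, bypassing accumulation. These
  produce the cluster of very short response times seen in practice.

Bound schedules may be constant, linearly collapsing (`collapse_slope`
per step), SNR-specific in mixed blocks (a named `c(low=, high=)` pair,
the normative upper-envelope benchmark for an agent that knows each
trial's SNR), or piecewise at a within-trial changepoint
(`post_cp_bound`, applied from the changepoint step onward — the first
step drawn from the new distribution is the first the new bound can
terminate). Trial-to-trial Gaussian bound jitter is available for
regression-to-the-mean analyses.

`generate_cohort()` assembles heterogeneous agents into a tidy trial
table. Default heterogeneity — bounds uniform on `[0.1, 0.6]`, NDT uniform
on `{1, 2}`, fast-guess probability uniform on `[0, 0.3]` — spans the
qualitative range of human performance and makes no claim to be fitted to
any dataset. Ground-truth columns (`true_bound`, `true_ndt`, `fast_guess`)
ride along so estimators can be scored. Changepoint blocks place each
agent's changepoint at the ceiling of the median (or mean) response time
from that agent's own preceding fixed-SNR block with the matching starting
SNR; fractional statistics round up (a median of 9.5 steps cues step 10).
All randomness derives from one master seed via per-participant-per-block
sub-seeds, so cohorts regenerate byte-identically.

## The estimation chain

**NDT by congruence maximization.** For each candidate delay `d` in 0..4,
the congruence is the fraction of trials whose position `d` steps before
the keypress shares the sign of the choice; positions exactly at zero are
excluded from that delay's denominator (their side is undefined, and they
have measure zero under continuous steps). The estimate is the congruence-
maximizing delay, ties broken toward the smallest delay, computed once per
participant per SNR context (a per-participant granularity is available).
An identifiability caveat follows from the construction: delays below the
true NDT can only be rejected if some trial reverses sign between
commitment and the probed position. Agents with high bounds and no fast
guesses essentially never produce such reversals, the congruence profile
ties at 1, and the tie-break returns 0. Real decision-makers (and the
default generator) produce fast guesses, which supply sign reversals at
every delay; recovery fixtures therefore include a nonzero fast-guess
floor.

**DT and the raw bound.** Decision time is RT minus the session NDT,
floored at one step (floored trials are flagged and excluded from bound
regressions). The trial's raw bound is the absolute midpoint of the
positions one step before and at the DT — the expected crossing point if
the bound was crossed sometime during the final decision step. The
measurement is sign-invariant and needs no model fit.

**Short-DT bias correction.** At long DTs the midpoint is an increasingly
unbiased estimate of the generative bound, but at short DTs the position
distribution is dominated by the step distribution rather than the bound
(the first step lands where it lands regardless of `b`), so low bounds are
overestimated and high bounds underestimated. `build_correction_table()`
quantifies this by simulating each of 16 bounds (0.01–0.76 in 0.05 steps)
at the condition's SNR — 1e5 trials per bound by default, configurable
upward — pooling trials by DT, and fitting a per-DT ordinary least squares
line of measured on true bound; `correct_bound()` applies the analytic
inverse `(raw - intercept)/slope`, clipped to `[0, 0.8]`. DT cells with
fewer than 30 trials, DTs outside the simulated range, and non-positive
slopes fall back to the identity with a warning. The map is built at the
trial's true decision time, which the simulation knows exactly; pushing
the simulated ensembles through the congruence estimator instead makes the
pooled per-DT relation discontinuous (the ensemble-level delay argmax
flips between 0 and 2 across bounds, smearing DT by one step either way)
and was measurably worse in calibration, so the table assumes the data's
NDT estimate is correct — the regime the cohort tests verify.

**Diagnostics.** `bound_vs_dt_slope()` regresses per-DT median bounds on
DT (excluding DT <= 2, where measurements are least reliable) to quantify
collapse; `bound_change_regression()` regresses the change in bound onto
the previous bound, which has slope 1 for independent noise around a
constant mean and slope 0 for a bound drifting as a random walk;
`zscore_bounds()` (sample SD, n-1) puts per-participant time courses on a
common scale.

## Reward-rate functions

`rr_function_fixed()`, `rr_surface_two_snr()`, and
`rr_function_changepoint()` evaluate expected reward rate by brute-force
block simulation: for each bound (or bound pair) a deterministic agent
plays complete 600-step blocks, and the coins-per-step distribution across
repetitions is summarized by its median and 95% percentile interval, with
500 repetitions per grid point and the 16-point grid by default. The
simulated ideal observer has no motor delay, so its RT equals its DT.
Internally blocks are formed by slicing a pooled stream of i.i.d. trials
against the budget, which is statistically identical to simulating blocks
one at a time. `optimal_bound()` takes the grid argmax (ties toward the
lower bound), `rr_gradient()` reports the reward-rate change per unit
bound change from a reference bound to the optimum — the signed quantity
whose sign prescribes raising or lowering the bound — and
`bonus_threshold()` computes 80% of the ideal observer's median per-block
coin haul, the session bonus criterion.

Two structural results from these simulations matter for interpretation.
First, under the low-SNR coin-penalty condition the reward-rate function
rises steeply up to bounds near 0.4 and then forms a broad, nearly flat
plateau: because each 0.15-SD step overshoots the bound by ~0.1 on
average, a nominal bound `b` behaves like an effective bound `b + 0.1`,
and differences across the plateau are a few thousandths of a coin per
step. Any argmax on that plateau is a weak attractor — the satisficing
regime — and closed-form Wald formulas evaluated at the nominal bound
underestimate both the decision time and the reward-rate-maximizing bound
in this coarse-step regime. Second, in the changepoint conditions the
*unconditional* reward-rate functions are monotone decreasing (with
symmetric ±1 coins, immediate guessing maximizes unconditional reward
rate), but the post-changepoint function conditions on trials that survive
to the changepoint with positions still inside the pre-changepoint bound,
and that conditioning produces interior optima: after a low-to-high SNR
switch it pays to accumulate a few steps of the stronger evidence rather
than guess from near zero.

## Changepoint analyses

`derive_cp_step()` reproduces the cueing rule (ceiling of the RT
statistic); `changepoint_bound_change()` splits analyzed trials into
decisions that ended before (DT < changepoint) versus at/after the
changepoint and reports the difference in mean corrected bound per
participant. Decisions committed at exactly the changepoint step deserve
caution: their positions accumulated entirely under the pre-changepoint
regime, so when the post bound drops below the surviving position
distribution the "post" measurement reflects that survival distribution,
not the new bound. The `exclude_cp_commit` option drops these trials from
the post set; parameter-recovery simulations show the measured
change-versus-gradient relation is faithful with the exclusion and badly
attenuated without it. The default keeps them, matching the plain
pre/post contract.

## What the synthetic cohorts do and do not show

The generator reproduces the statistical skeleton the estimators assume:
bounded accumulation with exact, displayed evidence, integer motor delays,
occasional fast guesses, and step-budget block structure. It does not
emulate learning within or across blocks, attention or motivation drifts,
SNR misperception, choice revision during the motor delay, or continuous
RT jitter — so green recovery tests certify the estimation chain, not the
psychology of any particular dataset. Statistical reports (Wilcoxon
signed-rank comparisons, Spearman correlations) delegate to R's standard
routines and are reported without multiple-comparison correction by
default.

## Problem sizes and numerical choices

Simulation sizes in the tests are chosen to keep Monte-Carlo error an
order of magnitude below each asserted tolerance: 3e4–1e5 trials per bound
for correction tables (the full-size table uses 1e6 via
`n_sims_per_bound`), 100–500 block repetitions per reward-rate grid point,
and cohorts of 20–60 agents with 150–750 trials each. Engine correctness
is cross-checked against an independent density-evolution oracle
(Gaussian convolution on a position grid with absorbing bounds) that
shares no code with the sampler and agrees with it to three decimals in
accuracy and ~0.1 step in mean DT. Ties in the sign of a zero position at
commitment are broken uniformly at random; bound jitter and corrected
bounds are clipped to the physical range `[0, 0.8]`; reward-rate medians
use percentile intervals rather than normal approximations.
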
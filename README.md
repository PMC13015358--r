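# pigeonbound

Simulation and trialwise analysis of decisions about an **explicit decision
variable**: a pigeon taking a biased random walk toward one of two seed
piles. Because the accumulated evidence is displayed rather than hidden,
the decision rule — the bound on the decision variable at which the
decision-maker commits — can be measured on every single trial instead of
being inferred by fitting a sequential-sampling model to many trials.

The package is for computational cognitive scientists who want to

* simulate the task (Gaussian steps of mean ±μ and SD σ every 200 ms,
  positions clipped at the piles ±0.8, blocks budgeted at 600 steps, coin
  and step payoffs per condition, within-trial SNR changepoints),
* generate synthetic cohorts of bounded-accumulation agents with motor
  delays (NDT), fast guesses, and heterogeneous bounds — with ground truth
  retained for parameter-recovery scoring,
* run the trialwise estimation chain: NDT by choice-congruence
  maximization over delays 0–4, decision time DT = RT − NDT, the raw
  bound as the midpoint position over the final decision step, and a
  simulation-based correction for the short-DT measurement bias, and
* map Monte-Carlo **reward-rate functions** RR(b) (coins per step across
  whole simulated blocks) to locate optimal bounds, two-SNR bound
  surfaces, post-changepoint bound optima, and reward-rate gradients that
  prescribe raising or lowering the bound.

The core model is a discrete-step drift-diffusion process: evidence
`x_k = clip(x_{k-1} + N(±μ, σ))`, commitment at the first `k` with
`|x_k| ≥ b`, choice `sign(x_k)`, keypress NDT steps later while the walk
continues. The per-step SNR is μ/σ. Closed-form Wald limits
(accuracy `1/(1+exp(−2bμ/σ²))`, mean DT `(b/μ)tanh(bμ/σ²)`) serve as
small-step reference points; note that with σ = 0.15 per step, crossings
overshoot the bound by ≈0.1 on average, so the discrete process is
systematically slower and more accurate than the continuous formulas at
the same nominal bound.

## Worked example

```r
library(pigeonbound)

cond <- block_condition_fixture(1, 2)   # low SNR, +1/−4 coins, 600 steps
cond
#> <block_condition> mode=fixed mu=0.05 sigma=0.15 (SNR 0.333)
#>   payoffs: +1 correct, -4 error, 0 penalty steps; budget 600 steps

set.seed(7)
blk <- simulate_block(agent_policy(bound = 0.35, ndt = 2,
                                   fast_guess_prob = 0.1), cond)
blk$ledger
#> <block_ledger> 57 trials, 601 steps, 2 coins (0.0033 coins/step)

# a 12-agent synthetic cohort, analyzed end to end
spec <- cohort_spec(n_participants = 12, cohort = 1, blocks = list(cond),
                    fast_guess_range = c(0.05, 0.3))
trials <- generate_cohort(spec, seed = 7)
tab <- build_correction_table(cond, n_sims_per_bound = 3e4, seed = 7)
an <- analyze_trials(trials, correction = tab)
head(participant_summary(an), 4)
#>   participant_id n_trials accuracy median_dt mean_bound median_bound reward_rate
#> 1              1       54    0.833         6      0.433       0.5672     0.01461
#> 2              2       73    0.795         4      0.278       0.3025    -0.00326
#> 3              3      116    0.690         2      0.131       0.1381    -0.10667
#> 4              4      147    0.660         1      0.105       0.0905    -0.17081
```

Slow, high-bound agents are more accurate and (under the −4 coin penalty)
earn more per step than fast guessers; the per-agent mean corrected bound
rank-correlates with the generating bound at ρ ≈ 0.94 in this small run.

```r
rrf <- rr_function_fixed(cond, n_reps = 200, seed = 7)
rrf
#> <rr_function> 16 bounds x 200 reps; argmax 0.51 (RR 0.0600)
rr_gradient(rrf, 0.21)
#> <gradient_result> pre 0.21 -> optimum 0.51; gradient +0.2389 (increase)
```

The reward-rate function rises steeply to bounds ≈0.4 and then forms a
broad plateau (differences of ~0.003 coins/step); the gradient from a low
reference bound is strongly positive — a bound of 0.21 costs about 0.24
coins per step per unit of bound it sits below the optimum.

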
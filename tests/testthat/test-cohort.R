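test_that("deterministic noise-free agents commit at the predicted step", {
  set.seed(201)
  cond <- cond_noiseless()                    # mu = 0.05, sigma ~ 0
  rec <- simulate_trial(agent_policy(bound = 0.4, ndt = 0), cond)
  expect_identical(rec$commit_step, 8L)       # first k with 0.05 k >= 0.4
  expect_identical(rec$rt_steps, 8L)
  expect_identical(rec$choice, as.integer(rec$drift_sign))
  expect_true(rec$correct)

  rec2 <- simulate_trial(agent_policy(bound = 0.4, ndt = 3), cond)
  expect_identical(rec2$rt_steps, rec2$commit_step + 3L)
  expect_identical(length(rec2$positions), rec2$rt_steps + 1L)

  sim <- pigeonbound:::simulate_trials_bulk(
    agent_policy(bound = 0.3, fast_guess_prob = 1), cond_block2(), 200)
  expect_true(all(sim$trials$commit_step == 1L))
  expect_true(all(sim$trials$fast_guess))
})

test_that("bound crossings bracket the bound on accumulation trials", {
  set.seed(202)
  pol <- agent_policy(bound = 0.35, ndt = 1)
  sim <- pigeonbound:::simulate_trials_bulk(pol, cond_block2(), 3000)
  tr <- sim$trials
  acc <- !tr$fast_guess & !tr$forced
  i <- which(acc)
  at <- sim$positions[cbind(i, tr$commit_step[i])]
  expect_true(all(abs(at) >= 0.35))
  j <- which(acc & tr$commit_step > 1L)
  before <- sim$positions[cbind(j, tr$commit_step[j] - 1L)]
  expect_true(all(abs(before) < 0.35))
  expect_true(all(tr$true_bound[acc] == 0.35))
})

test_that("the walk continues through the motor delay, producing incongruent keypresses", {
  set.seed(203)
  pol2 <- agent_policy(bound = 0.15, ndt = 2)
  sim <- pigeonbound:::simulate_trials_bulk(pol2, cond_block2(), 4000)
  at_rt <- sim$positions[cbind(seq_len(4000), sim$trials$rt_steps)]
  congruence2 <- mean(sign(at_rt) == sim$trials$choice)
  expect_lt(congruence2, 1)

  pol0 <- agent_policy(bound = 0.15, ndt = 0)
  sim0 <- pigeonbound:::simulate_trials_bulk(pol0, cond_block2(), 2000)
  at0 <- sim0$positions[cbind(seq_len(2000), sim0$trials$rt_steps)]
  expect_equal(mean(sign(at0) == sim0$trials$choice), 1)
})

test_that("fast-guess-only agents complete three hundred two-step trials", {
  set.seed(204)
  blk <- simulate_block(agent_policy(bound = 0.4, ndt = 0, fast_guess_prob = 1),
                        block_condition_fixture(1, 1))
  expect_identical(blk$ledger$trials_completed, 300L)
  expect_identical(blk$ledger$steps_used, 600L)
  expect_true(all(blk$trials$steps_cost == 2L))
})

test_that("cohort tables are byte-identical across repeated generation", {
  spec <- cohort_spec(n_participants = 2, cohort = 1,
                      blocks = list(block_condition_fixture(1, 2)))
  t1 <- generate_cohort(spec, seed = 7)
  t2 <- generate_cohort(spec, seed = 7)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trials(t1, f1); write_trials(t2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and the round trip preserves content
  rt <- read_trials(f1)
  expect_equal(rt$rt_steps, t1$rt_steps)
  expect_equal(parse_positions(rt$positions)[[5]],
               parse_positions(t1$positions)[[5]])
})

test_that("accuracy and decision bounds rise with decision time across agents", {
  set.seed(206)
  n_agents <- 20
  agents <- data.frame(bound = seq(0.08, 0.55, length.out = n_agents),
                       ndt = 1L, fast_guess_prob = 0.1, bound_jitter_sd = 0)
  spec <- cohort_spec(n_participants = n_agents, cohort = 1,
                      blocks = list(block_condition_fixture(1, 2)),
                      agents = agents)
  tr <- generate_cohort(spec, seed = 11)
  acc <- tapply(tr$correct, tr$participant_id, mean)
  med_dt <- tapply(tr$rt_steps - tr$true_ndt, tr$participant_id, median)
  mean_dt <- tapply(tr$rt_steps - tr$true_ndt, tr$participant_id, mean)
  expect_gt(cor(acc, med_dt, method = "spearman"), 0)
  expect_gt(cor(agents$bound, mean_dt, method = "spearman"), 0.5)
})

test_that("per-trial SNR labels select the matching SNR-specific bound", {
  set.seed(207)
  cond <- block_condition_fixture(2, 2)        # trial-mixed 0.05 / 0.15
  pol <- agent_policy(bound = c(low = 0.15, high = 0.35), ndt = 0)
  sim <- pigeonbound:::simulate_trials_bulk(pol, cond, 1500)
  tr <- sim$trials
  expect_setequal(unique(tr$snr_label), c("low", "high"))
  expect_true(all(tr$true_bound[tr$snr_label == "low"] == 0.15))
  expect_true(all(tr$true_bound[tr$snr_label == "high"] == 0.35))
  expect_true(all(tr$trial_mu[tr$snr_label == "high"] == 0.15))
  # both magnitudes drawn roughly 50/50
  expect_gt(mean(tr$snr_label == "high"), 0.4)
  expect_lt(mean(tr$snr_label == "high"), 0.6)
})

test_that("cohort-3 changepoints sit at the ceiling RT statistic of the source block", {
  spec <- cohort_spec(n_participants = 6, cohort = 3,
                      blocks = list(block_condition_fixture(3, 1),
                                    block_condition_fixture(3, 4,
                                                            changepoint_step = NA)),
                      agents = data.frame(bound = seq(0.1, 0.3, length.out = 6),
                                          ndt = 2L, fast_guess_prob = 0.1,
                                          bound_jitter_sd = 0))
  tr <- generate_cohort(spec, seed = 13)
  for (p in 1:6) {
    src_rt <- tr$rt_steps[tr$participant_id == p & tr$block_index == 1]
    cp <- unique(tr$changepoint_step[tr$participant_id == p & tr$block_index == 2])
    expect_identical(cp, derive_cp_step(src_rt, "median"))
    expect_identical(cp, as.integer(ceiling(median(src_rt))))
  }
  # changepoints fall in a plausible band around the source DT medians + NDT
  cps <- unique(tr$changepoint_step[tr$block_index == 2])
  expect_true(all(cps >= 2 & cps <= 40))
})

test_that("block reward rates match the numerically integrated expectation", {
  set.seed(209)
  cond <- cond_block2()
  rrs <- replicate(30, block_reward_rate(
    simulate_block(agent_policy(bound = 0.4), cond)$ledger))
  o <- fp_oracle(0.05, 0.15, 0.4, coins_error = -4)
  expect_lt(abs(mean(rrs) - o$rr), 0.015)
})
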
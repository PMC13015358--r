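test_that("step increments match the generative mean and SD", {
  set.seed(101)
  cond <- cond_block2()
  n <- 6e4
  pos <- pigeonbound:::walk_matrix(n, cond, drift = rep(1, n), n_steps = 1L)
  inc <- pos[, 1L]                       # one step from 0; clipping can't bind
  expect_lt(abs(mean(inc) - cond$step_mean), 3 * cond$step_std / sqrt(n))
  expect_lt(abs(sd(inc) - cond$step_std), 3 * cond$step_std / sqrt(2 * n))

  # zero drift: symmetric displacement after 10 steps
  cond0 <- block_condition(step_mean = 0, step_std = 0.15)
  pos0 <- pigeonbound:::walk_matrix(n, cond0, drift = rep(1, n), n_steps = 10L)
  expect_lt(abs(mean(pos0[, 10L])), 3 * 0.15 * sqrt(10) / sqrt(n))
})

test_that("noise-free walks advance by mu per step and clip at the piles", {
  set.seed(102)
  w <- sample_walk(cond_noiseless(), max_steps = 30, drift_sign = 1)
  expect_equal(w$positions, pmin(0.05 * 0:30, 0.8), tolerance = 1e-6)

  # strong drift, noisy: positions never escape the piles
  condb <- block_condition(step_mean = 0.3, step_std = 0.3)
  pos <- pigeonbound:::walk_matrix(2000, condb, drift = rep(1, 2000), 40L)
  expect_true(all(abs(pos) <= 0.8 + 1e-12))

  expect_equal(snr(cond_block2()), 1 / 3)
})

test_that("changepoint walks switch drift magnitude at the cued step", {
  # magnitudes kept small relative to the piles so clipping never binds and
  # raw increments can be compared to the generative means
  cond <- block_condition(step_std = 0.08, snr_mode = "changepoint",
                          mean_magnitudes = c(0.02, 0.1),
                          changepoint_step = 4L, coins_error = -1)
  set.seed(103)
  n <- 4e4
  pos <- pigeonbound:::walk_matrix(n, cond, drift = rep(1, n), n_steps = 5L)
  se <- 3 * 0.08 / sqrt(n)
  expect_lt(abs(mean(pos[, 1L]) - 0.02), se)            # first magnitude
  expect_lt(abs(mean(pos[, 3L] - pos[, 2L]) - 0.02), se)
  expect_lt(abs(mean(pos[, 4L] - pos[, 3L]) - 0.1), se) # switch at step 4
  expect_lt(abs(mean(pos[, 5L] - pos[, 4L]) - 0.1), se)

  # noise-free changepoint walk advances by the exact piecewise means
  cond0 <- block_condition(step_std = 1e-9, snr_mode = "changepoint",
                           mean_magnitudes = c(0.02, 0.1),
                           changepoint_step = 4L, coins_error = -1)
  w0 <- sample_walk(cond0, 6, drift_sign = 1)
  expect_equal(w0$positions, cumsum(c(0, 0.02, 0.02, 0.02, 0.1, 0.1, 0.1)),
               tolerance = 1e-6)

  # identical seeds give identical walks
  set.seed(42); w1 <- sample_walk(cond, 12)
  set.seed(42); w2 <- sample_walk(cond, 12)
  expect_identical(w1, w2)

  # a changepoint condition without a step index cannot be sampled
  condna <- block_condition(step_std = 0.15, snr_mode = "changepoint",
                            mean_magnitudes = c(0.05, 0.2),
                            changepoint_step = NA)
  expect_error(sample_walk(condna, 5), "changepoint_step")
})

test_that("trial step accounting follows the one-plus-RT-plus-penalty rule", {
  expect_identical(trial_step_cost(1, FALSE, block_condition_fixture(1, 1)), 2L)
  expect_identical(trial_step_cost(10, TRUE, block_condition_fixture(1, 3)), 41L)
  cond0 <- block_condition(step_mean = 0.05, step_std = 0.15)
  expect_identical(trial_step_cost(5, TRUE, cond0), 6L)
  expect_error(trial_step_cost(0, FALSE, cond0), "rt")

  expect_equal(block_reward_rate(block_ledger(600, 60, 30)), 0.1)
  expect_error(block_reward_rate(block_ledger(0, 0, 0)), "empty")
})

test_that("block ledgers equal independent re-summation of their trials", {
  set.seed(104)
  blk <- simulate_block(agent_policy(bound = 0.35, ndt = 1), cond_block2())
  tr <- blk$trials
  expect_identical(blk$ledger$steps_used, sum(tr$steps_cost))
  expect_identical(blk$ledger$coins_earned, sum(tr$coins_delta))
  expect_identical(blk$ledger$trials_completed, nrow(tr))
  expect_equal(block_reward_rate(blk$ledger),
               sum(tr$coins_delta) / sum(tr$steps_cost))
  # the block ends on the first trial reaching the budget, played out in full
  expect_gte(blk$ledger$steps_used, 600L)
  expect_lt(blk$ledger$steps_used - tr$steps_cost[nrow(tr)], 600L)
})

test_that("cohort fixtures round-trip through YAML and JSON", {
  tab <- cohort_conditions()
  expect_identical(nrow(tab), 17L)
  expect_identical(vapply(1:3, function(co) nrow(cohort_conditions(co)),
                          integer(1L)), c(6L, 6L, 5L))

  cond <- block_condition_fixture(3, 4, changepoint_step = 9)
  expect_identical(cond$snr_mode, "changepoint")
  expect_identical(cond$changepoint_step, 9L)
  expect_equal(cond$mean_magnitudes, c(0.01, 0.02))

  for (ext in c("yaml", "json")) {
    path <- tempfile(fileext = paste0(".", ext))
    write_block_condition(cond, path)
    expect_equal(read_block_condition(path), cond)
  }

  expect_error(block_condition(step_std = 0.15, snr_mode = "trial_mixed",
                               mean_magnitudes = 0.05), "two")
  expect_error(block_condition(step_mean = 0.05, step_std = 0), "step_std")
})
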
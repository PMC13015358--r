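test_that("congruence is maximal at the true motor delay", {
  # a monotone rightward trial is congruent at every delay; ties break to 0
  one <- data.frame(rt_steps = 5L, choice = 1L,
                    positions = "0;0.1;0.2;0.3;0.4;0.5")
  est <- estimate_ndt(one)
  expect_identical(est$ndt_steps, 0L)
  expect_true(all(est$congruence_by_delay == 1))

  # probing past the trial start leaves an empty denominator and a warning
  short <- data.frame(rt_steps = 2L, choice = 1L, positions = "0;0.1;0.2")
  expect_warning(est2 <- estimate_ndt(short, delay_range = 0:2), "delay 2")
  expect_identical(unname(est2$congruence_by_delay["2"]), 0)

  # synthetic participant with true NDT = 2 and fast guesses: exact recovery
  set.seed(301)
  tr <- simulate_agent_table(agent_policy(bound = 0.3, ndt = 2,
                                          fast_guess_prob = 0.2),
                             cond_block2(), 250)
  expect_identical(estimate_ndt(tr)$ndt_steps, 2L)

  # a realistic small cohort has modal NDT in {1, 2}
  spec <- cohort_spec(n_participants = 8, cohort = 1,
                      blocks = list(cond_block2()),
                      fast_guess_range = c(0.05, 0.3))
  coh <- generate_cohort(spec, seed = 302)
  an <- suppressWarnings(analyze_trials(coh))
  ndts <- tapply(an$ndt, an$participant_id, function(x) x[1])
  modal <- as.integer(names(which.max(table(ndts))))
  expect_true(modal %in% c(1L, 2L))
})

test_that("decision times floor at one step", {
  expect_identical(decision_time(10, 2), 8L)
  expect_identical(decision_time(1, 4), 1L)
  expect_error(decision_time(0, 1), "rt")
  rts <- 5:40
  expect_identical(median(decision_time(rts, 2)), median(rts) - 2)
})

test_that("midpoint bound measurement is exact arithmetic and mirror-invariant", {
  expect_equal(measure_raw_bound(c(0, 0.1, 0.25), 2), 0.175)
  expect_equal(measure_raw_bound(c(0, 0.12), 1), 0.06)
  expect_equal(measure_raw_bound(c(0, -0.1, -0.3), 2), 0.2)
  expect_error(measure_raw_bound(c(0, 0.1), 2), "walk length")

  set.seed(303)
  w <- sample_walk(cond_block2(), 12)
  mirrored <- w; mirrored$positions <- -w$positions
  for (dt in c(1, 5, 12))
    expect_equal(measure_raw_bound(w, dt), measure_raw_bound(mirrored, dt))

  # noise-free limit: the midpoint sits half a step below the bound
  w0 <- sample_walk(cond_noiseless(), 20, drift_sign = 1)
  expect_equal(measure_raw_bound(w0, 8), 0.4 - 0.05 / 2, tolerance = 1e-6)
})

test_that("bound-versus-DT slopes recover collapse rates", {
  set.seed(304)
  cond <- cond_block2()
  # constant-bound agent: slope indistinguishable from zero
  sim0 <- pigeonbound:::simulate_trials_bulk(agent_policy(bound = 0.35), cond, 2e4)
  dt0 <- sim0$trials$commit_step
  m0 <- ifelse(dt0 == 1, 0,
               sim0$positions[cbind(seq_along(dt0), pmax(dt0 - 1L, 1L))])
  meas0 <- abs(m0 + sim0$positions[cbind(seq_along(dt0), dt0)]) / 2
  expect_lt(abs(bound_vs_dt_slope(dt0, meas0)), 0.003)

  # linearly collapsing agent: slope recovered near the generative value
  simc <- pigeonbound:::simulate_trials_bulk(
    agent_policy(bound = 0.45, collapse_slope = -0.01), cond, 2e4)
  dtc <- simc$trials$commit_step
  mc <- ifelse(dtc == 1, 0,
               simc$positions[cbind(seq_along(dtc), pmax(dtc - 1L, 1L))])
  measc <- abs(mc + simc$positions[cbind(seq_along(dtc), dtc)]) / 2
  expect_lt(abs(bound_vs_dt_slope(dtc, measc) - (-0.01)), 0.003)

  expect_warning(s <- bound_vs_dt_slope(c(3, 3, 3), c(0.2, 0.3, 0.25)),
                 "distinct DT")
  expect_true(is.na(s))
})

test_that("trial-to-trial bound changes regress to the mean", {
  set.seed(305)
  iid <- rnorm(1e4, 0.3, 0.05)
  expect_lt(abs(bound_change_regression(iid) - 1), 0.05)

  rw <- 0.3 + cumsum(rnorm(1e4, 0, 0.01))
  expect_lt(abs(bound_change_regression(rw)), 0.05)

  expect_warning(s <- bound_change_regression(rep(0.3, 10)), "constant")
  expect_true(is.na(s))
  expect_warning(s2 <- bound_change_regression(c(0.1, 0.2)), "3 consecutive")
  expect_true(is.na(s2))
})

test_that("z-scored bounds have zero mean and unit variance", {
  expect_equal(zscore_bounds(c(0.2, 0.4)), c(-0.707, 0.707), tolerance = 1e-3)
  set.seed(306)
  z <- zscore_bounds(runif(50, 0, 0.8))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_warning(z0 <- zscore_bounds(rep(0.3, 5)), "zero variance")
  expect_identical(z0, rep(0, 5))
})

test_that("participant summaries match naive recomputation", {
  spec <- cohort_spec(n_participants = 4, cohort = 1,
                      blocks = list(cond_block2()),
                      fast_guess_range = c(0.05, 0.2))
  tr <- generate_cohort(spec, seed = 307)
  an <- suppressWarnings(analyze_trials(tr))
  s <- participant_summary(an)
  for (p in 1:4) {
    sub <- an[an$participant_id == p, ]
    expect_equal(s$accuracy[s$participant_id == p], mean(sub$correct))
    expect_equal(s$median_dt[s$participant_id == p], median(sub$dt))
    expect_equal(s$reward_rate[s$participant_id == p],
                 sum(sub$coins_delta) / sum(sub$steps_cost))
    expect_equal(s$mean_bound[s$participant_id == p], mean(sub$raw_bound))
  }
  all_correct <- an[an$correct, ][1:10, ]
  expect_equal(participant_summary(all_correct)$accuracy,
               rep(1, length(unique(all_correct$participant_id))))
})

test_that("left and right choices yield indistinguishable bounds", {
  set.seed(308)
  tr <- simulate_agent_table(agent_policy(bound = 0.3, ndt = 1,
                                          fast_guess_prob = 0.1),
                             cond_block2(), 500)
  an <- suppressWarnings(analyze_trials(tr))
  wt <- wilcox.test(an$raw_bound[an$choice == 1], an$raw_bound[an$choice == -1],
                    exact = FALSE)
  expect_gt(wt$p.value, 0.01)
})
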
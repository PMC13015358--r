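# Shared fixtures and cached heavyweight objects (built once per session).

cond_block2 <- function() block_condition_fixture(1, 2)

# near-deterministic condition for noise-free limits
cond_noiseless <- function(mu = 0.05) {
  block_condition(step_mean = mu, step_std = 1e-9,
                  coins_correct = 1, coins_error = -4)
}

# bulk-simulate an agent and return a minimal trial table (one participant)
simulate_agent_table <- function(policy, cond, n, max_steps = 60L) {
  sim <- pigeonbound:::simulate_trials_bulk(policy, cond, n, max_steps)
  tr <- sim$trials
  tr$positions <- pigeonbound:::format_positions(sim$positions, tr$rt_steps)
  tr$participant_id <- 1L
  tr$block_index <- 1L
  tr
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, builder(), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# moderate-size correction table at SNR 1/3 for module tests
corr_table_b2_small <- function() cached("corr_b2_small", function() {
  suppressWarnings(build_correction_table(cond_block2(),
                                          n_sims_per_bound = 3e4, seed = 42))
})

# full-size (scaled-default) correction table used by the acceptance suite
corr_table_b2_full <- function() cached("corr_b2_full", function() {
  suppressWarnings(build_correction_table(cond_block2(),
                                          n_sims_per_bound = 1e5, seed = 42))
})
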
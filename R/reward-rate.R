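# Monte-Carlo reward-rate machinery: blocks are simulated by drawing a pool
# of i.i.d. trials for the given policy/condition and consuming them
# sequentially against the step budget (the final trial of each block is
# played to completion, so ledgers may overshoot the budget).

# Simulate `n_reps` full blocks; returns data.frame(coins, steps, rr, trials).
simulate_rr_blocks <- function(policy, cond, n_reps, max_steps = 60L) {
  budget <- cond$block_step_budget
  pilot <- simulate_trials_bulk(policy, cond, 500L, max_steps)$trials
  mean_cost <- mean(pilot$steps_cost)
  n_pool <- ceiling(1.08 * n_reps * budget / mean_cost) + 100L
  sim <- simulate_trials_bulk(policy, cond, n_pool, max_steps)$trials
  cs <- cumsum(sim$steps_cost)
  cc <- cumsum(sim$coins_delta)
  ct <- seq_along(cs)
  coins <- steps <- trials <- numeric(n_reps)
  off_s <- 0; off_c <- 0; off_t <- 0
  for (r in seq_len(n_reps)) {
    e <- findInterval(off_s + budget - 1e-9, cs) + 1L
    while (e > length(cs)) {
      extra <- simulate_trials_bulk(policy, cond, max(2000L, n_pool %/% 10L),
                                    max_steps)$trials
      cs <- c(cs, cs[length(cs)] + cumsum(extra$steps_cost))
      cc <- c(cc, cc[length(cc)] + cumsum(extra$coins_delta))
      ct <- seq_along(cs)
    }
    coins[r] <- cc[e] - off_c
    steps[r] <- cs[e] - off_s
    trials[r] <- ct[e] - off_t
    off_s <- cs[e]; off_c <- cc[e]; off_t <- ct[e]
  }
  data.frame(coins = coins, steps = steps, trials = trials, rr = coins / steps)
}

rr_summary <- function(rr) {
  c(rr_median = stats::median(rr),
    rr_lo = unname(stats::quantile(rr, 0.025)),
    rr_hi = unname(stats::quantile(rr, 0.975)))
}

#' Reward-rate function of fixed bound height
#'
#' For each bound on the grid, simulates `n_reps` complete blocks played by
#' a deterministic fixed-bound agent (commitment at the first crossing,
#' keypress without motor delay) and summarizes the distribution of
#' coins-per-step across repetitions by its median and 95% percentile
#' interval.
#'
#' @param cond A fixed or trial-mixed [block_condition()] (a trial-mixed
#'   condition yields the single-bound mixed-SNR reward-rate function).
#' @param bound_grid Bound values to evaluate (default [default_bound_grid()]).
#' @param n_reps Block repetitions per bound (default 500).
#' @param max_steps Per-trial step cap.
#' @param seed Optional integer seed.
#' @return An `rr_function`: list with `grid` (data.frame `bound`,
#'   `rr_median`, `rr_lo`, `rr_hi`), the condition, and metadata.
#' @examples
#' \donttest{
#' rrf <- rr_function_fixed(block_condition_fixture(1, 2), n_reps = 100,
#'                          seed = 1)
#' optimal_bound(rrf)
#' }
#' @export
rr_function_fixed <- function(cond, bound_grid = default_bound_grid(),
                              n_reps = 500L, max_steps = 60L, seed = NULL) {
  stopifnot(inherits(cond, "block_condition"))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(bound_grid, function(b) {
    blocks <- simulate_rr_blocks(agent_policy(bound = b), cond, n_reps, max_steps)
    c(bound = b, rr_summary(blocks$rr))
  })
  grid <- as.data.frame(do.call(rbind, rows))
  structure(list(grid = grid, cond = cond, conditioning = NULL,
                 n_reps = n_reps, seed = seed),
            class = "rr_function")
}

#' @export
print.rr_function <- function(x, ...) {
  cat(sprintf("<rr_function> %d bounds x %d reps; argmax %.2f (RR %.4f)\n",
              nrow(x$grid), x$n_reps, optimal_bound(x),
              max(x$grid$rr_median)))
  invisible(x)
}

#' Reward-rate surface over SNR-specific bound pairs
#'
#' Evaluates the reward rate of agents that use one bound for low-SNR and
#' another for high-SNR evidence, either across blocks (`"blockwise"`: one
#' low-SNR and one high-SNR block are played and pooled, so the surface is
#' total coins over total steps) or within a block (`"trial_mixed"`: a
#' single block whose trials draw either SNR 50/50 and an agent assumed to
#' know each trial's SNR label -- the normative upper-envelope benchmark,
#' not a claim about what decision-makers perceive).
#'
#' @param cond_low,cond_high Fixed-SNR [block_condition()]s sharing a payoff
#'   structure (low/high by step-mean magnitude).
#' @param mode `"blockwise"` or `"trial_mixed"`.
#' @param bound_grid Bound values for both axes.
#' @param n_reps Block repetitions per grid point (default 500).
#' @param max_steps Per-trial step cap.
#' @param seed Optional integer seed.
#' @return An `rr_surface`: `grid` is a data.frame with `bound_low`,
#'   `bound_high`, `rr_median`, `rr_lo`, `rr_hi`.
#' @export
rr_surface_two_snr <- function(cond_low, cond_high,
                               mode = c("blockwise", "trial_mixed"),
                               bound_grid = default_bound_grid(),
                               n_reps = 500L, max_steps = 60L, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cond_low, "block_condition"),
            inherits(cond_high, "block_condition"))
  if (cond_low$step_mean >= cond_high$step_mean)
    stop("`cond_low` must have the smaller step-mean magnitude", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ng <- length(bound_grid)

  if (mode == "blockwise") {
    # per-bound block totals for each condition once; pair afterwards
    lo <- lapply(bound_grid, function(b)
      simulate_rr_blocks(agent_policy(bound = b), cond_low, n_reps, max_steps))
    hi <- lapply(bound_grid, function(b)
      simulate_rr_blocks(agent_policy(bound = b), cond_high, n_reps, max_steps))
    rows <- vector("list", ng * ng)
    k <- 0L
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      rr <- (lo[[i]]$coins + hi[[j]]$coins) / (lo[[i]]$steps + hi[[j]]$steps)
      k <- k + 1L
      rows[[k]] <- c(bound_low = bound_grid[i], bound_high = bound_grid[j],
                     rr_summary(rr))
    }
  } else {
    mixed <- block_condition(
      step_std = cond_low$step_std, snr_mode = "trial_mixed",
      mean_magnitudes = c(cond_low$step_mean, cond_high$step_mean),
      coins_correct = cond_low$coins_correct, coins_error = cond_low$coins_error,
      steps_error_penalty = cond_low$steps_error_penalty,
      block_step_budget = cond_low$block_step_budget)
    rows <- vector("list", ng * ng)
    k <- 0L
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      pol <- agent_policy(bound = c(low = bound_grid[i], high = bound_grid[j]))
      blocks <- simulate_rr_blocks(pol, mixed, n_reps, max_steps)
      k <- k + 1L
      rows[[k]] <- c(bound_low = bound_grid[i], bound_high = bound_grid[j],
                     rr_summary(blocks$rr))
    }
  }
  grid <- as.data.frame(do.call(rbind, rows))
  structure(list(grid = grid, mode = mode, cond_low = cond_low,
                 cond_high = cond_high, n_reps = n_reps, seed = seed),
            class = "rr_surface")
}

#' @export
print.rr_surface <- function(x, ...) {
  opt <- optimal_bound(x)
  cat(sprintf("<rr_surface> %s mode; optimum b_low=%.2f b_high=%.2f\n",
              x$mode, opt["bound_low"], opt["bound_high"]))
  invisible(x)
}

#' Reward-rate function of the post-changepoint bound
#'
#' For a condition whose SNR switches once within each trial, evaluates the
#' reward rate of agents that hold `pre_bound` before the changepoint and
#' switch to each candidate post-changepoint bound from the step of the
#' changepoint onward (the first step drawn from the new distribution is the
#' first the new bound can terminate).
#'
#' @param cond A changepoint-mode [block_condition()]; its
#'   `changepoint_step` is overridden by `changepoint_step` when supplied.
#' @param pre_bound Bound used before the changepoint, in `[0, 0.8]`.
#' @param changepoint_step Step index of the SNR switch (>= 1).
#' @param post_bound_grid Candidate post-changepoint bounds.
#' @param n_reps Block repetitions per post bound (default 500).
#' @param max_steps Per-trial step cap.
#' @param seed Optional integer seed.
#' @return An `rr_function` whose grid's `bound` axis is the post-changepoint
#'   bound; `conditioning` records `pre_bound` and `changepoint_step`.
#' @export
rr_function_changepoint <- function(cond, pre_bound,
                                    changepoint_step = cond$changepoint_step,
                                    post_bound_grid = default_bound_grid(),
                                    n_reps = 500L, max_steps = 60L,
                                    seed = NULL) {
  stopifnot(inherits(cond, "block_condition"))
  if (cond$snr_mode != "changepoint")
    stop("`cond` must be a changepoint condition", call. = FALSE)
  if (is.null(changepoint_step) || is.na(changepoint_step) || changepoint_step < 1)
    stop("`changepoint_step` must be a positive integer", call. = FALSE)
  if (pre_bound < 0 || pre_bound > PILE_DISTANCE)
    stop("`pre_bound` must lie in [0, 0.8]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cond$changepoint_step <- as.integer(changepoint_step)
  rows <- lapply(post_bound_grid, function(b) {
    pol <- agent_policy(bound = pre_bound, post_cp_bound = b)
    blocks <- simulate_rr_blocks(pol, cond, n_reps, max_steps)
    c(bound = b, rr_summary(blocks$rr))
  })
  grid <- as.data.frame(do.call(rbind, rows))
  structure(list(grid = grid, cond = cond,
                 conditioning = list(pre_bound = pre_bound,
                                     changepoint_step = as.integer(changepoint_step)),
                 n_reps = n_reps, seed = seed),
            class = "rr_function")
}

#' Reward-rate-maximizing bound of a reward-rate function or surface
#'
#' Grid argmax of the median reward rate; ties are broken toward the lowest
#' bound (lowest low-SNR bound, then lowest high-SNR bound, for surfaces).
#'
#' @param rrf An `rr_function` or `rr_surface`.
#' @return The argmax bound (named pair for surfaces).
#' @export
optimal_bound <- function(rrf) UseMethod("optimal_bound")

#' @export
optimal_bound.rr_function <- function(rrf) {
  g <- rrf$grid[order(rrf$grid$bound), ]
  g$bound[which.max(g$rr_median)]
}

#' @export
optimal_bound.rr_surface <- function(rrf) {
  g <- rrf$grid[order(rrf$grid$bound_low, rrf$grid$bound_high), ]
  i <- which.max(g$rr_median)
  c(bound_low = g$bound_low[i], bound_high = g$bound_high[i])
}

#' Reward-rate gradient from a reference bound toward the optimum
#'
#' The expected change in reward rate per unit bound change in the direction
#' of the reward-rate maximum: `(RR(b*) - RR(pre)) / (b* - pre)` with `b*`
#' the grid optimum. Positive values prescribe raising the bound, negative
#' values lowering it; the gradient is 0 when the reference bound is already
#' optimal.
#'
#' @param rrf An `rr_function`.
#' @param pre_bound Reference bound; snapped (with a flag) to the nearest
#'   grid point if it is not on the grid.
#' @return A `gradient_result`: list with `pre_bound`, `optimal_post_bound`,
#'   `gradient`, `expected_direction` (`"increase"`, `"decrease"`, `"none"`)
#'   and `snapped`.
#' @export
rr_gradient <- function(rrf, pre_bound) {
  stopifnot(inherits(rrf, "rr_function"))
  g <- rrf$grid
  i <- which.min(abs(g$bound - pre_bound))
  snapped <- abs(g$bound[i] - pre_bound) > 1e-9
  pre <- g$bound[i]
  bstar <- optimal_bound(rrf)
  if (isTRUE(all.equal(bstar, pre))) {
    grad <- 0; dir_ <- "none"
  } else {
    grad <- (g$rr_median[g$bound == bstar] - g$rr_median[i]) / (bstar - pre)
    dir_ <- if (bstar > pre) "increase" else "decrease"
  }
  structure(list(pre_bound = pre, optimal_post_bound = bstar,
                 gradient = grad, expected_direction = dir_,
                 snapped = snapped),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("<gradient_result> pre %.2f -> optimum %.2f; gradient %+.4f (%s)\n",
              x$pre_bound, x$optimal_post_bound, x$gradient,
              x$expected_direction))
  invisible(x)
}

#' Coin threshold for the performance bonus
#'
#' The bonus criterion pays out when a block earns at least 80% of the coins
#' an ideal observer playing the reward-rate-optimal fixed bound would earn:
#' this computes 0.8 times the median per-block coin total of that ideal
#' observer.
#'
#' @param cond A [block_condition()].
#' @param n_reps Block repetitions (default 500).
#' @param max_steps Per-trial step cap.
#' @param seed Optional integer seed.
#' @return A list with `threshold_coins`, `optimal_bound`, and
#'   `median_ideal_coins`.
#' @export
bonus_threshold <- function(cond, n_reps = 500L, max_steps = 60L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rrf <- rr_function_fixed(cond, n_reps = n_reps, max_steps = max_steps)
  bstar <- optimal_bound(rrf)
  blocks <- simulate_rr_blocks(agent_policy(bound = bstar), cond, n_reps,
                               max_steps)
  med <- stats::median(blocks$coins)
  list(threshold_coins = 0.8 * med, optimal_bound = bstar,
       median_ideal_coins = med)
}

#' Tidy a reward-rate function or surface for export
#'
#' @param rrf An `rr_function` or `rr_surface`.
#' @return Its grid data.frame (`bound[, bound2], rr_median, rr_lo, rr_hi`).
#' @export
rr_grid <- function(rrf) rrf$grid
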
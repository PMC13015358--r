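# Core random-walk engine. The pigeon's position starts at 0 and takes one
# Gaussian step per 200-ms frame; positions are clipped to +/-0.8 (the seed
# piles) after each update and the walk continues -- only the keypress ends a
# trial.

PILE_DISTANCE <- 0.8

# Per-step mean magnitudes for one trial: a length-`n_steps` vector.
# `trial_mu` is the magnitude assigned to the trial (fixed / trial_mixed);
# in changepoint mode the magnitude switches so that the step with index
# `changepoint_step` is the first drawn from the second distribution.
step_mean_profile <- function(cond, n_steps, trial_mu = NULL) {
  if (cond$snr_mode == "changepoint") {
    cp <- cond$changepoint_step
    if (is.null(cp) || is.na(cp))
      stop("changepoint condition has no `changepoint_step` set", call. = FALSE)
    mu <- rep(cond$mean_magnitudes[1L], n_steps)
    if (cp <= n_steps) mu[cp:n_steps] <- cond$mean_magnitudes[2L]
    mu
  } else {
    rep(if (is.null(trial_mu)) cond$step_mean else trial_mu, n_steps)
  }
}

# Vectorized clipped walk: n trials x n_steps increments.
# mu_by_trial: length-n magnitudes (fixed/trial_mixed); in changepoint mode
# the switch is applied by column. Returns the n x n_steps position matrix.
walk_matrix <- function(n, cond, drift, n_steps, mu_by_trial = NULL) {
  sigma <- cond$step_std
  if (cond$snr_mode == "changepoint") {
    cp <- cond$changepoint_step
    if (is.null(cp) || is.na(cp))
      stop("changepoint condition has no `changepoint_step` set", call. = FALSE)
    mu_col <- rep(cond$mean_magnitudes[1L], n_steps)
    if (cp <= n_steps) mu_col[cp:n_steps] <- cond$mean_magnitudes[2L]
    inc <- matrix(stats::rnorm(n * n_steps, sd = sigma), n, n_steps)
    inc <- inc + drift * matrix(mu_col, n, n_steps, byrow = TRUE)
  } else {
    if (is.null(mu_by_trial)) mu_by_trial <- rep(cond$step_mean, n)
    inc <- matrix(stats::rnorm(n * n_steps, sd = sigma), n, n_steps)
    inc <- inc + drift * mu_by_trial
  }
  pos <- matrix(0, n, n_steps)
  cur <- numeric(n)
  for (k in seq_len(n_steps)) {
    cur <- pmin(pmax(cur + inc[, k], -PILE_DISTANCE), PILE_DISTANCE)
    pos[, k] <- cur
  }
  pos
}

#' Sample one pigeon random walk
#'
#' Generates the latent decision-variable trajectory of one trial: the drift
#' sign is drawn 50/50, each step adds an independent Gaussian increment with
#' mean `drift_sign * mu` and the block's step standard deviation, and the
#' cumulative position is clipped to +/-0.8 after every update (the pigeon
#' cannot pass the seed piles; sampling continues after touching one).
#'
#' @param cond A [block_condition()]. In `"trial_mixed"` mode the trial's
#'   magnitude is drawn 50/50 from `cond$mean_magnitudes` unless supplied; in
#'   `"changepoint"` mode the magnitude switches at `cond$changepoint_step`.
#' @param max_steps Number of steps to generate (>= 1; default 60).
#' @param drift_sign Optional fixed drift sign (-1 or +1) instead of a draw.
#' @param trial_mu Optional fixed step-mean magnitude for the trial.
#' @return A `pigeon_walk`: list with `positions` (length `max_steps + 1`,
#'   starting at 0), `drift_sign`, `trial_mu`, `changepoint_step`, `sigma`.
#' @examples
#' set.seed(1)
#' w <- sample_walk(block_condition_fixture(1, 2), max_steps = 10)
#' w$positions
#' @export
sample_walk <- function(cond, max_steps = 60L, drift_sign = NULL, trial_mu = NULL) {
  stopifnot(inherits(cond, "block_condition"))
  if (max_steps < 1) stop("`max_steps` must be >= 1", call. = FALSE)
  if (is.null(drift_sign)) drift_sign <- sample(c(-1, 1), 1L)
  if (!drift_sign %in% c(-1, 1)) stop("`drift_sign` must be -1 or +1", call. = FALSE)
  if (is.null(trial_mu)) {
    trial_mu <- if (cond$snr_mode == "trial_mixed")
      sample(cond$mean_magnitudes, 1L) else cond$step_mean
  }
  pos <- walk_matrix(1L, cond, drift_sign, as.integer(max_steps),
                     mu_by_trial = trial_mu)
  structure(list(
    positions = c(0, pos[1L, ]),
    drift_sign = drift_sign,
    trial_mu = trial_mu,
    changepoint_step = cond$changepoint_step,
    sigma = cond$step_std
  ), class = "pigeon_walk")
}

#' @export
print.pigeon_walk <- function(x, ...) {
  cat(sprintf("<pigeon_walk> %d steps, drift %+d, mu %g, sigma %g\n",
              length(x$positions) - 1L, x$drift_sign, x$trial_mu, x$sigma))
  invisible(x)
}

#' Steps charged to the block ledger for one trial
#'
#' Every trial costs one step to start, plus one step per pigeon step taken
#' before the keypress (the response time), plus the block's error penalty in
#' steps when the choice was wrong.
#'
#' @param rt Response time in pigeon steps (>= 1).
#' @param is_error Logical; was the choice incorrect?
#' @param cond A [block_condition()].
#' @return Integer step cost, vectorized over `rt`/`is_error`.
#' @examples
#' trial_step_cost(10, TRUE, block_condition_fixture(1, 3))  # 41
#' @export
trial_step_cost <- function(rt, is_error, cond) {
  stopifnot(inherits(cond, "block_condition"))
  if (any(rt < 1)) stop("`rt` must be >= 1", call. = FALSE)
  as.integer(1L + rt + cond$steps_error_penalty * as.integer(is_error))
}

#' Block ledger: step and coin accounting for one completed block
#'
#' @param steps_used Total steps charged across the block's trials.
#' @param coins_earned Total coins earned (can be negative).
#' @param trials_completed Number of trials played.
#' @return An object of class `block_ledger`.
#' @export
block_ledger <- function(steps_used, coins_earned, trials_completed) {
  structure(list(steps_used = as.integer(steps_used),
                 coins_earned = as.integer(coins_earned),
                 trials_completed = as.integer(trials_completed)),
            class = "block_ledger")
}

#' @export
print.block_ledger <- function(x, ...) {
  cat(sprintf("<block_ledger> %d trials, %d steps, %d coins (%.4f coins/step)\n",
              x$trials_completed, x$steps_used, x$coins_earned,
              x$coins_earned / x$steps_used))
  invisible(x)
}

#' Reward rate of a completed block
#'
#' With a fixed step budget per block, reward rate (coins per step) is
#' equivalent to the total coins earned in the block up to the budget
#' constant.
#'
#' @param ledger A [block_ledger()].
#' @return Coins per step.
#' @export
block_reward_rate <- function(ledger) {
  stopifnot(inherits(ledger, "block_ledger"))
  if (ledger$trials_completed < 1 || ledger$steps_used < 1)
    stop("empty block ledger", call. = FALSE)
  ledger$coins_earned / ledger$steps_used
}
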
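#' Define a simulated decision-maker
#'
#' An agent policy describes how a simulated participant terminates evidence
#' accumulation: a bound schedule on the absolute pigeon position (constant,
#' linearly collapsing, and/or switching at a within-trial SNR changepoint),
#' a non-decision time (motor delay between commitment and keypress, in
#' steps), an occasional fast-guess probability (commitment at the first
#' step, bypassing accumulation), and optional trial-to-trial bound jitter.
#'
#' @param bound Bound height in `[0, 0.8]`. Either a single value, or a
#'   named vector `c(low = , high = )` giving SNR-specific bounds for
#'   trial-mixed conditions (an agent assumed to know each trial's SNR).
#' @param ndt Non-decision time in steps. A single integer in 0..4, or a
#'   vector of integers from which the per-trial NDT is drawn uniformly.
#' @param fast_guess_prob Probability in `[0, 1]` of committing at step 1
#'   (choice = side of the first position) instead of accumulating.
#' @param bound_jitter_sd Standard deviation of Gaussian trial-to-trial
#'   jitter added to the bound (clipped back to `[0, 0.8]`).
#' @param collapse_slope Change in bound per step (0 = constant bound;
#'   negative values collapse the bound over the trial).
#' @param post_cp_bound Bound applied from the changepoint step onward in
#'   changepoint conditions (`NULL` = keep the pre-changepoint schedule).
#' @return An object of class `agent_policy`.
#' @examples
#' agent_policy(bound = 0.4, ndt = 2)
#' agent_policy(bound = c(low = 0.3, high = 0.2), ndt = 1)
#' @export
agent_policy <- function(bound, ndt = 0L, fast_guess_prob = 0,
                         bound_jitter_sd = 0, collapse_slope = 0,
                         post_cp_bound = NULL) {
  if (!is.numeric(bound) || length(bound) < 1L || length(bound) > 2L)
    stop("`bound` must be one value or a named low/high pair", call. = FALSE)
  if (any(bound < 0 | bound > PILE_DISTANCE))
    stop("`bound` must lie in [0, 0.8]", call. = FALSE)
  if (length(bound) == 2L && !all(c("low", "high") %in% names(bound)))
    stop("a two-element `bound` must be named c(low = , high = )", call. = FALSE)
  if (any(!ndt %in% 0:4)) stop("`ndt` values must be integers in 0..4", call. = FALSE)
  if (fast_guess_prob < 0 || fast_guess_prob > 1)
    stop("`fast_guess_prob` must be in [0, 1]", call. = FALSE)
  if (bound_jitter_sd < 0) stop("`bound_jitter_sd` must be >= 0", call. = FALSE)
  if (!is.null(post_cp_bound) &&
      (post_cp_bound < 0 || post_cp_bound > PILE_DISTANCE))
    stop("`post_cp_bound` must lie in [0, 0.8]", call. = FALSE)
  structure(list(bound = bound, ndt = as.integer(ndt),
                 fast_guess_prob = fast_guess_prob,
                 bound_jitter_sd = bound_jitter_sd,
                 collapse_slope = collapse_slope,
                 post_cp_bound = post_cp_bound),
            class = "agent_policy")
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf("<agent_policy> bound %s, ndt %s, fast-guess p=%g, jitter sd=%g\n",
              paste(format(x$bound), collapse = "/"),
              paste(x$ndt, collapse = ","), x$fast_guess_prob,
              x$bound_jitter_sd))
  if (x$collapse_slope != 0) cat(sprintf("  collapse %+g/step\n", x$collapse_slope))
  if (!is.null(x$post_cp_bound))
    cat(sprintf("  post-changepoint bound %g\n", x$post_cp_bound))
  invisible(x)
}

# Simulate n independent trials of `policy` under `cond`, vectorized.
# Returns list(trials = data.frame, positions = n x (max_steps + max(ndt))
# matrix). Commitment is the first step k with |position[k]| >= bound(k)
# (or step 1 for fast guesses, or `max_steps` as a forced choice); the
# choice is the sign of the position at commitment and is never revised
# during the non-decision time, although the walk continues.
simulate_trials_bulk <- function(policy, cond, n, max_steps = 60L) {
  stopifnot(inherits(policy, "agent_policy"), inherits(cond, "block_condition"))
  n <- as.integer(n); max_steps <- as.integer(max_steps)
  ndt_max <- max(policy$ndt)
  n_steps <- max_steps + ndt_max

  drift <- sample(c(-1, 1), n, replace = TRUE)
  if (cond$snr_mode == "trial_mixed") {
    mags <- sort(cond$mean_magnitudes)
    trial_mu <- sample(cond$mean_magnitudes, n, replace = TRUE)
    snr_label <- ifelse(trial_mu == mags[1L], "low", "high")
  } else {
    trial_mu <- rep(cond$step_mean, n)
    snr_label <- rep(NA_character_, n)
  }
  pos <- walk_matrix(n, cond, drift, n_steps, mu_by_trial = trial_mu)

  # per-trial base bound (SNR-specific for mixed conditions) plus jitter
  base <- if (length(policy$bound) == 2L && cond$snr_mode == "trial_mixed") {
    unname(policy$bound[snr_label])
  } else rep(unname(policy$bound[1L]), n)
  jit <- if (policy$bound_jitter_sd > 0)
    stats::rnorm(n, 0, policy$bound_jitter_sd) else numeric(n)
  base <- pmin(pmax(base + jit, 0), PILE_DISTANCE)
  post_base <- if (!is.null(policy$post_cp_bound))
    pmin(pmax(policy$post_cp_bound + jit, 0), PILE_DISTANCE) else NULL
  cp <- if (cond$snr_mode == "changepoint") cond$changepoint_step else NA_integer_

  bound_at <- function(k) {
    b <- pmin(pmax(base + policy$collapse_slope * (k - 1), 0), PILE_DISTANCE)
    if (!is.null(post_base) && !is.na(cp) && k >= cp) b <- post_base
    b
  }

  commit <- rep(NA_integer_, n)
  bound_commit <- numeric(n)
  undec <- rep(TRUE, n)
  for (k in seq_len(max_steps)) {
    if (!any(undec)) break
    bk <- bound_at(k)
    hit <- undec & (abs(pos[, k]) >= bk)
    if (any(hit)) {
      commit[hit] <- k
      bound_commit[hit] <- bk[hit]
      undec[hit] <- FALSE
    }
  }
  forced <- undec
  commit[forced] <- max_steps
  bound_commit[forced] <- bound_at(max_steps)[forced]

  fg <- stats::runif(n) < policy$fast_guess_prob
  commit[fg] <- 1L
  bound_commit[fg] <- bound_at(1L)[fg]
  forced <- forced & !fg

  ndt <- if (length(policy$ndt) == 1L) rep(policy$ndt, n)
         else sample(policy$ndt, n, replace = TRUE)
  rt <- commit + ndt

  pos_commit <- pos[cbind(seq_len(n), commit)]
  choice <- sign(pos_commit)
  ties <- choice == 0
  if (any(ties)) choice[ties] <- sample(c(-1, 1), sum(ties), replace = TRUE)
  correct <- choice == drift
  coins <- ifelse(correct, cond$coins_correct, cond$coins_error)
  cost <- 1L + rt + cond$steps_error_penalty * as.integer(!correct)

  trials <- data.frame(
    drift_sign = drift, trial_mu = trial_mu, snr = trial_mu / cond$step_std,
    snr_label = snr_label,
    commit_step = commit, rt_steps = rt,
    choice = as.integer(choice), correct = correct,
    coins_delta = as.integer(coins), steps_cost = as.integer(cost),
    true_bound = bound_commit, true_ndt = ndt,
    fast_guess = fg, forced = forced,
    stringsAsFactors = FALSE
  )
  list(trials = trials, positions = pos)
}

# Join positions 0..rt into the semicolon-separated serialization used by
# trial tables.
format_positions <- function(positions, rt) {
  vapply(seq_along(rt), function(i) {
    paste(formatC(c(0, positions[i, seq_len(rt[i])]), format = "g", digits = 6),
          collapse = ";")
  }, character(1L))
}

#' Parse serialized pigeon positions from a trial table
#'
#' @param x Character vector of semicolon-separated positions
#'   (`position[0];...;position[rt]`).
#' @return A list of numeric vectors, each starting at position 0.
#' @export
parse_positions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), as.numeric)
}

#' Simulate a single trial
#'
#' Runs one trial of `policy` under `cond`: the pigeon walk is sampled, the
#' agent commits at its first bound crossing (or fast-guesses at step 1, or
#' is forced to choose at `max_steps`), and the keypress occurs `ndt` steps
#' later while the walk continues (so the position at the keypress can be on
#' the other side of the midline -- an incongruent trial).
#'
#' @param policy An [agent_policy()].
#' @param cond A [block_condition()].
#' @param max_steps Per-trial step cap (default 60); agents that never cross
#'   their bound make a forced choice at the cap.
#' @return A `trial_record`: the trial row (see [simulate_block()]) plus a
#'   `positions` element covering positions 0..rt.
#' @export
simulate_trial <- function(policy, cond, max_steps = 60L) {
  sim <- simulate_trials_bulk(policy, cond, 1L, max_steps)
  rec <- as.list(sim$trials[1L, ])
  rec$positions <- c(0, sim$positions[1L, seq_len(rec$rt_steps)])
  structure(rec, class = "trial_record")
}

#' Simulate one full block
#'
#' Trials are generated until the cumulative step cost (1 start step + RT
#' steps + any error penalty per trial) reaches the block's step budget; the
#' final trial is played to completion, so the ledger may overshoot the
#' budget.
#'
#' @inheritParams simulate_trial
#' @return A list with `trials` (a data.frame, one row per trial, including
#'   a serialized `positions` column) and `ledger` (a [block_ledger()]).
#' @examples
#' set.seed(1)
#' blk <- simulate_block(agent_policy(bound = 0.3, ndt = 1),
#'                       block_condition_fixture(1, 2))
#' blk$ledger
#' @export
simulate_block <- function(policy, cond, max_steps = 60L) {
  budget <- cond$block_step_budget
  trials <- NULL
  pos_strings <- character(0)
  total <- 0L
  chunk <- max(16L, ceiling(budget / 12))
  while (total < budget) {
    sim <- simulate_trials_bulk(policy, cond, chunk, max_steps)
    cum <- total + cumsum(sim$trials$steps_cost)
    done <- which(cum >= budget)
    take <- if (length(done)) done[1L] else chunk
    idx <- seq_len(take)
    tr <- sim$trials[idx, , drop = FALSE]
    tr$positions <- format_positions(sim$positions, tr$rt_steps)
    trials <- if (is.null(trials)) tr else rbind(trials, tr)
    total <- cum[take]
    chunk <- max(16L, ceiling((budget - total) / 12))
  }
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  ledger <- block_ledger(total, sum(trials$coins_delta), nrow(trials))
  list(trials = trials, ledger = ledger)
}
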
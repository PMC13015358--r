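#' Estimate non-decision time by congruence maximization
#'
#' The non-decision time (NDT) is the motor delay, in pigeon steps, between
#' mental commitment and the keypress. For each candidate delay `d`, the
#' congruence is the fraction of trials on which the pigeon position `d`
#' steps before the keypress was on the same side of the midline as the
#' choice. The NDT estimate is the delay with maximal congruence, ties
#' broken toward the smallest (most parsimonious) delay. Trials whose probed
#' position is exactly zero, or whose probed index falls before the trial
#' start, are excluded from that delay's denominator.
#'
#' @param trials A trial table (or subset) with columns `rt_steps`,
#'   `choice`, and `positions` (serialized, or a list of numeric vectors).
#' @param delay_range Integer delays probed (default 0..4, the plausible
#'   sensorimotor range given the 200-ms step duration).
#' @return An `ndt_estimate`: list with `ndt_steps` and
#'   `congruence_by_delay` (named fraction per delay).
#' @examples
#' set.seed(2)
#' blk <- simulate_block(agent_policy(bound = 0.2, ndt = 2,
#'                                    fast_guess_prob = 0.15),
#'                       block_condition_fixture(1, 2))
#' estimate_ndt(blk$trials)
#' @export
estimate_ndt <- function(trials, delay_range = 0:4) {
  if (length(trials$rt_steps) < 1L) stop("need at least one trial", call. = FALSE)
  pos <- if (is.list(trials$positions) && !is.character(trials$positions))
    trials$positions else parse_positions(trials$positions)
  rt <- trials$rt_steps
  choice <- trials$choice
  cong <- vapply(delay_range, function(d) {
    idx <- rt - d
    probed <- rep(NA_real_, length(rt))
    ok <- idx >= 1
    probed[ok] <- mapply(function(p, i) p[i + 1L], pos[ok], idx[ok])
    use <- ok & !is.na(probed) & probed != 0
    if (!any(use)) {
      warning(sprintf("all trials excluded at delay %d; scoring congruence 0", d),
              call. = FALSE)
      return(0)
    }
    mean(sign(probed[use]) == choice[use])
  }, numeric(1L))
  names(cong) <- delay_range
  structure(list(ndt_steps = delay_range[which.max(cong)],
                 congruence_by_delay = cong),
            class = "ndt_estimate")
}

#' @export
print.ndt_estimate <- function(x, ...) {
  cat(sprintf("<ndt_estimate> NDT = %d steps\n", x$ndt_steps))
  print(round(x$congruence_by_delay, 3))
  invisible(x)
}

#' Decision time from response time and non-decision time
#'
#' DT = RT - NDT, floored at 1 step (a decision takes at least one step;
#' floored trials should be flagged and excluded from bound regressions).
#'
#' @param rt_steps Response times in steps (>= 1).
#' @param ndt_steps Non-decision time in steps.
#' @return Integer decision times.
#' @export
decision_time <- function(rt_steps, ndt_steps) {
  if (any(rt_steps < 1)) stop("`rt_steps` must be >= 1", call. = FALSE)
  pmax(as.integer(rt_steps) - as.integer(ndt_steps), 1L)
}

#' Measure the raw decision bound of one trial
#'
#' The bound is measured as the absolute distance of the pigeon from the
#' midline halfway between one step before the decision time and at the
#' decision time: the crossing is assumed to have happened sometime during
#' that final decision step, and the midpoint is its expected value. For
#' `dt = 1` the pre-step position is the trial start (0).
#'
#' @param positions Numeric vector of positions starting at position 0, or a
#'   `pigeon_walk`.
#' @param dt_steps Decision time in steps (>= 1; at most the number of steps
#'   in the walk).
#' @return The raw bound, a value in `[0, 0.8]`.
#' @examples
#' measure_raw_bound(c(0, 0.1, 0.25), 2)  # 0.175
#' @export
measure_raw_bound <- function(positions, dt_steps) {
  if (inherits(positions, "pigeon_walk")) positions <- positions$positions
  if (dt_steps < 1) stop("`dt_steps` must be >= 1", call. = FALSE)
  if (dt_steps > length(positions) - 1L)
    stop("`dt_steps` exceeds the walk length", call. = FALSE)
  abs(positions[dt_steps] + positions[dt_steps + 1L]) / 2
}

# vectorized bound measurement over a trial table with parsed positions
measure_raw_bounds <- function(pos_list, dt) {
  vapply(seq_along(dt), function(i) {
    p <- pos_list[[i]]
    abs(p[dt[i]] + p[dt[i] + 1L]) / 2
  }, numeric(1L))
}

#' Slope of bound versus decision time
#'
#' Ordinary least-squares slope of the median bound per DT against DT, the
#' collapse diagnostic: values near 0 indicate a flat (constant) bound,
#' negative values a collapsing bound. Short DTs (default <= 2) are excluded
#' because bound estimates there are unreliable.
#'
#' @param dt_steps,bounds Per-trial decision times and (raw or corrected)
#'   bound magnitudes.
#' @param exclude_dt_leq Exclude trials with DT at or below this value.
#' @param per_trial If `TRUE`, regress individual trials instead of per-DT
#'   medians.
#' @return Slope in bound units per step, or `NA` (with a warning) when
#'   fewer than two distinct DT values remain.
#' @export
bound_vs_dt_slope <- function(dt_steps, bounds, exclude_dt_leq = 2,
                              per_trial = FALSE) {
  keep <- dt_steps > exclude_dt_leq & !is.na(bounds)
  dt <- dt_steps[keep]; b <- bounds[keep]
  if (length(unique(dt)) < 2L) {
    warning("fewer than two distinct DT values after exclusion", call. = FALSE)
    return(NA_real_)
  }
  if (per_trial) {
    x <- dt; y <- b
  } else {
    med <- tapply(b, dt, stats::median)
    x <- as.numeric(names(med)); y <- as.numeric(med)
  }
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Regression-to-the-mean diagnostic for trial-to-trial bound changes
#'
#' OLS slope of `bound[t] - bound[t+1]` on `bound[t]` over consecutive
#' trials. If bounds vary as independent noise around a constant mean the
#' slope is 1 (pure regression to the mean); if bounds drift as a random
#' walk across trials the slope is 0.
#'
#' @param bounds Bound magnitudes in trial order.
#' @return The slope, or `NA` (with a warning) given fewer than 3 trials or
#'   a degenerate (constant) regressor.
#' @export
bound_change_regression <- function(bounds) {
  bounds <- bounds[!is.na(bounds)]
  n <- length(bounds)
  if (n < 3L) {
    warning("need at least 3 consecutive trials", call. = FALSE)
    return(NA_real_)
  }
  x <- bounds[-n]
  y <- bounds[-n] - bounds[-1L]
  if (stats::var(x) == 0) {
    warning("bounds are constant; slope undefined", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::coef(stats::lm(y ~ x))[2L])
}

#' Z-score bounds within a participant
#'
#' Centers and scales by the sample mean and SD (n - 1 denominator) across
#' all of the participant's trials, to put bound time courses from
#' participants with different characteristic bounds on a common scale.
#'
#' @param bounds Bound magnitudes for one participant.
#' @return Z-scored bounds (all zero, with a warning, if the SD is 0).
#' @export
zscore_bounds <- function(bounds) {
  if (length(bounds) < 2L) stop("need at least 2 trials", call. = FALSE)
  s <- stats::sd(bounds)
  if (is.na(s) || s == 0) {
    warning("zero variance; returning zeros", call. = FALSE)
    return(rep(0, length(bounds)))
  }
  (bounds - mean(bounds)) / s
}

#' Augment a trial table with the estimation chain
#'
#' Runs the per-participant estimation chain on a trial table: NDT by
#' congruence maximization (by default separately for each participant and
#' SNR context), decision times (floored at 1 and flagged), raw bound
#' measurements, optional short-DT bias correction, and within-participant
#' z-scored bounds (computed per block over the bound used downstream --
#' corrected when available, raw otherwise).
#'
#' @param trials A trial table, as produced by [generate_cohort()] or read
#'   with [read_trials()].
#' @param correction Optional [build_correction_table()] result, or a list
#'   of correction tables covering the SNR contexts present (each trial uses
#'   the table with the nearest SNR).
#' @param ndt_by `"participant_snr"` (default) or `"participant"`: the
#'   granularity at which a single NDT is estimated and shared.
#' @return The trial table with columns `ndt`, `dt`, `dt_floored`,
#'   `raw_bound`, `corrected_bound` (NA when no table is supplied), and
#'   `z_bound` appended.
#' @export
analyze_trials <- function(trials, correction = NULL,
                           ndt_by = c("participant_snr", "participant")) {
  ndt_by <- match.arg(ndt_by)
  pos <- parse_positions(trials$positions)
  if (is.null(trials$snr)) {
    # reconstruct per-step SNR is impossible without sigma; fall back to label
    trials$snr <- as.numeric(factor(trials$snr_label))
  }
  grp <- if (ndt_by == "participant_snr")
    paste(trials$participant_id, sprintf("%.6g", trials$snr))
  else as.character(trials$participant_id)

  ndt <- integer(nrow(trials))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    est <- estimate_ndt(list(rt_steps = trials$rt_steps[idx],
                             choice = trials$choice[idx],
                             positions = pos[idx]))
    ndt[idx] <- est$ndt_steps
  }
  trials$ndt <- ndt
  trials$dt <- decision_time(trials$rt_steps, ndt)
  trials$dt_floored <- (trials$rt_steps - ndt) < 1L
  trials$raw_bound <- measure_raw_bounds(pos, trials$dt)

  if (!is.null(correction)) {
    tables <- if (inherits(correction, "correction_table")) list(correction)
              else correction
    snrs <- vapply(tables, `[[`, numeric(1L), "snr")
    pick <- vapply(trials$snr, function(s) which.min(abs(snrs - s)), integer(1L))
    cb <- numeric(nrow(trials))
    for (j in seq_along(tables)) {
      sel <- pick == j
      if (any(sel))
        cb[sel] <- correct_bound(trials$raw_bound[sel], trials$dt[sel], tables[[j]])
    }
    trials$corrected_bound <- cb
  } else {
    trials$corrected_bound <- NA_real_
  }

  use_bound <- if (all(is.na(trials$corrected_bound))) trials$raw_bound
               else trials$corrected_bound
  zgrp <- paste(trials$participant_id,
                if (!is.null(trials$block_index)) trials$block_index else 1L)
  z <- rep(NA_real_, nrow(trials))
  for (g in unique(zgrp)) {
    idx <- which(zgrp == g)
    z[idx] <- if (length(idx) >= 2L)
      suppressWarnings(zscore_bounds(use_bound[idx])) else 0
  }
  trials$z_bound <- z
  trials
}

#' Per-participant performance summary
#'
#' @param trials An analyzed trial table (see [analyze_trials()]); at
#'   minimum `participant_id`, `correct`, `coins_delta`, `steps_cost`, plus
#'   `dt` and a bound column when available.
#' @param bound_col Which bound column to summarize (default the corrected
#'   bound, falling back to raw).
#' @return A data.frame with one row per participant: number of trials,
#'   accuracy, median DT, mean and median bound, and realized reward rate
#'   (coins per step).
#' @export
participant_summary <- function(trials, bound_col = NULL) {
  if (nrow(trials) < 1L) stop("need at least one trial", call. = FALSE)
  if (is.null(bound_col)) {
    bound_col <- if (!is.null(trials$corrected_bound) &&
                     !all(is.na(trials$corrected_bound))) "corrected_bound"
                 else if (!is.null(trials$raw_bound)) "raw_bound" else NA
  }
  ids <- sort(unique(trials$participant_id))
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    data.frame(
      participant_id = id,
      n_trials = nrow(tr),
      accuracy = mean(tr$correct),
      median_dt = if (!is.null(tr$dt)) stats::median(tr$dt) else NA_real_,
      mean_bound = if (!is.na(bound_col)) mean(tr[[bound_col]], na.rm = TRUE) else NA_real_,
      median_bound = if (!is.na(bound_col)) stats::median(tr[[bound_col]], na.rm = TRUE) else NA_real_,
      reward_rate = sum(tr$coins_delta) / sum(tr$steps_cost)
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
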
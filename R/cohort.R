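#' Describe a synthetic cohort of task participants
#'
#' A cohort spec bundles the block sequence and the distribution of agent
#' parameters used to generate a synthetic behavioral dataset with the
#' structure the analysis pipeline assumes: heterogeneous constant bounds,
#' small integer non-decision times, and occasional fast guesses.
#'
#' By default per-agent bounds are drawn uniformly on `[0.1, 0.6]`, NDTs
#' uniformly from `{1, 2}`, and fast-guess probabilities uniformly on
#' `[0, 0.3]` -- fixture parameters spanning the qualitative range of human
#' performance, not estimates of any particular dataset.
#'
#' @param n_participants Number of agents (>= 1).
#' @param cohort Cohort label (1, 2, or 3); used for block fixtures and
#'   bookkeeping.
#' @param blocks List of [block_condition()]s played in order. Defaults to
#'   the full block sequence of `cohort` from [cohort_conditions()].
#'   Changepoint blocks may carry `changepoint_step = NA`; the step is then
#'   derived per participant from their RTs in the preceding fixed-SNR block
#'   whose magnitude matches the changepoint block's starting magnitude.
#' @param bound_range Range of per-agent constant bounds (uniform draw).
#' @param ndt_values Integer NDT values sampled per agent.
#' @param fast_guess_range Range of per-agent fast-guess probabilities.
#' @param bound_jitter_sd Trial-to-trial bound jitter SD shared by agents.
#' @param block_bound_offsets Numeric vector (recycled over blocks) added to
#'   each agent's base bound in the corresponding block, emulating
#'   payoff-sensitive block-wise bound adjustments. Default 0.
#' @param cp_bound_shift Length-2 numeric `c(low_to_high, high_to_low)`:
#'   amount each agent shifts its bound at the within-trial changepoint in
#'   changepoint blocks of each direction. Default `c(0, 0)` (no
#'   within-trial adjustment).
#' @param cp_statistic `"median"` or `"mean"`: RT statistic used to place
#'   each participant's changepoint (ceiling-rounded to a whole step).
#' @param agents Optional data.frame overriding the agent draw; columns
#'   `bound`, `ndt`, `fast_guess_prob`, and optionally `bound_jitter_sd`.
#' @param max_steps Per-trial step cap passed to the simulator.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 60L,
                        cohort = 1L,
                        blocks = NULL,
                        bound_range = c(0.1, 0.6),
                        ndt_values = c(1L, 2L),
                        fast_guess_range = c(0, 0.3),
                        bound_jitter_sd = 0,
                        block_bound_offsets = 0,
                        cp_bound_shift = c(low_to_high = 0, high_to_low = 0),
                        cp_statistic = c("median", "mean"),
                        agents = NULL,
                        max_steps = 60L) {
  cp_statistic <- match.arg(cp_statistic)
  if (n_participants < 1) stop("`n_participants` must be >= 1", call. = FALSE)
  if (is.null(blocks)) {
    tab <- cohort_conditions(cohort)
    blocks <- lapply(tab$block, function(b)
      block_condition_fixture(cohort, b, changepoint_step = NA))
  }
  stopifnot(all(vapply(blocks, inherits, logical(1L), "block_condition")))
  if (length(cp_bound_shift) == 1L) cp_bound_shift <- rep(cp_bound_shift, 2L)
  structure(list(
    n_participants = as.integer(n_participants), cohort = as.integer(cohort),
    blocks = blocks, bound_range = bound_range, ndt_values = as.integer(ndt_values),
    fast_guess_range = fast_guess_range, bound_jitter_sd = bound_jitter_sd,
    block_bound_offsets = block_bound_offsets,
    cp_bound_shift = cp_bound_shift, cp_statistic = cp_statistic,
    agents = agents, max_steps = as.integer(max_steps)
  ), class = "cohort_spec")
}

# Session-wide SNR labels: rank each trial magnitude among the magnitudes
# occurring anywhere in the block sequence.
session_snr_labels <- function(blocks) {
  mags <- sort(unique(unlist(lapply(blocks, `[[`, "mean_magnitudes"))))
  labs <- if (length(mags) == 1L) "fixed"
          else if (length(mags) == 2L) c("low", "high")
          else c("low", "mid", "high")[seq_along(mags)]
  stats::setNames(labs, sprintf("%.10g", mags))
}

# For a changepoint block, find the index of the source block whose fixed
# magnitude equals the changepoint block's starting magnitude.
cp_source_block <- function(blocks, cp_index) {
  start_mu <- blocks[[cp_index]]$mean_magnitudes[1L]
  for (j in seq_len(cp_index - 1L)) {
    if (blocks[[j]]$snr_mode == "fixed" &&
        isTRUE(all.equal(blocks[[j]]$step_mean, start_mu))) return(j)
  }
  stop(sprintf("no preceding fixed-SNR block matches the starting magnitude %g of block %d",
               start_mu, cp_index), call. = FALSE)
}

#' Generate a synthetic cohort's trial table
#'
#' Simulates every participant through the spec's block sequence and returns
#' one tidy trial table. Ground-truth columns (`true_bound`, `true_ndt`,
#' `fast_guess`) are retained so that downstream estimators can be scored
#' against the generating parameters.
#'
#' For changepoint blocks whose `changepoint_step` is `NA`, each agent's
#' changepoint is placed at the ceiling of the `cp_statistic` of its RTs in
#' its own preceding fixed-SNR block with the matching starting SNR.
#'
#' All randomness flows from `seed`: agent parameters are drawn first, then
#' one sub-seed per participant x block drives that block's simulation, so a
#' cohort is reproducible as a whole and per block.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A data.frame, one row per trial, with columns `participant_id`,
#'   `cohort`, `block_index`, `trial_index`, `drift_sign`, `snr_label`,
#'   `changepoint_step`, `rt_steps`, `choice`, `correct`, `coins_delta`,
#'   `steps_cost`, `positions` (semicolon-joined, position 0..rt),
#'   `true_bound`, `true_ndt`, `fast_guess`, plus `snr`, `trial_mu`, and
#'   `forced` flags.
#' @examples
#' trials <- generate_cohort(cohort_spec(n_participants = 2, cohort = 1,
#'   blocks = list(block_condition_fixture(1, 2))), seed = 7)
#' head(trials[, c("participant_id", "rt_steps", "choice", "correct")])
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  np <- spec$n_participants
  nb <- length(spec$blocks)
  agents <- spec$agents
  if (is.null(agents)) {
    agents <- data.frame(
      bound = stats::runif(np, spec$bound_range[1L], spec$bound_range[2L]),
      ndt = sample(spec$ndt_values, np, replace = TRUE),
      fast_guess_prob = stats::runif(np, spec$fast_guess_range[1L],
                                     spec$fast_guess_range[2L]),
      bound_jitter_sd = spec$bound_jitter_sd
    )
  } else {
    if (nrow(agents) != np) stop("`agents` must have one row per participant",
                                 call. = FALSE)
    if (is.null(agents$bound_jitter_sd))
      agents$bound_jitter_sd <- spec$bound_jitter_sd
  }
  offsets <- rep_len(spec$block_bound_offsets, nb)
  labels <- session_snr_labels(spec$blocks)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, np * nb), np, nb)

  out <- vector("list", np * nb)
  rt_store <- vector("list", np * nb)  # per participant x block RTs
  k <- 0L
  for (p in seq_len(np)) {
    for (b in seq_len(nb)) {
      cond <- spec$blocks[[b]]
      base_bound <- min(max(agents$bound[p] + offsets[b], 0.02), 0.78)
      cpstep <- NA_integer_
      post_bound <- NULL
      if (cond$snr_mode == "changepoint") {
        if (is.null(cond$changepoint_step) || is.na(cond$changepoint_step)) {
          src <- cp_source_block(spec$blocks, b)
          rts <- rt_store[[(p - 1L) * nb + src]]
          if (is.null(rts) || !length(rts))
            stop("changepoint source block has no trials", call. = FALSE)
          cpstep <- derive_cp_step(rts, spec$cp_statistic)
        } else cpstep <- cond$changepoint_step
        cond$changepoint_step <- cpstep
        dir_ <- if (cond$mean_magnitudes[2L] > cond$mean_magnitudes[1L]) 1L else 2L
        shift <- spec$cp_bound_shift[dir_]
        if (!is.null(agents$cp_shift_low_to_high) && dir_ == 1L)
          shift <- agents$cp_shift_low_to_high[p]
        if (!is.null(agents$cp_shift_high_to_low) && dir_ == 2L)
          shift <- agents$cp_shift_high_to_low[p]
        post_bound <- min(max(base_bound + shift, 0), PILE_DISTANCE)
      }
      policy <- agent_policy(bound = base_bound, ndt = agents$ndt[p],
                             fast_guess_prob = agents$fast_guess_prob[p],
                             bound_jitter_sd = agents$bound_jitter_sd[p],
                             post_cp_bound = post_bound)
      set.seed(sub_seeds[p, b])
      blk <- simulate_block(policy, cond, spec$max_steps)
      tr <- blk$trials
      k <- k + 1L
      rt_store[[(p - 1L) * nb + b]] <- tr$rt_steps
      tr$participant_id <- p
      tr$cohort <- spec$cohort
      tr$block_index <- b
      tr$changepoint_step <- cpstep
      tr$snr_label <- if (cond$snr_mode == "trial_mixed")
        tr$snr_label else unname(labels[sprintf("%.10g", cond$step_mean)])
      out[[k]] <- tr
    }
  }
  trials <- do.call(rbind, out[seq_len(k)])
  cols <- c("participant_id", "cohort", "block_index", "trial_index",
            "drift_sign", "snr_label", "changepoint_step", "rt_steps",
            "choice", "correct", "coins_delta", "steps_cost", "positions",
            "true_bound", "true_ndt", "fast_guess", "forced", "trial_mu", "snr")
  trials <- trials[, cols]
  rownames(trials) <- NULL
  trials
}

#' Read and write trial tables
#'
#' Trial tables are plain CSV, one row per trial, with pigeon positions
#' serialized as a semicolon-joined string (see [generate_cohort()] for the
#' column layout). Identically-shaped real data can be read the same way.
#'
#' @param trials A trial table data.frame.
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial table.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("participant_id", "rt_steps", "choice", "positions")
  missing <- setdiff(needed, names(tr))
  if (length(missing))
    stop("trial table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  tr$positions <- as.character(tr$positions)
  tr
}
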
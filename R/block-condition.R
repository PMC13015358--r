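#' Define the generative and payoff parameters of one task block
#'
#' A block condition bundles everything that defines one block of the pigeon
#' task: the Gaussian step distribution of the pigeon's random walk, how the
#' step-mean magnitude (and hence signal-to-noise ratio, SNR) is assigned to
#' trials, the coin payoffs for correct and error choices, any step penalty
#' for errors, and the block's total step budget.
#'
#' Positions are expressed in normalized screen units: the screen edge is at
#' distance 1 from the central starting point and the seed piles sit at
#' +/-0.8, the furthest point the pigeon can reach. The per-step SNR is
#' `mu / sigma`, the absolute step mean divided by the step standard
#' deviation.
#'
#' @param step_mean Step-mean magnitude `mu` (drift per step, position units).
#'   For `snr_mode = "fixed"` this is the single magnitude used on every
#'   trial; for the other modes it defaults to `mean_magnitudes[1]`.
#' @param step_std Step standard deviation `sigma` (> 0, position units).
#' @param snr_mode How the step-mean magnitude is assigned: `"fixed"` (one
#'   magnitude for the whole block), `"trial_mixed"` (drawn 50/50 from
#'   `mean_magnitudes` on each trial, then fixed within the trial), or
#'   `"changepoint"` (switches from `mean_magnitudes[1]` to
#'   `mean_magnitudes[2]` at `changepoint_step` within every trial).
#' @param mean_magnitudes Numeric vector of exactly two magnitudes; required
#'   for `"trial_mixed"` and `"changepoint"` modes.
#' @param changepoint_step Positive integer step index at which the step mean
#'   switches (the step with this index is the first drawn from the second
#'   distribution). Required in `"changepoint"` mode; `NA` allowed as a
#'   placeholder to be filled in per participant.
#' @param coins_correct Integer coins gained per correct choice.
#' @param coins_error Integer coins for an error (<= 0).
#' @param steps_error_penalty Non-negative integer steps added to the block
#'   ledger after an error.
#' @param block_step_budget Positive integer total step budget per block
#'   (default 600).
#' @param step_duration Step duration in seconds (default 0.2); informational.
#' @return An object of class `block_condition`.
#' @examples
#' cond <- block_condition(step_mean = 0.05, step_std = 0.15,
#'                         coins_correct = 1, coins_error = -4)
#' snr(cond)  # 1/3
#' @export
block_condition <- function(step_mean = NULL,
                            step_std,
                            snr_mode = c("fixed", "trial_mixed", "changepoint"),
                            mean_magnitudes = NULL,
                            changepoint_step = NULL,
                            coins_correct = 1L,
                            coins_error = 0L,
                            steps_error_penalty = 0L,
                            block_step_budget = 600L,
                            step_duration = 0.2) {
  snr_mode <- match.arg(snr_mode)
  if (!is.numeric(step_std) || length(step_std) != 1L || step_std <= 0)
    stop("`step_std` must be a single positive number", call. = FALSE)
  if (snr_mode == "fixed") {
    if (is.null(step_mean) && length(mean_magnitudes) == 1L)
      step_mean <- mean_magnitudes
    if (is.null(step_mean) || length(step_mean) != 1L || step_mean < 0)
      stop("fixed mode needs a single non-negative `step_mean`", call. = FALSE)
    mean_magnitudes <- step_mean
  } else {
    if (length(mean_magnitudes) != 2L || any(mean_magnitudes < 0))
      stop(sprintf("%s mode requires exactly two non-negative `mean_magnitudes`",
                   snr_mode), call. = FALSE)
    if (is.null(step_mean)) step_mean <- mean_magnitudes[1L]
  }
  if (snr_mode == "changepoint") {
    if (is.null(changepoint_step))
      stop("changepoint mode requires `changepoint_step` (use NA as placeholder)",
           call. = FALSE)
    if (!is.na(changepoint_step) &&
        (changepoint_step < 1 || changepoint_step != round(changepoint_step)))
      stop("`changepoint_step` must be a positive integer", call. = FALSE)
  } else {
    changepoint_step <- NULL
  }
  if (coins_error > 0) stop("`coins_error` must be <= 0", call. = FALSE)
  if (steps_error_penalty < 0) stop("`steps_error_penalty` must be >= 0", call. = FALSE)
  if (block_step_budget < 1) stop("`block_step_budget` must be >= 1", call. = FALSE)
  structure(list(
    step_mean = as.numeric(step_mean),
    step_std = as.numeric(step_std),
    snr_mode = snr_mode,
    mean_magnitudes = as.numeric(mean_magnitudes),
    changepoint_step = if (is.null(changepoint_step)) NULL else as.integer(changepoint_step),
    coins_correct = as.integer(coins_correct),
    coins_error = as.integer(coins_error),
    steps_error_penalty = as.integer(steps_error_penalty),
    block_step_budget = as.integer(block_step_budget),
    step_duration = as.numeric(step_duration)
  ), class = "block_condition")
}

#' @export
print.block_condition <- function(x, ...) {
  mus <- paste(format(x$mean_magnitudes), collapse = "/")
  cat(sprintf("<block_condition> mode=%s mu=%s sigma=%g (SNR %s)\n",
              x$snr_mode, mus, x$step_std,
              paste(format(round(snr(x), 3)), collapse = "/")))
  cat(sprintf("  payoffs: %+d correct, %+d error, %d penalty steps; budget %d steps\n",
              x$coins_correct, x$coins_error, x$steps_error_penalty,
              x$block_step_budget))
  if (!is.null(x$changepoint_step))
    cat(sprintf("  changepoint at step %s\n", x$changepoint_step))
  invisible(x)
}

#' Per-step signal-to-noise ratio of a block condition
#'
#' @param cond A [block_condition()].
#' @return `mean_magnitudes / step_std`, one value per magnitude.
#' @export
snr <- function(cond) {
  stopifnot(inherits(cond, "block_condition"))
  cond$mean_magnitudes / cond$step_std
}

#' Task-parameter fixtures for the three study cohorts
#'
#' Returns the packaged table of block parameters used by the three cohorts
#' of the pigeon task: cohort 1 (six fixed-SNR blocks crossing two step-mean
#' magnitudes with three payoff regimes), cohort 2 (three trial-mixed-SNR
#' blocks plus three fixed intermediate-SNR blocks), and cohort 3 (low/high
#' fixed-SNR blocks, a trial-mixed block, and two within-trial changepoint
#' blocks, low-to-high and high-to-low).
#'
#' @param cohort Optional cohort number (1, 2, or 3) to filter on.
#' @return A data.frame with one row per cohort x block.
#' @seealso [block_condition_fixture()] to build a [block_condition()] from a
#'   row of this table.
#' @export
cohort_conditions <- function(cohort = NULL) {
  path <- system.file("extdata", "task-conditions.yaml", package = "pigeonbound")
  raw <- yaml::read_yaml(path)
  tab <- do.call(rbind, lapply(raw$blocks, function(b) {
    data.frame(cohort = b$cohort, block = b$block,
               mu1 = b$mean_magnitudes[[1]],
               mu2 = if (length(b$mean_magnitudes) > 1) b$mean_magnitudes[[2]] else NA_real_,
               step_std = b$step_std, snr_mode = b$snr_mode,
               coins_correct = b$coins_correct, coins_error = b$coins_error,
               steps_error_penalty = b$steps_error_penalty,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(cohort)) tab <- tab[tab$cohort == cohort, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Build a block condition for a given cohort and block of the study design
#'
#' @param cohort Cohort number (1, 2, or 3).
#' @param block Block number within the cohort.
#' @param changepoint_step Step index of the within-trial SNR switch; only
#'   used (and then required, `NA` allowed as a per-participant placeholder)
#'   for changepoint blocks.
#' @param block_step_budget Total step budget (default 600).
#' @return A [block_condition()].
#' @examples
#' block_condition_fixture(1, 2)  # low SNR, +1/-4 coins
#' @export
block_condition_fixture <- function(cohort, block, changepoint_step = NA,
                                    block_step_budget = 600L) {
  tab <- cohort_conditions(cohort)
  row <- tab[tab$block == block, , drop = FALSE]
  if (nrow(row) != 1L)
    stop(sprintf("no fixture for cohort %s block %s", cohort, block), call. = FALSE)
  mags <- c(row$mu1, row$mu2)
  mags <- mags[!is.na(mags)]
  block_condition(
    step_mean = mags[1L],
    step_std = row$step_std,
    snr_mode = row$snr_mode,
    mean_magnitudes = if (length(mags) == 2L) mags else NULL,
    changepoint_step = if (row$snr_mode == "changepoint") changepoint_step else NULL,
    coins_correct = row$coins_correct,
    coins_error = row$coins_error,
    steps_error_penalty = row$steps_error_penalty,
    block_step_budget = block_step_budget
  )
}

#' Read or write a block condition as a YAML or JSON config
#'
#' Serialization keys mirror the task-parameter table columns so that
#' conditions can be shared between sessions and the command line.
#'
#' @param cond A [block_condition()].
#' @param path File path ending in `.yaml`, `.yml`, or `.json`.
#' @return `write_block_condition()` returns `path` invisibly;
#'   `read_block_condition()` returns a [block_condition()].
#' @export
write_block_condition <- function(cond, path) {
  stopifnot(inherits(cond, "block_condition"))
  x <- unclass(cond)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_block_condition
#' @export
read_block_condition <- function(path) {
  x <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
       else yaml::read_yaml(path)
  block_condition(
    step_mean = x$step_mean, step_std = x$step_std, snr_mode = x$snr_mode,
    mean_magnitudes = if (x$snr_mode == "fixed") NULL else unlist(x$mean_magnitudes),
    changepoint_step = x$changepoint_step,
    coins_correct = x$coins_correct, coins_error = x$coins_error,
    steps_error_penalty = x$steps_error_penalty,
    block_step_budget = x$block_step_budget,
    step_duration = if (is.null(x$step_duration)) 0.2 else x$step_duration
  )
}
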
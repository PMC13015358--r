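#' Place a participant's within-trial changepoint from their RTs
#'
#' The changepoint of a changepoint block is cued at a fixed time per
#' participant, chosen as the median (or mean) RT from that participant's
#' preceding fixed-SNR block with the same starting SNR, rounded up to a
#' whole step.
#'
#' @param rt_steps RTs (in steps) from the source block (>= 1 trial).
#' @param statistic `"median"` or `"mean"`.
#' @return Integer changepoint step.
#' @examples
#' derive_cp_step(c(8, 11))  # median 9.5 -> 10
#' @export
derive_cp_step <- function(rt_steps, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  if (!length(rt_steps)) stop("no RTs supplied", call. = FALSE)
  val <- if (statistic == "median") stats::median(rt_steps) else mean(rt_steps)
  as.integer(ceiling(val))
}

#' Per-participant bound change at the within-trial changepoint
#'
#' Splits each participant's analyzed changepoint-block trials into
#' decisions that ended before the changepoint (DT < changepoint step) and
#' at/after it (DT >= changepoint step) and reports the difference in mean
#' bound (post minus pre; positive values are bound increases). Corrected
#' bounds are used when available.
#'
#' @param analyzed An analyzed trial table (see [analyze_trials()])
#'   restricted to one changepoint block.
#' @param cp_steps Optional named vector of changepoint steps per
#'   participant; defaults to the table's `changepoint_step` column.
#' @param bound_col Bound column to compare (default corrected, falling
#'   back to raw).
#' @param exclude_floored Drop DT-floored trials (default TRUE).
#' @param exclude_cp_commit If `TRUE`, decisions committed at exactly the
#'   changepoint step are dropped from the post set. Such commitments are
#'   triggered by positions that accumulated entirely under the
#'   pre-changepoint regime, so their measured bounds reflect the
#'   pre-changepoint survival distribution rather than the post bound;
#'   excluding them de-biases the post mean at the cost of trials. Default
#'   `FALSE` (post = all decisions with DT at or after the changepoint).
#' @return A data.frame with one row per participant: `pre_mean_bound`,
#'   `post_mean_bound`, `bound_change`, and the pre/post trial counts.
#'   Participants lacking pre or post trials are dropped with a message.
#' @export
changepoint_bound_change <- function(analyzed, cp_steps = NULL,
                                     bound_col = NULL,
                                     exclude_floored = TRUE,
                                     exclude_cp_commit = FALSE) {
  if (is.null(bound_col)) {
    bound_col <- if (!is.null(analyzed$corrected_bound) &&
                     !all(is.na(analyzed$corrected_bound))) "corrected_bound"
                 else "raw_bound"
  }
  if (exclude_floored && !is.null(analyzed$dt_floored))
    analyzed <- analyzed[!analyzed$dt_floored, , drop = FALSE]
  ids <- sort(unique(analyzed$participant_id))
  rows <- lapply(ids, function(id) {
    tr <- analyzed[analyzed$participant_id == id, , drop = FALSE]
    cp <- if (!is.null(cp_steps)) cp_steps[[as.character(id)]]
          else tr$changepoint_step[1L]
    pre <- tr[[bound_col]][tr$dt < cp]
    post <- if (exclude_cp_commit) tr[[bound_col]][tr$dt > cp]
            else tr[[bound_col]][tr$dt >= cp]
    if (!length(pre) || !length(post)) {
      message(sprintf("participant %s lacks pre or post trials; excluded", id))
      return(NULL)
    }
    data.frame(participant_id = id, changepoint_step = cp,
               n_pre = length(pre), n_post = length(post),
               pre_mean_bound = mean(pre), post_mean_bound = mean(post),
               bound_change = mean(post) - mean(pre))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the end-to-end analysis pipeline
#'
#' Simulates (or ingests) a cohort, runs the estimation chain, and produces
#' the cross-participant reports: per-participant summaries per block,
#' accuracy-versus-DT and bound-versus-DT rank correlations, paired
#' block-versus-block bound comparisons (Wilcoxon signed-rank), per-
#' participant collapse and regression-to-the-mean slopes, and, when
#' changepoint blocks are present, pre/post changepoint bound changes.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `cohort_spec` (a [cohort_spec()]) or `trials_csv` (path to a trial
#'   table); optional `correction` (a correction table, list of tables, or
#'   `list(n_sims_per_bound = ...)` to build tables per SNR context);
#'   optional `seed` (default 1); optional `out_dir` to write CSV/JSON
#'   artifacts.
#' @return A `report_bundle`: list with `trials` (analyzed table),
#'   `summaries` (per participant x block), `block_comparisons`,
#'   `slopes` (per-participant diagnostics), `changepoint` (or `NULL`),
#'   and `provenance`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  trials <- if (!is.null(config$trials_csv)) read_trials(config$trials_csv)
            else if (!is.null(config$cohort_spec))
              generate_cohort(config$cohort_spec, seed = seed)
            else stop("config needs `cohort_spec` or `trials_csv`", call. = FALSE)

  correction <- config$correction
  if (is.list(correction) && !is.null(correction$n_sims_per_bound)) {
    # build one table per SNR context present in the data
    snrs <- sort(unique(round(trials$snr, 6)))
    sigma <- if (!is.null(trials$trial_mu))
      stats::median(trials$trial_mu / trials$snr, na.rm = TRUE) else 0.15
    correction <- lapply(snrs, function(s) {
      cond <- block_condition(step_mean = s * sigma, step_std = sigma)
      build_correction_table(cond,
                             n_sims_per_bound = correction$n_sims_per_bound,
                             seed = seed + 17L)
    })
  }
  analyzed <- analyze_trials(trials, correction = correction)
  ok <- !analyzed$dt_floored

  blocks <- sort(unique(analyzed$block_index))
  summaries <- do.call(rbind, lapply(blocks, function(b) {
    s <- participant_summary(analyzed[analyzed$block_index == b & ok, ,
                                      drop = FALSE])
    s$block_index <- b
    s
  }))

  bcol <- if (!all(is.na(analyzed$corrected_bound))) "corrected_bound"
          else "raw_bound"

  # paired block-vs-block comparisons of per-participant mean bounds
  comparisons <- NULL
  if (length(blocks) > 1L) {
    pairs <- cbind(blocks[-length(blocks)], blocks[-1L])
    comparisons <- do.call(rbind, apply(pairs, 1L, function(pr) {
      a <- summaries[summaries$block_index == pr[1L], ]
      b <- summaries[summaries$block_index == pr[2L], ]
      m <- merge(a[, c("participant_id", "mean_bound")],
                 b[, c("participant_id", "mean_bound")],
                 by = "participant_id")
      if (nrow(m) < 3L) return(NULL)
      wt <- stats::wilcox.test(m$mean_bound.y, m$mean_bound.x, paired = TRUE,
                               exact = FALSE)
      data.frame(block_a = pr[1L], block_b = pr[2L], n = nrow(m),
                 median_diff = stats::median(m$mean_bound.y - m$mean_bound.x),
                 p_value = wt$p.value)
    }))
  }

  # per-participant diagnostic slopes (collapse; regression to the mean)
  ids <- sort(unique(analyzed$participant_id))
  slopes <- do.call(rbind, lapply(ids, function(id) {
    tr <- analyzed[analyzed$participant_id == id & ok, , drop = FALSE]
    data.frame(
      participant_id = id,
      collapse_slope = suppressWarnings(
        bound_vs_dt_slope(tr$dt, tr[[bcol]])),
      change_slope = suppressWarnings(
        bound_change_regression(tr[[bcol]])))
  }))

  # cross-participant rank correlations (first block as reference context)
  ref <- summaries[summaries$block_index == blocks[1L], ]
  correlations <- NULL
  if (nrow(ref) >= 4L) {
    ct1 <- stats::cor.test(ref$accuracy, ref$median_dt, method = "spearman",
                           exact = FALSE)
    ct2 <- stats::cor.test(ref$mean_bound, ref$median_dt, method = "spearman",
                           exact = FALSE)
    correlations <- data.frame(
      comparison = c("accuracy_vs_median_dt", "mean_bound_vs_median_dt"),
      rho = c(unname(ct1$estimate), unname(ct2$estimate)),
      p_value = c(ct1$p.value, ct2$p.value))
  }

  changepoint <- NULL
  cp_blocks <- blocks[vapply(blocks, function(b)
    any(!is.na(analyzed$changepoint_step[analyzed$block_index == b])),
    logical(1L))]
  if (length(cp_blocks)) {
    changepoint <- do.call(rbind, lapply(cp_blocks, function(b) {
      ch <- changepoint_bound_change(
        analyzed[analyzed$block_index == b, , drop = FALSE])
      if (!is.null(ch)) ch$block_index <- b
      ch
    }))
  }

  bundle <- structure(list(
    trials = analyzed, summaries = summaries,
    block_comparisons = comparisons, slopes = slopes,
    correlations = correlations, changepoint = changepoint,
    provenance = list(seed = seed, package_version =
                        as.character(utils::packageVersion("pigeonbound")),
                      timestamp = format(Sys.time(), tz = "UTC"))
  ), class = "report_bundle")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(analyzed, file.path(config$out_dir, "trials-analyzed.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "participant-summaries.csv"),
                     row.names = FALSE)
    stats_out <- list(block_comparisons = comparisons, slopes = slopes,
                      correlations = correlations, changepoint = changepoint,
                      provenance = bundle$provenance)
    jsonlite::write_json(stats_out, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         null = "null", na = "null")
  }
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle> %d trials, %d participants, %d blocks (seed %s)\n",
              nrow(x$trials), length(unique(x$trials$participant_id)),
              length(unique(x$trials$block_index)), x$provenance$seed))
  invisible(x)
}
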
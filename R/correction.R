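#' Build a simulation-based correction table for short-DT bound bias
#'
#' The midpoint bound measurement is increasingly unbiased at long decision
#' times, but at short DTs the pigeon position is not independent of the
#' chosen bound (the first step is distributed according to the generative
#' step distribution regardless of the bound), so low bounds tend to be
#' overestimated and high bounds underestimated.
#'
#' To quantify the bias, decisions are simulated for the condition's SNR at
#' each of the fixed bound values on `bound_grid`, with a per-trial NDT
#' drawn uniformly from `ndt_values` governing the keypress time while the
#' walk continues. The midpoint bound is measured at each trial's decision
#' time, which the simulation knows exactly (the commitment step) and which
#' the estimation chain on data reproduces whenever the participant-level
#' NDT estimate is correct. For each DT, trials are pooled across all
#' simulated bounds and an OLS line of measured bound on true bound is
#' fitted; its analytic inverse is stored so that applying the table to
#' measured values calibrates them to the true simulated bounds.
#'
#' @param cond A fixed-SNR [block_condition()] (supplies `mu` and `sigma`).
#' @param bound_grid True bound values to simulate (default 16 values, 0.01
#'   to 0.76 in steps of 0.05).
#' @param n_sims_per_bound Simulated trials per bound (default 1e5).
#' @param ndt_values Integer NDT values drawn uniformly per trial
#'   (default 0..2).
#' @param max_steps Per-trial step cap.
#' @param min_cell Minimum pooled trials a DT needs for its own fit; sparser
#'   DTs fall back to the identity map with a warning.
#' @param seed Optional integer seed for reproducibility.
#' @return A `correction_table`: per-DT `(slope, intercept)` of the
#'   measured-versus-true relation, plus metadata.
#' @export
build_correction_table <- function(cond,
                                   bound_grid = default_bound_grid(),
                                   n_sims_per_bound = 1e5,
                                   ndt_values = 0:2,
                                   max_steps = 60L,
                                   min_cell = 30L,
                                   seed = NULL) {
  stopifnot(inherits(cond, "block_condition"))
  if (cond$snr_mode != "fixed")
    stop("correction tables are built per fixed-SNR condition", call. = FALSE)
  if (n_sims_per_bound < 1e3)
    stop("`n_sims_per_bound` must be at least 1000", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  true_b <- dt_all <- meas <- vector("list", length(bound_grid))
  for (j in seq_along(bound_grid)) {
    b <- bound_grid[j]
    policy <- agent_policy(bound = b, ndt = ndt_values)
    sim <- simulate_trials_bulk(policy, cond, n_sims_per_bound, max_steps)
    tr <- sim$trials
    # the simulation knows each trial's DT exactly (the commitment step);
    # the analysis chain on data reproduces it whenever the participant's
    # NDT is estimated correctly, so the map is built at the true DT
    dt <- tr$commit_step
    prev <- ifelse(dt == 1L, 0,
                   sim$positions[cbind(seq_len(nrow(tr)), pmax(dt - 1L, 1L))])
    at <- sim$positions[cbind(seq_len(nrow(tr)), dt)]
    true_b[[j]] <- rep(b, nrow(tr))
    dt_all[[j]] <- dt
    meas[[j]] <- abs(prev + at) / 2
  }
  true_b <- unlist(true_b); dt_all <- unlist(dt_all); meas <- unlist(meas)

  dts <- sort(unique(dt_all))
  fits <- lapply(dts, function(d) {
    idx <- dt_all == d
    if (sum(idx) < min_cell || stats::var(true_b[idx]) == 0) {
      warning(sprintf("DT %d has a sparse or degenerate cell; using identity map", d),
              call. = FALSE)
      return(c(slope = 1, intercept = 0, identity = 1, n = sum(idx)))
    }
    co <- stats::coef(stats::lm(meas[idx] ~ true_b[idx]))
    c(slope = unname(co[2L]), intercept = unname(co[1L]), identity = 0,
      n = sum(idx))
  })
  map <- do.call(rbind, fits)
  tab <- data.frame(dt = dts, slope = map[, "slope"],
                    intercept = map[, "intercept"],
                    identity = map[, "identity"] == 1, n = map[, "n"])
  structure(list(
    snr = cond$step_mean / cond$step_std,
    sigma = cond$step_std,
    map = tab,
    metadata = list(n_sims_per_bound = n_sims_per_bound,
                    bound_grid = bound_grid, ndt_values = ndt_values,
                    max_steps = max_steps, seed = seed)
  ), class = "correction_table")
}

#' @export
print.correction_table <- function(x, ...) {
  cat(sprintf("<correction_table> SNR %.3g (sigma %.3g), DTs %d..%d, %g sims/bound\n",
              x$snr, x$sigma, min(x$map$dt), max(x$map$dt),
              x$metadata$n_sims_per_bound))
  invisible(x)
}

#' Apply a correction table to measured bounds
#'
#' Inverts the per-DT measured-versus-true fit: `corrected =
#' (raw - intercept) / slope`, clipped to the physical range `[0, 0.8]`.
#' DTs outside the table's range (and any fit with non-positive slope) map
#' through the identity.
#'
#' @param raw_bound Measured raw bound(s).
#' @param dt_steps Decision time(s) matching `raw_bound`.
#' @param table A [build_correction_table()] result.
#' @return Corrected bound(s) in `[0, 0.8]`.
#' @export
correct_bound <- function(raw_bound, dt_steps, table) {
  stopifnot(inherits(table, "correction_table"))
  idx <- match(dt_steps, table$map$dt)
  slope <- ifelse(is.na(idx), 1, table$map$slope[idx])
  inter <- ifelse(is.na(idx), 0, table$map$intercept[idx])
  bad <- slope <= 0
  if (any(bad)) {
    warning("non-positive slope in correction table; identity used", call. = FALSE)
    slope[bad] <- 1; inter[bad] <- 0
  }
  pmin(pmax((raw_bound - inter) / slope, 0), PILE_DISTANCE)
}

#' The standard 16-point bound grid
#'
#' Bound values 0.01 to 0.76 in steps of 0.05, spanning the physically
#' reachable range below the seed piles at 0.8.
#'
#' @return Numeric vector of 16 bound values.
#' @export
default_bound_grid <- function() seq(0.01, 0.76, by = 0.05)

#' Read or write a correction table as JSON
#'
#' @param table A `correction_table`.
#' @param path JSON file path.
#' @return `write_correction_table()` returns `path` invisibly;
#'   `read_correction_table()` returns the `correction_table`.
#' @export
write_correction_table <- function(table, path) {
  stopifnot(inherits(table, "correction_table"))
  jsonlite::write_json(unclass(table), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_correction_table
#' @export
read_correction_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$map <- as.data.frame(x$map)
  structure(x, class = "correction_table")
}
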
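#' Six-number summary of a Monte-Carlo run
#'
#' One row per result variable with the minimum, first quartile, median,
#' mean, third quartile and maximum across the simulated trials.
#' Quartiles use linear interpolation of order statistics
#' (`stats::quantile()` type 7). Absent values (interim statistics of
#' trials whose trigger was never reached, odds ratios of degenerate
#' zero-cell fits) are excluded, with the exclusion count reported in
#' `n_missing` rather than silently dropped. Indicator variables such as
#' `interim_stop` are summarised with all six statistics even though only
#' their mean is interpretable, keeping one fixed table schema.
#'
#' @param run A `trial_sims` object from [simulate_trials()].
#' @return A `data.frame` with columns `variable, minimum, q1, median,
#'   mean, q3, maximum, n_missing`, in the canonical result-column order.
#' @export
summarise_run <- function(run) {
  stopifnot(inherits(run, "trial_sims"), run$n_sims >= 1L)
  vars <- result_columns
  stats_one <- function(v) {
    x <- run$results[[v]]
    miss <- sum(is.na(x))
    x <- x[!is.na(x)]
    if (length(x) == 0L)
      return(data.frame(variable = v, minimum = NA_real_, q1 = NA_real_,
                        median = NA_real_, mean = NA_real_, q3 = NA_real_,
                        maximum = NA_real_, n_missing = miss))
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    data.frame(variable = v, minimum = min(x), q1 = q[1], median = q[2],
               mean = mean(x), q3 = q[3], maximum = max(x),
               n_missing = miss)
  }
  out <- do.call(rbind, lapply(vars, stats_one))
  rownames(out) <- NULL
  out
}

#' Operating characteristics of a simulated design
#'
#' Aggregates a Monte-Carlo run into the frequentist operating
#' characteristics of the design: the proportion of conclusive trials
#' (`p_success` — the type I error under a null scenario, the power
#' otherwise), the probability of stopping at the interim, the expected
#' sample size, the flip-flop (false early stopping) probability, and the
#' mean final-analysis effect estimates. Odds-ratio and CI means are
#' taken over non-degenerate fits only; `n_or_excluded` counts the
#' degenerate trials excluded.
#'
#' @param run A `trial_sims` object.
#' @return A one-row `data.frame` of class `trial_oc` with columns
#'   `scenario, p0, p1, n_sims, p_success, p_interim_stop,
#'   mean_sample_size, p_flipflop, mean_final_or, mean_final_lci,
#'   mean_final_uci, mean_final_p, n_or_excluded`.
#' @export
extract_oc <- function(run) {
  stopifnot(inherits(run, "trial_sims"), run$n_sims >= 1L)
  r <- run$results
  oc <- data.frame(
    scenario = run$scenario$name,
    p0 = run$scenario$p0,
    p1 = run$scenario$p1,
    n_sims = run$n_sims,
    p_success = mean(r$stop),
    p_interim_stop = mean(r$interim_stop),
    mean_sample_size = mean(r$sample_size),
    p_flipflop = mean(r$flipflop),
    mean_final_or = mean(r$final_or, na.rm = TRUE),
    mean_final_lci = mean(r$final_lci, na.rm = TRUE),
    mean_final_uci = mean(r$final_uci, na.rm = TRUE),
    mean_final_p = mean(r$final_p),
    n_or_excluded = sum(is.na(r$final_or))
  )
  class(oc) <- c("trial_oc", "data.frame")
  oc
}

#' Operating characteristics over a scenario grid
#'
#' Runs an independent Monte-Carlo replication of the design for each
#' scenario and stacks the operating characteristics, one row per
#' scenario. Per-scenario master seeds are derived deterministically from
#' `seed`, so a single scenario's row equals a direct
#' [simulate_trials()] + [extract_oc()] call with that derived seed.
#'
#' @param design A [trial_design()].
#' @param scenarios List of [scenario()] objects with unique names.
#' @param n_sims Simulated trials per scenario.
#' @param seed Master seed for the whole grid.
#' @param log_every Progress logging interval passed through; 0 silences.
#' @return A `data.frame` of `trial_oc` rows keyed by scenario, with the
#'   derived per-scenario seed in column `scenario_seed`.
#' @examples
#' grid <- scenario_grid(trial_design(n = 60, events_at_interim = 5),
#'                       pims_scenarios(), n_sims = 10, seed = 1)
#' @export
scenario_grid <- function(design, scenarios, n_sims, seed, log_every = 0L) {
  validate_design(design)
  if (length(scenarios) < 1L) stop("need at least one scenario", call. = FALSE)
  nms <- vapply(scenarios, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop("duplicate scenario names", call. = FALSE)
  set.seed(as.integer(seed))
  scen_seeds <- sample.int(.Machine$integer.max, length(scenarios))
  rows <- lapply(seq_along(scenarios), function(i) {
    run <- simulate_trials(design, scenarios[[i]], n_sims,
                           seed = scen_seeds[i], log_every = log_every)
    cbind(extract_oc(run), scenario_seed = scen_seeds[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
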
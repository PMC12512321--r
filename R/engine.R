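#' Simulate and analyse a single trial
#'
#' Deterministic function of (design, scenario, seed): seeds the RNG, then
#' runs the full pipeline [simulate_trial_data()] (allocation, accrual,
#' outcomes) -> [select_interim()] -> [analyse_trial()].
#'
#' @param design A [trial_design()].
#' @param scenario A [scenario()].
#' @param seed Integer seed for this trial.
#' @return An object of class `trial_run`: list with the annotated `data`,
#'   the interim `selection`, the one-row `result` and the `seed` used.
#' @examples
#' tr <- run_trial(pims_design(), scenario("As powered", 0.10, 0.04), seed = 42)
#' tr
#' @export
run_trial <- function(design, scenario, seed) {
  validate_design(design)
  set.seed(as.integer(seed))
  data <- simulate_trial_data(design, scenario)
  sel <- select_interim(data, design$events_at_interim)
  result <- analyse_trial(sel$data, sel$selection, design)
  structure(
    list(data = sel$data, selection = sel$selection, result = result,
         seed = as.integer(seed), design = design, scenario = scenario),
    class = "trial_run"
  )
}

#' @export
print.trial_run <- function(x, ...) {
  r <- x$result
  cat(sprintf("Simulated trial under scenario '%s' (seed %d)\n",
              x$scenario$name, x$seed))
  cat(sprintf("  events (control/treatment): %d / %d\n",
              r$nevents0, r$nevents1))
  if (!is.na(r$interim_p))
    cat(sprintf("  interim: day %.0f, OR %.2f, p = %.3g, stop = %d\n",
                r$interim_time, r$interim_or, r$interim_p, r$interim_stop))
  else
    cat("  interim: trigger not reached\n")
  cat(sprintf("  final:   OR %.2f (%.2f, %.2f), p = %.3g, stop = %d\n",
              r$final_or, r$final_lci, r$final_uci, r$final_p,
              r$final_stop))
  cat(sprintf("  conclusive = %d, flip-flop = %d, sample size = %d\n",
              r$stop, r$flipflop, r$sample_size))
  invisible(x)
}

#' Monte-Carlo replication of a trial design
#'
#' Runs `n_sims` independent simulated trials of a design under one
#' scenario and collects the per-trial result rows. Per-trial seeds are
#' derived deterministically from the master seed (a seeded
#' `sample.int()` draw), so any single trial can be replayed in isolation
#' with [run_trial()] and results are independent of execution order.
#'
#' @param design A [trial_design()].
#' @param scenario A [scenario()].
#' @param n_sims Number of simulated trials (>= 1).
#' @param seed Master seed.
#' @param persist Optional directory: when given, `results.csv` and a
#'   `run_manifest.yaml` are written there (and each trial's dataset as
#'   `trial_<i>.csv` when `persist_datasets` is `TRUE`).
#' @param persist_datasets Write every simulated dataset (can be large).
#' @param log_every Progress message to standard error every so many
#'   trials; `0` silences logging. Default 500.
#' @return An object of class `trial_sims`: list with `results` (one row
#'   per trial: `simno`, `seed`, then the 18 result columns), `seeds`,
#'   `n_sims`, and echoes of `design`, `scenario` and the master `seed`.
#' @examples
#' sims <- simulate_trials(pims_design(), scenario("Null", 0.1, 0.1),
#'                         n_sims = 20, seed = 1, log_every = 0)
#' summary(sims)
#' @export
simulate_trials <- function(design, scenario, n_sims, seed,
                            persist = NULL, persist_datasets = FALSE,
                            log_every = 500L) {
  validate_design(design)
  n_sims <- as.integer(n_sims)
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  if (!is.null(persist)) {
    dir.create(persist, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(persist) || file.access(persist, 2L) != 0L)
      stop("persist path is not a writable directory", call. = FALSE)
  }

  set.seed(as.integer(seed))
  trial_seeds <- sample.int(.Machine$integer.max, n_sims)

  rows <- vector("list", n_sims)
  for (i in seq_len(n_sims)) {
    tr <- run_trial(design, scenario, trial_seeds[i])
    rows[[i]] <- tr$result
    if (!is.null(persist) && persist_datasets)
      write_trial_data(tr$data, file.path(persist, sprintf("trial_%d.csv", i)))
    if (log_every > 0L && i %% log_every == 0L)
      message(sprintf("  simulated %d / %d trials", i, n_sims))
  }
  results <- do.call(rbind, rows)
  class(results) <- "data.frame"
  results <- cbind(simno = seq_len(n_sims), seed = trial_seeds, results)

  run <- structure(
    list(results = results, seeds = trial_seeds, n_sims = n_sims,
         design = design, scenario = scenario, seed = as.integer(seed)),
    class = "trial_sims"
  )
  if (!is.null(persist)) {
    utils::write.csv(results, file.path(persist, "results.csv"),
                     row.names = FALSE, na = "")
    write_manifest(run, file.path(persist, "run_manifest.yaml"))
  }
  run
}

#' @export
print.trial_sims <- function(x, ...) {
  oc <- extract_oc(x)
  cat(sprintf("Monte-Carlo run: %d simulated trials, scenario '%s' (p0 = %g, p1 = %g)\n",
              x$n_sims, x$scenario$name, x$scenario$p0, x$scenario$p1))
  cat(sprintf("  P(conclusive)        : %.4f\n", oc$p_success))
  cat(sprintf("  P(stop at interim)   : %.4f\n", oc$p_interim_stop))
  cat(sprintf("  P(flip-flop)         : %.4f\n", oc$p_flipflop))
  cat(sprintf("  mean sample size     : %.1f (max %d)\n",
              oc$mean_sample_size, x$design$n))
  cat(sprintf("  mean final OR        : %.3f (%.3f, %.3f)\n",
              oc$mean_final_or, oc$mean_final_lci, oc$mean_final_uci))
  invisible(x)
}

#' @export
summary.trial_sims <- function(object, ...) {
  out <- list(
    scenario = object$scenario,
    n_sims = object$n_sims,
    table = summarise_run(object),
    oc = extract_oc(object)
  )
  class(out) <- "summary.trial_sims"
  out
}

#' @export
print.summary.trial_sims <- function(x, ...) {
  cat(sprintf("Summary of %d simulated trials, scenario '%s'\n\n",
              x$n_sims, x$scenario$name))
  tbl <- x$table
  num <- vapply(tbl, is.numeric, TRUE)
  tbl[num] <- lapply(tbl[num], round, 3)
  print.data.frame(tbl, row.names = FALSE)
  cat("\nOperating characteristics:\n")
  print.data.frame(round_df(as.data.frame(x$oc), 4), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  df
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a Monte-Carlo run bit-for-bit
#' with the same package version: the design parameters, scenario,
#' number of simulations, master seed and package version.
#'
#' @param run A `trial_sims` object.
#' @param path Output file (YAML).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(run, path) {
  manifest <- list(
    package = "adaptsim",
    version = as.character(utils::packageVersion("adaptsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    design = unclass(run$design),
    scenario = unclass(run$scenario),
    n_sims = run$n_sims,
    master_seed = run$seed
  )
  yaml::write_yaml(manifest, path)
  invisible(path)
}
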
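#' Simulate a complete trial dataset
#'
#' Composes the randomisation list, accrual times and binomial outcome
#' generation into one per-participant table. Rows are ordered by accrual
#' time; participant `obs_no` is the rank in that order, so the i-th
#' recruited participant receives the i-th entry of the allocation list.
#' Each outcome is an independent Bernoulli draw with probability
#' `scenario$p0` in the control arm and `scenario$p1` in the treatment
#' arm, available immediately at accrual (zero outcome lag).
#'
#' The three random components are consumed from the current RNG stream in
#' a fixed order — allocation permutations, then accrual times, then
#' outcomes — so a single seed fully determines the dataset.
#'
#' @param design A [trial_design()].
#' @param scenario A [scenario()].
#' @return A `data.frame` with columns `obs_no` (1..n), `trt` (0 control /
#'   1 treatment), `accrual_time` (days, sorted ascending) and `event`
#'   (0/1 primary-outcome indicator).
#' @examples
#' set.seed(7)
#' head(simulate_trial_data(pims_design(), scenario("As powered", 0.10, 0.04)))
#' @export
simulate_trial_data <- function(design, scenario) {
  validate_design(design)
  stopifnot(inherits(scenario, "trial_scenario") ||
              all(c("p0", "p1") %in% names(scenario)))
  trt <- simulate_randomisation(design)
  accrual_time <- simulate_accrual(design)
  p <- c(scenario$p0, scenario$p1)
  event <- stats::rbinom(design$n, 1L, p[trt + 1L])
  data.frame(
    obs_no = seq_len(design$n),
    trt = trt,
    accrual_time = accrual_time,
    event = event
  )
}

#' Read and write trial datasets
#'
#' Trial datasets travel as delimited text with header
#' `obs_no,trt,accrual_time,event` plus, when present, the interim
#' annotation columns `cum_events,interim_flag,event_interim`
#' (`event_interim` is empty for participants recruited after the interim
#' cut).
#'
#' @param data A trial `data.frame` as returned by [simulate_trial_data()]
#'   (optionally annotated by [select_interim()]).
#' @param path File path.
#' @return `read_trial_data()` returns the data.frame; `write_trial_data()`
#'   returns `path` invisibly.
#' @export
write_trial_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("obs_no", "trt", "accrual_time", "event")
  if (!all(need %in% names(df)))
    stop("trial data file must have columns obs_no,trt,accrual_time,event",
         call. = FALSE)
  if ("interim_flag" %in% names(df))
    df$interim_flag <- as.logical(df$interim_flag)
  df
}
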
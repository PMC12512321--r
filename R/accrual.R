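#' Simulate participant accrual times
#'
#' Recruitment is assumed constant over the recruitment period: the `n`
#' accrual times are the order statistics of independent
#' Uniform(0, `recruit_period`) draws, in days since trial start.
#'
#' Non-uniform accrual patterns (site ramp-up/ramp-down) can be plugged in
#' through the `generator` hook, which must return `n` unsorted times in
#' `[0, recruit_period]`; only the uniform generator is provided.
#'
#' @param design A [trial_design()].
#' @param generator Function `(n, recruit_period)` returning `n` raw
#'   (unsorted) accrual times. Defaults to uniform accrual.
#' @return Numeric vector of `design$n` non-decreasing times in
#'   `[0, recruit_period]`.
#' @examples
#' set.seed(1)
#' head(simulate_accrual(pims_design()))
#' @export
simulate_accrual <- function(design,
                             generator = function(n, recruit_period)
                               stats::runif(n, 0, recruit_period)) {
  validate_design(design)
  times <- generator(design$n, design$recruit_period)
  if (length(times) != design$n)
    stop("accrual generator returned wrong length", call. = FALSE)
  if (any(times < 0 | times > design$recruit_period))
    stop("accrual times outside [0, recruit_period]", call. = FALSE)
  sort(times)
}
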
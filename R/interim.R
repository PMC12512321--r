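#' Identify the dataset available at the event-triggered interim analysis
#'
#' Computes the running event total over participants in accrual order and
#' locates the participant at whom the `events_at_interim`-th event
#' accrues: that participant's `obs_no` is the interim index and their
#' accrual time the interim calendar time. All participants up to and
#' including the triggering one form the interim dataset; because outcomes
#' are available immediately, their interim outcome equals their final
#' outcome. If the trial never accumulates enough events the interim is
#' never reached and no rows are marked.
#'
#' @param data A trial `data.frame` ordered by accrual time
#'   ([simulate_trial_data()]).
#' @param events_at_interim Positive integer event trigger.
#' @return A list with components
#'   \describe{
#'     \item{data}{`data` with added columns `cum_events` (prefix sum of
#'       `event`), `interim_flag` (row in interim dataset) and
#'       `event_interim` (outcome for interim rows, `NA` otherwise).}
#'     \item{selection}{object of class `interim_selection`: `reached`
#'       (logical), `interim_ind` (obs_no of the triggering participant,
#'       `NA` if unreached) and `interim_time` (days, `NA` if unreached).}
#'   }
#' @examples
#' d <- data.frame(obs_no = 1:10, trt = rep(0:1, 5),
#'                 accrual_time = 1:10,
#'                 event = c(0, 1, 0, 1, 1, 0, 1, 0, 1, 1))
#' select_interim(d, 4)$selection
#' @export
select_interim <- function(data, events_at_interim) {
  if (nrow(data) == 0L)
    stop("empty trial dataset", call. = FALSE)
  events_at_interim <- as.integer(events_at_interim)
  if (events_at_interim < 1L)
    stop("events_at_interim must be >= 1", call. = FALSE)
  if (is.unsorted(data$accrual_time))
    stop("trial data must be ordered by accrual time", call. = FALSE)

  cum_events <- cumsum(data$event)
  reached <- cum_events[length(cum_events)] >= events_at_interim
  if (reached) {
    interim_ind <- match(events_at_interim, cum_events)
    interim_time <- data$accrual_time[interim_ind]
    flag <- data$obs_no <= data$obs_no[interim_ind]
  } else {
    interim_ind <- NA_integer_
    interim_time <- NA_real_
    flag <- rep(FALSE, nrow(data))
  }

  data$cum_events <- cum_events
  data$interim_flag <- flag
  data$event_interim <- ifelse(flag, data$event, NA_integer_)

  selection <- structure(
    list(reached = reached, interim_ind = interim_ind,
         interim_time = interim_time,
         events_at_interim = events_at_interim),
    class = "interim_selection"
  )
  list(data = data, selection = selection)
}

#' @export
print.interim_selection <- function(x, ...) {
  if (x$reached) {
    cat(sprintf(
      "Interim triggered by event %d at participant %d (day %.1f)\n",
      x$events_at_interim, x$interim_ind, x$interim_time))
  } else {
    cat(sprintf("Interim trigger of %d events never reached\n",
                x$events_at_interim))
  }
  invisible(x)
}
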
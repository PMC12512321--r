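#' 2x2 treatment-by-outcome table
#'
#' Sufficient statistic for the logistic regression of a binary outcome on
#' a binary treatment indicator: `a` events and `b` non-events in the
#' treatment arm, `c` events and `d` non-events in the control arm.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `two_by_two`.
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

#' Tabulate a trial dataset into a 2x2 table
#'
#' @param trt 0/1 treatment indicators.
#' @param event 0/1 outcomes, same length.
#' @return A [two_by_two()] table.
#' @export
two_by_two_from_data <- function(trt, event) {
  two_by_two(
    a = sum(event == 1L & trt == 1L),
    b = sum(event == 0L & trt == 1L),
    c = sum(event == 1L & trt == 0L),
    d = sum(event == 0L & trt == 0L)
  )
}

#' Wald logistic-regression inference on a 2x2 table
#'
#' For a logistic regression of outcome on a single binary treatment
#' indicator the maximum-likelihood fit is closed-form: the log odds ratio
#' is \eqn{\log(ad/bc)} with Wald standard error
#' \eqn{\sqrt{1/a + 1/b + 1/c + 1/d}}. The two-sided p-value comes from
#' the standard-normal Wald z statistic and the confidence interval is
#' \eqn{\exp(\log OR \pm z_{(1+level)/2} \cdot SE)} — identical to the
#' `summary()` of a `glm(..., family = binomial)` fit of the expanded
#' per-participant data.
#'
#' A table with any zero cell is separated (or empty in one outcome
#' category): the Wald statistic degenerates, so the estimate is flagged
#' `degenerate`, the p-value set to 1, and no finite odds ratio or
#' interval is reported. An entirely empty arm is an error.
#'
#' @param table A [two_by_two()] table.
#' @param ci_level Confidence level in (0, 1); default 0.95.
#' @return An object of class `effect_estimate` with components
#'   `odds_ratio`, `lci`, `uci`, `p_value` and `degenerate`.
#' @examples
#' fit_binary_logistic(two_by_two(12, 280, 30, 262))
#' @export
fit_binary_logistic <- function(table, ci_level = 0.95) {
  stopifnot(inherits(table, "two_by_two"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  if (a + b == 0L || cc + d == 0L)
    stop("empty arm: analysis impossible", call. = FALSE)
  if (min(a, b, cc, d) == 0L) {
    est <- list(odds_ratio = NA_real_, lci = NA_real_, uci = NA_real_,
                p_value = 1, degenerate = TRUE)
    return(structure(est, class = "effect_estimate"))
  }
  log_or <- log((a * d) / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- log_or / se
  zq <- stats::qnorm((1 + ci_level) / 2)
  structure(
    list(
      odds_ratio = exp(log_or),
      lci = exp(log_or - zq * se),
      uci = exp(log_or + zq * se),
      p_value = 2 * stats::pnorm(-abs(z)),
      degenerate = FALSE
    ),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  if (x$degenerate) {
    cat("Degenerate 2x2 table (zero cell): no finite odds ratio; p = 1\n")
  } else {
    cat(sprintf("OR %.3f (%.3f, %.3f), p = %.4g\n",
                x$odds_ratio, x$lci, x$uci, x$p_value))
  }
  invisible(x)
}

#' Apply the alpha-spending decision rules
#'
#' Efficacy is declared at the interim if the interim p-value is strictly
#' below `alpha_interim`, and at the final analysis if the final p-value
#' is strictly below `alpha_final`. A trial is conclusive (`stop = 1`) if
#' either threshold is met; it flip-flops (`flipflop = 1`) if the interim
#' threshold is met but the final one is not.
#'
#' @param interim An `effect_estimate` from the interim dataset, or `NULL`
#'   when the interim was never reached.
#' @param final An `effect_estimate` from the full dataset.
#' @param design A [trial_design()] holding the thresholds.
#' @return Named integer vector `interim_stop`, `final_stop`, `stop`,
#'   `flipflop` (each 0/1).
#' @export
evaluate_decisions <- function(interim, final, design) {
  stopifnot(inherits(final, "effect_estimate"))
  interim_stop <- if (!is.null(interim))
    as.integer(interim$p_value < design$alpha_interim) else 0L
  final_stop <- as.integer(final$p_value < design$alpha_final)
  c(
    interim_stop = interim_stop,
    final_stop = final_stop,
    stop = max(interim_stop, final_stop),
    flipflop = interim_stop * (1L - final_stop)
  )
}

# canonical column order of a per-trial result row
result_columns <- c(
  "nevents0", "nevents1", "pevents0", "pevents1", "sample_size",
  "interim_time", "interim_or", "interim_lci", "interim_uci", "interim_p",
  "interim_stop", "final_or", "final_lci", "final_uci", "final_p",
  "final_stop", "stop", "flipflop"
)

#' Analyse one simulated trial
#'
#' Fits the Wald logistic model on the interim dataset (when the interim
#' was reached) and on the full dataset, applies the decision thresholds,
#' and assembles the per-trial result row. Both analyses are always
#' computed — interim stopping is evaluated in post-processing — so the
#' flip-flop indicator is measurable for every trial. When the trial
#' stops at the interim, the event counts, proportions and sample size
#' describe the interim dataset; otherwise the full trial.
#'
#' @param data A trial `data.frame` annotated by [select_interim()].
#' @param selection The matching `interim_selection`.
#' @param design A [trial_design()].
#' @return One-row `data.frame` of class `trial_result` with columns
#'   `nevents0, nevents1, pevents0, pevents1, sample_size, interim_time,
#'   interim_or, interim_lci, interim_uci, interim_p, interim_stop,
#'   final_or, final_lci, final_uci, final_p, final_stop, stop, flipflop`.
#' @export
analyse_trial <- function(data, selection, design) {
  stopifnot(inherits(selection, "interim_selection"))
  validate_design(design)

  final_fit <- fit_binary_logistic(
    two_by_two_from_data(data$trt, data$event), design$ci_level)

  interim_fit <- NULL
  if (selection$reached) {
    rows <- data$interim_flag
    interim_fit <- fit_binary_logistic(
      two_by_two_from_data(data$trt[rows], data$event_interim[rows]),
      design$ci_level)
  }

  dec <- evaluate_decisions(interim_fit, final_fit, design)

  # counts reflect the interim dataset when the trial stopped early
  if (dec[["interim_stop"]] == 1L) {
    rows <- data$interim_flag
    trt <- data$trt[rows]; event <- data$event[rows]
    sample_size <- selection$interim_ind
  } else {
    trt <- data$trt; event <- data$event
    sample_size <- nrow(data)
  }
  n0 <- sum(trt == 0L); n1 <- sum(trt == 1L)
  nevents0 <- sum(event[trt == 0L]); nevents1 <- sum(event[trt == 1L])

  int_or <- if (is.null(interim_fit))
    list(odds_ratio = NA_real_, lci = NA_real_, uci = NA_real_,
         p_value = NA_real_) else interim_fit

  res <- data.frame(
    nevents0 = nevents0,
    nevents1 = nevents1,
    pevents0 = if (n0 > 0L) nevents0 / n0 else NA_real_,
    pevents1 = if (n1 > 0L) nevents1 / n1 else NA_real_,
    sample_size = sample_size,
    interim_time = selection$interim_time,
    interim_or = int_or$odds_ratio,
    interim_lci = int_or$lci,
    interim_uci = int_or$uci,
    interim_p = int_or$p_value,
    interim_stop = dec[["interim_stop"]],
    final_or = final_fit$odds_ratio,
    final_lci = final_fit$lci,
    final_uci = final_fit$uci,
    final_p = final_fit$p_value,
    final_stop = dec[["final_stop"]],
    stop = dec[["stop"]],
    flipflop = dec[["flipflop"]]
  )
  class(res) <- c("trial_result", "data.frame")
  res
}
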
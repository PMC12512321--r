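#' Two-proportion sample size (pooled-variance normal approximation)
#'
#' Per-arm sample size for detecting a difference between two independent
#' proportions with a two-sided Pearson chi-square test:
#' \deqn{n = \left\lceil \frac{\left(z_{1-\alpha/2}\sqrt{2\bar p \bar q}
#'   + z_{1-\beta}\sqrt{p_0 q_0 + p_1 q_1}\right)^2}
#'   {(p_0 - p_1)^2} \right\rceil}
#' with \eqn{\bar p = (p_0 + p_1)/2}, \eqn{q = 1 - p}. With
#' `continuity_correction` the Fleiss adjustment
#' \eqn{n' = (n/4)(1 + \sqrt{1 + 4/(n|p_0 - p_1|)})^2} is applied to the
#' real-valued solution before the ceiling. The pooled-variance form is
#' used because it matches the chi-square test; note that
#' `stats::power.prop.test()` uses an unpooled variance and gives a
#' slightly different n.
#'
#' @param p0,p1 True event probabilities in the two arms, both in (0, 1)
#'   and unequal.
#' @param alpha Two-sided significance level in (0, 1).
#' @param power Target power in (0, 1).
#' @param continuity_correction Apply the Fleiss continuity correction.
#' @return An object of class `samplesize_calc` with `n_per_arm`,
#'   `n_total` (= 2 per-arm) and an echo of the inputs.
#' @examples
#' two_proportion_n(0.10, 0.04, alpha = 0.045, power = 0.80)  # 292 per arm
#' @export
two_proportion_n <- function(p0, p1, alpha = 0.05, power = 0.80,
                             continuity_correction = FALSE) {
  if (!(p0 > 0 && p0 < 1) || !(p1 > 0 && p1 < 1))
    stop("probabilities must be in (0, 1)", call. = FALSE)
  if (p0 == p1)
    stop("p0 = p1: required sample size is infinite", call. = FALSE)
  if (!(alpha > 0 && alpha < 1) || !(power > 0 && power < 1))
    stop("alpha and power must be in (0, 1)", call. = FALSE)

  pbar <- (p0 + p1) / 2
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  n_real <- (za * sqrt(2 * pbar * (1 - pbar)) +
               zb * sqrt(p0 * (1 - p0) + p1 * (1 - p1)))^2 / (p0 - p1)^2
  if (continuity_correction)
    n_real <- (n_real / 4) * (1 + sqrt(1 + 4 / (n_real * abs(p0 - p1))))^2
  n_per_arm <- as.integer(ceiling(n_real))

  structure(
    list(n_per_arm = n_per_arm, n_total = 2L * n_per_arm,
         p0 = p0, p1 = p1, alpha = alpha, power = power,
         continuity_correction = continuity_correction),
    class = "samplesize_calc"
  )
}

#' @export
print.samplesize_calc <- function(x, ...) {
  cat("Two-proportion sample size (pooled variance",
      if (x$continuity_correction) ", Fleiss continuity correction)\n"
      else ")\n", sep = "")
  cat(sprintf("  p0 = %g, p1 = %g, two-sided alpha = %g, power = %g\n",
              x$p0, x$p1, x$alpha, x$power))
  cat(sprintf("  n per arm = %d, total n = %d\n", x$n_per_arm, x$n_total))
  invisible(x)
}

#' Odds ratio implied by two event probabilities
#'
#' Treatment-versus-control odds ratio
#' \eqn{\frac{p_1/(1-p_1)}{p_0/(1-p_0)}}.
#'
#' @param p0,p1 Probabilities strictly inside (0, 1).
#' @return A positive number.
#' @examples
#' odds_ratio_from_props(0.10, 0.04)  # 0.375
#' @export
odds_ratio_from_props <- function(p0, p1) {
  if (!(p0 > 0 && p0 < 1) || !(p1 > 0 && p1 < 1))
    stop("probabilities must be strictly inside (0, 1)", call. = FALSE)
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}
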
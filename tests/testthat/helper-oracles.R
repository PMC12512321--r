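# Independent oracles and small fixtures shared across test files.

# IRLS logistic-regression oracle for the 2x2 Wald inference: Newton /
# iteratively-reweighted-least-squares on the aggregated binomial
# log-likelihood, iterated to coefficient convergence (glm() stops on the
# deviance, which caps coefficient accuracy around 1e-7; near-extreme
# tables need better than that for p-value comparison).
glm_wald_oracle <- function(a, b, c, d, ci_level = 0.95) {
  X <- cbind(1, c(1, 1, 0, 0))
  y <- c(1, 0, 1, 0)
  w <- c(a, b, c, d)
  beta <- c(0, 0)
  for (iter in 1:60) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    W <- w * mu * (1 - mu)
    XtWX <- crossprod(X, W * X)
    score <- crossprod(X, w * (y - mu))
    delta <- solve(XtWX, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < 1e-13) break
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  vc <- solve(crossprod(X, (w * mu * (1 - mu)) * X))
  est <- beta[2]
  se <- sqrt(vc[2, 2])
  zq <- stats::qnorm((1 + ci_level) / 2)
  list(odds_ratio = exp(est),
       lci = exp(est - zq * se),
       uci = exp(est + zq * se),
       p_value = 2 * stats::pnorm(-abs(est / se)))
}

# draw a random non-degenerate 2x2 table (all cells >= 1)
random_table <- function(max_arm = 400L) {
  repeat {
    n1 <- sample(10:max_arm, 1L)
    n0 <- sample(10:max_arm, 1L)
    a <- stats::rbinom(1L, n1, stats::runif(1, 0.05, 0.95))
    cc <- stats::rbinom(1L, n0, stats::runif(1, 0.05, 0.95))
    if (a >= 1L && cc >= 1L && a < n1 && cc < n0)
      return(two_by_two(a, n1 - a, cc, n0 - cc))
  }
}

# exact power of the two-sided continuity-corrected (Yates) chi-square
# test for two independent proportions at equal per-arm size n, by full
# enumeration of the two binomial outcome counts
yates_exact_power <- function(n, p0, p1, alpha = 0.05) {
  x <- 0:n
  grid <- expand.grid(x1 = x, x0 = x)
  a <- grid$x1; cc <- grid$x0
  N <- 2 * n
  num <- N * pmax(abs(a * (n - cc) - cc * (n - a)) - N / 2, 0)^2
  den <- as.numeric(n) * n * (a + cc) * (N - a - cc)
  chi2 <- ifelse(den > 0, num / den, 0)
  rej <- stats::pchisq(chi2, df = 1, lower.tail = FALSE) < alpha
  sum(stats::dbinom(a, n, p1) * stats::dbinom(cc, n, p0) * rej)
}

# compact design for fast engine-level tests
small_design <- function(n = 60L, events_at_interim = 5L, ...) {
  trial_design(n = n, recruit_period = 100, events_at_interim = events_at_interim, ...)
}
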
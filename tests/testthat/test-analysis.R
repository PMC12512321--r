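test_that("symmetric tables give an odds ratio of exactly 1 and p = 1", {
  est <- fit_binary_logistic(two_by_two(10, 90, 10, 90))
  expect_equal(est$odds_ratio, 1)
  expect_equal(est$p_value, 1)
  expect_false(est$degenerate)
  expect_true(est$lci <= 1 && est$uci >= 1)
})

test_that("closed-form Wald inference matches the IRLS logistic oracle", {
  # the worked 584-participant table
  est <- fit_binary_logistic(two_by_two(12, 280, 30, 262))
  orc <- glm_wald_oracle(12, 280, 30, 262)
  expect_equal(est$odds_ratio, orc$odds_ratio, tolerance = 1e-6)
  expect_equal(est$lci, orc$lci, tolerance = 1e-6)
  expect_equal(est$uci, orc$uci, tolerance = 1e-6)
  expect_equal(est$p_value, orc$p_value, tolerance = 1e-6)

  set.seed(501)
  for (i in 1:200) {
    tab <- random_table()
    est <- fit_binary_logistic(tab)
    orc <- glm_wald_oracle(tab$a, tab$b, tab$c, tab$d)
    expect_equal(est$odds_ratio, orc$odds_ratio, tolerance = 1e-6)
    expect_equal(est$p_value, orc$p_value, tolerance = 1e-6)
    expect_equal(est$lci, orc$lci, tolerance = 1e-6)
    expect_equal(est$uci, orc$uci, tolerance = 1e-6)
    # the point estimate is the table cross-ratio exactly
    expect_equal(est$odds_ratio, (tab$a / tab$b) / (tab$c / tab$d))
  }
})

test_that("zero cells degenerate to p = 1 and empty arms error", {
  est <- fit_binary_logistic(two_by_two(0, 100, 10, 90))
  expect_true(est$degenerate)
  expect_equal(est$p_value, 1)
  expect_true(is.na(est$odds_ratio))
  expect_error(fit_binary_logistic(two_by_two(0, 0, 10, 90)), "empty arm")
  expect_error(two_by_two(-1, 5, 5, 5), "non-negative")
})

test_that("swapping arm labels inverts the odds ratio and preserves the p-value", {
  set.seed(502)
  for (i in 1:25) {
    tab <- random_table()
    est <- fit_binary_logistic(tab)
    swp <- fit_binary_logistic(two_by_two(tab$c, tab$d, tab$a, tab$b))
    expect_equal(est$odds_ratio * swp$odds_ratio, 1, tolerance = 1e-12)
    expect_equal(est$p_value, swp$p_value, tolerance = 1e-12)
    expect_equal(est$lci, 1 / swp$uci, tolerance = 1e-12)
  }
})

test_that("decision rules implement strict thresholds and the flip-flop algebra", {
  d <- pims_design()
  ee <- function(p) structure(list(odds_ratio = 0.5, lci = 0.3, uci = 0.9,
                                   p_value = p, degenerate = FALSE),
                              class = "effect_estimate")
  expect_identical(evaluate_decisions(ee(0.001), ee(0.5), d),
                   c(interim_stop = 1L, final_stop = 0L, stop = 1L,
                     flipflop = 1L))
  expect_identical(evaluate_decisions(ee(0.5), ee(0.5), d),
                   c(interim_stop = 0L, final_stop = 0L, stop = 0L,
                     flipflop = 0L))
  expect_identical(evaluate_decisions(ee(0.5), ee(0.01), d)[["stop"]], 1L)
  # boundary: p equal to the threshold does not stop (strict comparison)
  expect_identical(evaluate_decisions(ee(0.005), ee(0.045), d),
                   c(interim_stop = 0L, final_stop = 0L, stop = 0L,
                     flipflop = 0L))
  # absent interim (trigger unreached): only the final analysis counts
  expect_identical(evaluate_decisions(NULL, ee(0.01), d)[["interim_stop"]], 0L)
})

test_that("the per-trial result row respects the stopping-rule bookkeeping", {
  set.seed(503)
  d <- pims_design()
  # deterministic check across a batch of simulated trials
  for (i in 1:30) {
    sc <- scenario("x", 0.10, sample(c(0.03, 0.04, 0.10), 1))
    tr <- run_trial(d, sc, seed = i)
    r <- tr$result
    expect_identical(names(r), adaptsim:::result_columns)
    expect_identical(r$stop, max(r$interim_stop, r$final_stop))
    expect_identical(r$flipflop, r$interim_stop * (1L - r$final_stop))
    if (r$interim_stop == 1L) {
      expect_identical(r$sample_size, tr$selection$interim_ind)
      expect_lt(r$sample_size, d$n)
      rows <- tr$data$interim_flag
      expect_identical(r$nevents0,
                       sum(tr$data$event[rows & tr$data$trt == 0L]))
    } else {
      expect_identical(r$sample_size, d$n)
      expect_identical(r$nevents0 + r$nevents1, sum(tr$data$event))
      expect_equal(r$pevents0, r$nevents0 / 292)
    }
  }
})
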
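fake_run <- function(results, scen = scenario("fake", 0.1, 0.1)) {
  structure(list(results = results, seeds = seq_len(nrow(results)),
                 n_sims = nrow(results), design = pims_design(),
                 scenario = scen, seed = 1L),
            class = "trial_sims")
}

blank_results <- function(n) {
  res <- as.data.frame(
    setNames(rep(list(rep(0, n)), length(adaptsim:::result_columns)),
             adaptsim:::result_columns))
  cbind(simno = seq_len(n), seed = seq_len(n), res)
}

test_that("six-number summaries follow the linear-interpolation quantile rule", {
  res <- blank_results(5)
  res$sample_size <- c(1, 2, 3, 4, 5)
  res$interim_or <- c(NA, NA, 2, 2, 2)
  tbl <- summarise_run(fake_run(res))
  expect_identical(tbl$variable, adaptsim:::result_columns)
  row <- tbl[tbl$variable == "sample_size", ]
  expect_equal(unlist(row[c("minimum", "q1", "median", "mean", "q3",
                            "maximum")], use.names = FALSE),
               c(1, 2, 3, 3, 4, 5))
  # constant columns collapse to a single value across all six statistics
  cst <- tbl[tbl$variable == "final_stop", ]
  expect_true(all(cst[, 2:7] == 0))
  # absent values are excluded and counted, never silently dropped
  orr <- tbl[tbl$variable == "interim_or", ]
  expect_identical(orr$n_missing, 2L)
  expect_equal(orr$mean, 2)
  expect_true(all(tbl$minimum <= tbl$q1 & tbl$q1 <= tbl$median &
                    tbl$median <= tbl$q3 & tbl$q3 <= tbl$maximum))
})

test_that("operating characteristics are the advertised means with exclusions reported", {
  res <- blank_results(4)
  res$stop <- c(1, 1, 0, 0)
  res$interim_stop <- c(1, 0, 0, 0)
  res$flipflop <- c(0, 0, 0, 0)
  res$sample_size <- c(200, 584, 584, 584)
  res$final_or <- c(0.4, 0.5, NA, 0.6)   # one degenerate fit
  res$final_lci <- res$final_or / 2
  res$final_uci <- c(0.8, 1.0, NA, 1.2)
  res$final_p <- c(0.01, 0.02, 1, 0.2)
  oc <- extract_oc(fake_run(res))
  expect_equal(oc$p_success, 0.5)
  expect_equal(oc$p_interim_stop, 0.25)
  expect_equal(oc$mean_sample_size, 488)
  expect_equal(oc$mean_final_or, 0.5)
  expect_identical(oc$n_or_excluded, 1L)
  expect_true(oc$p_flipflop <= oc$p_interim_stop)
  expect_true(oc$mean_sample_size <= oc$n_sims * 584)
})

test_that("operating-characteristic invariants hold on a real run", {
  run <- simulate_trials(small_design(n = 80L, events_at_interim = 6L),
                         scenario("x", 0.25, 0.1), n_sims = 60, seed = 5,
                         log_every = 0)
  oc <- extract_oc(run)
  probs <- unlist(oc[c("p_success", "p_interim_stop", "p_flipflop")])
  expect_true(all(probs >= 0 & probs <= 1))
  expect_lte(oc$p_flipflop, oc$p_interim_stop)
  expect_lte(oc$mean_sample_size, 80)
  s <- summary(run)
  expect_s3_class(s, "summary.trial_sims")
  expect_output(print(s), "Operating characteristics")
})

test_that("a single-scenario grid equals the composed run, and duplicates error", {
  d <- small_design(n = 60L, events_at_interim = 5L)
  sc <- scenario("only", 0.3, 0.1)
  grid <- scenario_grid(d, list(sc), n_sims = 25, seed = 7)
  set.seed(7)
  derived <- sample.int(.Machine$integer.max, 1)
  direct <- extract_oc(simulate_trials(d, sc, 25, seed = derived,
                                       log_every = 0))
  expect_equal(grid[, names(direct)], direct, ignore_attr = TRUE)
  expect_error(scenario_grid(d, list(sc, sc), 5, 1), "duplicate")
  expect_error(scenario_grid(d, list(), 5, 1), "at least one")
})
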
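#' Trial design parameters
#'
#' Collects all fixed design inputs of a two-arm adaptive trial with a
#' single event-triggered interim analysis: the maximum sample size, the
#' recruitment period, the permuted-block randomisation structure, the
#' cumulative event count that triggers the interim look, and the fixed
#' alpha-spending decision thresholds applied at the interim and final
#' analyses.
#'
#' @param n Maximum trial sample size (positive integer).
#' @param recruit_period Recruitment duration in days (positive).
#' @param events_at_interim Cumulative number of primary-outcome events
#'   that triggers the interim analysis; must be at least 1 and strictly
#'   less than `n`.
#' @param alpha_interim Two-sided efficacy threshold applied to the interim
#'   p-value, in (0, 1).
#' @param alpha_final Two-sided efficacy threshold applied to the final
#'   p-value, in (0, 1).
#' @param block_size Randomisation block length (positive even integer).
#' @param allocation Integer vector of length 2: participants allocated to
#'   (control, treatment) within each block; must sum to `block_size`.
#' @param ci_level Confidence level for interval estimates (default 0.95).
#'
#' @return An object of class `trial_design`: a validated list with the
#'   above components.
#' @seealso [pims_design()] for the worked-example defaults,
#'   [validate_design()] for the invariant checks.
#' @examples
#' d <- trial_design(n = 100, recruit_period = 365, events_at_interim = 10)
#' d
#' @export
trial_design <- function(n = 584L,
                         recruit_period = 928,
                         events_at_interim = 20L,
                         alpha_interim = 0.005,
                         alpha_final = 0.045,
                         block_size = 4L,
                         allocation = c(2L, 2L),
                         ci_level = 0.95) {
  design <- structure(
    list(
      n = as.integer(n),
      recruit_period = as.numeric(recruit_period),
      events_at_interim = as.integer(events_at_interim),
      alpha_interim = as.numeric(alpha_interim),
      alpha_final = as.numeric(alpha_final),
      block_size = as.integer(block_size),
      allocation = as.integer(allocation),
      ci_level = as.numeric(ci_level)
    ),
    class = "trial_design"
  )
  validate_design(design)
}

#' Validate trial design parameters
#'
#' Checks every invariant of a [trial_design()] object and stops with the
#' name of the first violated one.
#'
#' @param design A `trial_design` object (or bare list with its fields).
#' @return `design`, unchanged, invisibly classed as `trial_design`.
#' @export
validate_design <- function(design) {
  stopifnot(is.list(design))
  with(design, {
    if (length(n) != 1L || is.na(n) || n < 1L)
      stop("n must be a positive integer", call. = FALSE)
    if (length(recruit_period) != 1L || is.na(recruit_period) ||
        recruit_period <= 0)
      stop("recruit_period must be positive", call. = FALSE)
    if (length(events_at_interim) != 1L || is.na(events_at_interim) ||
        events_at_interim < 1L)
      stop("events_at_interim must be >= 1", call. = FALSE)
    if (events_at_interim >= n)
      stop("interim trigger must be < n", call. = FALSE)
    if (!(alpha_interim > 0 && alpha_interim < 1))
      stop("alpha_interim must be in (0, 1)", call. = FALSE)
    if (!(alpha_final > 0 && alpha_final < 1))
      stop("alpha_final must be in (0, 1)", call. = FALSE)
    if (length(block_size) != 1L || is.na(block_size) || block_size < 2L ||
        block_size %% 2L != 0L)
      stop("block_size must be a positive even integer", call. = FALSE)
    if (length(allocation) != 2L || any(is.na(allocation)) ||
        any(allocation < 0L))
      stop("allocation must be two non-negative counts", call. = FALSE)
    if (sum(allocation) != block_size)
      stop("allocation must sum to block_size", call. = FALSE)
    if (!(ci_level > 0 && ci_level < 1))
      stop("ci_level must be in (0, 1)", call. = FALSE)
  })
  invisible(structure(design, class = "trial_design"))
}

#' @export
print.trial_design <- function(x, ...) {
  cat("Two-arm adaptive trial design\n")
  cat(sprintf("  maximum sample size : %d\n", x$n))
  cat(sprintf("  recruitment period  : %g days\n", x$recruit_period))
  cat(sprintf("  randomisation       : permuted blocks of %d, allocation %d:%d\n",
              x$block_size, x$allocation[1], x$allocation[2]))
  cat(sprintf("  interim trigger     : %d events\n", x$events_at_interim))
  cat(sprintf("  efficacy thresholds : p < %g (interim), p < %g (final)\n",
              x$alpha_interim, x$alpha_final))
  cat(sprintf("  confidence level    : %g%%\n", 100 * x$ci_level))
  invisible(x)
}

#' Design defaults of the PIMS worked example
#'
#' The PIMS trial (intravenous fluids in children; binary primary outcome
#' hyponatraemia) re-designed with a single interim analysis: n = 584
#' participants (292 per arm), uniform recruitment over 928 days, 1:1
#' permuted-block randomisation with blocks of 4, interim analysis
#' triggered at 20 events, efficacy thresholds 0.005 (interim) and 0.045
#' (final), 95% confidence intervals.
#'
#' @return A `trial_design` object.
#' @examples
#' pims_design()
#' @export
pims_design <- function() trial_design()

#' Scenario: a named pair of true event probabilities
#'
#' @param name Short, non-empty label.
#' @param p0 Control-arm event probability in \[0, 1\].
#' @param p1 Treatment-arm event probability in \[0, 1\].
#' @return An object of class `trial_scenario`.
#' @examples
#' scenario("As powered", 0.10, 0.04)
#' @export
scenario <- function(name, p0, p1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("scenario name must be a non-empty string", call. = FALSE)
  if (!(p0 >= 0 && p0 <= 1) || !(p1 >= 0 && p1 <= 1))
    stop("event probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(name = name, p0 = as.numeric(p0), p1 = as.numeric(p1)),
            class = "trial_scenario")
}

#' @export
print.trial_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s': p0 = %g (control), p1 = %g (treatment)\n",
              x$name, x$p0, x$p1))
  invisible(x)
}

#' The four PIMS simulation scenarios
#'
#' Null (0.10, 0.10), As powered (0.10, 0.04), Smaller difference
#' (0.10, 0.06) and Larger difference (0.10, 0.03).
#'
#' @return A named list of `trial_scenario` objects.
#' @export
pims_scenarios <- function() {
  scens <- list(
    scenario("Null", 0.10, 0.10),
    scenario("As powered", 0.10, 0.04),
    scenario("Smaller difference", 0.10, 0.06),
    scenario("Larger difference", 0.10, 0.03)
  )
  names(scens) <- vapply(scens, `[[`, "", "name")
  scens
}

#' Read and write scenario files
#'
#' Scenario sets are exchanged as delimited text with header `name,p0,p1`,
#' one row per scenario. Names must be unique.
#'
#' @param path File path.
#' @return `read_scenarios()` returns a named list of `trial_scenario`
#'   objects; `write_scenarios()` returns `path` invisibly.
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("name", "p0", "p1") %in% names(df)))
    stop("scenario file must have columns name,p0,p1", call. = FALSE)
  if (anyDuplicated(df$name))
    stop("scenario names must be unique", call. = FALSE)
  scens <- lapply(seq_len(nrow(df)),
                  function(i) scenario(df$name[i], df$p0[i], df$p1[i]))
  names(scens) <- df$name
  scens
}

#' @rdname read_scenarios
#' @param scenarios A list of `trial_scenario` objects.
#' @export
write_scenarios <- function(scenarios, path) {
  df <- data.frame(
    name = vapply(scenarios, `[[`, "", "name"),
    p0 = vapply(scenarios, `[[`, 0, "p0"),
    p1 = vapply(scenarios, `[[`, 0, "p1")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read design parameters from a flat key-value config file
#'
#' The config is flat YAML whose keys mirror the [trial_design()] argument
#' names exactly; missing keys take the PIMS defaults. `allocation` is a
#' two-element sequence.
#'
#' @param path Path to the YAML config file.
#' @return A validated `trial_design`.
#' @export
read_design_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(trial_design))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  do.call(trial_design, cfg)
}
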
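#' Permuted-block randomisation sequence
#'
#' Generates the sequential treatment-allocation list for `n` consecutively
#' recruited participants by permuted-block randomisation: whole blocks of
#' `block_size` are built with the per-arm counts given by
#' `design$allocation` and independently permuted, uniformly at random,
#' within each block. When `n` is not a multiple of the block size the
#' final block is a freshly permuted block truncated to length.
#'
#' Arms are coded 0 for control and 1 for treatment. Draws come from the
#' current R random-number stream; seed the stream (or use [run_trial()])
#' for reproducibility.
#'
#' @param design A [trial_design()].
#' @return Integer vector of length `design$n` of 0/1 arm indicators;
#'   within every complete block each arm appears exactly its per-block
#'   count of times.
#' @examples
#' set.seed(1)
#' trt <- simulate_randomisation(trial_design(n = 12, events_at_interim = 2))
#' table(trt)  # 6 and 6
#' @export
simulate_randomisation <- function(design) {
  validate_design(design)
  n <- design$n
  bs <- design$block_size
  n_blocks <- ceiling(n / bs)
  template <- rep.int(rep.int(c(0L, 1L), design$allocation), n_blocks)
  block_id <- rep(seq_len(n_blocks), each = bs)
  # one uniform key per slot; ordering keys within a block is a uniform
  # random permutation of the block's template
  trt <- template[order(block_id, stats::runif(n_blocks * bs))]
  trt[seq_len(n)]
}
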
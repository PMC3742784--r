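#' Exact enumeration of stripe statistics on a clone ring
#'
#' Brute-force oracle for the run statistics that underlie the stripe-number
#' correction. For a ring of `K` stem-cell clones, each independently
#' marker-positive with probability `p`, all `2^K` labelings are enumerated
#' and weighted by their probability `p^k (1-p)^(K-k)`. For each labeling the
#' number of positive stripes is counted as the number of (negative to
#' positive) boundaries around the ring (the convention of
#' [count_positive_runs()]; a monochrome ring has 0 stripes).
#'
#' Exact identities (used as acceptance checks for the analytic formulas):
#' * `E[positive stripes] = K * p * (1 - p)`
#' * `E[positive clones] / E[positive stripes] = 1/(1 - p)` — the ratio of
#'   expectations matching [clones_per_patch()];
#' * `E[positive stripes] / (1 - p) = K * p` — [corrected_stripe_number()]
#'   recovers the expected number of labelled clones.
#'
#' @param K number of clones on the ring (2..20; cost is `O(K 2^K)`).
#' @param p labelling probability per clone, in `(0, 1)` (0 and 1 are
#'   permitted for the expectations, though the corrections are undefined
#'   there).
#' @return A list: `e_runs` (expected positive stripes), `e_pos_clones`
#'   (expected positive clones, `= K p`), `clones_per_patch`
#'   (`e_pos_clones / e_runs`), `e_corrected_stripes`
#'   (`e_runs / (1 - p)`), and `K`, `p`.
#' @examples
#' ring_run_enumeration(10, 0.5)$e_runs # 2.5
#' @export
ring_run_enumeration <- function(K, p) {
  assert_that(is_count(K, min = 2L) && K <= 20, "'K' must be an integer in 2..20")
  assert_that(is_prob(p), "'p' must be a proportion in [0, 1]")
  n_lab <- 2L^K
  ## bit matrix of all labelings, one row per labeling
  idx <- 0:(n_lab - 1L)
  bits <- matrix(FALSE, n_lab, K)
  for (j in seq_len(K)) {
    bits[, j] <- bitwAnd(idx, bitwShiftL(1L, j - 1L)) > 0L
  }
  prev <- bits[, c(K, seq_len(K - 1L)), drop = FALSE]
  runs <- rowSums(bits & !prev)
  npos <- rowSums(bits)
  w <- p^npos * (1 - p)^(K - npos)
  e_runs <- sum(w * runs)
  e_pos <- sum(w * npos)
  list(
    K = K, p = p,
    e_runs = e_runs,
    e_pos_clones = e_pos,
    clones_per_patch = if (e_runs > 0) e_pos / e_runs else NA_real_,
    e_corrected_stripes = if (p < 1) e_runs / (1 - p) else NA_real_
  )
}
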
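# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: run counting by explicit looping, enumeration by
# direct recursion over label vectors, and detection scoring by greedy
# nearest-centroid matching against generator ground truth.

# positive runs on a ring by walking the sequence cell by cell,
# counting (-,+) boundaries (monochrome-positive ring -> 0)
loop_ring_runs <- function(x) {
  n <- length(x)
  runs <- 0L
  for (i in seq_len(n)) {
    prev <- if (i == 1L) x[n] else x[i - 1L]
    if (x[i] && !prev) runs <- runs + 1L
  }
  runs
}

# exact expectations over all 2^K ring labelings by explicit recursion-free
# enumeration with per-labeling probability weights
enumerate_ring <- function(K, p) {
  e_runs <- 0
  e_pos <- 0
  for (i in 0:(2^K - 1L)) {
    x <- as.logical(bitwAnd(i, 2^(0:(K - 1L))) > 0L)
    k <- sum(x)
    w <- p^k * (1 - p)^(K - k)
    e_runs <- e_runs + w * loop_ring_runs(x)
    e_pos <- e_pos + w * k
  }
  list(e_runs = e_runs, e_pos = e_pos)
}

# greedy one-to-one matching of detections to ground-truth nuclei within
# half a nucleus diameter; returns TP / FP / FN
match_detections <- function(det, truth, max_dist_frac = 0.5) {
  if (nrow(truth) == 0L) {
    return(list(tp = 0L, fp = nrow(det), fn = 0L))
  }
  if (nrow(det) == 0L) {
    return(list(tp = 0L, fp = 0L, fn = nrow(truth)))
  }
  d <- sqrt(outer(det$x_um, truth$x_um, "-")^2 +
              outer(det$y_um, truth$y_um, "-")^2)
  used_det <- rep(FALSE, nrow(det))
  used_tr <- rep(FALSE, nrow(truth))
  tp <- 0L
  repeat {
    d2 <- d
    d2[used_det, ] <- Inf
    d2[, used_tr] <- Inf
    if (all(!is.finite(d2))) break
    ij <- arrayInd(which.min(d2), dim(d2))
    if (d2[ij] > truth$diameter_um[ij[2L]] * max_dist_frac) break
    used_det[ij[1L]] <- TRUE
    used_tr[ij[2L]] <- TRUE
    tp <- tp + 1L
  }
  list(tp = tp, fp = sum(!used_det), fn = sum(!used_tr))
}

# standard WT-like and fast-loss cohort parameter sets used in several tests
wt_like_params <- function(...) cohort_params(...)
fast_loss_params <- function(...) cohort_params(transfer_rate = 0.6, ...)
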
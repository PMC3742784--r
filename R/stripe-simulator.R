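#' Configuration for limbal clone-ring stripe simulations
#'
#' Describes one generative scenario for the ring of limbal epithelial stem
#' cell (LESC) clones whose marker states produce the radial stripe pattern
#' of the adult cornea:
#' * `K` — number of LESC clones on the ring;
#' * `p` — probability that a clone carries the marker;
#' * `mixing_clusters` — number of independent label draws. The ring is cut
#'   into `mixing_clusters` contiguous blocks and each block receives a
#'   single label draw, so `mixing_clusters = K` is full developmental cell
#'   mixing (every clone independent) and smaller values give the
#'   coarse-grained mosaics expected when mixing is reduced (adjacent clones
#'   share ancestry and hence marker state).
#'
#' Reduced clone number (small `K`, full mixing) and reduced mixing
#' (`mixing_clusters < K`) are the two competing explanations for a
#' fewer-wider-stripes phenotype; see [hypothesis_experiment()].
#'
#' @param K integer number of LESC clones (>= 2).
#' @param p labelled proportion in `[0, 1]`.
#' @param mixing_clusters integer in `1..K`.
#' @param replicates number of simulated rings.
#' @param seed integer seed.
#' @return An object of class `stripe_sim_config`.
#' @export
stripe_sim_config <- function(K, p, mixing_clusters = K, replicates = 1000L,
                              seed = NULL) {
  assert_that(is_count(K, min = 2L), "'K' must be an integer >= 2")
  assert_that(is_prob(p), "'p' must be a proportion in [0, 1]")
  assert_that(is_count(mixing_clusters) && mixing_clusters <= K,
              "'mixing_clusters' must be an integer in 1..K")
  assert_that(is_count(replicates), "'replicates' must be a positive integer")
  structure(list(K = as.integer(K), p = p,
                 mixing_clusters = as.integer(mixing_clusters),
                 replicates = as.integer(replicates), seed = seed),
            class = "stripe_sim_config")
}

block_sizes <- function(K, m) {
  base <- K %/% m
  extra <- K %% m
  sizes <- rep.int(base, m)
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

#' Simulate rings of LESC clone labels
#'
#' Draws `replicates` rings under a [stripe_sim_config()]: the `K`-clone ring
#' is divided into `mixing_clusters` contiguous blocks (sizes differing by at
#' most one) and each block's marker state is drawn once as positive with
#' probability `p`.
#'
#' @param config a [stripe_sim_config()].
#' @return An object of class `ring_ensemble`: the label matrix
#'   (`replicates` x `K`, logical), and the generating config. Use
#'   [stripe_pattern_stats()] to summarise, or [ring_sequences()] to extract
#'   individual [mosaic_sequence()] objects.
#' @examples
#' rs <- simulate_ring(stripe_sim_config(K = 10, p = 0.5, replicates = 100,
#'                                       seed = 1))
#' stripe_pattern_stats(rs)
#' @export
simulate_ring <- function(config) {
  assert_that(inherits(config, "stripe_sim_config"),
              "'config' must be a stripe_sim_config")
  with_seed(config$seed, {
    m <- config$mixing_clusters
    sizes <- block_sizes(config$K, m)
    blocks <- matrix(stats::rbinom(config$replicates * m, 1L, config$p) == 1L,
                     nrow = config$replicates, ncol = m)
    labels <- blocks[, rep.int(seq_len(m), sizes), drop = FALSE]
    structure(list(labels = labels, config = config), class = "ring_ensemble")
  })
}

#' @rdname simulate_ring
#' @param ensemble a `ring_ensemble`.
#' @param i replicate index (or indices).
#' @export
ring_sequences <- function(ensemble, i = seq_len(nrow(ensemble$labels))) {
  assert_that(inherits(ensemble, "ring_ensemble"),
              "'ensemble' must be a ring_ensemble")
  lapply(i, function(k) {
    mosaic_sequence(ensemble$labels[k, ], topology = "circular",
                    p = ensemble$config$p)
  })
}

#' Stripe-pattern summary statistics for a ring ensemble
#'
#' Counts positive stripes per replicate ring (boundary convention of
#' [count_positive_runs()]) and applies the `1/(1 - p)` adjacency correction.
#'
#' @param ensemble a `ring_ensemble` from [simulate_ring()].
#' @return An object of class `stripe_pattern_stats`:
#'   `mean_observed_stripes`, `mean_corrected_stripes`, `var_corrected`,
#'   `replicates`, plus the per-replicate counts in `observed`.
#' @export
stripe_pattern_stats <- function(ensemble) {
  assert_that(inherits(ensemble, "ring_ensemble"),
              "'ensemble' must be a ring_ensemble")
  M <- ensemble$labels
  K <- ncol(M)
  prev <- M[, c(K, seq_len(K - 1L)), drop = FALSE]
  observed <- rowSums(M & !prev)
  p <- ensemble$config$p
  corrected <- if (p > 0 && p < 1) observed / (1 - p) else rep(NA_real_, length(observed))
  structure(list(
    mean_observed_stripes = mean(observed),
    mean_corrected_stripes = mean(corrected),
    var_corrected = stats::var(corrected),
    replicates = length(observed),
    observed = observed,
    config = ensemble$config
  ), class = "stripe_pattern_stats")
}

#' @export
print.stripe_pattern_stats <- function(x, ...) {
  cat(sprintf(
    "<stripe_pattern_stats> K = %d, p = %.2f, mixing_clusters = %d, %d reps\n",
    x$config$K, x$config$p, x$config$mixing_clusters, x$replicates))
  cat(sprintf("  mean observed stripes:  %.3f\n", x$mean_observed_stripes))
  cat(sprintf("  mean corrected stripes: %.3f (var %.3f)\n",
              x$mean_corrected_stripes, x$var_corrected))
  invisible(x)
}

#' Contrast reduced clone number against reduced cell mixing
#'
#' Runs two stripe-simulation scenarios sharing the same labelled proportion
#' and replicate count — typically one with fewer clones at full mixing
#' (hypothesis 1) and one with the full clone complement but coarser label
#' blocks (hypothesis 2) — and computes, for each, (a) the stripe-pattern
#' statistics of the adult ring and (b) the *developmental* patch statistic
#' that discriminates the two: sections simulated with [generate_mosaic()]
#' before stripes emerge, whose corrected mean patch length estimates the
#' coherent clone length. Reduced mixing coarsens the developmental mosaic
#' (coherence factor `K / mixing_clusters` multiplies the clone length)
#' whereas a reduced clone number leaves it untouched, so scenarios matched
#' for expected stripe count separate on this statistic.
#'
#' @param config_a,config_b [stripe_sim_config()] objects sharing `p` and
#'   `replicates`.
#' @param dev_n_cells cells per simulated developmental section.
#' @param dev_clone_len baseline mean coherent clone length (cells) under
#'   full mixing.
#' @param seed integer seed for the whole experiment.
#' @return An object of class `hypothesis_experiment`: a `comparison` data
#'   frame (one row per scenario: K, mixing_clusters, mean observed and
#'   corrected stripes, mean developmental corrected mean patch length), the
#'   per-replicate developmental corrected-mean-patch-length vectors
#'   (`dev_cmpl_a`, `dev_cmpl_b`), and `ks_patch_distance`, the
#'   Kolmogorov-Smirnov distance between those two distributions.
#' @export
hypothesis_experiment <- function(config_a, config_b,
                                  dev_n_cells = 300L, dev_clone_len = 2,
                                  seed = NULL) {
  assert_that(inherits(config_a, "stripe_sim_config") &&
                inherits(config_b, "stripe_sim_config"),
              "both configs must be stripe_sim_config objects")
  assert_that(isTRUE(all.equal(config_a$p, config_b$p)),
              "configs must share the labelled proportion p")
  assert_that(config_a$replicates == config_b$replicates,
              "configs must share the replicate count")
  assert_that(is_count(dev_n_cells, min = 10L),
              "'dev_n_cells' must be an integer >= 10")
  assert_that(dev_clone_len >= 1, "'dev_clone_len' must be >= 1")

  run_one <- function(config, seed_offset) {
    cfg <- config
    cfg$seed <- child_seed(seed, seed_offset) %||% config$seed
    stats <- stripe_pattern_stats(simulate_ring(cfg))
    coherence <- config$K / config$mixing_clusters
    cmpl <- with_seed(child_seed(seed, seed_offset + 1L), {
      vapply(seq_len(config$replicates), function(r) {
        ms <- generate_mosaic(dev_n_cells, p = config$p,
                              clone_len_mean = dev_clone_len * coherence)
        corrected_mean_patch_length(extract_patches(ms))
      }, numeric(1))
    })
    list(stats = stats, cmpl = cmpl, coherence = coherence)
  }

  a <- run_one(config_a, 1L)
  b <- run_one(config_b, 3L)
  ks <- suppressWarnings(stats::ks.test(a$cmpl, b$cmpl))$statistic

  comparison <- data.frame(
    scenario = c("A", "B"),
    K = c(config_a$K, config_b$K),
    mixing_clusters = c(config_a$mixing_clusters, config_b$mixing_clusters),
    coherence = c(a$coherence, b$coherence),
    mean_observed_stripes = c(a$stats$mean_observed_stripes,
                              b$stats$mean_observed_stripes),
    mean_corrected_stripes = c(a$stats$mean_corrected_stripes,
                               b$stats$mean_corrected_stripes),
    mean_dev_corrected_patch_len = c(mean(a$cmpl), mean(b$cmpl))
  )
  structure(list(comparison = comparison,
                 dev_cmpl_a = a$cmpl, dev_cmpl_b = b$cmpl,
                 ks_patch_distance = unname(ks),
                 stats_a = a$stats, stats_b = b$stats),
            class = "hypothesis_experiment")
}

#' @export
print.hypothesis_experiment <- function(x, ...) {
  cat("<hypothesis_experiment>\n")
  print(x$comparison, row.names = FALSE)
  cat(sprintf("KS distance (developmental corrected mean patch length): %.3f\n",
              x$ks_patch_distance))
  invisible(x)
}

#' Neutral drift of clone labels on the limbal ring
#'
#' Moran-type neutral competition among LESC clones: at each step one
#' uniformly chosen ring position is replaced by a copy of a random
#' neighbour (left or right); one generation is `K` steps. Clonal labels
#' coalesce over time, so the expected corrected stripe number declines with
#' generations — the candidate explanation for age-related coarsening of
#' stripe patterns without any loss of stem-cell function.
#'
#' @param K ring size (number of clone positions).
#' @param p initial labelling probability (full mixing at generation 0).
#' @param generations number of Moran generations to simulate.
#' @param replicates independent rings.
#' @param seed integer seed.
#' @return Data frame with one row per generation (0..`generations`):
#'   `generation`, `mean_corrected_stripes`, `mean_observed_stripes`.
#' @export
moran_drift <- function(K, p, generations, replicates = 200L, seed = NULL) {
  assert_that(is_count(K, min = 3L), "'K' must be an integer >= 3")
  assert_that(is_prob(p) && p > 0 && p < 1, "'p' must be inside (0, 1)")
  assert_that(is_count(generations, min = 0L),
              "'generations' must be a non-negative integer")
  assert_that(is_count(replicates), "'replicates' must be a positive integer")

  with_seed(seed, {
    obs <- matrix(0, nrow = replicates, ncol = generations + 1L)
    for (r in seq_len(replicates)) {
      ring <- stats::rbinom(K, 1L, p) == 1L
      obs[r, 1L] <- count_positive_runs(ring, "circular")
      if (generations > 0L) {
        targets <- sample.int(K, generations * K, replace = TRUE)
        sides <- sample(c(-1L, 1L), generations * K, replace = TRUE)
        step <- 0L
        for (g in seq_len(generations)) {
          for (s in seq_len(K)) {
            step <- step + 1L
            i <- targets[step]
            j <- (i - 1L + sides[step]) %% K + 1L
            ring[i] <- ring[j]
          }
          obs[r, g + 1L] <- count_positive_runs(ring, "circular")
        }
      }
    }
    data.frame(
      generation = 0:generations,
      mean_observed_stripes = colMeans(obs),
      mean_corrected_stripes = colMeans(obs) / (1 - p)
    )
  })
}
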
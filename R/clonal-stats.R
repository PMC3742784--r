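#' Decompose a mosaic sequence into patches
#'
#' A *patch* is a maximal run of adjacent cells with the same marker state;
#' because adjacent coherent clones of the same colour merge visually, a patch
#' may contain several clones. On circular topology the run spanning the
#' start/end junction is merged into a single patch (a ring has no natural
#' start point).
#'
#' @param seq a [mosaic_sequence()].
#' @return An object of class `patch_summary`: patch counts, mean and median
#'   patch lengths for each population, the raw per-patch length vectors
#'   (`len_pos`, `len_neg`), the labelled proportion `p` (carried over from
#'   the sequence), `total_cells` and `total_patches`.
#' @examples
#' extract_patches(mosaic_sequence(c("+", "+", "-", "-", "-", "+")))
#' @export
extract_patches <- function(seq) {
  assert_that(inherits(seq, "mosaic_sequence"),
              "'seq' must be a mosaic_sequence")
  assert_that(length(seq$labels) >= 1L, "empty sequence")
  r <- rle(seq$labels)
  if (seq$topology == "circular" && length(r$lengths) > 1L &&
      r$values[1L] == r$values[length(r$values)]) {
    ## wrap-around: fold the final run into the first
    r$lengths[1L] <- r$lengths[1L] + r$lengths[length(r$lengths)]
    r$lengths <- r$lengths[-length(r$lengths)]
    r$values <- r$values[-length(r$values)]
  }
  len_pos <- as.integer(r$lengths[r$values])
  len_neg <- as.integer(r$lengths[!r$values])
  structure(
    list(
      n_patches_pos = length(len_pos),
      n_patches_neg = length(len_neg),
      mean_len_pos = if (length(len_pos)) mean(len_pos) else NA_real_,
      mean_len_neg = if (length(len_neg)) mean(len_neg) else NA_real_,
      median_len_pos = if (length(len_pos)) stats::median(len_pos) else NA_real_,
      median_len_neg = if (length(len_neg)) stats::median(len_neg) else NA_real_,
      len_pos = len_pos,
      len_neg = len_neg,
      p = seq$p,
      p_source = seq$p_source,
      topology = seq$topology,
      total_cells = length(seq$labels),
      total_patches = length(r$lengths)
    ),
    class = "patch_summary"
  )
}

#' @export
print.patch_summary <- function(x, ...) {
  cat(sprintf(
    "<patch_summary> %d cells, %d patches (%d +, %d -), p = %.4f (%s)\n",
    x$total_cells, x$total_patches, x$n_patches_pos, x$n_patches_neg,
    x$p, x$p_source))
  cat(sprintf("  + patches: mean %.3f, median %.1f\n",
              x$mean_len_pos, x$median_len_pos))
  cat(sprintf("  - patches: mean %.3f, median %.1f\n",
              x$mean_len_neg, x$median_len_neg))
  invisible(x)
}

#' @export
as.data.frame.patch_summary <- function(x, ...) {
  data.frame(n_patches_pos = x$n_patches_pos, n_patches_neg = x$n_patches_neg,
             mean_len_pos = x$mean_len_pos, mean_len_neg = x$mean_len_neg,
             median_len_pos = x$median_len_pos,
             median_len_neg = x$median_len_neg,
             p = x$p, total_cells = x$total_cells,
             total_patches = x$total_patches)
}

#' Expected number of coherent clones per marker-positive patch
#'
#' In a one-dimensional string of marker-positive and marker-negative cells
#' with labelled proportion `p`, consecutive positive clones merge into one
#' visible patch whenever no negative clone separates them; the number of
#' clones in a positive patch is geometric and its mean is `1/(1 - p)`.
#'
#' @param p labelled proportion, `0 <= p < 1`.
#' @return `1/(1 - p)`, always >= 1.
#' @examples
#' clones_per_patch(0.5) # 2
#' @export
clones_per_patch <- function(p) {
  assert_that(length(p) == 1L && is.numeric(p) && is.finite(p) &&
                p >= 0 && p <= 1, "'p' must be a proportion in [0, 1]")
  if (p == 1) {
    stop("clone-per-patch correction is undefined at p = 1 ",
         "(every cell is labelled; patches contain unboundedly many clones)",
         call. = FALSE)
  }
  1 / (1 - p)
}

#' Corrected mean patch length (mean coherent clone length estimate)
#'
#' Divides the observed mean positive-patch length by the expected number of
#' clones per patch, `1/(1 - p)`, i.e. multiplies it by `(1 - p)`. The result
#' estimates the mean coherent clone length, which is the quantity that
#' reflects developmental cell mixing, independently of the labelled
#' proportion realised in a particular mosaic.
#'
#' @param x a `patch_summary` (from [extract_patches()]), or a numeric
#'   observed mean positive-patch length.
#' @param p labelled proportion; taken from `x` when `x` is a
#'   `patch_summary`.
#' @return Corrected mean patch length in cells.
#' @examples
#' corrected_mean_patch_length(4, p = 0.5) # 2
#' @export
corrected_mean_patch_length <- function(x, p = NULL) {
  if (inherits(x, "patch_summary")) {
    assert_that(x$n_patches_pos >= 1L,
                "no marker-positive patches: corrected mean patch length is undefined")
    p <- p %||% x$p
    mlen <- x$mean_len_pos
  } else {
    assert_that(length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0,
                "'x' must be a positive mean patch length or a patch_summary")
    assert_that(!is.null(p), "'p' is required when 'x' is numeric")
    mlen <- x
  }
  mlen / clones_per_patch(p)
}

#' Median patch length of the minority population
#'
#' The uncorrected median patch length of whichever cell population is in the
#' minority (proportion < 0.5). Used alongside the corrected mean patch
#' length as a correction-free measure of mosaic grain. At exactly p = 0.5
#' the minority is taken as the population with fewer patches; if that also
#' ties, the negative population (deterministic, documented tie-break).
#'
#' @param summary a `patch_summary` from [extract_patches()].
#' @return Median patch length (cells) of the minority population, with the
#'   chosen population in attribute `"population"`.
#' @export
median_minority_patch_length <- function(summary) {
  assert_that(inherits(summary, "patch_summary"),
              "'summary' must be a patch_summary")
  assert_that(summary$n_patches_pos >= 1L && summary$n_patches_neg >= 1L,
              "both populations must be present to define a minority")
  p <- summary$p
  pop <- if (p < 0.5) {
    "pos"
  } else if (p > 0.5) {
    "neg"
  } else if (summary$n_patches_pos < summary$n_patches_neg) {
    "pos"
  } else if (summary$n_patches_neg < summary$n_patches_pos) {
    "neg"
  } else {
    "neg"
  }
  out <- if (pop == "pos") summary$median_len_pos else summary$median_len_neg
  attr(out, "population") <- pop
  out
}

#' Corrected stripe number
#'
#' Corrects an observed radial stripe count for the probability that one
#' visible stripe contains multiple adjacent marker-positive stem-cell
#' clones: `observed_stripes * 1/(1 - p)`. The result estimates the number of
#' *labelled* stem-cell clones contributing stripes; dividing further by `p`
#' to estimate the total clone number (labelled plus unlabelled) is provided
#' separately as [total_clone_number()].
#'
#' @param observed_stripes non-negative observed stripe count.
#' @param p labelled proportion, strictly inside `(0, 1)` (at 0 or 1 the
#'   mosaic is monochrome and the correction is undefined).
#' @return Estimated number of labelled stem-cell clones.
#' @examples
#' corrected_stripe_number(10, p = 0.5) # 20
#' @export
corrected_stripe_number <- function(observed_stripes, p) {
  assert_that(is.numeric(observed_stripes) && all(is.finite(observed_stripes)) &&
                all(observed_stripes >= 0),
              "'observed_stripes' must be non-negative")
  assert_that(is_prob(p), "'p' must be a proportion in [0, 1]")
  if (p == 0 || p == 1) {
    stop("stripe correction is undefined at p = 0 or p = 1 ",
         "(monochrome mosaic carries no stripe information)", call. = FALSE)
  }
  observed_stripes / (1 - p)
}

#' Total clone number estimate (extension)
#'
#' Extends the adjacency correction of [corrected_stripe_number()] to an
#' estimate of the *total* number of stem-cell clones around the ring,
#' labelled and unlabelled: `observed_stripes / (p * (1 - p))`, since on a
#' ring of `K` clones the expected number of visible positive stripes is
#' `K * p * (1 - p)`. This goes beyond the published adjacency correction
#' (which stops at the labelled clone count) and is exposed under its own
#' name for that reason.
#'
#' @inheritParams corrected_stripe_number
#' @return Estimated total clone number.
#' @export
total_clone_number <- function(observed_stripes, p) {
  corrected_stripe_number(observed_stripes, p) / p
}

#' Stripe number per mm of corneal circumference
#'
#' Normalises a corrected stripe number by the corneal circumference so that
#' eyes of different sizes are comparable.
#'
#' @param corrected corrected stripe number.
#' @param circumference_mm corneal circumference in mm (> 0).
#' @return Stripes per mm.
#' @examples
#' stripes_per_mm(20, 10) # 2
#' @export
stripes_per_mm <- function(corrected, circumference_mm) {
  assert_that(is.numeric(corrected) && all(is.finite(corrected)) &&
                all(corrected >= 0), "'corrected' must be non-negative")
  assert_that(length(circumference_mm) == 1L &&
                is.numeric(circumference_mm) &&
                is.finite(circumference_mm) && circumference_mm > 0,
              "'circumference_mm' must be a positive length")
  corrected / circumference_mm
}

#' Count marker-positive stripes (runs) in a label sequence
#'
#' On linear topology this is the number of maximal runs of positive labels.
#' On circular topology stripes are counted as (negative to positive)
#' boundaries around the ring, so a monochrome all-positive ring counts 0
#' stripes: a uniform ring shows no stripe boundaries, and this convention
#' makes the expected stripe count on a ring of `K` independent clones
#' exactly `K * p * (1 - p)` (see [ring_run_enumeration()]). Note the
#' deliberate difference from [extract_patches()], whose literal run
#' decomposition assigns a monochrome circular sequence one patch.
#'
#' @param x a [mosaic_sequence()] or a logical/`"+"`/`"-"` label vector.
#' @param topology used when `x` is a bare vector.
#' @return Integer stripe count.
#' @export
count_positive_runs <- function(x, topology = c("linear", "circular")) {
  if (inherits(x, "mosaic_sequence")) {
    labels <- x$labels
    topology <- x$topology
  } else {
    labels <- coerce_labels(x)
    topology <- match.arg(topology)
  }
  n <- length(labels)
  if (topology == "linear") {
    sum(labels & !c(FALSE, labels[-n]))
  } else {
    prev <- labels[c(n, seq_len(n - 1L))]
    sum(labels & !prev)
  }
}

#' Corrected clonal statistics for a per-eye stripe-count table
#'
#' Applies [corrected_stripe_number()] and [stripes_per_mm()] row-wise to a
#' table of per-eye observations: observed stripe count, labelled proportion
#' `p` (per-eye by default) and three diameter measurements of the cornea in
#' mm, from which the circumference is taken as `pi` times their mean.
#'
#' @param df data frame with columns `eye_id`, `observed_stripes`, `p` and
#'   three `diameter*_mm` columns (any columns matching `^diameter`), e.g. as
#'   read by [read_tsv()]. Additional columns (such as a group label) are
#'   carried through.
#' @param p_group optional single proportion applied to every eye instead of
#'   the per-eye `p` column.
#' @return The input with `clones_per_patch`, `corrected_stripes`,
#'   `total_clones`, `circumference_mm` and `corrected_stripes_per_mm`
#'   columns appended.
#' @examples
#' path <- system.file("extdata", "synthetic_stripe_counts.tsv",
#'                     package = "corneamosaic")
#' corrected_stripe_table(read_tsv(path))
#' @export
corrected_stripe_table <- function(df, p_group = NULL) {
  needed <- c("eye_id", "observed_stripes", if (is.null(p_group)) "p")
  assert_that(is.data.frame(df) && all(needed %in% names(df)),
              "'df' needs eye_id, observed_stripes and p columns")
  dia_cols <- grep("^diameter", names(df), value = TRUE)
  assert_that(length(dia_cols) >= 1L,
              "'df' needs at least one diameter*_mm column")
  p <- if (is.null(p_group)) df$p else rep(p_group, nrow(df))
  out <- df
  out$clones_per_patch <- vapply(p, clones_per_patch, numeric(1))
  out$corrected_stripes <- vapply(seq_len(nrow(df)), function(i) {
    corrected_stripe_number(df$observed_stripes[i], p[i])
  }, numeric(1))
  out$total_clones <- out$corrected_stripes / p
  out$circumference_mm <- pi * rowMeans(df[, dia_cols, drop = FALSE])
  out$corrected_stripes_per_mm <- vapply(seq_len(nrow(df)), function(i) {
    stripes_per_mm(out$corrected_stripes[i], out$circumference_mm[i])
  }, numeric(1))
  out
}
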
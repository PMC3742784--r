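#' Binary mosaic cell sequence
#'
#' An ordered sequence of marker-positive / marker-negative cell labels along
#' a tissue section (linear topology) or around a ring such as the limbal
#' circumference (circular topology), together with the labelled proportion
#' `p`. This is the container consumed by [extract_patches()] and produced by
#' [generate_mosaic()] and [simulate_ring()].
#'
#' `p` defaults to the observed labelled fraction of the sequence itself
#' (`p_source = "observed"`); a group-level proportion can be supplied instead
#' (e.g. the mean percentage of beta-gal-positive cells for a genotype), in
#' which case `p_source = "supplied"` is recorded.
#'
#' @param labels logical vector (`TRUE` = marker-positive), or a character
#'   vector over `"+"`/`"-"`, or 0/1 integers.
#' @param topology `"linear"` (section across a diameter) or `"circular"`
#'   (ring around a circumference).
#' @param p labelled proportion in `[0, 1]`, or `NULL` to use the observed
#'   fraction.
#' @return An object of class `mosaic_sequence`: a list with elements
#'   `labels` (logical), `topology`, `p`, `p_source`, and optionally
#'   `clone_id` (generator ground truth, see [generate_mosaic()]).
#' @examples
#' ms <- mosaic_sequence(c("+", "+", "-", "-", "-", "+"))
#' extract_patches(ms)
#' @export
mosaic_sequence <- function(labels, topology = c("linear", "circular"),
                            p = NULL) {
  topology <- match.arg(topology)
  labels <- coerce_labels(labels)
  assert_that(length(labels) >= 1L, "sequence must contain at least one cell")
  if (is.null(p)) {
    p <- mean(labels)
    p_source <- "observed"
  } else {
    assert_that(is_prob(p), "'p' must be a single proportion in [0, 1]")
    p_source <- "supplied"
  }
  structure(
    list(labels = labels, topology = topology, p = p, p_source = p_source),
    class = "mosaic_sequence"
  )
}

coerce_labels <- function(labels) {
  if (is.character(labels)) {
    assert_that(all(labels %in% c("+", "-")),
                "character labels must be '+' or '-'")
    labels == "+"
  } else if (is.logical(labels)) {
    assert_that(!anyNA(labels), "labels must not contain NA")
    labels
  } else if (is.numeric(labels)) {
    assert_that(all(labels %in% c(0, 1)), "numeric labels must be 0 or 1")
    labels == 1
  } else {
    stop("labels must be logical, '+'/'-', or 0/1", call. = FALSE)
  }
}

#' @export
print.mosaic_sequence <- function(x, ...) {
  cat(sprintf("<mosaic_sequence> %d cells, %s topology, p = %.4f (%s)\n",
              length(x$labels), x$topology, x$p, x$p_source))
  n <- min(length(x$labels), 60L)
  cat(paste(ifelse(x$labels[seq_len(n)], "+", "-"), collapse = ""),
      if (length(x$labels) > n) "..." else "", "\n")
  invisible(x)
}

#' @export
length.mosaic_sequence <- function(x) length(x$labels)

#' Generate a coherent-clone binary mosaic sequence
#'
#' Simulates the mosaic of two genetically marked cell populations along a
#' section (or ring) as a tiling of *coherent clones*: contiguous groups of
#' cells descended from one progenitor and therefore sharing one marker state.
#' Clone lengths are geometric with mean `clone_len_mean` (the simplest
#' one-parameter positive length law), and each clone is independently
#' marker-positive with probability `p`. `clone_len_mean = 1` reduces exactly
#' to i.i.d. Bernoulli(`p`) cells, i.e. complete cell mixing; larger values
#' emulate coarser-grained mosaics with less developmental cell mixing.
#'
#' On circular topology the tiling closes around the ring and the last clone
#' is truncated to fit; it remains a clone distinct from the first even when
#' both happen to carry the same marker.
#'
#' The returned sequence carries the generator's internal clone boundaries as
#' `clone_id`, so clone-level ground truth (e.g. the realised mean coherent
#' clone length) is available for parameter-recovery checks against the
#' patch-based estimators.
#'
#' @param n_cells number of cells in the sequence (>= 1).
#' @param p probability that a clone is marker-positive, in `[0, 1]`.
#' @param clone_len_mean mean coherent clone length in cells (>= 1).
#' @param topology `"linear"` or `"circular"`.
#' @param seed integer seed; identical seeds give identical sequences.
#' @return A [mosaic_sequence()] with an extra `clone_id` element (integer
#'   vector mapping each cell to its generating clone) and the generating
#'   parameters in `gen_params`. `p` is stored as the supplied generative
#'   proportion (`p_source = "supplied"`).
#' @examples
#' ms <- generate_mosaic(50, p = 0.5, clone_len_mean = 4, seed = 1)
#' tabulate(ms$clone_id) # realised clone lengths
#' @export
generate_mosaic <- function(n_cells, p, clone_len_mean = 1,
                            topology = c("linear", "circular"), seed = NULL) {
  topology <- match.arg(topology)
  assert_that(is_count(n_cells), "'n_cells' must be a positive integer")
  assert_that(is_prob(p), "'p' must be a single proportion in [0, 1]")
  assert_that(length(clone_len_mean) == 1L && is.finite(clone_len_mean) &&
                clone_len_mean >= 1, "'clone_len_mean' must be >= 1")

  with_seed(seed, {
    ## geometric clone lengths, mean m: L = 1 + Geom(prob = 1/m)
    pr <- 1 / clone_len_mean
    lens <- integer(0)
    while (sum(lens) < n_cells) {
      need <- max(16L, ceiling((n_cells - sum(lens)) / clone_len_mean * 1.5))
      lens <- c(lens, 1L + stats::rgeom(need, pr))
    }
    n_clones <- which(cumsum(lens) >= n_cells)[1L]
    lens <- lens[seq_len(n_clones)]
    clone_lab <- stats::rbinom(n_clones, 1L, p) == 1L
    clone_id <- rep.int(seq_len(n_clones), lens)[seq_len(n_cells)]
    labels <- clone_lab[clone_id]
    ms <- mosaic_sequence(labels, topology = topology, p = p)
    ms$clone_id <- clone_id
    ms$gen_params <- list(n_cells = n_cells, p = p,
                          clone_len_mean = clone_len_mean,
                          topology = topology, seed = seed)
    ms
  })
}

#' Write / read a mosaic sequence as TSV
#'
#' Columns `position` (1-based) and `label` (`+`/`-`); topology and `p`
#' travel as explicit columns so the file is self-contained.
#'
#' @param x a [mosaic_sequence()].
#' @param path file path.
#' @return `path` invisibly (`write_mosaic_tsv`); a `mosaic_sequence`
#'   (`read_mosaic_tsv`).
#' @export
write_mosaic_tsv <- function(x, path) {
  stopifnot(inherits(x, "mosaic_sequence"))
  df <- data.frame(position = seq_along(x$labels),
                   label = ifelse(x$labels, "+", "-"),
                   topology = x$topology,
                   p = x$p, p_source = x$p_source)
  write_tsv(df, path)
}

#' @rdname write_mosaic_tsv
#' @export
read_mosaic_tsv <- function(path) {
  df <- read_tsv(path)
  assert_that(all(c("position", "label") %in% names(df)),
              "file must have 'position' and 'label' columns")
  df <- df[order(df$position), , drop = FALSE]
  topology <- if ("topology" %in% names(df)) df$topology[1L] else "linear"
  if ("p_source" %in% names(df) && df$p_source[1L] == "supplied") {
    mosaic_sequence(df$label, topology = topology, p = df$p[1L])
  } else {
    mosaic_sequence(df$label, topology = topology)
  }
}
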
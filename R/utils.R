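## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= min &&
    abs(x - round(x)) < .Machine$double.eps^0.5
}

is_prob <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

## Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
## seed = NULL leaves the global stream untouched (still reproducible if the
## caller set a seed). All package randomness funnels through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_that(is_count(seed, min = -.Machine$integer.max),
              "'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream-specific child seed from a master seed so that independent
## components (replicates, modules) never share a stream. Kept < 2^31.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 48271 + 7919 * k) %% 2147483647)
}

#' Write a data frame as tab-separated text
#'
#' Convenience wrapper used for all tabular outputs (sequences, count tables,
#' patch summaries, LRC tables): TSV with a header, no quoting, no row names.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path file path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
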
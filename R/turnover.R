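#' Build a per-cell layer count table
#'
#' Container for BrdU scoring of one corneal mid-section: every basal cell
#' across the diameter scored positive/negative, with the suprabasal column
#' above each basal position scored in the same way. Rows are ordered across
#' the diameter. Aggregated tables (e.g. one row per region group, as
#' produced by [generate_cohort_timecourse()]) use the same columns with
#' counts > 1.
#'
#' @param basal_pos integer vector, BrdU-positive basal cells per position.
#' @param basal_total integer vector, total basal cells per position.
#' @param suprabasal_pos,suprabasal_total suprabasal counts per position.
#' @param time_days chase time in days.
#' @param eye_id,genotype identifiers.
#' @return A data frame of class `layer_count_table`.
#' @export
layer_count_table <- function(basal_pos, basal_total = 1L,
                              suprabasal_pos = 0L, suprabasal_total = 0L,
                              time_days = NA_real_, eye_id = "eye1",
                              genotype = NA_character_) {
  n <- length(basal_pos)
  tab <- data.frame(position = seq_len(n),
                    basal_pos = as.integer(basal_pos),
                    basal_total = as.integer(rep_len(basal_total, n)),
                    suprabasal_pos = as.integer(rep_len(suprabasal_pos, n)),
                    suprabasal_total = as.integer(rep_len(suprabasal_total, n)),
                    time_days = time_days, eye_id = eye_id,
                    genotype = genotype)
  assert_that(all(tab$basal_pos <= tab$basal_total) &&
                all(tab$suprabasal_pos <= tab$suprabasal_total),
              "positive counts cannot exceed totals")
  assert_that(all(tab$basal_pos >= 0) && all(tab$suprabasal_pos >= 0),
              "counts must be non-negative")
  class(tab) <- c("layer_count_table", "data.frame")
  tab
}

#' Assign corneal regions by the six-group partition
#'
#' Splits the ordered cells (or positions) across the diameter into six
#' contiguous, equal-sized groups and maps them to regions: the two outermost
#' groups are peripheral (P), the next two intermediate (I) and the middle
#' two central (C). When the cell number is not divisible by 6, group sizes
#' differ by at most one; the extra cells go to the outermost groups first,
#' allocated symmetrically (group order 1, 6, 2, 5, 3, 4).
#'
#' @param table a `layer_count_table` (rows ordered across the diameter).
#' @return The table with `group` (1..6) and `region` (`"P"`, `"I"`, `"C"`)
#'   columns added.
#' @examples
#' tab <- layer_count_table(basal_pos = rep(0L, 12))
#' partition_regions(tab)$region
#' @export
partition_regions <- function(table) {
  assert_that(inherits(table, "data.frame") &&
                all(c("position", "basal_pos", "basal_total") %in% names(table)),
              "'table' must be a layer_count_table-like data frame")
  n <- nrow(table)
  assert_that(n >= 6L, "at least 6 cells are required for the six-region partition")
  sizes <- six_group_sizes(n)
  table <- table[order(table$position), , drop = FALSE]
  table$group <- rep.int(1:6, sizes)
  table$region <- c("P", "I", "C", "C", "I", "P")[table$group]
  if (!inherits(table, "layer_count_table")) {
    class(table) <- c("layer_count_table", class(table))
  }
  table
}

## largest-remainder allocation of n cells to 6 contiguous groups, extras to
## the outermost groups first, symmetrically: priority 1, 6, 2, 5, 3, 4
six_group_sizes <- function(n) {
  base <- n %/% 6L
  extra <- n %% 6L
  sizes <- rep.int(base, 6L)
  priority <- c(1L, 6L, 2L, 5L, 3L, 4L)
  if (extra > 0L) {
    idx <- priority[seq_len(extra)]
    sizes[idx] <- sizes[idx] + 1L
  }
  sizes
}

#' BrdU labelling indices per region and whole eye
#'
#' Computes, per region (P, I, C) and for the whole section:
#' * `BLI` — basal labelling index, BrdU-positive basal cells as a
#'   percentage of total basal cells;
#' * `SLI` — suprabasal labelling index, positive suprabasal cells as a
#'   percentage of total suprabasal cells;
#' * `ASLI` — adjusted suprabasal labelling index, positive suprabasal cells
#'   as a percentage of the *basal* total. The adjustment removes the
#'   dependence on how many suprabasal layers an epithelium has (identically,
#'   `ASLI/SLI = suprabasal_total/basal_total`), so genotypes with thinner
#'   epithelia are comparable; `ASLI` may exceed 100.
#'
#' Each region pools its two groups. With `pooling = "weighted"` (default)
#' the counts are summed before forming the ratio, i.e. cells are weighted
#' equally; `pooling = "unweighted"` averages the two groups' indices, i.e.
#' groups are weighted equally ("one mean value per eye" reading). The
#' whole-eye row always pools all counts.
#'
#' @param table a `layer_count_table`; if it lacks a `region` column and has
#'   more than 6 rows, [partition_regions()] is applied first. A 6-row table
#'   without regions is treated as the six ordered groups.
#' @param pooling `"weighted"` or `"unweighted"` (see above).
#' @return Data frame of class `labelling_indices` with columns `region`
#'   (`P`, `I`, `C`, `whole`), `BLI`, `SLI`, `ASLI` and `defined` (FALSE
#'   where a zero denominator makes an index undefined; the index is `NA`).
#' @examples
#' tab <- layer_count_table(basal_pos = rbinom(12, 1, 0.3),
#'                          suprabasal_pos = rbinom(12, 2, 0.2),
#'                          suprabasal_total = 2L)
#' labelling_indices(tab)
#' @export
labelling_indices <- function(table, pooling = c("weighted", "unweighted")) {
  pooling <- match.arg(pooling)
  assert_that(inherits(table, "data.frame") &&
                all(c("basal_pos", "basal_total", "suprabasal_pos",
                      "suprabasal_total") %in% names(table)),
              "'table' must carry basal/suprabasal count columns")
  if (!"region" %in% names(table)) {
    if (nrow(table) == 6L) {
      table$group <- 1:6
      table$region <- c("P", "I", "C", "C", "I", "P")
    } else {
      table <- partition_regions(table)
    }
  }
  ## region-annotated tables without explicit groups: each row is its own
  ## group, so unweighted pooling averages the per-row indices
  if (!"group" %in% names(table)) table$group <- seq_len(nrow(table))

  idx_of <- function(bp, bt, sp, st) {
    c(BLI = if (bt > 0) 100 * bp / bt else NA_real_,
      SLI = if (st > 0) 100 * sp / st else NA_real_,
      ASLI = if (bt > 0) 100 * sp / bt else NA_real_)
  }

  region_row <- function(reg) {
    sub <- table[table$region == reg, , drop = FALSE]
    if (pooling == "weighted") {
      v <- idx_of(sum(sub$basal_pos), sum(sub$basal_total),
                  sum(sub$suprabasal_pos), sum(sub$suprabasal_total))
    } else {
      per_group <- lapply(split(sub, sub$group), function(g) {
        idx_of(sum(g$basal_pos), sum(g$basal_total),
               sum(g$suprabasal_pos), sum(g$suprabasal_total))
      })
      v <- colMeans(do.call(rbind, per_group))
    }
    v
  }

  rows <- rbind(P = region_row("P"), I = region_row("I"), C = region_row("C"),
                whole = idx_of(sum(table$basal_pos), sum(table$basal_total),
                               sum(table$suprabasal_pos),
                               sum(table$suprabasal_total)))
  out <- data.frame(region = rownames(rows), rows, row.names = NULL)
  out$defined <- !is.na(out$BLI) & !is.na(out$SLI) & !is.na(out$ASLI)
  class(out) <- c("labelling_indices", "data.frame")
  out
}

#' Percentage of labelled cells that are suprabasal
#'
#' `100 * SLI / (SLI + BLI)`, the share of all labelled cells that sit in the
#' suprabasal layers — the summary used to compare how quickly labelled basal
#' cells move upward between genotypes. The adjusted variant substitutes
#' `ASLI` for `SLI` and thereby removes the dependence on suprabasal layer
#' number.
#'
#' @param sli suprabasal labelling index (or `ASLI` for the adjusted
#'   variant), percent.
#' @param bli basal labelling index, percent.
#' @return Percentage in `[0, 100]`; `NA` (with a warning) where
#'   `sli + bli == 0` leaves the fraction undefined.
#' @examples
#' suprabasal_fraction(40, 60) # 40
#' @export
suprabasal_fraction <- function(sli, bli) {
  assert_that(is.numeric(sli) && is.numeric(bli) &&
                length(sli) == length(bli), "'sli' and 'bli' must match")
  assert_that(all(sli >= 0 | is.na(sli)) && all(bli >= 0 | is.na(bli)),
              "indices must be non-negative")
  denom <- sli + bli
  out <- ifelse(denom > 0, 100 * sli / denom, NA_real_)
  if (anyNA(out[!is.na(denom)]) || any(denom == 0, na.rm = TRUE)) {
    warning("suprabasal fraction undefined where SLI + BLI = 0; returning NA")
  }
  out
}

#' Estimate the epithelial turnover time from a pulse-chase time course
#'
#' The turnover time is bounded by the first chase time, after the labelled
#' cohort's peak, at which the total labelled cell count falls below a set
#' fraction of that peak (default 10%). If the label never declines below
#' the threshold within the observed window the estimate is right-censored
#' at the last time point rather than an error.
#'
#' @param timecourse a list of `layer_count_table`s (e.g. from
#'   [generate_cohort_timecourse()]) or a data frame with columns
#'   `time_days` and `labelled`.
#' @param threshold fraction of the peak labelled count (default 0.1).
#' @return An object of class `turnover_estimate`: `turnover_days` (the
#'   bound; `NA` if censored), `censored`, `threshold`, `peak_time`, and the
#'   labelled-count trajectory in `trajectory`.
#' @examples
#' tc <- data.frame(time_days = c(0, 3, 7, 14),
#'                  labelled = c(100, 300, 50, 5))
#' estimate_turnover_time(tc)
#' @export
estimate_turnover_time <- function(timecourse, threshold = 0.1) {
  assert_that(is_prob(threshold) && threshold > 0,
              "'threshold' must be a fraction in (0, 1]")
  if (is.data.frame(timecourse)) {
    assert_that(all(c("time_days", "labelled") %in% names(timecourse)),
                "data frame input needs 'time_days' and 'labelled' columns")
    traj <- timecourse[order(timecourse$time_days), c("time_days", "labelled")]
  } else {
    assert_that(is.list(timecourse) && length(timecourse) >= 1L &&
                  all(vapply(timecourse, is.data.frame, logical(1))),
                "'timecourse' must be a list of layer count tables")
    traj <- do.call(rbind, lapply(timecourse, function(tab) {
      data.frame(time_days = tab$time_days[1L],
                 labelled = sum(tab$basal_pos) + sum(tab$suprabasal_pos))
    }))
    traj <- traj[order(traj$time_days), , drop = FALSE]
  }
  assert_that(nrow(traj) >= 3L, "at least 3 time points are required")
  peak_i <- which.max(traj$labelled)
  peak <- traj$labelled[peak_i]
  after <- traj[seq(peak_i, nrow(traj)), , drop = FALSE]
  below <- which(after$labelled < threshold * peak)
  censored <- length(below) == 0L
  structure(list(
    turnover_days = if (censored) NA_real_ else after$time_days[below[1L]],
    censored = censored,
    threshold = threshold,
    peak_time = traj$time_days[peak_i],
    trajectory = traj
  ), class = "turnover_estimate")
}

#' @export
print.turnover_estimate <- function(x, ...) {
  if (x$censored) {
    cat(sprintf(
      "<turnover_estimate> right-censored at %g days (label never fell below %g%% of peak)\n",
      max(x$trajectory$time_days), 100 * x$threshold))
  } else {
    cat(sprintf(
      "<turnover_estimate> turnover time <= %g days (first time below %g%% of the peak at day %g)\n",
      x$turnover_days, 100 * x$threshold, x$peak_time))
  }
  invisible(x)
}
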
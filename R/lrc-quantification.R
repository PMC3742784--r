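#' Detect nuclei on a calibrated limbal image
#'
#' Global threshold (Otsu by default, overridable), 8-connected component
#' labelling, and a particle-size filter keeping components whose pixel area
#' lies in `[min_size_px, max_size_px]` — by default 150-5000 px, the window
#' that corresponds to 3-15 um nucleus diameters at a calibration of about
#' 0.2 um/px. Fluorescent spots outside the size window (debris, clumps) are
#' excluded. Touching nuclei are not split (no watershed); synthetic fixtures
#' avoid contact, and this limitation is documented.
#'
#' @param image a `limbal_image`, or a numeric matrix (rows = y, cols = x)
#'   with intensities in `[0, 1]`.
#' @param um_per_px calibration; taken from a `limbal_image` input.
#' @param min_size_px,max_size_px particle-size filter bounds in pixels.
#' @param threshold manual global threshold in `[0, 1]`; `NULL` for Otsu.
#' @return Data frame with one row per accepted component: `x_um`, `y_um`
#'   (intensity-weighted centroid is not used; the centroid is the unweighted
#'   mean of member pixel centres), `area_px`, `diameter_um` (equivalent
#'   circular diameter) and `intensity` (mean intensity). Zero rows for a
#'   blank image.
#' @examples
#' li <- generate_limbal_image(128, 128, 0.2,
#'                             nuclei = data.frame(x_um = 12, y_um = 14,
#'                                                 diameter_um = 10))
#' detect_nuclei(li)
#' @export
detect_nuclei <- function(image, um_per_px = NULL, min_size_px = 150L,
                          max_size_px = 5000L, threshold = NULL) {
  if (inherits(image, "limbal_image")) {
    um_per_px <- um_per_px %||% image$um_per_px
    image <- image$image
  }
  assert_that(is.matrix(image) && is.numeric(image),
              "'image' must be a numeric matrix or limbal_image")
  assert_that(!is.null(um_per_px) && um_per_px > 0,
              "'um_per_px' calibration is required")
  assert_that(min_size_px >= 1 && max_size_px >= min_size_px,
              "size filter bounds must satisfy 1 <= min <= max")

  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_px = integer(0), diameter_um = numeric(0),
                      intensity = numeric(0))
  if (all(image <= 0)) return(empty)

  img01 <- pmin(pmax(image, 0), 1)
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
  }
  mask <- img01 > threshold
  if (!any(mask)) return(empty)

  lab <- label_components_8(mask)
  n_lab <- max(lab)
  if (n_lab == 0L) return(empty)

  keep_px <- lab > 0L
  ids <- lab[keep_px]
  area <- tabulate(ids, nbins = n_lab)
  rows <- row(lab)[keep_px]
  cols <- col(lab)[keep_px]
  cy <- rowsum(rows, ids)[, 1L] / area  # row index ~ y
  cx <- rowsum(cols, ids)[, 1L] / area  # col index ~ x
  inten <- rowsum(img01[keep_px], ids)[, 1L] / area

  sel <- area >= min_size_px & area <= max_size_px
  data.frame(
    x_um = (cx[sel] - 0.5) * um_per_px,
    y_um = (cy[sel] - 0.5) * um_per_px,
    area_px = as.integer(area[sel]),
    diameter_um = 2 * sqrt(area[sel] / pi) * um_per_px,
    intensity = inten[sel],
    row.names = NULL
  )
}

## 8-connected component labelling: EBImage::bwlabel (4-connectivity) plus a
## union-find merge of labels that touch diagonally.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1, -1])),   # down-right
    cbind(as.vector(lab[-nr, -1]), as.vector(lab[-1, -nc]))    # down-left
  )
  pairs <- pairs[pairs[, 1L] > 0L & pairs[, 2L] > 0L &
                   pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    for (k in seq_len(nrow(pairs))) unite(pairs[k, 1L], pairs[k, 2L])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relabel[lab[lab > 0L]]
  out
}

#' Count detections inside a sampling box
#'
#' Membership is by centroid with half-open bounds
#' `[x0, x0 + width) x [y0, y0 + height)`, so a detection exactly on the far
#' edge belongs to the next box and nothing is double-counted across
#' adjacent sectors. The standard limbal LRC sampling box is 340 x 200 um.
#'
#' @param detections data frame from [detect_nuclei()] (columns `x_um`,
#'   `y_um`).
#' @param origin_um `c(x0, y0)` of the box in um.
#' @param width_um,height_um box size in um (default 340 x 200).
#' @param image_dim_um optional `c(width, height)` of the image in um; when
#'   given, a box exceeding the image bounds is an error.
#' @return Integer count.
#' @export
count_in_box <- function(detections, origin_um, width_um = 340,
                         height_um = 200, image_dim_um = NULL) {
  assert_that(is.data.frame(detections) &&
                all(c("x_um", "y_um") %in% names(detections)),
              "'detections' must have x_um and y_um columns")
  assert_that(length(origin_um) == 2L && all(is.finite(origin_um)),
              "'origin_um' must be c(x0, y0)")
  assert_that(width_um > 0 && height_um > 0, "box dimensions must be positive")
  if (!is.null(image_dim_um)) {
    assert_that(origin_um[1L] >= 0 && origin_um[2L] >= 0 &&
                  origin_um[1L] + width_um <= image_dim_um[1L] &&
                  origin_um[2L] + height_um <= image_dim_um[2L],
                "sampling box exceeds the image bounds")
  }
  sum(detections$x_um >= origin_um[1L] &
        detections$x_um < origin_um[1L] + width_um &
        detections$y_um >= origin_um[2L] &
        detections$y_um < origin_um[2L] + height_um)
}

#' Extrapolate a per-box LRC count to the limbal circumference
#'
#' `mean_per_box * circumference / box_length`, where the circumference is
#' `pi` times the mean of three diameter measurements of the flattened
#' cornea. Estimates the number of LRCs in a 200 um wide ring around the
#' whole circumference, correcting for eye-size differences.
#'
#' @param mean_per_box mean LRC count per 340-um sampling box.
#' @param diameters_mm numeric vector of diameter measurements in mm
#'   (conventionally 3).
#' @param box_len_um sampling-box length along the circumference (340 um).
#' @return Estimated LRCs per circumference.
#' @examples
#' per_circumference(10, c(3, 3, 3)) # 10 * pi * 3000 / 340
#' @export
per_circumference <- function(mean_per_box, diameters_mm, box_len_um = 340) {
  assert_that(is.numeric(mean_per_box) && all(mean_per_box >= 0),
              "'mean_per_box' must be non-negative")
  assert_that(length(diameters_mm) >= 1L && all(is.finite(diameters_mm)) &&
                all(diameters_mm > 0), "diameters must be positive")
  assert_that(box_len_um > 0, "'box_len_um' must be positive")
  circumference_um <- pi * mean(diameters_mm) * 1000
  mean_per_box * circumference_um / box_len_um
}

#' Assemble one per-eye LRC record
#'
#' @param eye_id,group,experiment_id identifiers; `group` is one of the four
#'   compared groups (e.g. genotype x age).
#' @param sector_counts LRC counts, one 340 x 200 um box per corneal sector
#'   (1-8 sectors).
#' @param diameters_mm three diameter measurements of the flattened cornea.
#' @return One-row data frame with `mean_per_box` and `per_circumference`
#'   computed.
#' @export
lrc_record <- function(eye_id, group, experiment_id, sector_counts,
                       diameters_mm) {
  assert_that(length(sector_counts) >= 1L && length(sector_counts) <= 8L,
              "1 to 8 sector counts are expected")
  assert_that(all(sector_counts >= 0), "sector counts must be non-negative")
  mpb <- mean(sector_counts)
  data.frame(eye_id = eye_id, group = group, experiment_id = experiment_id,
             n_sectors = length(sector_counts),
             mean_per_box = mpb,
             per_circumference = per_circumference(mpb, diameters_mm))
}

#' Cross-experiment normalised LRC indices
#'
#' For each immunofluorescence experiment that yielded results for at least
#' one eye from each of the four groups, the group means (per sampling box,
#' or per circumference) are expressed as percentages of their four-group
#' sum. Row sums are exactly 100 within each experiment, which removes
#' between-experiment staining variability; experiments missing a group are
#' excluded with a warning (the inclusion rule).
#'
#' @param records data frame of per-eye rows as built by [lrc_record()]
#'   (columns `experiment_id`, `group`, and the variant column).
#' @param variant `"per_box"` (uses `mean_per_box`) or `"per_circumference"`.
#' @param groups the four group labels expected in every experiment; default
#'   is the sorted unique groups of `records` (must be exactly 4).
#' @return Data frame of class `lrc_index_table`: `experiment_id`, `group`,
#'   `group_mean`, `index` (percent), `variant`.
#' @examples
#' recs <- do.call(rbind, Map(lrc_record,
#'   eye_id = 1:4, group = c("WT15", "Pax6_15", "WT30", "Pax6_30"),
#'   experiment_id = "exp1",
#'   sector_counts = list(2, 2, 2, 6), diameters_mm = list(3)))
#' lrc_index(recs)
#' @export
lrc_index <- function(records, variant = c("per_box", "per_circumference"),
                      groups = NULL) {
  variant <- match.arg(variant)
  value_col <- if (variant == "per_box") "mean_per_box" else "per_circumference"
  assert_that(is.data.frame(records) &&
                all(c("experiment_id", "group", value_col) %in% names(records)),
              sprintf("'records' must have experiment_id, group and %s columns",
                      value_col))
  groups <- groups %||% sort(unique(as.character(records$group)))
  assert_that(length(groups) == 4L,
              "exactly four groups are compared per experiment")

  out <- list()
  for (ex in unique(records$experiment_id)) {
    sub <- records[records$experiment_id == ex, , drop = FALSE]
    present <- groups %in% sub$group
    if (!all(present)) {
      warning(sprintf(
        "experiment '%s' excluded: missing group(s) %s", ex,
        paste(groups[!present], collapse = ", ")), call. = FALSE)
      next
    }
    gm <- vapply(groups, function(g) {
      mean(sub[[value_col]][sub$group == g])
    }, numeric(1))
    total <- sum(gm)
    assert_that(total > 0, sprintf(
      "experiment '%s' has zero total LRC count; index undefined", ex))
    out[[ex]] <- data.frame(experiment_id = ex, group = groups,
                            group_mean = unname(gm),
                            index = unname(100 * gm / total),
                            variant = variant, row.names = NULL)
  }
  assert_that(length(out) > 0L, "no experiment had all four groups")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("lrc_index_table", "data.frame")
  res
}

#' Nucleus packing density in a 150 x 150 um box
#'
#' Detects nuclei (same pipeline and size filter as [detect_nuclei()]) and
#' counts those whose centroids fall in a 150 x 150 um sampling box —
#' the comparison of cell-packing densities between groups.
#'
#' @param image a `limbal_image` or numeric matrix.
#' @param origin_um box origin `c(x0, y0)` in um.
#' @param box_um box side length (150 um).
#' @inheritParams detect_nuclei
#' @return Integer count.
#' @export
packing_density <- function(image, origin_um, box_um = 150, um_per_px = NULL,
                            min_size_px = 150L, max_size_px = 5000L,
                            threshold = NULL) {
  det <- detect_nuclei(image, um_per_px = um_per_px,
                       min_size_px = min_size_px, max_size_px = max_size_px,
                       threshold = threshold)
  dims <- if (inherits(image, "limbal_image")) {
    c(ncol(image$image), nrow(image$image)) *
      (um_per_px %||% image$um_per_px)
  } else NULL
  count_in_box(det, origin_um, width_um = box_um, height_um = box_um,
               image_dim_um = dims)
}
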
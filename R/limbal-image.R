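#' Generate a synthetic limbal whole-mount image
#'
#' Renders a calibrated grayscale image containing fluorescent nuclei as
#' soft-edged disks: intensity `peak * pnorm((d/2 - r) / edge_um)` around
#' each centre, i.e. a filled disk of the stated diameter with a Gaussian
#' edge of width `edge_um`, plus optional Gaussian background noise (clipped
#' at zero). The soft-disk profile keeps the thresholded particle area close
#' to the nominal `pi * (d/2)^2` for any threshold well inside the dynamic
#' range, so the ground-truth diameters drive the size filter predictably.
#' The ground truth travels with the image.
#'
#' This emulates a maximum-intensity projection of a confocal stack; it makes
#' no attempt at real optics, staining variability or 3-D structure.
#'
#' @param width_px,height_px image size in pixels.
#' @param um_per_px calibration, micrometres per pixel (> 0).
#' @param nuclei data frame with columns `x_um`, `y_um`, `diameter_um` and
#'   optionally `intensity` (default 0.8 of full scale). May have zero rows.
#' @param background_noise_sd Gaussian noise s.d. in intensity units
#'   (full scale = 1).
#' @param edge_um Gaussian edge width of the nucleus profile, in um.
#' @param seed integer seed (noise only; nucleus placement is deterministic
#'   given `nuclei`).
#' @return An object of class `limbal_image`: `image` (numeric matrix,
#'   rows = y, cols = x, values in `[0, 1]`), `um_per_px`, and `nuclei`
#'   (the ground-truth table).
#' @examples
#' img <- generate_limbal_image(128, 128, um_per_px = 0.2,
#'                              nuclei = data.frame(x_um = 12, y_um = 12,
#'                                                  diameter_um = 10))
#' @export
generate_limbal_image <- function(width_px, height_px, um_per_px,
                                  nuclei = data.frame(), background_noise_sd = 0,
                                  edge_um = 0.5, seed = NULL) {
  assert_that(is_count(width_px) && is_count(height_px),
              "image dimensions must be positive integers")
  assert_that(length(um_per_px) == 1L && is.finite(um_per_px) && um_per_px > 0,
              "'um_per_px' must be positive")
  assert_that(background_noise_sd >= 0, "'background_noise_sd' must be >= 0")
  nuclei <- as.data.frame(nuclei)
  if (nrow(nuclei) > 0L) {
    assert_that(all(c("x_um", "y_um", "diameter_um") %in% names(nuclei)),
                "'nuclei' needs x_um, y_um, diameter_um columns")
    assert_that(all(nuclei$diameter_um > 0), "nucleus diameters must be > 0")
    if (is.null(nuclei$intensity)) nuclei$intensity <- 0.8
    w_um <- width_px * um_per_px
    h_um <- height_px * um_per_px
    r <- nuclei$diameter_um / 2
    inside <- nuclei$x_um - r >= 0 & nuclei$x_um + r <= w_um &
      nuclei$y_um - r >= 0 & nuclei$y_um + r <= h_um
    assert_that(all(inside), "every nucleus must fit inside the frame")
  }

  img <- matrix(0, nrow = height_px, ncol = width_px)
  ## pixel centres in um
  for (k in seq_len(nrow(nuclei))) {
    d <- nuclei$diameter_um[k]
    reach_px <- ceiling((d / 2 + 4 * edge_um) / um_per_px)
    cx <- nuclei$x_um[k] / um_per_px + 0.5
    cy <- nuclei$y_um[k] / um_per_px + 0.5
    cols <- max(1L, floor(cx - reach_px)):min(width_px, ceiling(cx + reach_px))
    rows <- max(1L, floor(cy - reach_px)):min(height_px, ceiling(cy + reach_px))
    dx <- ((cols - 0.5) * um_per_px) - nuclei$x_um[k]
    dy <- ((rows - 0.5) * um_per_px) - nuclei$y_um[k]
    rr <- sqrt(outer(dy^2, dx^2, `+`))
    prof <- nuclei$intensity[k] * stats::pnorm((d / 2 - rr) / edge_um)
    img[rows, cols] <- pmax(img[rows, cols], prof)
  }
  if (background_noise_sd > 0) {
    img <- with_seed(seed, {
      img + matrix(stats::rnorm(length(img), 0, background_noise_sd),
                   nrow = height_px)
    })
  }
  img <- pmin(pmax(img, 0), 1)
  structure(list(image = img, um_per_px = um_per_px, nuclei = nuclei),
            class = "limbal_image")
}

#' Sample a non-touching nucleus layout with distractors
#'
#' Places `n_in` in-range nuclei and optional out-of-range distractors
#' (sub-nuclear specks and over-sized blobs) uniformly in the frame, with
#' rejection sampling so that no two objects touch (edge-to-edge gap of at
#' least `min_gap_um`). Returns a ground-truth table ready for
#' [generate_limbal_image()], with an `in_range` flag marking nuclei whose
#' diameters fall inside `in_range_um`.
#'
#' @param n_in number of in-range nuclei.
#' @param n_speck,n_blob numbers of under- and over-sized distractors.
#' @param width_um,height_um frame size in micrometres.
#' @param in_range_um diameter range (um) sampled for real nuclei; kept
#'   inside the detector's nominal 3-15 um window with margin by default.
#' @param speck_um,blob_um diameter ranges for distractors.
#' @param min_gap_um minimum edge-to-edge gap between objects.
#' @param seed integer seed.
#' @return Data frame `x_um`, `y_um`, `diameter_um`, `intensity`,
#'   `in_range`.
#' @export
random_nucleus_layout <- function(n_in, n_speck = 0L, n_blob = 0L,
                                  width_um, height_um,
                                  in_range_um = c(4, 13),
                                  speck_um = c(0.8, 1.5),
                                  blob_um = c(25, 30),
                                  min_gap_um = 2, seed = NULL) {
  assert_that(is_count(n_in, min = 0L) && is_count(n_speck, min = 0L) &&
                is_count(n_blob, min = 0L), "counts must be non-negative integers")
  with_seed(seed, {
    diam <- c(stats::runif(n_in, in_range_um[1L], in_range_um[2L]),
              stats::runif(n_speck, speck_um[1L], speck_um[2L]),
              stats::runif(n_blob, blob_um[1L], blob_um[2L]))
    in_range <- rep(c(TRUE, FALSE, FALSE), c(n_in, n_speck, n_blob))
    ## place largest first to keep rejection sampling efficient
    ord <- order(diam, decreasing = TRUE)
    diam <- diam[ord]
    in_range <- in_range[ord]
    xs <- ys <- numeric(0)
    for (k in seq_along(diam)) {
      r <- diam[k] / 2
      placed <- FALSE
      for (try in seq_len(5000L)) {
        x <- stats::runif(1L, r, width_um - r)
        y <- stats::runif(1L, r, height_um - r)
        if (length(xs) == 0L ||
            all(sqrt((xs - x)^2 + (ys - y)^2) >=
                  (diam[seq_along(xs)] / 2 + r + min_gap_um))) {
          placed <- TRUE
          break
        }
      }
      assert_that(placed,
                  "could not place all nuclei without contact; enlarge the frame")
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
    data.frame(x_um = xs, y_um = ys, diameter_um = diam,
               intensity = 0.8, in_range = in_range)
  })
}

#' Write / read a limbal image as 16-bit TIFF with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records the calibration and the ground-truth
#' nucleus table, so a written image round-trips completely.
#'
#' @param x a `limbal_image`.
#' @param path output TIFF path.
#' @return `path` invisibly (`write_limbal_image`); a `limbal_image`
#'   (`read_limbal_image`).
#' @export
write_limbal_image <- function(x, path) {
  assert_that(inherits(x, "limbal_image"), "'x' must be a limbal_image")
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to write TIFF images", call. = FALSE)
  }
  tiff::writeTIFF(x$image, path, bits.per.sample = 16L)
  sidecar <- list(um_per_px = x$um_per_px, nuclei = x$nuclei)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_limbal_image
#' @export
read_limbal_image <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("the 'tiff' package is required to read TIFF images", call. = FALSE)
  }
  img <- tiff::readTIFF(path)
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(image = img, um_per_px = sidecar$um_per_px,
                 nuclei = as.data.frame(sidecar$nuclei)),
            class = "limbal_image")
}
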
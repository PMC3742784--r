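# Calibration used throughout: 0.2 um/px, where the default 150-5000 px
# particle filter corresponds to ~3-15 um equivalent diameters.

test_that("a blank image yields no detections, without error", {
  img <- generate_limbal_image(64, 64, 0.2)
  expect_true(all(img$image == 0))
  expect_identical(nrow(detect_nuclei(img)), 0L)
})

test_that("a single in-range nucleus is detected once, at its position", {
  img <- generate_limbal_image(256, 256, 0.2,
                               nuclei = data.frame(x_um = 25, y_um = 30,
                                                   diameter_um = 10))
  det <- detect_nuclei(img)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_um - 25), 0.5)
  expect_lt(abs(det$y_um - 30), 0.5)
  expect_lt(abs(det$diameter_um - 10), 2)
})

test_that("out-of-range particles are filtered by size", {
  img <- generate_limbal_image(512, 512, 0.2,
                               nuclei = data.frame(
                                 x_um = c(20, 70), y_um = c(20, 70),
                                 diameter_um = c(1, 30)))
  expect_identical(nrow(detect_nuclei(img)), 0L)
})

test_that("nuclei fitting checks and parameter validation fire", {
  expect_error(generate_limbal_image(64, 64, 0.2,
                                     nuclei = data.frame(x_um = 1, y_um = 5,
                                                         diameter_um = 10)),
               "inside the frame")
  expect_error(generate_limbal_image(64, 64, -1), "um_per_px")
  expect_error(generate_limbal_image(64, 64, 0.2,
                                     nuclei = data.frame(x_um = 5, y_um = 5,
                                                         diameter_um = -2)),
               "diameters")
})

test_that("ground-truth layouts are recovered exactly on clean images", {
  lay <- random_nucleus_layout(25, n_speck = 5, n_blob = 5,
                               width_um = 102, height_um = 102, seed = 3)
  expect_identical(nrow(lay), 35L)
  expect_identical(sum(lay$in_range), 25L)
  img <- generate_limbal_image(512, 512, 0.2, nuclei = lay,
                               background_noise_sd = 0.02, seed = 4)
  det <- detect_nuclei(img)
  m <- match_detections(det, lay[lay$in_range, , drop = FALSE])
  expect_identical(m$tp, 25L)
  expect_identical(m$fp, 0L)
  expect_identical(m$fn, 0L)
})

test_that("diagonally touching components are one 8-connected particle", {
  # two diagonal pixel blocks joined only at a corner
  img <- matrix(0, 40, 40)
  img[10:19, 10:19] <- 1
  img[20:29, 20:29] <- 1
  det <- detect_nuclei(img, um_per_px = 1, min_size_px = 1,
                       max_size_px = 1e5, threshold = 0.5)
  expect_identical(nrow(det), 1L)
  expect_identical(det$area_px, 200L)
})

test_that("sampling-box membership is half-open on the far edges", {
  det <- data.frame(x_um = c(0, 339.999, 340, 100, 100),
                    y_um = c(0, 100, 100, 199.999, 200))
  expect_identical(count_in_box(det, c(0, 0)), 3L)
  expect_identical(count_in_box(data.frame(x_um = numeric(0),
                                           y_um = numeric(0)), c(0, 0)), 0L)
  expect_error(count_in_box(det, c(0, 0), image_dim_um = c(300, 300)),
               "exceeds")
})

test_that("box counts agree with generator ground truth", {
  lay <- random_nucleus_layout(12, width_um = 500, height_um = 300, seed = 6)
  inside <- lay$x_um >= 50 & lay$x_um < 390 & lay$y_um >= 50 & lay$y_um < 250
  cnt <- count_in_box(lay, c(50, 50), 340, 200)
  expect_identical(cnt, sum(inside))
})

test_that("per-circumference extrapolation follows the box-length scaling", {
  # circumference equal to one box length: identity
  d_mm <- 0.340 / pi
  expect_equal(per_circumference(1, rep(d_mm, 3)), 1)
  expect_equal(per_circumference(0, c(3, 3, 3)), 0)
  expect_equal(per_circumference(10, c(3, 3, 3)), 10 * pi * 3000 / 340)
  expect_error(per_circumference(1, c(3, -1, 3)), "positive")
  # boxes tiling the circumference exactly: recovers the true total
  n_boxes <- 8
  d_mm_tile <- n_boxes * 0.340 / pi
  per_box_counts <- c(3, 5, 2, 7, 4, 6, 1, 4)
  expect_equal(per_circumference(mean(per_box_counts), rep(d_mm_tile, 3)),
               sum(per_box_counts))
})

test_that("LRC indices normalise within experiment and sum to 100", {
  groups <- c("WT15", "Pax6_15", "WT30", "Pax6_30")
  recs <- do.call(rbind, Map(lrc_record,
                             eye_id = 1:4, group = groups,
                             experiment_id = "e1",
                             sector_counts = list(2, 2, 2, 6),
                             diameters_mm = list(c(3, 3, 3))))
  idx <- lrc_index(recs)
  expect_equal(sum(idx$index), 100, tolerance = 1e-9)
  expect_equal(sort(idx$index), sort(c(16 + 2 / 3, 16 + 2 / 3, 16 + 2 / 3, 50)),
               tolerance = 1e-9)

  equal <- do.call(rbind, Map(lrc_record, eye_id = 1:4, group = groups,
                              experiment_id = "e2",
                              sector_counts = list(5, 5, 5, 5),
                              diameters_mm = list(c(3, 3, 3))))
  expect_true(all(abs(lrc_index(equal)$index - 25) < 1e-9))
})

test_that("indices are invariant to per-experiment count rescaling", {
  groups <- c("WT15", "Pax6_15", "WT30", "Pax6_30")
  base <- do.call(rbind, Map(lrc_record, eye_id = 1:4, group = groups,
                             experiment_id = "e1",
                             sector_counts = list(c(2, 4), c(1, 3), c(6, 2),
                                                  c(5, 5)),
                             diameters_mm = list(c(3, 3.1, 2.9))))
  scaled <- base
  scaled$mean_per_box <- scaled$mean_per_box * 7
  scaled$per_circumference <- scaled$per_circumference * 7
  for (v in c("per_box", "per_circumference")) {
    expect_equal(lrc_index(base, variant = v)$index,
                 lrc_index(scaled, variant = v)$index, tolerance = 1e-12)
  }
})

test_that("experiments missing a group are excluded with a warning", {
  groups <- c("WT15", "Pax6_15", "WT30", "Pax6_30")
  full <- do.call(rbind, Map(lrc_record, eye_id = 1:4, group = groups,
                             experiment_id = "e1",
                             sector_counts = list(1, 2, 3, 4),
                             diameters_mm = list(3)))
  partial <- do.call(rbind, Map(lrc_record, eye_id = 5:7, group = groups[1:3],
                                experiment_id = "e2",
                                sector_counts = list(1, 2, 3),
                                diameters_mm = list(3)))
  expect_warning(idx <- lrc_index(rbind(full, partial), groups = groups),
                 "missing group")
  expect_identical(unique(idx$experiment_id), "e1")
  expect_error(suppressWarnings(lrc_index(partial, groups = groups)),
               "no experiment")
})

test_that("packing density counts nuclei in the 150 um box", {
  lay <- random_nucleus_layout(12, width_um = 140, height_um = 140,
                               min_gap_um = 1, seed = 8)
  img <- generate_limbal_image(750, 750, 0.2, nuclei = lay)
  expect_identical(packing_density(img, c(0, 0)), 12L)
  # a 150x150 box elsewhere in a larger empty region counts zero
  img2 <- generate_limbal_image(1600, 800, 0.2, nuclei = lay)
  expect_identical(packing_density(img2, c(170, 0)), 0L)
})

test_that("limbal images round-trip through 16-bit TIFF with JSON sidecar", {
  lay <- random_nucleus_layout(3, width_um = 50, height_um = 50, seed = 10)
  img <- generate_limbal_image(256, 256, 0.2, nuclei = lay)
  path <- withr::local_tempfile(fileext = ".tif")
  write_limbal_image(img, path)
  back <- read_limbal_image(path)
  expect_equal(back$um_per_px, 0.2)
  expect_equal(back$nuclei$x_um, lay$x_um, tolerance = 1e-6)
  expect_lt(max(abs(back$image - img$image)), 1 / 65535)
  expect_identical(nrow(detect_nuclei(back)), nrow(detect_nuclei(img)))
})
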
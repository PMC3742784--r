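test_that("patch extraction decomposes linear and circular sequences", {
  lin <- extract_patches(mosaic_sequence(c("+", "+", "-", "-", "-", "+")))
  expect_identical(sort(lin$len_pos), c(1L, 2L))
  expect_identical(lin$len_neg, 3L)
  expect_identical(lin$total_patches, 3L)

  circ <- extract_patches(mosaic_sequence(c("+", "-", "-", "+"),
                                          topology = "circular"))
  expect_identical(circ$len_pos, 2L)   # wrap-merged
  expect_identical(circ$len_neg, 2L)
  expect_identical(circ$total_patches, 2L)

  mono <- extract_patches(mosaic_sequence(rep("+", 7)))
  expect_identical(mono$len_pos, 7L)
  expect_identical(mono$n_patches_neg, 0L)
})

test_that("patch counts and lengths satisfy the conservation invariants", {
  for (seed in 1:25) {
    topo <- if (seed %% 2) "linear" else "circular"
    n <- sample(5:200, 1)
    ms <- generate_mosaic(n, p = stats::runif(1, 0.1, 0.9),
                          clone_len_mean = sample(1:6, 1),
                          topology = topo, seed = seed)
    ps <- extract_patches(ms)
    expect_identical(sum(ps$len_pos) + sum(ps$len_neg), n)
    if (ps$n_patches_pos > 0L && ps$n_patches_neg > 0L) {
      diff <- ps$n_patches_pos - ps$n_patches_neg
      if (topo == "linear") {
        expect_true(abs(diff) <= 1L)
      } else {
        expect_identical(diff, 0L)
      }
    }
  }
})

test_that("clones per patch follows 1/(1-p) and rejects the degenerate p", {
  expect_equal(clones_per_patch(0), 1)
  expect_equal(clones_per_patch(0.5), 2)
  expect_equal(clones_per_patch(0.9), 10)
  expect_error(clones_per_patch(1), "undefined")
  expect_error(clones_per_patch(-0.1), "proportion")
  expect_error(clones_per_patch(1.1), "proportion")
})

test_that("clones per patch matches exact ring enumeration (ratio of expectations)", {
  en <- enumerate_ring(10, 0.5)
  expect_equal(en$e_pos / en$e_runs, clones_per_patch(0.5), tolerance = 1e-12)
  en <- enumerate_ring(8, 0.3)
  expect_equal(en$e_pos / en$e_runs, clones_per_patch(0.3), tolerance = 1e-12)
})

test_that("corrected mean patch length divides by the clone-per-patch factor", {
  expect_equal(corrected_mean_patch_length(4, p = 0.5), 2)
  expect_equal(corrected_mean_patch_length(3.7, p = 0), 3.7)  # identity at p=0
  ps <- extract_patches(mosaic_sequence(c("-", "-", "-", "-")))
  expect_error(corrected_mean_patch_length(ps), "undefined")
})

test_that("corrected mean patch length recovers the generating clone length", {
  ms <- generate_mosaic(1e5, p = 0.5, clone_len_mean = 5, seed = 42)
  cmpl <- corrected_mean_patch_length(extract_patches(ms))
  expect_lt(abs(cmpl - 5) / 5, 0.05)
})

test_that("minority median uses the rarer population with the documented tie-break", {
  # p < 0.5: minority is the positive population
  ms <- mosaic_sequence(c("+", "-", "-", "+", "+", "-", "-", "-", "+", "-"))
  s <- extract_patches(ms)
  expect_lt(s$p, 0.5)
  m <- median_minority_patch_length(s)
  expect_identical(attr(m, "population"), "pos")
  expect_equal(as.numeric(m), s$median_len_pos)

  # p = 0.5 with equal patch counts: negative population by convention
  s2 <- extract_patches(mosaic_sequence(c("+", "+", "-", "-")))
  m2 <- median_minority_patch_length(s2)
  expect_identical(attr(m2, "population"), "neg")

  # p = 0.5, positive population has fewer patches -> positive chosen
  s3 <- extract_patches(mosaic_sequence(c("-", "-", "+", "+", "+", "+",
                                          "-", "-")))
  expect_equal(s3$p, 0.5, tolerance = 1e-12)
  expect_identical(c(s3$n_patches_pos, s3$n_patches_neg), c(1L, 2L))
  m3 <- median_minority_patch_length(s3)
  expect_identical(attr(m3, "population"), "pos")
  expect_equal(as.numeric(m3), 4)

  # odd-count median
  s4 <- extract_patches(mosaic_sequence(c("-", "+", "-", "-", "+", "+", "-",
                                          "-", "-", "-", "+", "+", "+", "+",
                                          "-")))
  expect_identical(sort(s4$len_pos), c(1L, 2L, 4L))
  expect_equal(as.numeric(median_minority_patch_length(s4)), 2)

  expect_error(median_minority_patch_length(
    extract_patches(mosaic_sequence(rep("+", 5)))), "both populations")
})

test_that("corrected stripe number applies 1/(1-p) and guards monochrome p", {
  expect_equal(corrected_stripe_number(0, 0.5), 0)
  expect_equal(corrected_stripe_number(10, 0.5), 20)
  expect_error(corrected_stripe_number(10, 0), "undefined")
  expect_error(corrected_stripe_number(10, 1), "undefined")
  expect_error(corrected_stripe_number(-1, 0.5), "non-negative")
})

test_that("corrected stripe number recovers labelled clone count on the enumeration oracle", {
  en <- enumerate_ring(12, 0.4)
  # E[observed stripes] = K p (1-p); the correction recovers K p
  expect_equal(en$e_runs, 12 * 0.4 * 0.6, tolerance = 1e-12)
  expect_equal(corrected_stripe_number(en$e_runs, 0.4), 12 * 0.4,
               tolerance = 1e-12)
  # ... and the per-mm normalisation composes with it (d = 3 mm)
  expect_equal(stripes_per_mm(corrected_stripe_number(en$e_runs, 0.4), pi * 3),
               4.8 / (3 * pi), tolerance = 1e-12)
})

test_that("total clone number extension rescales by p", {
  expect_equal(total_clone_number(12 * 0.4 * 0.6, 0.4), 12, tolerance = 1e-12)
})

test_that("per-mm normalisation validates the circumference", {
  expect_equal(stripes_per_mm(20, 10), 2)
  expect_equal(stripes_per_mm(0, 5), 0)
  expect_error(stripes_per_mm(20, 0), "positive")
  expect_error(stripes_per_mm(20, -3), "positive")
})

test_that("uncorrected patch length grows with p while the corrected one does not", {
  cmpl <- numeric(0)
  raw <- numeric(0)
  for (p in c(0.3, 0.5, 0.7)) {
    ms <- generate_mosaic(1e5, p = p, clone_len_mean = 4,
                          seed = 100 + round(10 * p))
    s <- extract_patches(ms)
    raw <- c(raw, s$mean_len_pos)
    cmpl <- c(cmpl, corrected_mean_patch_length(s))
  }
  expect_true(all(diff(raw) > 0))               # raw length increases with p
  expect_lt(max(abs(cmpl - 4)) / 4, 0.05)       # corrected stays at clone length
})

test_that("ring stripe counting uses the boundary convention", {
  # wrap-around joins the flanking positive cells into one run
  expect_identical(count_positive_runs(c(TRUE, TRUE, FALSE, TRUE), "circular"), 1L)
  expect_identical(count_positive_runs(c(TRUE, FALSE, TRUE, FALSE), "circular"), 2L)
  expect_identical(count_positive_runs(rep(TRUE, 5), "circular"), 0L)
  expect_identical(count_positive_runs(rep(TRUE, 5), "linear"), 1L)
  expect_identical(count_positive_runs(c(FALSE, TRUE, TRUE, FALSE), "linear"), 1L)
  # agrees with the loop oracle on random rings
  for (seed in 1:20) {
    set.seed(seed)
    x <- stats::rbinom(sample(3:30, 1), 1, stats::runif(1)) == 1
    expect_identical(count_positive_runs(x, "circular"), loop_ring_runs(x))
  }
})

test_that("per-eye stripe tables gain corrected statistics from the shipped fixture", {
  path <- system.file("extdata", "synthetic_stripe_counts.tsv",
                      package = "corneamosaic")
  tab <- corrected_stripe_table(read_tsv(path))
  expect_identical(nrow(tab), 6L)
  # row-wise agreement with the scalar operations
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$corrected_stripes[i],
                 tab$observed_stripes[i] / (1 - tab$p[i]))
    circ <- pi * mean(as.numeric(tab[i, grep("^diameter", names(tab))][1:3]))
    expect_equal(tab$corrected_stripes_per_mm[i],
                 tab$corrected_stripes[i] / circ)
  }
  # a supplied group-level p overrides the per-eye column
  tab2 <- corrected_stripe_table(read_tsv(path), p_group = 0.5)
  expect_equal(tab2$corrected_stripes, tab2$observed_stripes * 2)
})

test_that("the shipped mosaic section round-trips and summarises", {
  path <- system.file("extdata", "synthetic_mosaic_section.tsv",
                      package = "corneamosaic")
  ms <- read_mosaic_tsv(path)
  expect_s3_class(ms, "mosaic_sequence")
  s <- extract_patches(ms)
  expect_identical(s$total_cells, 72L)
  expect_identical(sum(s$len_pos) + sum(s$len_neg), 72L)
})
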
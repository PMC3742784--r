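test_that("six-region partition splits exact multiples evenly", {
  tab <- partition_regions(layer_count_table(basal_pos = rep(0L, 12)))
  expect_identical(tab$region,
                   rep(c("P", "I", "C", "C", "I", "P"), each = 2))
  tab6 <- partition_regions(layer_count_table(basal_pos = rep(0L, 6)))
  expect_identical(tab6$group, 1:6)
})

test_that("non-divisible diameters use symmetric largest-remainder allocation", {
  tab13 <- partition_regions(layer_count_table(basal_pos = rep(0L, 13)))
  expect_identical(as.integer(table(tab13$group)), c(3L, 2L, 2L, 2L, 2L, 2L))
  # exhaustive: group sizes never differ by more than one, n = 6..30
  for (n in 6:30) {
    tab <- partition_regions(layer_count_table(basal_pos = rep(0L, n)))
    sizes <- table(tab$group)
    expect_lte(max(sizes) - min(sizes), 1L)
    expect_identical(sum(sizes), as.integer(n))
    # extras land on the outer groups first, symmetrically
    extras <- which(sizes == max(sizes))
    if (max(sizes) > min(sizes)) {
      priority <- c(1L, 6L, 2L, 5L, 3L, 4L)
      expect_setequal(extras, priority[seq_len(n %% 6L)])
    }
  }
  expect_error(partition_regions(layer_count_table(basal_pos = rep(0L, 5))),
               "at least 6")
})

test_that("labelling indices are the stated percentages", {
  tab <- data.frame(position = 1:6,
                    region = c("P", "I", "C", "C", "I", "P"),
                    basal_pos = rep(c(10L, 0L), 3),
                    basal_total = c(49L, 33L, 33L, 33L, 33L, 17L),
                    suprabasal_pos = rep(c(5L, 5L), 3),
                    suprabasal_total = rep(100L, 6))
  # whole-eye check against direct ratios
  li <- labelling_indices(tab)
  w <- li[li$region == "whole", ]
  expect_equal(w$BLI, 100 * sum(tab$basal_pos) / sum(tab$basal_total))
  expect_equal(w$SLI, 100 * sum(tab$suprabasal_pos) / sum(tab$suprabasal_total))
  expect_equal(w$ASLI, 100 * sum(tab$suprabasal_pos) / sum(tab$basal_total))

  simple <- data.frame(position = 1, region = "C",
                       basal_pos = 10L, basal_total = 100L,
                       suprabasal_pos = 20L, suprabasal_total = 200L)
  li2 <- labelling_indices(simple)
  w2 <- li2[li2$region == "whole", ]
  expect_equal(unname(unlist(w2[c("BLI", "SLI", "ASLI")])), c(10, 10, 20))
})

test_that("ASLI/SLI equals the suprabasal-to-basal cell ratio (algebraic identity)", {
  set.seed(14)
  for (i in 1:30) {
    bt <- sample(50:400, 6)
    st <- sample(50:600, 6)
    tab <- data.frame(position = 1:6, region = c("P", "I", "C", "C", "I", "P"),
                      basal_pos = vapply(bt, function(n) sample.int(n, 1), 1L),
                      basal_total = bt,
                      suprabasal_pos = vapply(st, function(n) sample.int(n, 1), 1L),
                      suprabasal_total = st)
    li <- labelling_indices(tab)
    w <- li[li$region == "whole", ]
    expect_equal(w$ASLI / w$SLI, sum(st) / sum(bt), tolerance = 1e-12)
  }
})

test_that("whole-eye indices are the count-weighted pooling, not the unweighted mean", {
  tab <- data.frame(position = 1:6, region = c("P", "I", "C", "C", "I", "P"),
                    basal_pos = c(30L, 1L, 1L, 1L, 1L, 0L),
                    basal_total = c(100L, 10L, 10L, 10L, 10L, 10L),
                    suprabasal_pos = c(10L, 0L, 0L, 0L, 0L, 0L),
                    suprabasal_total = c(100L, 10L, 10L, 10L, 10L, 10L))
  li_w <- labelling_indices(tab, pooling = "weighted")
  li_u <- labelling_indices(tab, pooling = "unweighted")
  p_w <- li_w[li_w$region == "P", "BLI"]
  p_u <- li_u[li_u$region == "P", "BLI"]
  expect_equal(p_w, 100 * 30 / 110)            # pooled counts
  expect_equal(p_u, mean(c(30, 0)))            # mean of the two group indices
  expect_false(isTRUE(all.equal(p_w, p_u)))
})

test_that("zero denominators flag the region as undefined", {
  tab <- data.frame(position = 1:6, region = c("P", "I", "C", "C", "I", "P"),
                    basal_pos = 0L, basal_total = 10L,
                    suprabasal_pos = 0L,
                    suprabasal_total = c(0L, 0L, 5L, 5L, 5L, 0L))
  li <- labelling_indices(tab)
  expect_false(li$defined[li$region == "P"])
  expect_true(is.na(li$SLI[li$region == "P"]))
  expect_true(li$defined[li$region == "C"])
})

test_that("suprabasal fraction follows the SLI/(SLI+BLI) formula", {
  expect_equal(suprabasal_fraction(10, 10), 50)
  expect_equal(suprabasal_fraction(0, 25), 0)
  expect_equal(suprabasal_fraction(40, 60), 40)
  expect_warning(out <- suprabasal_fraction(0, 0), "undefined")
  expect_true(is.na(out))
})

test_that("turnover time is the first post-peak sub-threshold chase time", {
  tc <- data.frame(time_days = c(0, 3, 7, 14), labelled = c(100, 300, 50, 5))
  et <- estimate_turnover_time(tc, threshold = 0.1)
  expect_false(et$censored)
  expect_equal(et$turnover_days, 14)
  expect_equal(et$peak_time, 3)

  rising <- data.frame(time_days = c(0, 3, 7, 14),
                       labelled = c(10, 40, 80, 120))
  et2 <- estimate_turnover_time(rising)
  expect_true(et2$censored)
  expect_true(is.na(et2$turnover_days))

  expect_error(estimate_turnover_time(
    data.frame(time_days = c(0, 1), labelled = c(5, 1))), "3 time points")
})

test_that("cohort-simulated turnover under default rates is at most 14 days", {
  tc <- generate_cohort_timecourse(
    cohort_params(transfer_rate = 0.3, transit_days = 1, n_layers = 4),
    times = c(1 / 6, 1, 3, 7, 14), seed = 77)
  et <- estimate_turnover_time(tc)
  expect_false(et$censored)
  expect_lte(et$turnover_days, 14)
})
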
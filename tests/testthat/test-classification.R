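test_that("disk dilation obeys the distance predicate", {
  m <- matrix(FALSE, 21, 21); m[11, 11] <- TRUE
  expect_identical(dilate_mask(m, 0), m)
  d4 <- dilate_mask(m, 4)
  o <- -10:10
  pred <- outer(o, o, function(a, b) a^2 + b^2 <= 16)
  expect_identical(unname(d4), pred)
  # extensivity on random masks
  set.seed(5)
  for (r in c(1, 3)) {
    m <- matrix(runif(400) < 0.2, 20, 20)
    expect_true(all(m <= dilate_mask(m, r)))
  }
})

make_two_segment_labels <- function() {
  lab <- matrix(0L, 20, 40)
  lab[3:18, 3:18] <- 1L
  lab[3:18, 23:38] <- 2L
  lab
}

test_that("threshold rule assigns classes from dilated fractions", {
  lab <- make_two_segment_labels()
  # cell 1: f_ryr just above 0.15 after dilation; no dextran anywhere
  ryr <- matrix(FALSE, 20, 40)
  # single pixels dilate to disks of 49 px (r=4); segment area 256
  ryr[8, 8] <- TRUE                      # 49/256 = 0.19 >= 0.15
  dx <- matrix(FALSE, 20, 40)
  rec <- classify_cells(lab, ryr, dx, pixel_size_um = 0.1)
  expect_equal(as.character(rec$class), c("live", "double_negative"))
  expect_gte(rec$f_ryr[1], 0.15)
  expect_equal(rec$f_dextran, c(0, 0))
  # exact boundary: fraction exactly at the threshold counts as positive
  rec2 <- classify_cells(lab, ryr, dx, theta_ryr = rec$f_ryr[1],
                         pixel_size_um = 0.1)
  expect_equal(as.character(rec2$class)[1], "live")
})

test_that("empty masks classify every segment double-negative", {
  lab <- make_two_segment_labels()
  none <- matrix(FALSE, 20, 40)
  rec <- classify_cells(lab, none, none)
  expect_true(all(rec$class == "double_negative"))
  expect_equal(nrow(classify_cells(matrix(0L, 5, 5),
                                   matrix(FALSE, 5, 5),
                                   matrix(FALSE, 5, 5))), 0)
})

test_that("classes partition the records and respect threshold monotonicity", {
  an <- analysis_200()
  rec <- an$records
  expect_false(any(is.na(rec$class)))
  expect_equal(sum(table(rec$class)), nrow(rec))
  pos_counts <- vapply(c(0.05, 0.15, 0.3, 0.6), function(th) {
    r <- classify_cells(an$labels, an$masks$RyR, an$masks$dextran,
                        theta_ryr = th)
    sum(r$class %in% c("live", "double_positive"))
  }, numeric(1))
  expect_true(all(diff(pos_counts) <= 0))
})

test_that("classification recovers ground-truth viability states", {
  an <- analysis_200()
  agree <- as.character(an$records$class) == an$truth_state
  expect_gte(mean(agree), 0.9)
})

test_that("image summary reports union-referenced overlap", {
  # cells A,B,C RyR-positive; C,D dextran-positive -> DP fraction 1/4
  rec <- data.frame(
    cell_id = 1:5,
    f_ryr = c(0.5, 0.5, 0.5, 0.0, 0.0),
    f_dextran = c(0.0, 0.0, 0.5, 0.5, 0.0),
    class = factor(c("live", "live", "double_positive", "dead",
                     "double_negative"),
                   levels = c("live", "dead", "double_positive",
                              "double_negative")))
  lab <- matrix(0L, 4, 10)
  for (k in 1:5) lab[, (2 * k - 1):(2 * k)] <- k
  none <- matrix(FALSE, 4, 10)
  s <- summarize_image(rec, lab, none, none)
  expect_equal(s$double_positive_cell_fraction, 0.25)
  # no double-positives at all
  rec$class <- factor(rep(c("live", "dead"), c(3, 2)),
                      levels = levels(rec$class))
  s2 <- summarize_image(rec, lab, none, none)
  expect_equal(s2$double_positive_cell_fraction, 0)
})

test_that("Pearson correlation hits the bounds for identical channels", {
  lab <- matrix(1L, 5, 5)
  rec <- data.frame(cell_id = 1, f_ryr = 1, f_dextran = 0,
                    class = factor("live", levels = CELL_CLASSES_test()))
  ch <- matrix(seq_len(25), 5, 5)
  none <- matrix(FALSE, 5, 5)
  s_pos <- summarize_image(rec, lab, none, none, ch, ch)
  s_neg <- summarize_image(rec, lab, none, none, ch, -ch)
  expect_equal(s_pos$pearson_r, 1)
  expect_equal(s_neg$pearson_r, -1)
})

test_that("exclusive-state slices show near-zero stain overlap", {
  an <- analysis_excl()
  s <- summarize_image(an$records, an$labels, an$masks$RyR, an$masks$dextran)
  expect_lt(s$double_positive_pixel_fraction, 0.05)
})
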
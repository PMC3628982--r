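ref <- reference_gradient_tables()

test_that("per-day log2 fold change matches the published columns", {
  # strongly dorsal TBX5 transcript, day 4 and day 8
  expect_equal(log2_fold_change(4.549, 0.272), 4.062, tolerance = 0.01)
  expect_equal(log2_fold_change(12.007, 0.248), 5.595, tolerance = 0.01)
  expect_equal(log2_fold_change(3, 3), 0)
  # one-sided zero is undefined
  expect_true(is.na(log2_fold_change(4.070, 0)))
  expect_true(is.na(log2_fold_change(0, 2)))
  expect_error(log2_fold_change(-1, 2), "non-negative")
  # full tables: every defined printed per-day value within +/- 0.02
  for (tab in ref) {
    fc4 <- log2_fold_change(tab$d4, tab$v4)
    fc8 <- log2_fold_change(tab$d8, tab$v8)
    expect_equal(is.na(fc4), is.na(tab$log2fc4))
    expect_equal(is.na(fc8), is.na(tab$log2fc8))
    expect_true(all(abs(fc4 - tab$log2fc4) < 0.02, na.rm = TRUE))
    expect_true(all(abs(fc8 - tab$log2fc8) < 0.02, na.rm = TRUE))
  }
})

test_that("combined statistic is log2 of summed dorsal over summed ventral", {
  expect_equal(combined_log2_fold_change(4.549, 12.007, 0.272, 0.248),
               4.990, tolerance = 0.02)
  expect_equal(combined_log2_fold_change(0.141, 0.066, 5.052, 7.897),
               -5.965, tolerance = 0.02)
  expect_equal(combined_log2_fold_change(2, 3, 2, 3), 0)
  # defined despite a single zero day, undefined when a whole side is zero
  expect_false(is.na(combined_log2_fold_change(0, 0.124, 2.2, 3.177)))
  expect_true(is.na(combined_log2_fold_change(0, 0, 2.2, 3.177)))
  # every defined printed combined value of both tables within +/- 0.02,
  # and the undefined placeholders line up exactly
  for (tab in ref) {
    fc <- combined_log2_fold_change(tab$d4, tab$d8, tab$v4, tab$v8)
    expect_equal(is.na(fc), is.na(tab$log2fc))
    expect_true(all(abs(fc - tab$log2fc) < 0.02, na.rm = TRUE))
  }
})

test_that("dorsoventral classification follows the exclusivity and fold rules", {
  cuts <- reference_cutoffs()
  # zero ventral reads both days, dorsal expressed both days -> exclusive
  expect_equal(classify_dorsoventral(0, 2.987, 0, 1.296, cuts),
               "dorsal_exclusive")
  # all four above thresholds, both per-day folds >= 2 -> dorsal_up
  expect_equal(classify_dorsoventral(0.272, 4.549, 0.248, 12.007, cuts),
               "dorsal_up")
  # equal expression -> unclassified
  expect_equal(classify_dorsoventral(5, 5, 5, 5, cuts), "unclassified")
  # one zero-ventral day is not exclusive but still passes the fold rule
  expect_equal(classify_dorsoventral(0, 4.070, 0.193, 2.527, cuts),
               "dorsal_up")
  # sub-cutoff dorsal day blocks dorsal_up
  expect_equal(classify_dorsoventral(0.1, 1.0, 0.1, 5, cuts), "unclassified")
  # require_both_sides demands ventral expression too
  expect_equal(classify_dorsoventral(0.272, 4.549, 0.248, 12.007, cuts,
                                     require_both_sides = TRUE),
               "unclassified")
  expect_error(classify_dorsoventral(1, 2, 1, 2, cuts, fold_threshold = 1),
               "exceed 1")
})

test_that("exactly 3 transcripts of the dorsal reference table are exclusive", {
  d <- ref$dorsal
  cl <- classify_dorsoventral(d$v4, d$d4, d$v8, d$d8, reference_cutoffs())
  expect_equal(sum(cl == "dorsal_exclusive"), 3)
  expect_setequal(d$transcript_id[cl == "dorsal_exclusive"],
                  c("transcript114225", "transcript89311", "transcript53947"))
})

test_that("temporal classification needs both sides past the strict fold", {
  cuts <- cutoff_set(1, 1, 1, 1)
  expect_equal(classify_temporal(8, 10, 1, 1, cuts), "day4_up")
  expect_equal(classify_temporal(1.5, 10, 1, 1, cuts), "neither")
  # zero denominator counts as an infinite fold
  expect_equal(classify_temporal(8, 10, 0, 1, cuts), "day4_up")
  # strictness: exactly 2-fold does not pass
  expect_equal(classify_temporal(4, 4, 2, 2, cuts), "neither")
  expect_equal(classify_temporal(2, 2, 5, 5, cuts), "day8_up")
})

test_that("swapping dorsal and ventral negates folds and mirrors classes", {
  set.seed(33)
  n <- 300
  v4 <- rexp(n); d4 <- rexp(n); v8 <- rexp(n); d8 <- rexp(n)
  zero <- sample(n, 30)
  v4[zero[1:10]] <- 0; d4[zero[11:20]] <- 0; v8[zero[21:30]] <- 0
  cuts <- cutoff_set(0.2, 0.2, 0.2, 0.2)
  fc <- combined_log2_fold_change(d4, d8, v4, v8)
  fc_sw <- combined_log2_fold_change(v4, v8, d4, d8)
  expect_equal(fc_sw, -fc)
  expect_equal(log2_fold_change(v4, d4), -log2_fold_change(d4, v4))
  cl <- classify_dorsoventral(v4, d4, v8, d8, cuts)
  cl_sw <- classify_dorsoventral(d4, v4, d8, v8, cuts)
  flip <- c(dorsal_up = "ventral_up", ventral_up = "dorsal_up",
            dorsal_exclusive = "ventral_exclusive",
            ventral_exclusive = "dorsal_exclusive",
            unclassified = "unclassified")
  expect_equal(cl_sw, unname(flip[cl]))
})

test_that("raising the fold threshold never grows the up-regulated sets", {
  set.seed(44)
  n <- 300
  v4 <- rexp(n); d4 <- rexp(n); v8 <- rexp(n); d8 <- rexp(n)
  cuts <- cutoff_set(0.1, 0.1, 0.1, 0.1)
  prev_up <- NULL
  for (thr in c(1.5, 2, 4, 8)) {
    cl <- classify_dorsoventral(v4, d4, v8, d8, cuts, fold_threshold = thr)
    up <- which(cl %in% c("dorsal_up", "ventral_up"))
    if (!is.null(prev_up)) expect_true(all(up %in% prev_up))
    prev_up <- up
    clt <- classify_temporal(v4, d4, v8, d8, cuts, fold_threshold = thr)
  }
})

test_that("gradient table ranks by combined fold with exclusives on top", {
  cuts <- cutoff_set(0.5, 0.5, 0.5, 0.5)
  expr <- data.frame(
    transcript_id = c("mid", "top", "excl", "vent", "allzero"),
    v4 = c(1, 0.5, 0, 8, 0), d4 = c(4, 8, 3, 1, 0),
    v8 = c(1, 0.5, 0, 8, 0), d8 = c(4, 8, 3, 1, 0),
    stringsAsFactors = FALSE)
  gt <- build_gradient_table(expr, cuts)
  expect_equal(gt$transcript_id,
               c("excl", "top", "mid", "vent", "allzero"))
  expect_equal(gt$dv_class[1], "dorsal_exclusive")
  expect_true(is.na(gt$log2fc[1]))
  # empty input gives an empty, well-formed table
  empty <- build_gradient_table(expr[0, ], cuts)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("log2fc", "dv_class") %in% names(empty)))
  # planted strongest dorsal transcript ranks first among defined folds
  expect_gt(gt$log2fc[2], gt$log2fc[3])
})
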
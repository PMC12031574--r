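test_that("the descriptor sums correlation weights with multiplicity", {
  wt <- weight_table(c("C..........." = 0.5, "C...C......." = 1.0),
                     threshold_T = 1L, epochs_N = 1L)
  expect_equal(dcw("CC", wt), 2 * 0.5 + 1.0)
  # unknown and blocked attributes contribute zero
  wt0 <- weight_table(c("N..........." = 2), blocked = "C...........",
                      threshold_T = 1L, epochs_N = 1L)
  expect_equal(dcw("CC", wt0), 0)
  expect_equal(dcw("CC", weight_table(threshold_T = 1L, epochs_N = 1L)), 0)
})

test_that("the semi-correlation line is ordinary least squares", {
  expect_equal(semicorr_line(c(0, 1), c(0L, 1L)), c(c0 = 0, c1 = 1))
  expect_equal(semicorr_line(c(0, 0, 1, 1), c(0L, 1L, 0L, 1L)),
               c(c0 = 0.5, c1 = 0))
  # against the standard linear-model fitter on random data
  set.seed(21)
  d <- rnorm(40); y <- rbinom(40, 1, 0.5)
  ref <- unname(coef(lm(y ~ d)))
  expect_equal(unname(semicorr_line(d, y)), ref, tolerance = 1e-12)
  expect_error(semicorr_line(c(2, 2, 2), c(0L, 1L, 0L)), "degenerate")
  expect_error(semicorr_line(1, 1L), "at least two")
})

test_that("classification thresholds inclusively at 0.5", {
  expect_identical(classify_activity(c(0.5, 0.4999, -3.2, 1.7)),
                   c(1L, 0L, 0L, 1L))
  expect_error(classify_activity(NaN), "finite")
  expect_error(classify_activity(0.2, threshold = 0), "strictly between")
  # monotone non-decreasing in the model value
  v <- sort(runif(50, -1, 2))
  expect_true(!is.unsorted(classify_activity(v)))
})

test_that("confusion matrices use the active-as-positive convention", {
  cm <- confusion_matrix(c(1L, 0L), c(1L, 0L))
  expect_identical(cm[c("tp", "tn", "fp", "fn")],
                   list(tp = 1L, tn = 1L, fp = 0L, fn = 0L))
  cm <- confusion_matrix(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L))
  expect_identical(cm[c("tp", "tn", "fp", "fn")],
                   list(tp = 0L, tn = 0L, fp = 2L, fn = 2L))
  expect_error(confusion_matrix(c(1L, 2L), c(0L, 1L)), "0/1")
})

test_that("metrics reproduce published statistics from raw counts", {
  m <- classification_metrics(structure(list(tp = 86L, tn = 85L, fp = 12L,
                                             fn = 7L),
                                        class = "confusion_matrix"))
  expect_equal(m$acc, 171 / 190)
  expect_equal(round(m$mcc, 4), 0.8012, tolerance = 5e-4)
  m2 <- classification_metrics(structure(list(tp = 79L, tn = 73L, fp = 23L,
                                              fn = 17L),
                                         class = "confusion_matrix"))
  expect_equal(round(m2$mcc, 4), 0.5845, tolerance = 5e-4)
  # a perfect classifier scores 1 everywhere
  mp <- classification_metrics(confusion_matrix(rep(c(1L, 0L), 5),
                                                rep(c(1L, 0L), 5)))
  expect_equal(unlist(mp[c("sens", "spec", "acc", "mcc")]),
               c(sens = 1, spec = 1, acc = 1, mcc = 1))
})

test_that("degenerate confusion matrices are flagged, not fatal", {
  m <- classification_metrics(confusion_matrix(c(1L, 1L), c(1L, 1L)))
  expect_true(m$degenerate)
  expect_identical(m$mcc, 0)
  expect_true(is.nan(m$spec))
})

test_that("MCC stays in [-1, 1], is swap-symmetric and matches the
           correlation of the underlying 0/1 vectors", {
  set.seed(31)
  for (i in 1:1000) {
    cm <- random_confusion()
    if (cm$tp + cm$tn + cm$fp + cm$fn == 0) next
    m <- classification_metrics(structure(cm, class = "confusion_matrix"))
    expect_gte(m$mcc, -1); expect_lte(m$mcc, 1)
    expect_gte(m$acc, 0); expect_lte(m$acc, 1)
    swapped <- classification_metrics(structure(
      list(tp = cm$tn, tn = cm$tp, fp = cm$fn, fn = cm$fp),
      class = "confusion_matrix"))
    expect_equal(swapped$acc, m$acc)
    expect_equal(swapped$mcc, m$mcc)
    if (!m$degenerate && i <= 200) {
      expect_equal(m$mcc, mcc_by_correlation(cm$tp, cm$tn, cm$fp, cm$fn),
                   tolerance = 1e-12)
    }
  }
})

test_that("model JSON serialization round-trips bit-exactly", {
  wt <- weight_table(stats::setNames(c(pi, -exp(1), 1 / 3),
                                     c("C...........", "N...C.......",
                                       "O...C...C...")),
                     blocked = "S...........",
                     threshold_T = 3L, epochs_N = 15L)
  model <- semicorr_model(0.3787, 0.04072, wt)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(model, path)
  back <- read_model(path)
  expect_identical(back$c0, model$c0)
  expect_identical(back$c1, model$c1)
  expect_identical(back$weight_table$weights, model$weight_table$weights)
  expect_identical(back$weight_table$blocked, model$weight_table$blocked)
  expect_identical(back$weight_table$threshold_T, 3L)
  expect_identical(back$weight_table$epochs_N, 15L)
})
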
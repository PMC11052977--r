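test_that("prediction_set validates its inputs", {
  expect_error(prediction_set(c(1, 0), c(0.2, 0.9, 0.1), c("a", "b")),
               "length")
  expect_error(prediction_set(c(1, 2), c(0.2, 0.9), c("a", "b")),
               "binary")
  expect_error(prediction_set(c(1, 0), c(0.2, 1.9), c("a", "b")),
               "0, 1")
  p <- prediction_set(c(1, 0), c(0.9, 0.2), c("a", "b"))
  expect_identical(p$y_pred, c(1L, 0L))  # default 0.5 threshold
})

test_that("per-group confusion counts are exact", {
  p <- prediction_set(
    y_true = c(1, 0, 1, 0), y_score = c(0.9, 0.8, 0.1, 0.2),
    group = rep("g", 4)
  )
  cm <- confusion_by_group(p)
  expect_equal(cm$tp, 1L)
  expect_equal(cm$fp, 1L)
  expect_equal(cm$fn, 1L)
  expect_equal(cm$tn, 1L)

  withr::with_seed(1, {
    q <- random_prediction_set(150, 3)
  })
  cmq <- confusion_by_group(q)
  expect_equal(sum(cmq$tp + cmq$tn + cmq$fp + cmq$fn), 150L)
  perfect <- prediction_set(q$y_true, q$y_score, q$group,
                            y_pred = q$y_true)
  cmp <- confusion_by_group(perfect)
  expect_true(all(cmp$fp == 0L & cmp$fn == 0L))
})

test_that("demographic parity difference is the worst pairwise gap", {
  mk <- function(rates, n_per = 10L) {
    prediction_set(
      y_true = rep(0L, n_per * length(rates)),
      y_score = rep(0.5, n_per * length(rates)),
      group = rep(letters[seq_along(rates)], each = n_per),
      y_pred = unlist(lapply(rates, function(r)
        rep(c(1L, 0L), c(round(r * n_per), n_per - round(r * n_per)))))
    )
  }
  expect_equal(demographic_parity_difference(mk(c(0.8, 0.4))), 0.4)
  expect_equal(demographic_parity_difference(mk(c(0.2, 0.5, 0.9))), 0.7)
  expect_equal(demographic_parity_difference(mk(c(0.3, 0.3, 0.3))), 0)
  expect_error(demographic_parity_difference(mk(0.5)), "two groups")

  # invariance under group relabeling
  p <- mk(c(0.2, 0.6, 0.7))
  q <- p
  q$group <- chartr("abc", "zyx", p$group)
  expect_equal(demographic_parity_difference(p),
               demographic_parity_difference(q))
})

test_that("error-rate parity handles defined and degenerate groups", {
  p <- prediction_set(
    y_true = c(0, 0, 0, 0, 1, 1),
    y_score = c(0.9, 0.1, 0.2, 0.3, 0.8, 0.2),
    group = rep("a", 6)
  )
  p2 <- prediction_set(
    y_true = c(1, 1, 1), y_score = c(0.9, 0.1, 0.8), group = rep("b", 3)
  )
  both <- prediction_set(c(p$y_true, p2$y_true), c(p$y_score, p2$y_score),
                         c(p$group, p2$group))
  expect_warning(res <- error_rate_parity(both), "undefined FPR")
  expect_equal(res$rates$fpr[res$rates$group == "a"], 0.25)  # 1/(1+3)
  expect_true(is.na(res$rates$fpr[res$rates$group == "b"]))
  expect_false(is.na(res$rates$fnr[res$rates$group == "b"]))

  perfect <- prediction_set(
    y_true = rep(c(0, 1), 10), y_score = rep(c(0.1, 0.9), 10),
    group = rep(c("a", "b"), each = 10)
  )
  resp <- error_rate_parity(perfect)
  expect_equal(resp$fpr_difference, 0)
  expect_equal(resp$fnr_difference, 0)
})

test_that("Mann-Whitney AUC equals pair counting", {
  expect_equal(mann_whitney_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  expect_equal(mann_whitney_auc(c(1, 0, 1, 0), c(0.9, 0.1, 0.8, 0.2)), 1)
  expect_equal(mann_whitney_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_true(is.na(mann_whitney_auc(c(1, 1), c(0.2, 0.3))))

  # invariance under strictly monotone transforms of the score
  withr::with_seed(4, {
    y <- sample(0:1, 60, replace = TRUE)
    s <- runif(60)
  })
  expect_equal(mann_whitney_auc(y, s), mann_whitney_auc(y, plogis(5 * s)))
  expect_equal(mann_whitney_auc(y, s), auc_pairs(y, s))
})

test_that("fairness_report assembles consistent per-group metrics", {
  withr::with_seed(10, {
    p <- random_prediction_set(200, 4)
  })
  fr <- suppressWarnings(fairness_report(p))
  bg <- fr$by_group

  # conservation: group-size-weighted accuracy equals overall accuracy
  expect_equal(sum(bg$accuracy * bg$n) / sum(bg$n), fr$overall_accuracy)
  # conservation: weighted positive rate equals overall positive rate
  expect_equal(sum(bg$positive_rate * bg$n) / sum(bg$n), mean(p$y_pred))
  expect_equal(fr$accuracy_spread, diff(range(bg$accuracy)))
  expect_true(all(bg$positive_rate >= 0 & bg$positive_rate <= 1))

  oracle <- fairness_bruteforce(p$y_true, p$y_score, p$y_pred, p$group)
  expect_equal(fr$demographic_parity_difference, oracle$dp)
  expect_equal(setNames(bg$auc, bg$group), oracle$auc)
})

test_that("tidy/glance/write round-trips for fairness reports", {
  withr::with_seed(2, p <- random_prediction_set(120, 3))
  fr <- suppressWarnings(fairness_report(p))
  td <- tidy(fr)
  expect_true(all(c("group", "metric", "value") %in% names(td)))
  gl <- glance(fr)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$overall_accuracy, fr$overall_accuracy)

  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_fairness_report(fr, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(td))
  parsed <- jsonlite::read_json(js)
  expect_equal(parsed$overall_accuracy, fr$overall_accuracy)
  expect_s3_class(autoplot(fr), "ggplot")
})
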
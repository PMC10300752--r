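test_that("accuracy is the percentage of matching pairs", {
  expect_equal(accuracy_pct(rep("a", 436), rep("a", 436)), 100)
  expect_equal(accuracy_pct(c(0, 1, 2, 2), c(0, 1, 1, 2)), 75)
  # 402 of 436 correct
  pred <- c(rep("x", 402), rep("y", 34))
  truth <- rep("x", 436)
  expect_equal(round(accuracy_pct(pred, truth), 1), 92.2)
  expect_error(accuracy_pct(1:3, 1:4), "equal length")
  expect_error(accuracy_pct(character(0), character(0)), "empty")
})

test_that("accuracy agrees with a brute-force pair counter", {
  set.seed(14)
  for (rep_i in 1:20) {
    n <- sample(5:60, 1)
    pred <- sample(breathing_conditions(), n, replace = TRUE)
    truth <- sample(breathing_conditions(), n, replace = TRUE)
    brute <- 0
    for (i in seq_len(n)) if (pred[i] == truth[i]) brute <- brute + 1
    expect_equal(accuracy_pct(pred, truth), 100 * brute / n)
  }
})

test_that("confusion matrices follow the rows-true convention", {
  cls <- breathing_conditions()
  truth <- cls[c(1, 1, 2, 3)]
  pred <- cls[c(1, 2, 2, 3)]
  cr <- confusion_and_recall(pred, truth)
  expect_equal(unname(cr$recall), c(0.5, 1, 1))
  expect_equal(cr$confusion["baseline", "loaded"], 1)
  expect_equal(cr$confusion["loaded", "baseline"], 0)
  expect_equal(rowSums(cr$normalized), c(baseline = 1, loaded = 1,
                                         rapid_shallow = 1))
  expect_error(confusion_and_recall(c("a"), c("baseline")), "outside")
})

test_that("perfect predictions give the identity normalized matrix", {
  truth <- sample(breathing_conditions(), 30, replace = TRUE)
  cr <- confusion_and_recall(truth, truth)
  expect_equal(unname(cr$normalized), diag(3))
  expect_equal(unname(cr$recall), c(1, 1, 1))
})

test_that("the normalized diagonal equals per-class recall", {
  set.seed(15)
  for (rep_i in 1:10) {
    truth <- sample(breathing_conditions(), 40, replace = TRUE)
    pred <- sample(breathing_conditions(), 40, replace = TRUE)
    cr <- confusion_and_recall(pred, truth)
    present <- !is.na(cr$recall)
    expect_equal(diag(cr$normalized)[present], cr$recall[present])
  }
})

test_that("empty classes yield undefined recall, never zero", {
  truth <- c("baseline", "baseline", "loaded")
  pred <- c("baseline", "loaded", "loaded")
  cr <- confusion_and_recall(pred, truth)
  expect_true(is.na(cr$recall[["rapid_shallow"]]))
  expect_true(all(is.na(cr$normalized["rapid_shallow", ])))
  expect_error(balanced_accuracy_pct(cr$recall), "undefined")
})

test_that("balanced accuracy reproduces the published recall triples", {
  # the first triple's recalls are printed rounded to 2 dp, so the published
  # 89.66% is recoverable only to within one unit in the last digit
  expect_equal(balanced_accuracy_pct(c(0.92, 0.81, 0.96)), 89.66,
               tolerance = 0.011 / 89.66)
  expect_equal(round(balanced_accuracy_pct(c(0.94, 0.85, 0.95)), 2), 91.33)
  expect_equal(round(balanced_accuracy_pct(c(0.93, 0.90, 0.94)), 2), 92.33)
  expect_equal(balanced_accuracy_pct(c(1, 1, 1)), 100)
})

test_that("balanced accuracy is invariant to class rebalancing;
           plain accuracy is not", {
  cls <- breathing_conditions()
  # fixed per-class confusion behaviour: baseline 3/4 correct,
  # loaded 1/2 correct, rapid 1/1 correct
  block_truth <- cls[c(1, 1, 1, 1, 2, 2, 3)]
  block_pred <- cls[c(1, 1, 1, 2, 2, 3, 3)]
  base <- eval_report(block_pred, block_truth)
  # replicate the baseline block 5 times: per-class recalls unchanged
  truth2 <- c(rep(cls[c(1, 1, 1, 1)], 5), cls[c(2, 2, 3)])
  pred2 <- c(rep(cls[c(1, 1, 1, 2)], 5), cls[c(2, 3, 3)])
  boosted <- eval_report(pred2, truth2)
  expect_equal(boosted$balanced_accuracy, base$balanced_accuracy)
  expect_false(isTRUE(all.equal(boosted$accuracy, base$accuracy)))
})

test_that("accuracy decomposes as the recall-weighted row-share identity", {
  set.seed(16)
  for (rep_i in 1:10) {
    truth <- sample(breathing_conditions(), 50, replace = TRUE)
    pred <- sample(breathing_conditions(), 50, replace = TRUE)
    rep_ <- eval_report(pred, truth)
    rs <- rowSums(rep_$confusion)
    present <- rs > 0
    recon <- sum((rs[present] / rep_$n_test) *
                   rep_$per_class_recall[present]) * 100
    expect_equal(rep_$accuracy, recon)
  }
})

test_that("reports summarise counts consistently and serialise to JSON", {
  truth <- sample(breathing_conditions(), 25, replace = TRUE)
  pred <- sample(breathing_conditions(), 25, replace = TRUE)
  rp <- eval_report(pred, truth)
  expect_identical(sum(rp$confusion), 25L)
  expect_equal(rp$accuracy, 100 * sum(diag(rp$confusion)) / rp$n_test)
  path <- tempfile(fileext = ".json")
  write_eval_report(rp, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$accuracy, rp$accuracy)
  expect_identical(back$n_test, 25L)
})
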
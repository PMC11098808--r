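# independent per-sample tally used as the oracle throughout
tally_confusion <- function(true, pred, K) {
  m <- matrix(0L, K, K)
  for (i in seq_along(true))
    m[true[i] + 1L, pred[i] + 1L] <- m[true[i] + 1L, pred[i] + 1L] + 1L
  m
}

test_that("confusion matrix counts truth rows against prediction columns", {
  cm <- confusion_matrix(c(0, 1, 2), c(0, 1, 2), 3)
  expect_equal(unclass(cm), diag(1L, 3), ignore_attr = TRUE)
  cm2 <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unclass(cm2), matrix(c(1L, 0L, 1L, 1L), 2),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
  expect_error(confusion_matrix(c(0, 3), c(0, 1), 3), "labels")
})

test_that("confusion matrix agrees with a brute-force tally on random labels", {
  set.seed(8)
  for (rep in 1:100) {
    K <- sample(2:5, 1)
    n <- sample(5:40, 1)
    true <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    cm <- confusion_matrix(true, pred, K)
    expect_equal(unclass(cm), tally_confusion(true, pred, K),
                 ignore_attr = TRUE)
    expect_equal(sum(cm), n)
  }
})

test_that("the study's worked test-set example reproduces its printed metrics", {
  # test composition 27/21/13; one 3-5y error, one 7-12y error, adults 13/13
  cm <- matrix(c(26, 1, 0,
                 0, 20, 1,
                 0, 0, 13), 3, 3, byrow = TRUE)
  met <- metrics_from_confusion(cm)
  expect_equal(round(met$accuracy, 3), 0.967)   # 59/61
  expect_equal(round(met$macro_recall, 3), 0.972)
  expect_equal(met$per_class_recall, c(26 / 27, 20 / 21, 1))
  # accuracy and recall do not depend on where the two errors landed
  cm_alt <- matrix(c(26, 0, 1,
                     1, 20, 0,
                     0, 0, 13), 3, 3, byrow = TRUE)
  met_alt <- metrics_from_confusion(cm_alt)
  expect_equal(met_alt$accuracy, met$accuracy)
  expect_equal(met_alt$macro_recall, met$macro_recall)
})

test_that("metrics behave at the boundaries", {
  met <- metrics_from_confusion(diag(5L, 3))
  expect_equal(met$accuracy, 1)
  expect_equal(met$macro_recall, 1)
  expect_equal(met$macro_precision, 1)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "no counts")
  # never-predicted class contributes precision 0
  cm <- matrix(c(2L, 0L, 1L, 0L), 2, 2)
  expect_equal(metrics_from_confusion(cm)$per_class_precision[2], 0)
})

test_that("macro metrics are invariant under class-label permutation", {
  set.seed(9)
  for (rep in 1:50) {
    K <- sample(3:5, 1)
    cm <- matrix(rpois(K * K, 3), K, K)
    cm[1, 1] <- cm[1, 1] + 1  # ensure nonzero
    perm <- sample(K)
    met <- metrics_from_confusion(cm)
    met_p <- metrics_from_confusion(cm[perm, perm])
    expect_equal(met_p$accuracy, met$accuracy)
    expect_equal(met_p$macro_recall, met$macro_recall)
    expect_equal(met_p$macro_precision, met$macro_precision)
  }
})

test_that("metrics agree with a per-sample tally oracle", {
  set.seed(10)
  for (rep in 1:100) {
    K <- sample(2:4, 1)
    n <- sample(8:30, 1)
    true <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    met <- metrics_from_confusion(confusion_matrix(true, pred, K))
    expect_equal(met$accuracy, mean(true == pred))
    recall_by_hand <- vapply(0:(K - 1), function(k) {
      if (!any(true == k)) 0 else mean(pred[true == k] == k)
    }, numeric(1))
    expect_equal(unname(met$per_class_recall), recall_by_hand)
  }
})

test_that("evaluate is internally consistent and handles a constant model", {
  dat <- small_phantoms(4, seed = 6)
  m <- build_model(resmini_config(input_height = 32, input_width = 28),
                   seed = 6)
  ev <- evaluate(m, dat)
  expect_equal(ev$metrics$accuracy,
               metrics_from_confusion(ev$confusion)$accuracy)
  expect_equal(sum(ev$confusion), 12)
  # forcing one logit high makes the model constant: accuracy = 1/3
  m$params$dense.b <- c(100, 0, 0)
  ev0 <- evaluate(m, dat)
  expect_equal(ev0$metrics$accuracy, 1 / 3)
  expect_true(all(ev0$confusion[, 1] == 4))
  expect_error(evaluate(m, list(x = dat$x[, , , 0, drop = FALSE],
                                y = integer(0))), "empty")
})

test_that("parameter-economy ratios reproduce the printed comparisons", {
  rep <- comparison_report(c(resmini = 98907, resnet18 = 11181379,
                             bhcnet = 196595))
  expect_equal(rep$ratio_percent["resmini", "bhcnet"], 50.31)
  expect_equal(rep$ratio_percent["resmini", "resnet18"], 0.88)
  expect_equal(rep$ratio_percent["resmini", "resmini"], 100.00)
  expect_error(comparison_report(c(1, 2)), "named")
})
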
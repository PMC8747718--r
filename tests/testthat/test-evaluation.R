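test_that("confusion_matrix counts correctly and validates input", {
  cm <- confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2)
  expect_equal(unname(cm$counts), matrix(c(1L, 0L, 1L, 1L), 2, 2))
  perfect <- confusion_matrix(0:3, 0:3, 4)
  expect_equal(unname(perfect$counts), diag(4) * 1L)

  set.seed(2)
  t5 <- sample(0:4, 200, replace = TRUE)
  p5 <- sample(0:4, 200, replace = TRUE)
  cm5 <- confusion_matrix(t5, p5, 5)
  expect_equal(unname(rowSums(cm5$counts)), as.vector(table(factor(t5, 0:4))))
  expect_equal(sum(cm5$counts), 200)

  expect_error(confusion_matrix(c(0, 1), c(0), 2), "equal length")
  expect_error(confusion_matrix(c(0, 2), c(0, 1), 2), "labels")
})

test_that("per_class_counts collapses one-vs-rest correctly", {
  cm <- confusion_matrix(rep(0:1, c(6, 6)),
                         c(rep(0, 5), 1, 0, 0, rep(1, 4)), 2)
  expect_equal(unname(cm$counts), matrix(c(5L, 2L, 1L, 4L), 2, 2))
  expect_equal(per_class_counts(cm, 0), c(TP = 5, FP = 2, FN = 1, TN = 4))
  expect_equal(per_class_counts(cm, 1), c(TP = 4, FP = 1, FN = 2, TN = 5))
  for (c in 0:1) expect_equal(sum(per_class_counts(cm, c)), 12)
  expect_error(per_class_counts(cm, 2), "class_id")

  diagm <- confusion_matrix(0:2, 0:2, 3)
  for (c in 0:2) {
    ct <- per_class_counts(diagm, c)
    expect_equal(unname(ct[c("FP", "FN")]), c(0, 0))
  }
})

test_that("macro_metrics reproduces the worked example", {
  # [[5,1],[2,4]]: recalls 5/6, 4/6; precisions 5/7, 4/5; F1 0.7692, 0.7273
  cm <- structure(list(counts = matrix(c(5L, 2L, 1L, 4L), 2, 2),
                       class_names = c("a", "b")),
                  class = "leafcnn_confusion")
  m <- macro_metrics(cm)
  expect_equal(round(m$macro_recall, 4), 0.75)
  expect_equal(round(m$macro_precision, 4), 0.7571)
  expect_equal(round(m$macro_f1, 4), 0.7483)
  expect_equal(round(m$mean_accuracy, 4), 0.75)
  expect_equal(m$overall_accuracy, 9 / 12)

  ident <- macro_metrics(confusion_matrix(0:3, 0:3, 4))
  for (f in c("macro_recall", "macro_precision", "macro_f1", "mean_accuracy",
              "overall_accuracy"))
    expect_equal(ident[[f]], 1)

  # never-predicted class: precision 0 with warning, macros stay defined
  cm0 <- confusion_matrix(c(0, 0, 1), c(0, 0, 0), 2)
  expect_warning(m0 <- macro_metrics(cm0), "never predicted")
  expect_equal(m0$per_class$precision[2], 0)
})

test_that("macro_metrics matches the per-sample oracle on random labels", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(20:60, 1)
    truth <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    m <- suppressWarnings(macro_metrics(confusion_matrix(truth, pred, 5)))
    o <- oracle_macro_metrics(truth, pred, 5)
    expect_equal(m$macro_recall, o$macro_recall, tolerance = 1e-12)
    expect_equal(m$macro_precision, o$macro_precision, tolerance = 1e-12)
    expect_equal(m$macro_f1, o$macro_f1, tolerance = 1e-12)
    expect_equal(m$mean_accuracy, o$mean_accuracy, tolerance = 1e-12)
    expect_equal(m$overall_accuracy, o$overall, tolerance = 1e-12)
  }
})

test_that("permuting class ids permutes per-class metrics, macros invariant", {
  set.seed(7)
  truth <- sample(0:3, 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.7, truth, sample(0:3, 120, replace = TRUE))
  m <- macro_metrics(confusion_matrix(truth, pred, 4))
  perm <- c(2L, 0L, 3L, 1L)  # new id of old class k = perm[k+1]
  m2 <- macro_metrics(confusion_matrix(perm[truth + 1L], perm[pred + 1L], 4))
  expect_equal(m2$macro_recall, m$macro_recall, tolerance = 1e-12)
  expect_equal(m2$macro_f1, m$macro_f1, tolerance = 1e-12)
  expect_equal(m2$mean_accuracy, m$mean_accuracy, tolerance = 1e-12)
  expect_equal(m2$per_class$recall[perm + 1L], m$per_class$recall,
               tolerance = 1e-12)
})

test_that("mean accuracy exceeds macro recall when mass is off-diagonal", {
  # 9-class pattern of the published tables (e.g. recall 87.76 vs mean
  # accuracy 99.16): true negatives inflate one-vs-rest accuracy
  set.seed(13)
  truth <- rep(0:8, each = 30)
  pred <- ifelse(runif(270) < 0.85, truth, sample(0:8, 270, replace = TRUE))
  m <- suppressWarnings(macro_metrics(confusion_matrix(truth, pred, 9)))
  expect_gt(m$mean_accuracy, m$macro_recall)
})

test_that("per-class validation tables count and format like the published tables", {
  spec <- make_model_spec("N1", 3, c(16, 16, 3))
  net <- build_network(spec, seed = 1)
  ds <- generate_leaf_dataset(3, 5, image_size = c(16, 16, 3), seed = 3)
  tab <- per_class_validation_table(net, ds)
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$correct),
               sum(predict_classes(net, ds)$labels == ds$labels))
  # class absent from the holdout: reported missing, not zero
  sub <- leafcnn:::subset_image_set(ds, ds$labels != 2L)
  tab2 <- per_class_validation_table(net, sub)
  expect_true(is.na(tab2$accuracy_percent[3]))
  # the published tables' granularity: 37 of 40 -> 92.5
  expect_equal(round(100 * 37 / 40, 2), 92.5)

  rep <- format_metric_report(suppressWarnings(
    macro_metrics(confusion_matrix(c(0, 0, 1), c(0, 1, 1), 2))))
  expect_equal(rep$class[nrow(rep)], "macro")
  expect_true(all(rep$recall >= 0 & rep$recall <= 100))
})
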
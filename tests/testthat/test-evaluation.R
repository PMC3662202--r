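test_that("confusion matrices conserve subject counts", {
  truth <- rep(c("NC", "MCI", "AD"), times = c(4, 5, 3))
  pred <- c(rep("NC", 3), "AD", rep("MCI", 4), "NC", "AD", "AD", "MCI")
  cm <- confusion_matrix(truth, pred)
  expect_equal(sum(cm), 12)
  expect_equal(unname(rowSums(cm)), c(4, 5, 3))
  expect_equal(rownames(cm), c("NC", "MCI", "AD"))
  m <- binary_metrics(cm, positive = "AD", negative = "NC")
  expect_equal(m$tp + m$fn, 3)
  expect_equal(m$tn + m$fp, 4)
})

test_that("perfect and fully wrong predictions give boundary metrics", {
  truth <- rep(c("AD", "NC"), each = 5)
  cm1 <- confusion_matrix(truth, truth)
  m1 <- binary_metrics(cm1, "AD", "NC")
  expect_equal(c(m1$accuracy, m1$sensitivity, m1$specificity), c(1, 1, 1))
  wrong <- rep(c("NC", "AD"), each = 5)
  m0 <- binary_metrics(confusion_matrix(truth, wrong), "AD", "NC")
  expect_equal(c(m0$accuracy, m0$sensitivity, m0$specificity), c(0, 0, 0))
})

test_that("swapping positive and negative classes swaps sensitivity and
          specificity", {
  truth <- rep(c("AD", "NC"), times = c(6, 7))
  set.seed(1)
  pred <- sample(c("AD", "NC"), 13, replace = TRUE)
  cm <- confusion_matrix(truth, pred)
  a <- binary_metrics(cm, "AD", "NC")
  b <- binary_metrics(cm, "NC", "AD")
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
  expect_equal(a$accuracy, b$accuracy)
})

test_that("published confusion matrices reproduce every headline accuracy
          after two-decimal rounding", {
  cms <- published_confusions()
  sizes <- published_group_sizes()
  acc <- published_accuracies()
  for (i in seq_len(nrow(acc))) {
    cm <- cms[[paste(acc$classifier[i], acc$variant[i], sep = "_")]]
    cls <- acc$task[i]
    got <- round_half_up(100 * class_accuracy(cm, cls, total = sizes[[cls]]), 2)
    expect_equal(got, acc$accuracy[i],
                 label = sprintf("%s/%s %s", acc$classifier[i],
                                 acc$variant[i], cls))
  }
  # wherever printed rows are count-consistent, the row-sum form agrees
  cm <- cms$psosvm_pca
  expect_equal(round_half_up(100 * class_accuracy(cm, "AD"), 2), 94.12)
  expect_equal(round_half_up(100 * class_accuracy(cm, "MCI"), 2), 88.89)
})

test_that("LOOCV predicts every subject exactly once and refits without it", {
  tab <- toy_feature_table(n_per_class = 5, shift = 10, sd = 0.8, seed = 21)
  res <- loocv(tab, classifier = "svm", route = "I", feature_sets = "all",
               seed = 2)
  expect_equal(nrow(res$predictions), nrow(tab))
  expect_equal(sum(res$confusion), nrow(tab))
  expect_equal(unname(rowSums(res$confusion)[c("NC", "MCI", "AD")]),
               c(5, 5, 5))
  # strong separation: near-perfect recovery
  expect_gte(res$accuracy, 0.9)
})

test_that("route II and binary tasks run end to end on tabular features", {
  tab <- toy_feature_table(n_per_class = 6, shift = 8, sd = 1, seed = 22,
                           n_features = 8)
  r2 <- loocv(tab, classifier = "svm", route = "II", feature_sets = "all",
              seed = 3)
  expect_gte(r2$accuracy, 0.8)
  rb <- loocv(tab, classifier = "svm", route = "II", feature_sets = "all",
              task = c("AD", "NC"), seed = 3)
  expect_equal(sum(rb$confusion), 12)
  expect_equal(sort(rownames(rb$confusion)), c("AD", "NC"))
})

test_that("LOOCV rejects classes with fewer than two subjects and missing
          masks for MC features", {
  tab <- toy_feature_table(n_per_class = 3, seed = 23)
  tab <- tab[-(1:2), ]
  expect_error(loocv(tab, classifier = "svm", feature_sets = "all"),
               class = "vm_parameter_error")
  tab2 <- toy_feature_table(n_per_class = 3, seed = 24)
  expect_error(loocv(tab2, classifier = "svm",
                     feature_sets = c("all", "mc")),
               class = "vm_parameter_error")
})

test_that("LOOCV with a fixed seed is reproducible", {
  tab <- toy_feature_table(n_per_class = 4, shift = 6, seed = 25)
  r1 <- loocv(tab, classifier = "som", route = "I", feature_sets = "all",
              classifier_args = list(schedule = som_schedule(
                ordering_epochs = 10, tuning_epochs = 30)), seed = 5)
  r2 <- loocv(tab, classifier = "som", route = "I", feature_sets = "all",
              classifier_args = list(schedule = som_schedule(
                ordering_epochs = 10, tuning_epochs = 30)), seed = 5)
  expect_identical(r1$predictions, r2$predictions)
})
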
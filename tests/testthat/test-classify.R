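test_that("shuffle-and-split produces floor(0.8 n) training rows", {
  ds <- data.frame(x = 1:10, z = 10:1, label = rep(c(0L, 1L), 5))
  # a 2-row test partition can easily lose a class: that is warned about
  expect_warning(sp <- split_dataset(ds, seed = 1L), "single class")
  expect_identical(nrow(sp$train), 8L)
  expect_identical(nrow(sp$test), 2L)
  # the pooled two-class study size splits 6300 / 1576
  big <- data.frame(x = seq_len(7876), z = 1L,
                    label = rep(c(0L, 1L), length.out = 7876))
  sp_big <- split_dataset(big, seed = 1L)
  expect_identical(nrow(sp_big$train), 6300L)
  expect_identical(nrow(sp_big$test), 1576L)
})

test_that("splitting is deterministic in the seed and rejects degenerate input", {
  ds <- data.frame(x = 1:20, z = 1:20, label = rep(c(0L, 1L), 10))
  expect_identical(split_dataset(ds, seed = 5L), split_dataset(ds, seed = 5L))
  expect_error(split_dataset(ds[1:5, ], seed = 1L), "at least 10")
  ds$label <- 1L
  expect_error(split_dataset(ds, seed = 1L), "single-class")
})

test_that("a tree separates a one-split toy problem perfectly and reproducibly", {
  set.seed(42)
  ds <- data.frame(x = sample(100:200, 400, TRUE),
                   z = sample(100:220, 400, TRUE))
  ds$label <- as.integer(ds$z > 160)
  clf <- train_labor_classifier(ds, "tree", seed = 7L)
  expect_equal(clf$metrics$accuracy, 1.0)
  clf2 <- train_labor_classifier(ds, "tree", seed = 7L)
  expect_equal(clf$metrics, clf2$metrics)
})

test_that("metric formulas match the footnote definitions on hand cases", {
  # class-1 confusion TP=3, FP=1, FN=1 -> precision = recall = f1 = 0.75
  y_true <- c(1, 1, 1, 1, 0, 0, 0)
  y_pred <- c(1, 1, 1, 0, 1, 0, 0)
  m <- classification_metrics(y_true, y_pred)
  cls1 <- m$per_class[m$per_class$class == 1, ]
  expect_equal(cls1$precision, 0.75)
  expect_equal(cls1$recall, 0.75)
  expect_equal(cls1$f1, 0.75)

  perfect <- classification_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$macro["f1"]), 1)
  expect_equal(unname(perfect$weighted["precision"]), 1)

  # all-ones prediction against balanced truth
  all1 <- classification_metrics(rep(c(0, 1), 10), rep(1, 20))
  cls1 <- all1$per_class[all1$per_class$class == 1, ]
  expect_equal(cls1$precision, 0.5)
  expect_equal(cls1$recall, 1.0)
  expect_true(all1$zero_division)  # class 0 has no predictions
})

test_that("metrics agree with a brute-force confusion oracle on random labels", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(5:200, 1)
    y_true <- sample(0:1, n, TRUE)
    y_pred <- sample(0:1, n, TRUE)
    m <- classification_metrics(y_true, y_pred)
    o <- bf_metrics(y_true, y_pred)
    expect_equal(m$per_class$precision, c(o$class0["precision"],
                                          o$class1["precision"]),
                 ignore_attr = TRUE)
    expect_equal(m$per_class$recall, c(o$class0["recall"],
                                       o$class1["recall"]),
                 ignore_attr = TRUE)
    expect_equal(m$per_class$f1, c(o$class0["f1"], o$class1["f1"]),
                 ignore_attr = TRUE)
    expect_equal(m$accuracy, o$accuracy)
    # accuracy is identically the support-weighted recall
    expect_equal(m$accuracy, unname(m$weighted["recall"]))
  }
})

test_that("metrics validate their input", {
  expect_error(classification_metrics(numeric(0), numeric(0)), "empty")
  expect_error(classification_metrics(c(0, 1), c(0, 1, 1)), "lengths")
  expect_error(classification_metrics(c(0, 2), c(0, 1)), "0 or 1")
})

test_that("stream prediction is pointwise, order-preserving and memorizes a deep tree", {
  set.seed(11)
  ds <- data.frame(x = sample(100:220, 80, TRUE),
                   z = sample(100:220, 80, TRUE))
  ds$label <- as.integer(ds$z > ds$x)
  clf <- train_labor_classifier(ds, "tree", train_fraction = 0.9, seed = 2L,
                                tree_maxdepth = 30L, tree_minbucket = 1L,
                                tree_cp = 0)
  rec <- data.frame(ds[, c("x", "z")], activity = TRUE)
  labels <- predict_stream(clf, rec)
  expect_length(labels, nrow(rec))
  # permuting records permutes labels identically
  perm <- sample(nrow(rec))
  expect_identical(predict_stream(clf, rec[perm, ]), labels[perm])
  expect_identical(predict_stream(clf, rec[0, ]), integer(0))
  # near-memorization on the training points
  expect_gte(mean(labels == ds$label), 0.95)
})

test_that("unfitted models are rejected", {
  fake <- structure(list(kind = "tree", model = NULL), class = "labor_classifier")
  expect_error(predict_stream(fake, make_records(TRUE)), "fitted")
})

test_that("tree and svm both learn the simulated posture signal", {
  herd <- small_herd()
  ds <- clean_samples(build_dataset(herd, make_label_intervals(herd),
                                    balance = TRUE, seed = 5L))
  tree <- train_labor_classifier(ds, "tree", seed = 9L)
  svm <- train_labor_classifier(ds, "svm", seed = 9L)
  expect_gte(tree$metrics$accuracy, 0.9)
  expect_gte(tree$metrics$accuracy, svm$metrics$accuracy - 0.05)
})
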
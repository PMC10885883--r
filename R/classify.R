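#' Shuffle and split a labeled dataset
#'
#' Seeded uniform shuffle followed by a contiguous split: the first
#' `floor(train_fraction * n)` shuffled samples form the training set, the
#' remainder the test set. A warning is raised if either partition loses a
#' class.
#'
#' @param samples Labeled sample data.frame (needs a `label` column and at
#'   least 10 rows with both classes present).
#' @param train_fraction Training share, strictly between 0 and 1
#'   (default 0.8).
#' @param seed Shuffle seed.
#' @return List with elements `train` and `test`.
#' @export
split_dataset <- function(samples, train_fraction = 0.8, seed = 1L) {
  n <- nrow(samples)
  if (n < 10L) stop("need at least 10 samples to split")
  if (length(unique(samples$label)) < 2L) {
    stop("cannot split a single-class dataset")
  }
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  set.seed(seed)
  perm <- sample.int(n)
  n_train <- floor(train_fraction * n)
  train <- samples[perm[seq_len(n_train)], ]
  test <- samples[perm[(n_train + 1L):n], ]
  rownames(train) <- rownames(test) <- NULL
  if (length(unique(train$label)) < 2L || length(unique(test$label)) < 2L) {
    warning("split left a partition with a single class; ",
            "consider a different seed or stratification")
  }
  list(train = train, test = test)
}

#' Train the per-record labor / non-labor classifier
#'
#' Fits either a decision tree (Gini impurity, binary splits) or a support
#' vector machine on the selected axis features, after an 80/20
#' shuffle-and-split, and evaluates it on the held-out 20%. The tree is the
#' production model; the SVM is retained as the comparison baseline.
#'
#' @param samples Labeled sample data.frame.
#' @param kind `"tree"` (default) or `"svm"`.
#' @param features Feature columns (default `c("x", "z")`, the axes that
#'   carry the posture signal: Z rotates under lateral recumbency, X jitters
#'   with leg movement).
#' @param train_fraction,seed Passed to [split_dataset()].
#' @param svm_kernel Kernel for the SVM comparison (default `"radial"`).
#' @param tree_maxdepth,tree_minbucket,tree_cp Decision-tree controls
#'   (defaults: depth 10, minimum leaf size 5, complexity 1e-4).
#' @return Object of class `labor_classifier`: the fitted model, its kind,
#'   feature list, the held-out [classification_metrics()] report, and the
#'   split sizes.
#' @export
train_labor_classifier <- function(samples, kind = c("tree", "svm"),
                                   features = c("x", "z"),
                                   train_fraction = 0.8, seed = 42L,
                                   svm_kernel = "radial",
                                   tree_maxdepth = 10L, tree_minbucket = 5L,
                                   tree_cp = 1e-4) {
  kind <- match.arg(kind)
  if (!all(features %in% names(samples))) {
    stop("features missing from samples: ",
         paste(setdiff(features, names(samples)), collapse = ", "))
  }
  parts <- split_dataset(samples, train_fraction, seed)
  train <- parts$train
  test <- parts$test
  if (length(unique(train$label)) < 2L) stop("degenerate training set")
  fml <- stats::as.formula(paste("label ~", paste(features, collapse = " + ")))
  train$label <- factor(train$label, levels = c(0L, 1L))
  set.seed(seed)
  model <- switch(kind,
    tree = rpart::rpart(
      fml, data = train, method = "class",
      control = rpart::rpart.control(maxdepth = tree_maxdepth,
                                     minbucket = tree_minbucket,
                                     cp = tree_cp)),
    svm = e1071::svm(fml, data = train, kernel = svm_kernel)
  )
  clf <- structure(
    list(kind = kind, model = model, features = features, seed = seed,
         n_train = nrow(train), n_test = nrow(test), metrics = NULL),
    class = "labor_classifier"
  )
  pred <- predict_labels(clf, test)
  clf$metrics <- classification_metrics(test$label, pred)
  clf
}

predict_labels <- function(clf, newdata) {
  nd <- newdata[, clf$features, drop = FALSE]
  if (clf$kind == "tree") {
    as.integer(as.character(predict(clf$model, nd, type = "class")))
  } else {
    as.integer(as.character(predict(clf$model, nd)))
  }
}

#' @export
print.labor_classifier <- function(x, ...) {
  cat(sprintf("labor_classifier (%s) on features [%s]; train n=%d, test n=%d\n",
              x$kind, paste(x$features, collapse = ", "),
              x$n_train, x$n_test))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Classification metric suite
#'
#' Per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)` and F-1
#' score `2 * precision * recall / (precision + recall)`, with supports;
#' overall accuracy; macro averages (unweighted class means) and weighted
#' averages (support-weighted class means). A metric whose denominator is
#' zero is defined as 0 and flagged.
#'
#' @param y_true,y_pred Equal-length label vectors with values in `{0, 1}`.
#' @return Object of class `metrics_report`: `per_class` data.frame
#'   (`class, precision, recall, f1, support`), `accuracy`, `macro`,
#'   `weighted`, and `zero_division` flag.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.integer(as.character(y_true))
  y_pred <- as.integer(as.character(y_pred))
  if (length(y_true) == 0L) stop("empty input to classification_metrics")
  if (length(y_true) != length(y_pred)) stop("y_true and y_pred lengths differ")
  if (!all(c(y_true, y_pred) %in% c(0L, 1L))) {
    stop("labels must be 0 or 1")
  }
  zero_division <- FALSE
  safe_div <- function(a, b) {
    if (b == 0) { zero_division <<- TRUE; return(0) }
    a / b
  }
  per <- lapply(c(0L, 1L), function(cl) {
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    p <- safe_div(tp, tp + fp)
    r <- safe_div(tp, tp + fn)
    f1 <- safe_div(2 * p * r, p + r)
    data.frame(class = cl, precision = p, recall = r, f1 = f1,
               support = sum(y_true == cl))
  })
  per <- do.call(rbind, per)
  w <- per$support / sum(per$support)
  structure(
    list(per_class = per,
         accuracy = mean(y_true == y_pred),
         macro = c(precision = mean(per$precision), recall = mean(per$recall),
                   f1 = mean(per$f1)),
         weighted = c(precision = sum(w * per$precision),
                      recall = sum(w * per$recall), f1 = sum(w * per$f1)),
         zero_division = zero_division),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  # mirrors the usual two-class report layout, two decimals
  cat(sprintf("%-16s %9s %7s %10s %8s\n", "", "Precision", "Recall",
              "F-1 Score", "Support"))
  lab <- c("Non-labor (0)", "Labor (1)")
  for (i in 1:2) {
    cat(sprintf("%-16s %9.2f %7.2f %10.2f %8d\n", lab[i],
                x$per_class$precision[i], x$per_class$recall[i],
                x$per_class$f1[i], x$per_class$support[i]))
  }
  n <- sum(x$per_class$support)
  cat(sprintf("%-16s %9s %7s %10.2f %8d\n", "Accuracy", "", "",
              x$accuracy, n))
  cat(sprintf("%-16s %9.2f %7.2f %10.2f %8d\n", "Macro average",
              x$macro["precision"], x$macro["recall"], x$macro["f1"], n))
  cat(sprintf("%-16s %9.2f %7.2f %10.2f %8d\n", "Weighted average",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"], n))
  invisible(x)
}

#' Classify every record of a stream
#'
#' Applies the fitted classifier pointwise to a record stream, preserving
#' order; inactive records are classified too (the lateral labor posture can
#' be momentarily still), so they may count toward the windowed labor tally.
#'
#' @param model A `labor_classifier`.
#' @param records Record data.frame containing the model's feature columns.
#' @return Integer vector of labels (0/1), one per record.
#' @export
predict_stream <- function(model, records) {
  if (!inherits(model, "labor_classifier") || is.null(model$model)) {
    stop("model must be a fitted labor_classifier")
  }
  if (nrow(records) == 0L) return(integer(0))
  predict_labels(model, records)
}
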
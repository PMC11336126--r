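# Decision-tree disease classification: stratified 8:2 split, five-fold
# cross-validation, confusion-matrix report and ROC.

#' Stratified random train/test split
#'
#' Draws `round(n_c * test_fraction)` test subjects per class (stratified:
#' an unstratified draw can leave a small class unusable), reproducibly
#' given `seed`.
#'
#' @param features data.frame of per-subject features.
#' @param labels name of the class column in `features`.
#' @param test_fraction fraction held out (0 < f < 1; default 0.2).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames.
#' @export
split_train_test <- function(features, labels = "group", test_fraction = 0.2,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_invalid("test_fraction must be in (0, 1)")
  }
  g <- factor(features[[labels]])
  test_idx <- with_seed(seed, {
    unlist(lapply(levels(g), function(lv) {
      idx <- which(g == lv)
      n_test <- round(length(idx) * test_fraction)
      sample(idx, n_test)
    }))
  })
  train <- features[-test_idx, , drop = FALSE]
  if (any(table(factor(train[[labels]], levels = levels(g))) < 2L)) {
    stop_invalid("fewer than 2 training subjects in a class")
  }
  list(train = train, test = features[test_idx, , drop = FALSE])
}

.fit_tree <- function(train, labels) {
  dat <- train
  dat[[labels]] <- factor(dat[[labels]])
  fml <- stats::as.formula(paste(labels, "~ ."))
  rpart::rpart(fml, data = dat, method = "class",
               parms = list(split = "gini"),
               control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                              cp = 0, maxdepth = 30L,
                                              xval = 0L))
}

#' Five-fold cross-validated decision tree
#'
#' Fits a CART tree (Gini impurity, no depth limit, minimum leaf size 1,
#' no hyperparameter tuning) on each of `folds` stratified folds of the
#' training set and reports per-fold held-out accuracy; the returned model
#' is refit on the full training set.
#'
#' @param train training data.frame.
#' @param labels name of the class column.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed for fold assignment.
#' @return list with `fold_accuracy` (numeric vector), `model` (rpart fit
#'   on all training data), and `folds` (fold id per training row).
#' @export
crossvalidate_tree <- function(train, labels = "group", folds = 5L,
                               seed = 1L) {
  g <- factor(train[[labels]])
  if (nlevels(g) < 2L) stop_invalid("training data has a single class")
  fold_id <- integer(nrow(train))
  fold_id[] <- with_seed(seed, {
    out <- integer(nrow(train))
    for (lv in levels(g)) {
      idx <- which(g == lv)
      out[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    out
  })
  acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- train[fold_id != f, , drop = FALSE]
    te <- train[fold_id == f, , drop = FALSE]
    if (length(unique(tr[[labels]])) < 2L) {
      stop_invalid("a fold's training part has a single class")
    }
    fit <- .fit_tree(tr, labels)
    pred <- predict(fit, te, type = "class")
    acc[f] <- mean(as.character(pred) == as.character(te[[labels]]))
  }
  list(fold_accuracy = acc, model = .fit_tree(train, labels),
       folds = fold_id)
}

#' Evaluate a classifier on a held-out test set
#'
#' Confusion matrix, per-class precision/recall/F1/support, accuracy, and
#' a ROC curve with trapezoidal AUC from the tree's class-probability
#' scores (leaf class fractions).  With a single-class test set the ROC is
#' NULL and the other quantities are still reported.
#'
#' @param model an rpart classification fit.
#' @param test test data.frame.
#' @param labels name of the class column.
#' @param positive class treated as "positive" for the ROC score (default:
#'   the last factor level).
#' @return a `classification_report`: list with `confusion`, `per_class`
#'   (data.frame: class, precision, recall, f1, support), `accuracy`,
#'   `macro_avg`, `weighted_avg`, `roc` (data.frame of FPR/TPR points or
#'   NULL), `auc`.
#' @export
evaluate_classifier <- function(model, test, labels = "group",
                                positive = NULL) {
  if (!nrow(test)) stop_invalid("empty test set")
  truth <- factor(test[[labels]], levels = attr(model, "ylevels"))
  pred <- predict(model, test, type = "class")
  lv <- levels(truth)
  confusion <- table(truth = truth, predicted = factor(pred, levels = lv))
  per_class <- do.call(rbind, lapply(lv, function(cl) {
    tp <- confusion[cl, cl]
    support <- sum(confusion[cl, ])
    pred_n <- sum(confusion[, cl])
    precision <- if (pred_n > 0) tp / pred_n else NA_real_
    recall <- if (support > 0) tp / support else NA_real_
    f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else NA_real_
    data.frame(class = cl, precision = precision, recall = recall,
               f1 = f1, support = support, stringsAsFactors = FALSE)
  }))
  accuracy <- sum(diag(confusion)) / sum(confusion)
  avg <- summarize_report(per_class)

  roc_df <- NULL; auc <- NA_real_
  if (length(unique(truth)) == 2L) {
    positive <- positive %||% lv[2L]
    prob <- predict(model, test, type = "prob")[, positive]
    rr <- pROC::roc(response = truth, predictor = prob,
                    levels = setdiff(lv, positive) |> c(positive),
                    direction = "<", quiet = TRUE)
    auc <- as.numeric(pROC::auc(rr))
    roc_df <- data.frame(fpr = rev(1 - rr$specificities),
                         tpr = rev(rr$sensitivities))
  }
  structure(list(confusion = confusion, per_class = per_class,
                 accuracy = accuracy,
                 macro_avg = avg$macro, weighted_avg = avg$weighted,
                 roc = roc_df, auc = auc),
            class = "classification_report")
}

#' Macro and support-weighted averages of per-class rows
#'
#' Macro = unweighted mean over classes; weighted = support-weighted mean.
#' The support-weighted mean recall equals the overall accuracy.
#'
#' @param per_class data.frame with columns precision, recall, f1, support.
#' @return list with `macro` and `weighted`, each a named numeric
#'   (precision, recall, f1) plus `support` (total).
#' @export
summarize_report <- function(per_class) {
  if (!nrow(per_class)) stop_invalid("no class rows")
  w <- per_class$support / sum(per_class$support)
  cols <- c("precision", "recall", "f1")
  macro <- vapply(cols, function(cl) mean(per_class[[cl]]), numeric(1))
  weighted <- vapply(cols, function(cl) sum(per_class[[cl]] * w), numeric(1))
  list(macro = c(macro, support = sum(per_class$support)),
       weighted = c(weighted, support = sum(per_class$support)))
}

#' Full classification protocol
#'
#' Stratified 8:2 split, five-fold CV on the training set, refit on all
#' training data, evaluation on the held-out test set.
#'
#' @param features data.frame of per-subject features plus the class column.
#' @param labels name of the class column.
#' @param test_fraction held-out fraction.
#' @param folds CV folds.
#' @param seed integer seed (split and folds).
#' @param positive positive class for the ROC.
#' @return list with `report` (a `classification_report`),
#'   `fold_accuracy`, `model`, `split`.
#' @export
classify_cohort <- function(features, labels = "group", test_fraction = 0.2,
                            folds = 5L, seed = 1L, positive = NULL) {
  sp <- split_train_test(features, labels, test_fraction, seed)
  cv <- crossvalidate_tree(sp$train, labels, folds, seed + 1L)
  rep <- evaluate_classifier(cv$model, sp$test, labels, positive)
  list(report = rep, fold_accuracy = cv$fold_accuracy, model = cv$model,
       split = sp)
}
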
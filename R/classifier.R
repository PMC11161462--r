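# Random-Forest behavior classifiers: the two-class principal model
# (Interested vs Uninterested, thresholded at 0.52) and the eight-class
# fine-scale model, both with the study's fixed hyperparameters.

#' Random Forest hyperparameters for a behavior-classification task
#'
#' The tuned settings: principal task mtry = 1, ntree = 100, max 50 terminal
#' nodes, node size 2, per-tree bootstrap sample of 50; fine-scale task
#' mtry = 5, ntree = 650, max nodes 50, node size 5, sample size 150. Both
#' use inverse-class-frequency weighting and Gini splits.
#'
#' @param task `"principal"` or `"finescale"`; or pass the fields directly.
#' @param mtry,ntree,max_nodes,node_size,samp_size Forest geometry; see
#'   [randomForest::randomForest()] (`samp_size` is the per-tree bootstrap
#'   sample size, drawn with replacement).
#' @return List of class `bb_rf_hyperparams`.
#' @export
rf_hyperparams <- function(task = c("principal", "finescale"),
                           mtry = NULL, ntree = NULL, max_nodes = 50,
                           node_size = NULL, samp_size = NULL) {
  task <- match.arg(task)
  defaults <- switch(task,
    principal = list(mtry = 1L, ntree = 100L, max_nodes = 50L,
                     node_size = 2L, samp_size = 50L),
    finescale = list(mtry = 5L, ntree = 650L, max_nodes = 50L,
                     node_size = 5L, samp_size = 150L))
  hp <- list(
    task = task,
    mtry = if (is.null(mtry)) defaults$mtry else as.integer(mtry),
    ntree = if (is.null(ntree)) defaults$ntree else as.integer(ntree),
    max_nodes = as.integer(max_nodes),
    node_size = if (is.null(node_size)) defaults$node_size
                else as.integer(node_size),
    samp_size = if (is.null(samp_size)) defaults$samp_size
                else as.integer(samp_size),
    class_weights = "inverse_frequency",
    split_criterion = "gini")
  bad <- vapply(hp[c("mtry", "ntree", "max_nodes", "node_size",
                     "samp_size")], function(v) v < 1, logical(1))
  if (any(bad)) stopf("hyperparameters must be positive integers")
  structure(hp, class = "bb_rf_hyperparams")
}

#' Stratified train/test split
#'
#' Splits each stratum — each class, or each (dataset, class) cell when a
#' `dataset` grouping is given — separately at the requested fraction
#' (floor of n x fraction to train, remainder to test), so both halves keep
#' the class mix of every dataset. Deterministic given `seed`.
#'
#' @param labels Class label per row.
#' @param fraction Train fraction, default 0.5.
#' @param dataset Optional grouping factor (e.g. recording year) crossed
#'   with the class for stratification.
#' @param seed Integer seed.
#' @return List with integer row indices `train` and `test`. A stratum of
#'   size 1 goes to train with a warning.
#' @export
stratified_split <- function(labels, fraction = 0.5, dataset = NULL,
                             seed = NULL) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0, 1)")
  labels <- as.character(labels)
  strata <- if (is.null(dataset)) labels else paste(dataset, labels, sep = "\r")
  with_seed(seed, {
    train <- integer(0)
    for (s in unique(strata)) {
      idx <- which(strata == s)
      if (length(idx) == 1) {
        warnf("stratum of size 1 assigned to train")
        train <- c(train, idx)
      } else {
        n_train <- max(1L, floor(length(idx) * fraction))
        train <- c(train, sample(idx, n_train))
      }
    }
    train <- sort(train)
    list(train = train, test = setdiff(seq_along(labels), train))
  })
}

#' Train a behavior Random Forest
#'
#' Fits a forest with the task's fixed hyperparameters: per-tree bootstrap
#' of `samp_size` rows with replacement, at most `max_nodes` terminal nodes,
#' minimum node size `node_size`, inverse-class-frequency weights, Gini
#' splits. Deterministic given `seed`.
#'
#' @param table Numeric feature data frame (columns = selected metrics).
#' @param labels Class label per row (principal or fine-scale).
#' @param task `"principal"` or `"finescale"`.
#' @param hyperparams A [rf_hyperparams()]; defaults to the task's tuned
#'   values.
#' @param interest_threshold Probability above which (inclusive) a track is
#'   called Interested; principal task only. Default 0.52.
#' @param seed Integer seed.
#' @return A `bb_behavior_model`: the fitted forest, feature names, task,
#'   threshold, hyperparameters and a training report (OOB error, class
#'   counts).
#' @export
train_rf <- function(table, labels, task = c("principal", "finescale"),
                     hyperparams = NULL, interest_threshold = 0.52,
                     seed = NULL) {
  task <- match.arg(task)
  if (is.null(hyperparams)) hyperparams <- rf_hyperparams(task)
  table <- as.data.frame(table)
  y <- factor(as.character(labels),
              levels = if (task == "principal") principal_behaviors()
                       else finescale_behaviors())
  y <- droplevels(y)
  if (any(is.na(y))) stopf("labels contain values outside the %s taxonomy", task)
  if (nlevels(y) < 2) stopf("need >= 2 classes to train")
  if (hyperparams$mtry > ncol(table)) {
    stopf("mtry (%d) exceeds the number of features (%d)",
          hyperparams$mtry, ncol(table))
  }
  if (interest_threshold <= 0 || interest_threshold >= 1) {
    stopf("interest_threshold must be in (0, 1)")
  }
  freq <- base::table(y)
  classwt <- as.numeric(1 / freq)
  classwt <- classwt / sum(classwt)
  names(classwt) <- names(freq)
  fit <- with_seed(seed, randomForest::randomForest(
    x = as.matrix(table), y = y,
    mtry = hyperparams$mtry, ntree = hyperparams$ntree,
    maxnodes = hyperparams$max_nodes, nodesize = hyperparams$node_size,
    sampsize = min(hyperparams$samp_size, nrow(table)),
    classwt = classwt, replace = TRUE))
  structure(
    list(task = task, forest = fit, feature_names = colnames(table),
         hyperparams = hyperparams,
         interest_threshold = if (task == "principal") interest_threshold
                              else NA_real_,
         training_report = list(
           oob_error = unname(fit$err.rate[fit$ntree, "OOB"]),
           class_counts = as.integer(freq),
           classes = names(freq))),
    class = "bb_behavior_model")
}

#' @export
print.bb_behavior_model <- function(x, ...) {
  cat(sprintf("<bb_behavior_model> task: %s, %d features, OOB error %.3f\n",
              x$task, length(x$feature_names), x$training_report$oob_error))
  if (x$task == "principal") {
    cat(sprintf("  interest threshold: %.2f\n", x$interest_threshold))
  }
  invisible(x)
}

check_features <- function(model, table) {
  missing_cols <- setdiff(model$feature_names, names(table))
  if (length(missing_cols) > 0) {
    stopf("missing feature column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  as.matrix(as.data.frame(table)[, model$feature_names, drop = FALSE])
}

#' Predict interest from a principal behavior model
#'
#' A track is labeled Interested when its forest-vote probability of being
#' Interested reaches the model's threshold (closed at the threshold:
#' probability exactly 0.52 is Interested, since misclassifications prevail
#' below it).
#'
#' @param model A principal-task `bb_behavior_model`.
#' @param table Feature data frame containing the model's features (an id
#'   column such as `track_id`, if present, is carried into the output).
#' @return Data frame `prob_interested`, `label` (plus `track_id` when
#'   present in the input).
#' @export
predict_interest <- function(model, table) {
  if (model$task != "principal") stopf("model is not a principal-task model")
  x <- check_features(model, table)
  prob <- predict(model$forest, newdata = x, type = "prob")[, "Interested"]
  out <- data.frame(
    prob_interested = as.numeric(prob),
    label = ifelse(prob >= model$interest_threshold, "Interested",
                   "Uninterested"),
    stringsAsFactors = FALSE)
  if ("track_id" %in% names(table)) {
    out <- cbind(data.frame(track_id = table$track_id), out)
  }
  out
}

#' Predict fine-scale behavior classes
#'
#' @param model A finescale-task `bb_behavior_model`.
#' @param table Feature data frame containing the model's features.
#' @return Data frame `label` (fine-scale class), `parent_label` (mapped
#'   principal class), plus `track_id` when present in the input.
#' @export
predict_finescale <- function(model, table) {
  if (model$task != "finescale") stopf("model is not a finescale-task model")
  x <- check_features(model, table)
  lab <- as.character(predict(model$forest, newdata = x, type = "response"))
  out <- data.frame(label = lab,
                    parent_label = map_finescale_to_parent(lab),
                    stringsAsFactors = FALSE)
  if ("track_id" %in% names(table)) {
    out <- cbind(data.frame(track_id = table$track_id), out)
  }
  out
}

#' Classification evaluation report
#'
#' Confusion matrix and the standard metrics. For a two-class task,
#' accuracy, precision, recall and F1 refer to the declared positive class
#' (Interested, for the principal task); macro-averaged precision/recall/F1
#' over all classes are reported alongside.
#'
#' @param predictions,truth Equal-length label vectors.
#' @param positive_class The class precision/recall/F1 are computed for;
#'   default `"Interested"`.
#' @return List of class `bb_eval_report`: `confusion`, `accuracy`,
#'   `precision`, `recall`, `f1`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `n`.
#' @export
evaluate <- function(predictions, truth, positive_class = "Interested") {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  if (length(predictions) != length(truth)) stopf("length mismatch")
  if (length(truth) == 0) stopf("empty input")
  classes <- sort(unique(c(predictions, truth)))
  cm <- table(factor(truth, classes), factor(predictions, classes),
              dnn = c("truth", "predicted"))
  per_class <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, f1 = f1)
  })
  names(per_class) <- classes
  pos <- if (positive_class %in% classes) per_class[[positive_class]] else
    c(precision = NA_real_, recall = NA_real_, f1 = NA_real_)
  macro <- rowMeans(do.call(cbind, per_class))
  structure(
    list(confusion = cm,
         accuracy = sum(diag(cm)) / sum(cm),
         precision = unname(pos["precision"]),
         recall = unname(pos["recall"]),
         f1 = unname(pos["f1"]),
         macro_precision = unname(macro["precision"]),
         macro_recall = unname(macro["recall"]),
         macro_f1 = unname(macro["f1"]),
         positive_class = positive_class,
         n = length(truth)),
    class = "bb_eval_report")
}

#' @export
print.bb_eval_report <- function(x, ...) {
  cat(sprintf("<bb_eval_report> n = %d, accuracy %.3f | %s: precision %.3f, recall %.3f, F1 %.3f\n",
              x$n, x$accuracy, x$positive_class, x$precision, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold cross-validation of a behavior classifier
#'
#' Rows are dealt into k folds class by class so every fold sees the global
#' class mix; each fold is predicted by a forest trained on the other k - 1.
#' The confusion matrix is pooled over folds.
#'
#' @param table Numeric feature data frame.
#' @param labels Class label per row.
#' @param task `"principal"` or `"finescale"`.
#' @param k Number of folds, default 5. Every class must have >= k members.
#' @param hyperparams Optional [rf_hyperparams()].
#' @param interest_threshold Principal-task decision threshold, default 0.52.
#' @param seed Integer seed.
#' @return List of class `bb_cv_report`: `pooled` (a [evaluate()] report over
#'   all folds), `folds` (per-fold reports), `k`.
#' @export
kfold_cv <- function(table, labels, task = c("principal", "finescale"),
                     k = 5, hyperparams = NULL, interest_threshold = 0.52,
                     seed = NULL) {
  task <- match.arg(task)
  labels <- as.character(labels)
  table <- as.data.frame(table)
  counts <- base::table(labels)
  if (min(counts) < k) {
    stopf("class '%s' has %d members, fewer than k = %d; use a smaller k",
          names(counts)[which.min(counts)], min(counts), k)
  }
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in names(counts)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    preds <- character(length(labels))
    fold_reports <- vector("list", k)
    for (fi in seq_len(k)) {
      test_idx <- which(fold == fi)
      train_idx <- which(fold != fi)
      model <- train_rf(table[train_idx, , drop = FALSE], labels[train_idx],
                        task = task, hyperparams = hyperparams,
                        interest_threshold = interest_threshold)
      preds[test_idx] <- if (task == "principal") {
        predict_interest(model, table[test_idx, , drop = FALSE])$label
      } else {
        predict_finescale(model, table[test_idx, , drop = FALSE])$label
      }
      fold_reports[[fi]] <- evaluate(preds[test_idx], labels[test_idx],
        positive_class = if (task == "principal") "Interested"
                         else names(counts)[1])
    }
    pooled <- evaluate(preds, labels,
      positive_class = if (task == "principal") "Interested"
                       else names(counts)[1])
    structure(list(pooled = pooled, folds = fold_reports, k = k),
              class = "bb_cv_report")
  })
}

#' @export
print.bb_cv_report <- function(x, ...) {
  cat(sprintf("<bb_cv_report> %d folds, pooled accuracy %.3f, F1 %.3f\n",
              x$k, x$pooled$accuracy, x$pooled$f1))
  invisible(x)
}
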
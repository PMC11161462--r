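separable_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- rep(principal_behaviors(), length.out = n)
  X <- data.frame(a = rnorm(n) + ifelse(y == "Interested", 0, 6),
                  b = rnorm(n), c = rnorm(n))
  list(X = X, y = y)
}

test_that("hyperparameter presets echo the tuned values", {
  hp <- rf_hyperparams("principal")
  expect_equal(unlist(hp[c("mtry", "ntree", "max_nodes", "node_size",
                           "samp_size")]),
               c(mtry = 1L, ntree = 100L, max_nodes = 50L, node_size = 2L,
                 samp_size = 50L))
  hf <- rf_hyperparams("finescale")
  expect_equal(unlist(hf[c("mtry", "ntree", "max_nodes", "node_size",
                           "samp_size")]),
               c(mtry = 5L, ntree = 650L, max_nodes = 50L, node_size = 5L,
                 samp_size = 150L))
  expect_equal(hp$class_weights, "inverse_frequency")
  expect_equal(hp$split_criterion, "gini")
})

test_that("stratified split keeps class shares in both halves", {
  y <- rep(c("Interested", "Uninterested"), each = 10)
  sp <- stratified_split(y, 0.5, seed = 1)
  expect_equal(sum(y[sp$train] == "Interested"), 5)
  expect_equal(sum(y[sp$test] == "Interested"), 5)
  expect_equal(sort(c(sp$train, sp$test)), 1:20)
  # two datasets x two classes: the split applies within each of 4 strata
  ds <- rep(c("y2019", "y2020"), times = 10)
  sp2 <- stratified_split(y, 0.5, dataset = ds, seed = 2)
  for (d in unique(ds)) {
    for (cl in unique(y)) {
      idx <- which(ds == d & y == cl)
      expect_equal(sum(sp2$train %in% idx), floor(length(idx) / 2))
    }
  }
  # singleton stratum goes to train with a warning
  expect_warning(sp3 <- stratified_split(c("A", "A", "B"), 0.5, seed = 3),
                 "size 1")
  expect_true(which(c("A", "A", "B") == "B") %in% sp3$train)
})

test_that("training respects its preconditions and is seeded", {
  d <- separable_data()
  expect_error(train_rf(d$X, d$y, hyperparams = rf_hyperparams("principal",
                                                               mtry = 10)),
               "mtry")
  expect_error(train_rf(d$X, rep("Interested", nrow(d$X))), "2 classes")
  expect_error(train_rf(d$X, rep(c("Up", "Down"), 60)), "taxonomy")
  m1 <- train_rf(d$X, d$y, seed = 5)
  m2 <- train_rf(d$X, d$y, seed = 5)
  expect_equal(predict_interest(m1, d$X)$prob_interested,
               predict_interest(m2, d$X)$prob_interested)
})

test_that("OOB error is near chance on permuted labels and near zero when separable", {
  d <- separable_data(n = 200, seed = 2)
  sep_oob <- train_rf(d$X, d$y, seed = 1)$training_report$oob_error
  expect_lte(sep_oob, 0.05)
  null_oobs <- vapply(1:20, function(s) {
    set.seed(s)
    train_rf(d$X, sample(d$y), seed = s)$training_report$oob_error
  }, numeric(1))
  # labels are balanced: chance is 0.5
  expect_lt(abs(mean(null_oobs) - 0.5), 0.10)
})

test_that("the interest decision is closed at the threshold", {
  d <- separable_data(seed = 3)
  model <- train_rf(d$X, d$y, seed = 4)
  # exercise the decision rule across the probability range
  probs <- predict_interest(model, d$X)$prob_interested
  labs <- predict_interest(model, d$X)$label
  expect_equal(labs, ifelse(probs >= 0.52, "Interested", "Uninterested"))
  # boundary behavior of the rule itself
  expect_equal(ifelse(0.52 >= model$interest_threshold, "Interested",
                      "Uninterested"), "Interested")
  expect_equal(ifelse(0.519 >= model$interest_threshold, "Interested",
                      "Uninterested"), "Uninterested")
  # raising the threshold never increases the Interested count
  counts <- vapply(c(0.2, 0.4, 0.52, 0.7, 0.9),
                   function(th) sum(probs >= th), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(predict_interest(model, d$X[, 1:2]), "missing feature")
})

test_that("fine-scale labels map onto their principal parents", {
  expect_equal(map_finescale_to_parent("Feeding"), "Interested")
  expect_equal(map_finescale_to_parent("Fleeing"), "Uninterested")
  expect_equal(map_finescale_to_parent(finescale_behaviors()),
               rep(c("Interested", "Uninterested"), each = 4))
  expect_error(map_finescale_to_parent("Hovering"), "unknown")
})

test_that("evaluation metrics equal their closed forms", {
  # TP = 9, TN = 9, FP = 1, FN = 1
  truth <- c(rep("Interested", 10), rep("Uninterested", 10))
  pred <- c(rep("Interested", 9), "Uninterested",
            rep("Uninterested", 9), "Interested")
  ev <- evaluate(pred, truth, positive_class = "Interested")
  expect_equal(ev$accuracy, 0.9)
  expect_equal(ev$precision, 0.9)
  expect_equal(ev$recall, 0.9)
  expect_equal(ev$f1, 0.9)
  all_right <- evaluate(truth, truth)
  expect_equal(all_right$accuracy, 1)
  expect_equal(all_right$f1, 1)
  expect_error(evaluate(character(0), character(0)), "empty")
})

test_that("evaluation matches an independent hand recomputation", {
  set.seed(6)
  for (rep in 1:10) {
    truth <- sample(c("Interested", "Uninterested"), 100, replace = TRUE)
    pred <- ifelse(runif(100) < 0.3,
                   sample(c("Interested", "Uninterested"), 100, replace = TRUE),
                   truth)
    ev <- evaluate(pred, truth)
    tp <- sum(pred == "Interested" & truth == "Interested")
    fp <- sum(pred == "Interested" & truth == "Uninterested")
    fn <- sum(pred == "Uninterested" & truth == "Interested")
    tn <- sum(pred == "Uninterested" & truth == "Uninterested")
    expect_equal(ev$accuracy, (tp + tn) / 100)
    expect_equal(ev$precision, tp / (tp + fp))
    expect_equal(ev$recall, tp / (tp + fn))
    expect_equal(ev$f1, 2 * tp / (2 * tp + fp + fn))
  }
})

test_that("stratified k-fold CV pools folds and respects class shares", {
  d <- separable_data(n = 100, seed = 7)
  cv <- kfold_cv(d$X, d$y, task = "principal", k = 5, seed = 8)
  expect_length(cv$folds, 5)
  expect_equal(cv$pooled$n, 100)
  expect_gte(cv$pooled$accuracy, 0.95)
  expect_equal(sum(cv$pooled$confusion), 100)
  expect_error(kfold_cv(d$X[1:6, ], d$y[1:6], k = 5), "smaller k")
})

test_that("fine-to-parent evaluation conserves totals", {
  sc <- test_scene()
  d <- fixture_deployment()
  fish <- d$fish
  feats <- fixture_features()
  fine <- d$labels$fine_label[fish]
  model <- train_rf(feats$table, fine, task = "finescale",
                    hyperparams = rf_hyperparams("finescale", ntree = 150),
                    seed = 9)
  pred <- predict_finescale(model, feats$table)
  expect_equal(pred$parent_label, map_finescale_to_parent(pred$label))
  ev_fine <- evaluate(pred$label, fine, positive_class = "Feeding")
  ev_parent <- evaluate(pred$parent_label, map_finescale_to_parent(fine))
  expect_equal(sum(ev_parent$confusion), sum(ev_fine$confusion))
})
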
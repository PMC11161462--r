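# Metric-pool reduction: pairwise-correlation filtering followed by
# Random-Forest recursive feature elimination with out-of-bag averaging.

#' Drop highly correlated metrics
#'
#' Greedy pairwise filter: while any pair of columns has |Pearson r| above
#' the threshold, the pair with the largest |r| is examined and the member
#' with the larger mean |r| against all remaining columns is dropped (ties
#' broken toward the lexicographically later name). Redundant metrics tend
#' to dilute Random Forest importance, hence the filter precedes selection.
#'
#' @param table Numeric data frame (metrics only, no id column).
#' @param r_threshold Absolute Pearson correlation above which a pair is
#'   redundant; default 0.90.
#' @return List with `table` (the reduced data frame) and `report`, a data
#'   frame of `(kept, dropped, r)` rows in drop order.
#' @details Constant columns have undefined correlations; these are treated
#'   as 0 with a warning, so constant columns are never dropped by the
#'   filter. The filter is idempotent and its output contains no pair above
#'   the threshold.
#' @export
correlation_filter <- function(table, r_threshold = 0.90) {
  table <- as.data.frame(table)
  if (nrow(table) < 2) stopf("correlation filter needs >= 2 rows")
  non_num <- names(table)[!vapply(table, is.numeric, logical(1))]
  if (length(non_num) > 0) {
    stopf("non-numeric column(s): %s", paste(non_num, collapse = ", "))
  }
  cm <- suppressWarnings(abs(cor(table)))
  if (any(is.na(cm))) {
    warnf("constant column(s) give undefined correlations; treated as 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 0
  dropped <- list()
  # strict "exceeds" with a tiny numerical guard so that exact duplicates
  # (r = 1) are still redundant at threshold 1.0
  while (max(cm) > r_threshold - 1e-12) {
    idx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    a <- rownames(cm)[idx[1]]
    b <- colnames(cm)[idx[2]]
    mean_a <- mean(cm[a, ])
    mean_b <- mean(cm[b, ])
    drop <- if (mean_a > mean_b) a
            else if (mean_b > mean_a) b
            else sort(c(a, b))[2]  # tie: lexicographically later name
    keep <- setdiff(c(a, b), drop)
    dropped[[length(dropped) + 1L]] <- data.frame(
      kept = keep, dropped = drop, r = cm[a, b], stringsAsFactors = FALSE)
    cm <- cm[rownames(cm) != drop, colnames(cm) != drop, drop = FALSE]
    if (nrow(cm) < 2) break
  }
  report <- if (length(dropped) > 0) {
    do.call(rbind, dropped)
  } else {
    data.frame(kept = character(0), dropped = character(0), r = numeric(0))
  }
  list(table = table[, setdiff(names(table), report$dropped), drop = FALSE],
       report = report)
}

# Mean OOB error and mean per-feature Gini importance over n_iterations
# default-hyperparameter forests.
rf_oob_importance <- function(x, y, n_iterations, hyperparams = list()) {
  errs <- numeric(n_iterations)
  imp <- matrix(0, nrow = ncol(x), ncol = n_iterations,
                dimnames = list(colnames(x), NULL))
  for (i in seq_len(n_iterations)) {
    fit <- do.call(randomForest::randomForest,
                   c(list(x = x, y = y), hyperparams))
    errs[i] <- fit$err.rate[fit$ntree, "OOB"]
    imp[, i] <- fit$importance[colnames(x), "MeanDecreaseGini"]
  }
  # SE of the averaged OOB estimate: binomial uncertainty of an error rate
  # measured on nrow(x) out-of-bag predictions, plus the Monte Carlo
  # component from averaging a finite number of forests
  m <- mean(errs)
  mc_var <- if (n_iterations > 1) stats::var(errs) / n_iterations else 0
  list(mean_oob = m,
       se_oob = sqrt(m * (1 - m) / nrow(x) + mc_var),
       mean_importance = rowMeans(imp))
}

#' Recursive feature elimination by Random Forest importance
#'
#' Backward elimination on mean-decrease-Gini importance: at each step the
#' least important features are dropped (20% of the set while more than 30
#' features remain, one at a time below that). At every feature count the
#' out-of-bag error is averaged over `n_iterations` forests with default
#' hyperparameters. The selected set is, under the default `"one_se"` rule,
#' the smallest feature count whose mean OOB error is within one standard
#' error of the global minimum — operationalizing "lowest OOB error with the
#' smallest set of features"; `rule = "min"` takes the strict minimum
#' (smallest count among ties). The standard error combines the binomial
#' uncertainty of an error rate estimated on `nrow(table)` out-of-bag
#' predictions with the Monte Carlo error of the `n_iterations` average, so
#' the rule keys on real uncertainty rather than on forest-to-forest noise
#' alone.
#'
#' @param table Numeric feature data frame.
#' @param labels Factor (or coercible) class labels, one per row.
#' @param n_iterations Forests averaged per feature count; default 1000
#'   (use ~25 for small experiments).
#' @param rule `"one_se"` or `"min"`.
#' @param hyperparams Named list of [randomForest::randomForest()] arguments
#'   overriding its defaults (e.g. `list(ntree = 250)`); empty by default —
#'   the elimination runs on default-hyperparameter forests.
#' @param seed Master seed for the whole elimination path.
#' @return List of class `bb_selection_report`: `selected_features`,
#'   `rfe_curve` (data frame `n_features`, `mean_oob`, `se_oob`),
#'   `feature_sets` (the set at each count), `n_iterations`, `rule`.
#' @export
rfe_select <- function(table, labels, n_iterations = 1000,
                       rule = c("one_se", "min"), hyperparams = list(),
                       seed = NULL) {
  rule <- match.arg(rule)
  table <- as.data.frame(table)
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stopf("need >= 2 label classes")
  if (min(base::table(labels)) < 2) stopf("each class needs >= 2 samples")
  if (n_iterations < 1) stopf("n_iterations must be >= 1")
  with_seed(seed, {
    feats <- names(table)
    curve <- list()
    sets <- list()
    while (length(feats) >= 1) {
      x <- as.matrix(table[, feats, drop = FALSE])
      res <- rf_oob_importance(x, labels, n_iterations, hyperparams)
      curve[[length(curve) + 1L]] <- data.frame(
        n_features = length(feats), mean_oob = res$mean_oob,
        se_oob = res$se_oob)
      sets[[as.character(length(feats))]] <- feats
      if (length(feats) == 1) break
      n_drop <- if (length(feats) > 30) {
        max(1L, floor(0.2 * length(feats)))
      } else {
        1L
      }
      order_imp <- order(res$mean_importance, decreasing = FALSE)
      feats <- setdiff(feats, feats[order_imp[seq_len(n_drop)]])
    }
    curve <- do.call(rbind, curve)
    i_min <- which.min(curve$mean_oob)
    threshold <- curve$mean_oob[i_min] +
      if (rule == "one_se") curve$se_oob[i_min] else 0
    ok <- which(curve$mean_oob <= threshold)
    chosen <- ok[which.min(curve$n_features[ok])]
    structure(
      list(selected_features = sets[[as.character(curve$n_features[chosen])]],
           rfe_curve = curve, feature_sets = sets,
           n_iterations = n_iterations, rule = rule),
      class = "bb_selection_report")
  })
}

#' @export
print.bb_selection_report <- function(x, ...) {
  cat(sprintf("<bb_selection_report> %d features selected (rule: %s, %d iterations)\n",
              length(x$selected_features), x$rule, x$n_iterations))
  cat("  ", paste(x$selected_features, collapse = ", "), "\n")
  best <- x$rfe_curve[which.min(x$rfe_curve$mean_oob), ]
  cat(sprintf("  min mean OOB %.4f at %d features\n",
              best$mean_oob, best$n_features))
  invisible(x)
}
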
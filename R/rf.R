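#' Train the random-forest classifier
#'
#' Thin wrapper around [ranger::ranger()] growing a probability forest on a
#' numeric feature matrix with binary labels. A single integer seed controls
#' bootstrap sampling and tree construction, so repeated fits are identical.
#'
#' @param x Numeric feature matrix (rows = samples, named columns).
#' @param y Binary 0/1 labels, both classes present.
#' @param num_trees Number of trees, the one hyperparameter worth tuning
#'   here; default 1500.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [ranger::ranger()] (e.g. `mtry`,
#'   `min.node.size`).
#' @return A `ranger` probability forest.
#' @export
train_rf <- function(x, y, num_trees = 1500, seed = 1, ...) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) {
    stop("labels contain a single class; cannot train", call. = FALSE)
  }
  df <- as.data.frame(x)
  df$.class <- factor(y, levels = c(0L, 1L))
  ranger::ranger(dependent.variable.name = ".class", data = df,
                 num.trees = num_trees, probability = TRUE,
                 seed = seed, num.threads = 1L, ...)
}

# Positive-class probability scores from a trained forest.
rf_scores <- function(fit, x) {
  predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions[, "1"]
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `folds` test folds so that the folds
#' partition the indices and each class is spread across folds within one
#' sample of evenness.
#'
#' @param labels Class labels (used for stratification).
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..folds`, one per sample.
#' @export
kfold_split <- function(labels, folds = 10, seed = 1) {
  n <- length(labels)
  if (folds > n) stop("more folds than samples", call. = FALSE)
  if (any(table(labels) < folds)) {
    stop("every class must have at least `folds` members for stratified folds",
         call. = FALSE)
  }
  assign <- integer(n)
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      assign[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  assign
}

#' Cross-validate the IPCA + random-forest pipeline
#'
#' Runs stratified k-fold cross-validation of the full classification stage:
#' within each fold the IPCA reduction (optional) and the forest are fitted on
#' the training samples only and applied to the held-out fold, so no
#' information leaks from test to train. Threshold-0.5 metrics and the
#' fold-wise ROC/AUC are reported per fold and aggregated as mean and
#' standard deviation; the pooled out-of-fold scores are kept for plotting a
#' single ROC curve.
#'
#' @param x Feature matrix (rows = samples).
#' @param y Binary labels.
#' @param folds Number of folds (default 10).
#' @param num_trees Trees per forest.
#' @param seed Integer seed (controls folds and forests).
#' @param use_ipca Apply the IPCA reduction before the forest.
#' @param n_components,k IPCA size parameters (see [ipca()]).
#' @param f1 F1 variant, see [classification_metrics()].
#' @return Object of class `ipcarf_cv`: `per_fold` data frame, `aggregate`
#'   (mean/sd per metric), `roc` (pooled out-of-fold curve), `scores`,
#'   `labels`, `fold` assignment and the configuration used.
#' @export
cross_validate <- function(x, y, folds = 10, num_trees = 1500, seed = 1,
                           use_ipca = TRUE, n_components = NULL, k = NULL,
                           f1 = "standard") {
  y <- as.integer(y)
  fold <- kfold_split(y, folds = folds, seed = seed)
  scores <- numeric(length(y))
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold == f
    xtr <- x[!test, , drop = FALSE]; xte <- x[test, , drop = FALSE]
    if (use_ipca) {
      red <- ipca(xtr, n_components = n_components, k = k)
      xtr <- predict(red, xtr)
      xte <- predict(red, xte)
    }
    rf <- train_rf(xtr, y[!test], num_trees = num_trees, seed = seed + f)
    sc <- rf_scores(rf, xte)
    scores[test] <- sc
    m <- classification_metrics(labels = y[test],
                                predicted = as.integer(sc >= 0.5), f1 = f1)
    per_fold[[f]] <- c(fold = f, m, auc = roc_curve(y[test], sc)$auc)
  }
  per_fold <- as.data.frame(do.call(rbind, per_fold))
  metric_cols <- setdiff(names(per_fold), "fold")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(per_fold[metric_cols], function(v) mean(v[is.finite(v)]), 0),
    sd = vapply(per_fold[metric_cols], function(v) sd(v[is.finite(v)]), 0),
    row.names = NULL)
  structure(list(per_fold = per_fold, aggregate = aggregate,
                 roc = roc_curve(y, scores), scores = scores, labels = y,
                 fold = fold,
                 config = list(folds = folds, num_trees = num_trees,
                               seed = seed, use_ipca = use_ipca,
                               n_components = n_components, k = k, f1 = f1)),
            class = "ipcarf_cv")
}

#' @export
print.ipcarf_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (num_trees = %d, %s)\n",
              x$config$folds, x$config$num_trees,
              if (x$config$use_ipca) "IPCA + RF" else "RF only"))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-9s %.4f (sd %.4f)\n", agg$metric[i], agg$mean[i], agg$sd[i]))
  }
  invisible(x)
}

#' Grid search over the forest size
#'
#' Evaluates each candidate number of trees by k-fold cross-validated mean
#' AUC on a shared fold assignment and returns the winner; ties go to the
#' smallest forest. The full score table is returned for inspection.
#'
#' @inheritParams cross_validate
#' @param grid Candidate `num_trees` values; default
#'   `c(100, 500, 1000, 1500, 2000, 2500)`.
#' @param folds Folds for the inner evaluation (default 5).
#' @return List of class `ipcarf_grid`: `best` (the selected `num_trees`) and
#'   `table` (data frame of grid value, mean and sd of fold AUC).
#' @export
grid_search_trees <- function(x, y, grid = c(100, 500, 1000, 1500, 2000, 2500),
                              folds = 5, seed = 1, use_ipca = TRUE,
                              n_components = NULL, k = NULL) {
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  grid <- sort(unique(as.integer(grid)))
  rows <- lapply(grid, function(nt) {
    cv <- cross_validate(x, y, folds = folds, num_trees = nt, seed = seed,
                         use_ipca = use_ipca, n_components = n_components, k = k)
    data.frame(num_trees = nt,
               mean_auc = mean(cv$per_fold$auc),
               sd_auc = sd(cv$per_fold$auc))
  })
  tab <- do.call(rbind, rows)
  best <- tab$num_trees[which.max(tab$mean_auc)]  # grid sorted: ties -> smallest
  structure(list(best = best, table = tab), class = "ipcarf_grid")
}

#' @export
print.ipcarf_grid <- function(x, ...) {
  cat("grid search over num_trees:\n")
  print(x$table, row.names = FALSE)
  cat("best:", x$best, "\n")
  invisible(x)
}
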
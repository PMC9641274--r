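subset_features <- function(x, idx) {
  if (is.matrix(x)) return(x[idx, , drop = FALSE])
  if (is.list(x)) return(lapply(x, function(m) m[idx, , drop = FALSE]))
  config_error("features must be materialized (matrix or list) for an experiment")
}

#' Repeated-split evaluation of a burn classifier
#'
#' Mirrors the evaluation protocol used to report classifier performance:
#' the observations are split at the ROI level into 80% training / 20% test
#' (stratified), the classifier is tuned by five-fold cross-validation on
#' the training set and refit, and sensitivity, specificity, accuracy and
#' ROC-AUC are recorded on the training, validation (the pooled five-fold
#' estimates of the winning configuration) and test sets.  The whole
#' procedure is repeated `n_iterations` times with fresh random splits, and
#' the report carries the per-iteration values with their means and
#' standard deviations.
#'
#' @param x features: matrix or named list of matrices (see [burn_svm()]);
#'   a function is materialized over the grid's wavelet/level combinations
#'   first.
#' @param y class labels, one per observation.
#' @param grid a [tuning_grid()].
#' @param task `"binary"` or `"multiclass"` (default from `nlevels(y)`).
#' @param n_iterations number of random split iterations (default 20).
#' @param train_fraction training fraction of each split (default 0.8).
#' @param cv_folds cross-validation folds (default 5).
#' @param seed base seed; iteration `i` uses `seed + i`.
#' @param positive positive class for binary metrics (default: first factor
#'   level).
#' @return An object of class `burn_eval`: list with `metrics` (long data
#'   frame: iteration, set, class, the four metrics), `aggregate` (mean and
#'   sd by set and class), `configs` (winning configuration per iteration),
#'   `sizes`, `task`, `n_iterations`.
#' @export
burn_experiment <- function(x, y, grid = tuning_grid(), task = NULL,
                            n_iterations = 20, train_fraction = 0.8,
                            cv_folds = 5, seed = 1, positive = NULL) {
  y <- droplevels(as.factor(y))
  task <- task %||% if (nlevels(y) == 2) "binary" else "multiclass"
  if (is.function(x)) {
    mats <- list()
    for (w in grid$wavelets) for (l in grid$levels)
      mats[[feature_key(w, l)]] <- x(w, l)
    x <- mats
  }
  positive <- positive %||% levels(y)[1]
  classes <- if (task == "binary") positive else levels(y)

  metric_rows <- list()
  config_rows <- list()
  sizes <- NULL
  for (it in seq_len(n_iterations)) {
    it_seed <- seed + it
    sp <- split_observations(y, train_fraction, seed = it_seed)
    xtr <- subset_features(x, sp$train); ytr <- y[sp$train]
    xte <- subset_features(x, sp$test);  yte <- y[sp$test]
    fit <- burn_svm(xtr, ytr, grid, task = task, cv_folds = cv_folds,
                    seed = it_seed)
    sizes <- rbind(sizes, c(train = length(sp$train), test = length(sp$test)))

    sets <- list(
      training = list(truth = ytr,
                      pred = predict(fit, xtr, type = "class"),
                      prob = predict(fit, xtr, type = "prob")),
      validation = list(truth = fit$validation$truth,
                        pred = fit$validation$class,
                        prob = fit$validation$prob),
      test = list(truth = yte,
                  pred = predict(fit, xte, type = "class"),
                  prob = predict(fit, xte, type = "prob")))
    for (set_name in names(sets)) {
      s <- sets[[set_name]]
      for (cl in classes) {
        m <- classification_metrics(as.character(s$truth),
                                    as.character(s$pred),
                                    s$prob[, cl], positive = cl)
        metric_rows[[length(metric_rows) + 1L]] <-
          data.frame(iteration = it, set = set_name, class = cl,
                     sensitivity = m[["sensitivity"]],
                     specificity = m[["specificity"]],
                     accuracy = m[["accuracy"]],
                     roc_auc = m[["roc_auc"]])
      }
    }
    config_rows[[it]] <- cbind(iteration = it, fit$config)
  }
  metrics <- do.call(rbind, metric_rows)
  metrics$set <- factor(metrics$set, levels = c("training", "validation", "test"))
  agg <- do.call(rbind, lapply(split(metrics, metrics[c("set", "class")]),
    function(d) {
      data.frame(set = d$set[1], class = d$class[1],
                 t(colMeans(d[c("sensitivity", "specificity", "accuracy",
                                "roc_auc")])),
                 sd_accuracy = stats::sd(d$accuracy))
    }))
  rownames(agg) <- NULL
  structure(list(metrics = metrics, aggregate = agg,
                 configs = do.call(rbind, config_rows),
                 sizes = sizes, task = task,
                 n_iterations = n_iterations, positive = positive),
            class = "burn_eval")
}

#' @export
print.burn_eval <- function(x, ...) {
  cat(sprintf("<burn_eval> %s task, %d split iterations (train %d / test %d)\n",
              x$task, x$n_iterations, x$sizes[1, "train"], x$sizes[1, "test"]))
  cat("  mean (sd of accuracy) over iterations, %:\n")
  a <- x$aggregate
  a[c("sensitivity", "specificity", "accuracy", "roc_auc", "sd_accuracy")] <-
    round(a[c("sensitivity", "specificity", "accuracy", "roc_auc",
              "sd_accuracy")], 1)
  print(a, row.names = FALSE)
  invisible(x)
}

#' @export
summary.burn_eval <- function(object, ...) {
  print(object)
  invisible(object$aggregate)
}
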
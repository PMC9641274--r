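# Label assignment, splitting, metrics, SVM tuning, ECOC structure.

test_that("histological thresholds map to severity and healing classes", {
  mk <- function(d, r, e = "scald") site_label("s", e, d, r)
  expect_equal(assign_labels(mk(45, 50))$severity, "SPT")
  expect_equal(assign_labels(mk(60, 50))$severity, "DPT")   # closed interval
  expect_equal(assign_labels(mk(90, 50))$severity, "DPT")
  expect_equal(assign_labels(mk(90.1, 50))$severity, "FT")
  expect_equal(assign_labels(mk(59.9, 50))$severity, "SPT")
  expect_equal(assign_labels(mk(0, 100, "healthy"))$severity, "H")
  expect_equal(assign_labels(mk(45, 100))$healing, "FR")
  expect_equal(assign_labels(mk(45, 99))$healing, "NPR")
  expect_error(site_label("s", "scald", 101, 50),
               class = "thzburn_label_error")
})

test_that("splits are stratified, sized and reproducible", {
  y <- factor(rep(c("a", "b", "c"), c(50, 30, 20)))
  sp <- split_observations(y, 0.8, seed = 1)
  expect_length(sp$train, 80)
  expect_length(sp$test, 20)
  expect_equal(as.vector(table(y[sp$train])), c(40, 24, 16))
  expect_identical(split_observations(y, 0.8, seed = 1), sp)
  expect_false(identical(split_observations(y, 0.8, seed = 2)$train, sp$train))
  expect_error(split_observations(factor(c("a", "a", "b")), 0.8),
               class = "thzburn_partition_error")
})

test_that("confusion metrics and tie-aware AUC match hand arithmetic", {
  truth <- rep(c("P", "N"), c(10, 10))
  pred <- c(rep("P", 8), "N", "N", "P", rep("N", 9))
  m <- classification_metrics(truth, pred, positive = "P")
  expect_equal(unname(m[1:3]), c(80, 90, 85))
  expect_equal(roc_auc(truth == "P", c(11:20, 1:10)), 100)  # perfect ranking
  expect_equal(roc_auc(truth == "P", rep(0.5, 20)), 50)    # all tied
  expect_error(roc_auc(rep(TRUE, 5), rnorm(5)), class = "thzburn_metric_error")
  expect_error(classification_metrics(rep("P", 5), rep("P", 5), positive = "P"),
               class = "thzburn_metric_error")
})

test_that("rank-based AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  truth <- rbinom(60, 1, 0.4)
  scores <- rnorm(60) + truth
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE)))
  expect_equal(roc_auc(truth == 1, scores), 100 * ref, tolerance = 1e-10)
})

test_that("tuning grid enforces the searchable ranges", {
  expect_error(tuning_grid(levels = 7), class = "thzburn_config_error")
  expect_error(tuning_grid(polynomial_order = 1),
               class = "thzburn_config_error")
  expect_error(tuning_grid(wavelets = "db11"), class = "thzburn_config_error")
  g <- tuning_grid()
  expect_equal(g$polynomial_order, 2:20)
  expect_equal(g$levels, 8:13)
})

test_that("a single-candidate grid is chosen and refit", {
  set.seed(31)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  y <- factor(rep(c("a", "b"), each = 20))
  g <- tuning_grid(kernels = "gaussian", kernel_scale = 1,
                   box_constraint = 1, wavelets = "db1", levels = 8)
  fit <- burn_svm(x, y, g, seed = 1)
  expect_equal(nrow(fit$cv_table), 1)
  expect_equal(fit$config$kernel_scale, 1)
  p <- predict(fit, x, type = "prob")
  expect_equal(unname(rowSums(p)), rep(1, 40), tolerance = 1e-9)
  expect_true(all(p[cbind(seq_len(40), match(y, colnames(p)))] > 0.9))
  expect_equal(as.character(predict(fit, x)), as.character(y))
})

test_that("grid search picks the feature set that separates the classes", {
  # class signal lives only in the level-"12"-keyed features
  set.seed(32)
  y <- factor(rep(c("a", "b"), each = 30))
  noise <- matrix(rnorm(60 * 4), 60)
  signal <- noise + 2 * (as.integer(y) - 1.5)
  picks <- vapply(1:5, function(s) {
    feats <- list("db1.J8" = noise + rnorm(240) * 0.1,
                  "db1.J12" = signal)
    g <- tuning_grid(kernels = "gaussian", kernel_scale = 2,
                     box_constraint = 1, wavelets = "db1", levels = c(8, 12))
    burn_svm(feats, y, g, seed = s)$config$level
  }, numeric(1))
  expect_gte(sum(picks == 12), 4)
})

test_that("the winner's validation accuracy is at least every rival's", {
  d <- demo_binary_features(strong_pair, seed = 7, sites_per_class = 1)
  g <- tuning_grid(kernels = "gaussian", kernel_scale = c(0.1, 2, 50),
                   box_constraint = c(0.1, 10), wavelets = "db1", levels = 8)
  fit <- burn_svm(d$x, d$y, g, seed = 3)
  expect_equal(fit$config$cv_loss, min(fit$cv_table$cv_loss))
})

test_that("one-vs-all builds 4 learners for 4 classes, one-vs-one builds 6", {
  set.seed(33)
  x <- matrix(rnorm(80 * 3), 80)
  x[, 1] <- x[, 1] + rep(c(0, 4, 8, 12), each = 20)
  y <- factor(rep(c("H", "SPT", "DPT", "FT"), each = 20),
              levels = c("H", "SPT", "DPT", "FT"))
  for (cfg in list(c("onevsall", 4L), c("onevsone", 6L))) {
    g <- tuning_grid(kernels = "gaussian", kernel_scale = 2,
                     box_constraint = 1, coding = cfg[1],
                     wavelets = "db1", levels = 8)
    fit <- burn_svm(x, y, g, seed = 1)
    expect_length(fit$model$learners, as.integer(cfg[2]))
    pr <- predict(fit, x, type = "prob")
    expect_equal(dim(pr), c(80L, 4L))
    expect_equal(unname(rowSums(pr)), rep(1, 80), tolerance = 1e-9)
    expect_gt(mean(predict(fit, x) == y), 0.9)
  }
})

test_that("duplicating a training observation reproduces its label at large margin", {
  set.seed(34)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- factor(rep(c("a", "b"), each = 20))
  fit <- burn_svm(x, y, tuning_grid(kernels = "gaussian", kernel_scale = 2,
                                    box_constraint = 10, wavelets = "db1",
                                    levels = 8), seed = 2)
  expect_equal(as.character(predict(fit, x[c(3, 25), , drop = FALSE])),
               c("a", "b"))
})

test_that("the experiment report carries one row per iteration, set and class", {
  d <- demo_binary_features(strong_pair, seed = 7, sites_per_class = 1)
  ev <- burn_experiment(d$x, d$y, small_grid(), n_iterations = 3, seed = 5)
  expect_equal(nrow(ev$metrics), 3 * 3)      # 3 iterations x 3 sets, 1 class
  expect_equal(sum(ev$metrics$set == "test"), 3)
  # aggregates equal recomputation from the stored per-iteration values
  test_acc <- ev$metrics$accuracy[ev$metrics$set == "test"]
  agg <- ev$aggregate[ev$aggregate$set == "test", ]
  expect_equal(agg$accuracy, mean(test_acc))
  expect_equal(agg$sd_accuracy, sd(test_acc))
})

test_that("label permutation drives the classifier to chance", {
  d <- demo_binary_features(strong_pair, seed = 7)
  set.seed(42)
  yperm <- sample(d$y)
  sp <- split_observations(yperm, 0.8, seed = 1)
  fit <- burn_svm(d$x[sp$train, ], yperm[sp$train], small_grid(), seed = 1)
  acc <- 100 * mean(predict(fit, d$x[sp$test, ]) == yperm[sp$test])
  expect_lt(abs(acc - 50), 15)
})
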
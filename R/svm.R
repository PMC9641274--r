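#' Hyperparameter grid for burn classifiers
#'
#' The searchable space of the SVM and feature-extraction settings: kernel
#' family (Gaussian or polynomial), kernel scale, box constraint, polynomial
#' order 2-20, multiclass coding (one-vs-one or one-vs-all), Daubechies
#' mother wavelet db1-db10 and decomposition level 8-13.  Any subset of the
#' full ranges may be searched, but values outside them are rejected.
#'
#' The kernel scale `s` follows the convention `K(x, y) =
#' exp(-||x - y||^2 / s^2)` for the Gaussian kernel and `K(x, y) =
#' (1 + x'y / s^2)^d` for the polynomial kernel.
#'
#' @param kernels subset of `c("gaussian", "polynomial")`.
#' @param kernel_scale positive grid of kernel scales.
#' @param box_constraint positive grid of SVM cost values.
#' @param polynomial_order integer orders within 2..20 (used only with the
#'   polynomial kernel).
#' @param coding multiclass reduction: `"onevsone"` (6 binary learners for 4
#'   classes) or `"onevsall"` (4 learners).
#' @param wavelets Daubechies names within db1..db10.
#' @param levels decomposition levels within 8..13.
#' @return An object of class `tuning_grid`.
#' @export
tuning_grid <- function(kernels = c("gaussian", "polynomial"),
                        kernel_scale = 10^seq(-2, 2, length.out = 7),
                        box_constraint = 10^seq(-2, 2, length.out = 7),
                        polynomial_order = 2:20,
                        coding = c("onevsone", "onevsall"),
                        wavelets = paste0("db", 1:10),
                        levels = 8:13) {
  # config files may deliver sequences as lists; flatten before validating
  kernels <- as.character(unlist(kernels))
  coding <- as.character(unlist(coding))
  kernel_scale <- as.numeric(unlist(kernel_scale))
  box_constraint <- as.numeric(unlist(box_constraint))
  polynomial_order <- as.numeric(unlist(polynomial_order))
  wavelets <- as.character(unlist(wavelets))
  levels <- as.numeric(unlist(levels))
  kernels <- match.arg(kernels, c("gaussian", "polynomial"), several.ok = TRUE)
  coding <- match.arg(coding, c("onevsone", "onevsall"), several.ok = TRUE)
  if (length(kernel_scale) == 0 || any(kernel_scale <= 0))
    config_error("'kernel_scale' must be a non-empty positive grid")
  if (length(box_constraint) == 0 || any(box_constraint <= 0))
    config_error("'box_constraint' must be a non-empty positive grid")
  if (length(polynomial_order) == 0 ||
      any(polynomial_order != round(polynomial_order)) ||
      any(polynomial_order < 2 | polynomial_order > 20))
    config_error("'polynomial_order' must be integers within 2..20")
  if (!all(wavelets %in% paste0("db", 1:10)))
    config_error("'wavelets' must be within db1..db10")
  if (length(levels) == 0 || any(!levels %in% 8:13))
    config_error("'levels' must be within 8..13")
  structure(list(kernels = kernels, kernel_scale = kernel_scale,
                 box_constraint = box_constraint,
                 polynomial_order = as.integer(polynomial_order),
                 coding = coding, wavelets = wavelets,
                 levels = as.integer(levels)),
            class = "tuning_grid")
}

expand_candidates <- function(grid, task, tune_features) {
  combos <- if (tune_features)
    expand.grid(wavelet = grid$wavelets, level = grid$levels,
                stringsAsFactors = FALSE)
  else data.frame(wavelet = NA_character_, level = NA_integer_)
  kern <- list()
  if ("gaussian" %in% grid$kernels)
    kern$gaussian <- expand.grid(kernel = "gaussian",
                                 kernel_scale = grid$kernel_scale,
                                 degree = NA_integer_,
                                 box_constraint = grid$box_constraint,
                                 stringsAsFactors = FALSE)
  if ("polynomial" %in% grid$kernels)
    kern$polynomial <- expand.grid(kernel = "polynomial",
                                   kernel_scale = grid$kernel_scale,
                                   degree = grid$polynomial_order,
                                   box_constraint = grid$box_constraint,
                                   stringsAsFactors = FALSE)
  kern <- do.call(rbind, kern)
  coding <- if (task == "multiclass") grid$coding else "binary"
  out <- merge(merge(combos, kern, by = NULL),
               data.frame(coding = coding, stringsAsFactors = FALSE),
               by = NULL)
  rownames(out) <- NULL
  out
}

# Feature accessor: a matrix (fixed features), a named list keyed
# "dbX.JY", or a function(wavelet, level) returning a matrix.
feature_accessor <- function(x) {
  if (is.function(x)) return(list(fun = x, tune = TRUE))
  if (is.matrix(x)) return(list(fun = function(w, l) x, tune = FALSE))
  if (is.list(x)) {
    return(list(fun = function(w, l) {
      key <- feature_key(w, l)
      if (is.null(x[[key]]))
        config_error(sprintf("no feature matrix supplied for %s", key))
      x[[key]]
    }, tune = TRUE))
  }
  config_error("'x' must be a feature matrix, a named list of matrices, or a function(wavelet, level)")
}

#' @rdname burn_svm
#' @param wavelet,level the combination to key.
#' @export
feature_key <- function(wavelet, level) sprintf("%s.J%d", wavelet, as.integer(level))

make_folds <- function(y, k, max_tries = 20L) {
  for (try in seq_len(max_tries)) {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(sample.int(k), length(idx))
    }
    ok <- all(vapply(seq_len(k), function(f)
      nlevels(droplevels(y[fold != f])) == nlevels(y), logical(1)))
    if (ok) return(fold)
    warning("degenerate single-class fold; resampling folds")
  }
  partition_error("could not build folds with every class in each training part")
}

zscale <- function(x, center = NULL, scale = NULL) {
  if (is.null(center)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
  }
  list(x = sweep(sweep(x, 2, center), 2, scale, "/"),
       center = center, scale = scale)
}

svm_args <- function(params, d) {
  if (params$kernel == "gaussian")
    list(kernel = "radial", gamma = 1 / params$kernel_scale^2,
         cost = params$box_constraint)
  else
    list(kernel = "polynomial", degree = params$degree,
         gamma = 1 / params$kernel_scale^2, coef0 = 1,
         cost = params$box_constraint)
}

fit_learner <- function(x, y, params, probability = FALSE) {
  do.call(e1071::svm,
          c(list(x = x, y = y, probability = probability, scale = FALSE),
            svm_args(params, ncol(x))))
}

# --- ECOC: multiclass from binary SVMs under a coding design ---------------

coding_matrix <- function(classes, coding) {
  K <- length(classes)
  if (coding == "onevsall") {
    M <- matrix(-1, K, K, dimnames = list(classes, NULL))
    diag(M) <- 1
  } else {
    pairs <- utils::combn(K, 2)
    M <- matrix(0, K, ncol(pairs), dimnames = list(classes, NULL))
    for (l in seq_len(ncol(pairs))) {
      M[pairs[1, l], l] <- 1
      M[pairs[2, l], l] <- -1
    }
  }
  M
}

ecoc_fit <- function(x, y, params, coding) {
  classes <- levels(y)
  M <- coding_matrix(classes, coding)
  learners <- lapply(seq_len(ncol(M)), function(l) {
    m <- M[as.character(y), l]
    keep <- m != 0
    yl <- factor(ifelse(m[keep] > 0, "pos", "neg"), levels = c("pos", "neg"))
    fit_learner(x[keep, , drop = FALSE], yl, params)
  })
  structure(list(learners = learners, M = M, classes = classes,
                 params = params),
            class = "ecoc_svm")
}

ecoc_scores <- function(model, x) {
  f <- vapply(model$learners, function(lm) {
    dv <- attr(stats::predict(lm, x, decision.values = TRUE),
               "decision.values")
    # libsvm orients the decision value toward whichever class appeared
    # first in the training data; normalize so positive always means "pos"
    d <- as.numeric(dv[, 1])
    if (!startsWith(colnames(dv)[1], "pos")) -d else d
  }, numeric(nrow(x)))
  if (is.null(dim(f))) f <- matrix(f, nrow = nrow(x))
  scores <- sweep(f %*% t(model$M), 2, rowSums(abs(model$M)), "/")
  colnames(scores) <- model$classes
  scores
}

ecoc_predict <- function(model, x) {
  s <- ecoc_scores(model, x)
  p <- exp(s - apply(s, 1, max))
  p <- p / rowSums(p)
  cls <- factor(model$classes[max.col(p, ties.method = "first")],
                levels = model$classes)
  list(class = cls, prob = p)
}

fit_task_model <- function(x, y, params, task, probability = FALSE) {
  if (task == "binary") fit_learner(x, y, params, probability = probability)
  else ecoc_fit(x, y, params, params$coding)
}

predict_task_model <- function(model, x, task, levels_y) {
  if (task == "binary") {
    if (inherits(model, "svm") && !is.null(model$compprob) && model$compprob) {
      pr <- stats::predict(model, x, probability = TRUE)
      p <- attr(pr, "probabilities")[, levels_y, drop = FALSE]
      list(class = factor(as.character(pr), levels = levels_y), prob = p)
    } else {
      pr <- stats::predict(model, x, decision.values = TRUE)
      dv <- as.numeric(attr(pr, "decision.values"))
      pos <- sub("/.*$", "", colnames(attr(pr, "decision.values")))
      p1 <- 1 / (1 + exp(-dv))    # monotone score -> pseudo-probability
      p <- cbind(p1, 1 - p1)
      colnames(p) <- c(pos, setdiff(levels_y, pos))
      p <- p[, levels_y, drop = FALSE]
      list(class = factor(as.character(pr), levels = levels_y), prob = p)
    }
  } else {
    ecoc_predict(model, x)
  }
}

#' Fit a cross-validation-tuned SVM burn classifier
#'
#' The package's central fitting function.  Performs an exhaustive search
#' over the supplied [tuning_grid()] — SVM hyperparameters plus, when the
#' features are recomputable, the Daubechies mother wavelet and
#' decomposition level — selecting the candidate with the smallest mean
#' five-fold cross-validation misclassification loss on the training data,
#' then refits that winner on the full training set.  Binary tasks use a
#' single SVM with Platt-calibrated probabilities; multiclass tasks use an
#' error-correcting output code (ECOC) ensemble of binary SVMs under the
#' chosen coding (one-vs-one: 6 learners for 4 classes; one-vs-all: 4), with
#' probabilities from softmax-normalized per-class scores.
#'
#' Features are z-scored per sub-band with statistics computed on the
#' training portion only (of each fold during tuning, of the whole training
#' set for the final refit), so no information leaks from held-out data.
#'
#' @param x features: a numeric matrix (observations x sub-bands), a named
#'   list of matrices keyed by [feature_key()] (`"db1.J12"` etc.), or a
#'   function `(wavelet, level)` returning such a matrix.  With a plain
#'   matrix, the wavelet/level dimensions of the grid are not searched.
#' @param y class labels (factor or coercible); 2 levels give a binary task,
#'   more give a multiclass ECOC task.
#' @param grid a [tuning_grid()].
#' @param task `"binary"` or `"multiclass"`; inferred from `nlevels(y)` by
#'   default.
#' @param cv_folds number of cross-validation folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @return An object of class `burn_svm` with components `model`, `config`
#'   (the winning candidate row), `cv_table` (all candidates with their CV
#'   losses), `validation` (pooled five-fold predictions of the winner),
#'   `center`/`scale`, `levels`, `task`.
#' @seealso [predict.burn_svm()], [burn_experiment()]
#' @export
burn_svm <- function(x, y, grid = tuning_grid(), task = NULL, cv_folds = 5,
                     seed = NULL) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) config_error("'y' must have at least two classes")
  task <- task %||% if (nlevels(y) == 2) "binary" else "multiclass"
  acc <- feature_accessor(x)
  cand <- expand_candidates(grid, task, acc$tune)
  if (nrow(cand) == 0) config_error("empty tuning grid")
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(set_rng_state(old))
    set.seed(seed)
  }
  fold <- make_folds(y, cv_folds)

  feat_cache <- new.env(parent = emptyenv())
  get_feats <- function(w, l) {
    key <- if (is.na(w)) ".fixed" else feature_key(w, l)
    if (is.null(feat_cache[[key]])) {
      fx <- acc$fun(w, l)
      if (!is.matrix(fx) || nrow(fx) != length(y))
        config_error("feature matrix does not match the observations")
      feat_cache[[key]] <- fx
    }
    feat_cache[[key]]
  }

  cv_loss <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    fx <- get_feats(cand$wavelet[i], cand$level[i])
    errs <- vapply(seq_len(cv_folds), function(f) {
      tr <- fold != f; te <- !tr
      sc <- zscale(fx[tr, , drop = FALSE])
      m <- fit_task_model(sc$x, y[tr], cand[i, ], task)
      xe <- zscale(fx[te, , drop = FALSE], sc$center, sc$scale)$x
      pr <- predict_task_model(m, xe, task, levels(y))
      mean(pr$class != y[te])
    }, numeric(1))
    cv_loss[i] <- mean(errs)
  }
  cand$cv_loss <- cv_loss
  win <- which.min(cv_loss)
  winner <- cand[win, ]

  # Pooled five-fold predictions of the winner (the validation estimates).
  fx <- get_feats(winner$wavelet, winner$level)
  val_class <- factor(rep(NA_character_, length(y)), levels = levels(y))
  val_prob <- matrix(NA_real_, length(y), nlevels(y),
                     dimnames = list(NULL, levels(y)))
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; te <- !tr
    sc <- zscale(fx[tr, , drop = FALSE])
    m <- fit_task_model(sc$x, y[tr], winner, task, probability = TRUE)
    xe <- zscale(fx[te, , drop = FALSE], sc$center, sc$scale)$x
    pr <- predict_task_model(m, xe, task, levels(y))
    val_class[te] <- pr$class
    val_prob[te, ] <- pr$prob
  }

  sc <- zscale(fx)
  model <- fit_task_model(sc$x, y, winner, task, probability = TRUE)
  structure(list(model = model, task = task, levels = levels(y),
                 config = winner, cv_table = cand,
                 validation = list(class = val_class, prob = val_prob,
                                   truth = y),
                 center = sc$center, scale = sc$scale,
                 n_train = length(y), call = match.call()),
            class = "burn_svm")
}

#' Predict from a fitted burn classifier
#'
#' @param object a [burn_svm()] fit.
#' @param newdata features in the same form as the `x` used to fit (matrix,
#'   keyed list, or function); the winner's wavelet/level combination is
#'   selected automatically.
#' @param type `"class"` for predicted classes, `"prob"` for the per-class
#'   probability matrix (rows sum to 1).
#' @param ... unused.
#' @return A factor (`type = "class"`) or probability matrix
#'   (`type = "prob"`).
#' @export
predict.burn_svm <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  acc <- feature_accessor(newdata)
  fx <- acc$fun(object$config$wavelet, object$config$level)
  if (ncol(fx) != length(object$center))
    config_error("newdata features do not match the fitted configuration")
  xs <- zscale(fx, object$center, object$scale)$x
  pr <- predict_task_model(object$model, xs, object$task, object$levels)
  if (type == "class") pr$class else pr$prob
}

#' @export
print.burn_svm <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<burn_svm> %s task, %d training observations\n",
              x$task, x$n_train))
  cat(sprintf("  winner: %s kernel (scale %g, C %g%s)%s%s\n",
              cfg$kernel, cfg$kernel_scale, cfg$box_constraint,
              if (!is.na(cfg$degree)) sprintf(", degree %d", cfg$degree) else "",
              if (!is.na(cfg$wavelet))
                sprintf(", features %s level %d", cfg$wavelet, cfg$level) else "",
              if (x$task == "multiclass") sprintf(", coding %s", cfg$coding) else ""))
  cat(sprintf("  five-fold CV loss: %.4f (searched %d candidates)\n",
              cfg$cv_loss, nrow(x$cv_table)))
  invisible(x)
}

#' @export
summary.burn_svm <- function(object, ...) {
  v <- object$validation
  keep <- !is.na(v$class)
  metrics <- if (object$task == "binary") {
    pos <- object$levels[1]
    rbind(classification_metrics(as.character(v$truth)[keep],
                                 as.character(v$class)[keep],
                                 v$prob[keep, pos], positive = pos))
  } else {
    multiclass_metrics(as.character(v$truth)[keep],
                       as.character(v$class)[keep],
                       v$prob[keep, , drop = FALSE])
  }
  rownames(metrics) <- if (object$task == "binary") object$levels[1]
                       else object$levels
  out <- list(fit = object, validation_metrics = metrics)
  class(out) <- "summary.burn_svm"
  out
}

#' @export
print.summary.burn_svm <- function(x, ...) {
  print(x$fit)
  cat("  five-fold validation metrics (%):\n")
  print(round(x$validation_metrics, 1))
  invisible(x)
}

#' @export
plot.burn_svm <- function(x, ...) {
  tab <- x$cv_table
  if (!all(is.na(tab$level)) && length(unique(tab$level)) > 1) {
    agg <- stats::aggregate(cv_loss ~ level, tab, min)
    plot(agg$level, 100 * (1 - agg$cv_loss), type = "b", pch = 19,
         xlab = "decomposition level", ylab = "best CV accuracy (%)",
         main = "Cross-validation accuracy by decomposition level", ...)
  } else {
    plot(seq_len(nrow(tab)), 100 * (1 - tab$cv_loss), type = "h",
         xlab = "candidate", ylab = "CV accuracy (%)",
         main = "Cross-validation accuracy by candidate", ...)
  }
  invisible(x)
}
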
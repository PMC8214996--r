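#' Stratified train/test split of a feature matrix
#'
#' Splits rows into train and test partitions preserving per-class
#' proportions to within one row. Two policies are offered:
#'
#' * `"paper"` (default): rows are split independently, so rescaled variants
#'   of one original trace may land on both sides — the split used in the
#'   published analysis.
#' * `"grouped"`: all rows sharing an `origin_id` stay on one side, removing
#'   augmentation leakage between train and test.
#'
#' @param feature_matrix Tibble from [build_feature_matrix()] (needs `label`
#'   and, for the grouped policy, `origin_id`).
#' @param train_fraction Fraction of rows to train on, in (0, 1).
#' @param seed Integer seed controlling the partition.
#' @param policy `"paper"` or `"grouped"`.
#' @return A list of class `pa_split` with tibbles `train` and `test`.
#' @export
stratified_split <- function(feature_matrix, train_fraction = 0.8, seed = 1L,
                             policy = c("paper", "grouped")) {
  policy <- match.arg(policy)
  if (!(train_fraction > 0 && train_fraction < 1)) {
    abort("`train_fraction` must be strictly between 0 and 1.")
  }
  if (!"label" %in% names(feature_matrix)) abort("Need a `label` column.")
  counts <- table(feature_matrix$label)
  if (any(counts < 2L)) abort("Every class needs at least 2 rows to split.")

  take_train <- logical(nrow(feature_matrix))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  for (cls in names(counts)) {
    rows <- which(feature_matrix$label == cls)
    n_train <- round(train_fraction * length(rows))
    n_train <- max(1L, min(length(rows) - 1L, n_train))
    if (policy == "paper") {
      take_train[sample(rows, n_train)] <- TRUE
    } else {
      if (!"origin_id" %in% names(feature_matrix)) {
        abort("Grouped policy needs an `origin_id` column.")
      }
      origins <- sample(unique(feature_matrix$origin_id[rows]))
      sizes <- vapply(
        origins,
        function(o) sum(feature_matrix$origin_id[rows] == o), integer(1)
      )
      cum <- cumsum(sizes)
      n_groups <- which.min(abs(cum - n_train))
      n_groups <- max(1L, min(length(origins) - 1L, n_groups))
      keep <- feature_matrix$origin_id[rows] %in% origins[seq_len(n_groups)]
      take_train[rows[keep]] <- TRUE
    }
  }
  structure(
    list(
      train = as_tibble(feature_matrix[take_train, , drop = FALSE]),
      test = as_tibble(feature_matrix[!take_train, , drop = FALSE]),
      train_fraction = train_fraction, seed = as.integer(seed), policy = policy
    ),
    class = "pa_split"
  )
}

kernel_function <- function(kernel, gamma, degree, coef0) {
  switch(kernel,
    linear = function(x, z) sum(x * z),
    polynomial = function(x, z) (gamma * sum(x * z) + coef0)^degree,
    rbf = function(x, z) exp(-gamma * sum((x - z)^2)),
    abort(sprintf("Unknown kernel '%s'.", kernel))
  )
}

#' Train a multi-class SVM on a feature-matrix partition
#'
#' Fits a one-vs-one multi-class support vector machine (via libsvm) on the
#' feature columns, after standardizing each column with center and scale
#' learned from the training rows only — augmentation injects up to 9x
#' amplitude spread that would otherwise dominate every kernel. The same
#' standardization is applied at prediction time.
#'
#' @param train Training tibble (feature columns `aa2_*` plus `label`).
#' @param kernel `"rbf"`, `"polynomial"` or `"linear"`.
#' @param cost Soft-margin penalty C.
#' @param gamma RBF width / polynomial scale; default `1 / (d * var)` with
#'   `var` the overall variance of the standardized training features.
#' @param degree,coef0 Polynomial kernel degree and offset.
#' @return An object of class `pa_svm`.
#' @export
train_svm <- function(train, kernel = c("rbf", "polynomial", "linear"),
                      cost = 1, gamma = NULL, degree = 3L, coef0 = 1) {
  kernel <- match.arg(kernel)
  feats <- feature_columns(train)
  if (length(feats) == 0L) abort("No feature columns (`aa2_*`) found.")
  X <- as.matrix(train[, feats, drop = FALSE])
  if (any(!is.finite(X))) abort("Training features must be finite.")
  y <- factor(train$label)
  if (nlevels(y) < 2L) abort("Training data must contain at least 2 classes.")

  center <- colMeans(X)
  scale <- apply(X, 2L, sd)
  scale[scale == 0] <- 1
  Xs <- scale(X, center = center, scale = scale)
  if (is.null(gamma)) gamma <- 1 / (ncol(Xs) * max(var(as.vector(Xs)), 1e-12))

  fit <- e1071::svm(
    x = Xs, y = y,
    type = "C-classification",
    kernel = switch(kernel, rbf = "radial", kernel),
    cost = cost, gamma = gamma, degree = degree, coef0 = coef0,
    scale = FALSE
  )
  structure(
    list(
      fit = fit, kernel = kernel, levels = levels(y),
      center = center, scale = scale, features = feats,
      hyper = list(cost = cost, gamma = gamma, degree = degree, coef0 = coef0)
    ),
    class = "pa_svm"
  )
}

#' @export
predict.pa_svm <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  Xs <- scale(X, center = object$center, scale = object$scale)
  predict(object$fit, Xs, ...)
}

#' Hand-settable binary SVM decision model
#'
#' A minimal representation of one binary SVM subproblem: support vectors
#' `x_j`, dual coefficients `alpha_j * y_j`, bias `b` and a kernel
#' \eqn{G}. [decision_score()] evaluates the decision function
#' \deqn{\hat f(x) = \sum_j \alpha_j y_j G(x, x_j) + b,}
#' the signed distance-like score whose sign assigns the class: the higher
#' the score, the stronger the evidence for the subproblem's target class.
#'
#' @param support_vectors Matrix of support vectors (rows).
#' @param coefficients `alpha_j * y_j`, one per support vector.
#' @param bias Scalar offset b.
#' @param kernel `"linear"`, `"polynomial"` or `"rbf"`.
#' @param gamma,degree,coef0 Kernel parameters (defaults: `gamma = 1`,
#'   `degree = 3`, `coef0 = 1`).
#' @return An object of class `svm_binary`.
#' @export
svm_binary_model <- function(support_vectors, coefficients, bias = 0,
                             kernel = "linear", gamma = 1, degree = 3L,
                             coef0 = 1) {
  support_vectors <- as.matrix(support_vectors)
  if (nrow(support_vectors) != length(coefficients)) {
    abort("One coefficient per support vector is required.")
  }
  structure(
    list(
      sv = support_vectors, coef = as.double(coefficients), bias = bias,
      kernel = kernel, gamma = gamma, degree = degree, coef0 = coef0
    ),
    class = "svm_binary"
  )
}

#' Evaluate the SVM decision function
#'
#' @param model An [svm_binary_model()].
#' @param x A feature vector of the model's dimension.
#' @return The scalar decision score \eqn{\sum_j \alpha_j y_j G(x, x_j) + b}.
#' @export
decision_score <- function(model, x) {
  if (!inherits(model, "svm_binary")) abort("`model` must be an `svm_binary`.")
  x <- as.double(x)
  if (length(x) != ncol(model$sv)) {
    abort("`x` does not match the model's feature dimension.")
  }
  G <- kernel_function(model$kernel, model$gamma, model$degree, model$coef0)
  k <- apply(model$sv, 1L, G, z = x)
  sum(model$coef * k) + model$bias
}

#' Per-class performance of a fitted classifier on a test partition
#'
#' Predicts the test rows and tabulates a confusion matrix (rows = true
#' class), per-class sensitivity `TP / (TP + FN)` and one-vs-rest
#' specificity `TN / (TN + FP)` (both in percent), and the overall accuracy
#' `trace / total * 100`. A class absent from the test partition gets `NA`
#' sensitivity and a warning rather than being dropped.
#'
#' @param model A [train_svm()] fit (or any object with a `predict` method
#'   returning class labels).
#' @param test Test tibble with `label` and the model's feature columns.
#' @param seed Optional split seed recorded in the report.
#' @return An object of class `pa_eval`: confusion matrix, `metrics` tibble,
#'   `accuracy`, `kernel`, `seed`.
#' @export
evaluate_model <- function(model, test, seed = NA_integer_) {
  if (nrow(test) == 0L) abort("Test partition is empty.")
  lv <- if (inherits(model, "pa_svm")) {
    model$levels
  } else if (is.factor(test$label)) {
    levels(test$label)
  } else {
    sort(unique(test$label))
  }
  truth <- factor(test$label, levels = lv)
  pred <- factor(predict(model, test), levels = lv)
  confusion <- table(truth = truth, predicted = pred)
  if (any(rowSums(confusion) == 0L)) {
    warning("Some classes are absent from the test partition; their sensitivity is NA.")
  }
  total <- sum(confusion)
  tp <- unname(diag(confusion))
  fn <- unname(rowSums(confusion)) - tp
  fp <- unname(colSums(confusion)) - tp
  tn <- total - tp - fn - fp
  metrics <- tibble(
    class = lv,
    sensitivity = ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_),
    specificity = 100 * tn / (tn + fp)
  )
  structure(
    list(
      confusion = confusion, metrics = metrics,
      accuracy = 100 * sum(tp) / total,
      kernel = if (inherits(model, "pa_svm")) model$kernel else NA_character_,
      seed = seed
    ),
    class = "pa_eval"
  )
}

#' @export
print.pa_eval <- function(x, ...) {
  cat(sprintf(
    "<pa_eval> kernel %s, accuracy %.1f%%\n",
    x$kernel %||% "?", x$accuracy
  ))
  print(x$confusion)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @method tidy pa_eval
#' @export
tidy.pa_eval <- function(x, ...) {
  mutate(x$metrics, kernel = x$kernel, seed = x$seed)
}

#' @method glance pa_eval
#' @export
glance.pa_eval <- function(x, ...) {
  tibble(
    kernel = x$kernel, seed = x$seed, accuracy = x$accuracy,
    n_test = sum(x$confusion)
  )
}

#' Repeated stratified hold-out evaluation
#'
#' For each kernel, repeats the split / train / evaluate cycle `n_repeats`
#' times with distinct derived split seeds (identical across kernels, so
#' kernels are compared on the very same partitions), keeps every per-repeat
#' report, and nominates per kernel the repeat with the highest test
#' accuracy (ties towards the earlier seed) as the "best" model.
#'
#' @param feature_matrix A [build_feature_matrix()] tibble.
#' @param kernels Kernels to evaluate.
#' @param n_repeats Number of split/train/test cycles per kernel.
#' @param seed Master seed fanned out to the per-repeat split seeds.
#' @param train_fraction,policy Passed to [stratified_split()].
#' @param ... Passed to [train_svm()] (hyperparameters).
#' @return An object of class `pa_holdout`: `reports` (list of `pa_eval`),
#'   `best` (named per-kernel list of `list(model, report)`), `summary`
#'   tibble of per-repeat accuracies.
#' @export
repeated_holdout <- function(feature_matrix,
                             kernels = c("rbf", "polynomial", "linear"),
                             n_repeats = 10L, seed = 1L,
                             train_fraction = 0.8,
                             policy = c("paper", "grouped"), ...) {
  policy <- match.arg(policy)
  n_repeats <- as.integer(n_repeats)
  if (n_repeats < 1L) abort("`n_repeats` must be >= 1.")
  split_seeds <- vapply(
    seq_len(n_repeats),
    function(r) as.integer(substream_seed(seed, 4L, r)), integer(1)
  )
  reports <- list()
  best <- list()
  rows <- list()
  for (kernel in kernels) {
    best_acc <- -Inf
    for (r in seq_len(n_repeats)) {
      split <- stratified_split(feature_matrix, train_fraction,
                                seed = split_seeds[r], policy = policy)
      model <- train_svm(split$train, kernel = kernel, ...)
      report <- evaluate_model(model, split$test, seed = split_seeds[r])
      reports[[sprintf("%s_%02d", kernel, r)]] <- report
      rows[[length(rows) + 1L]] <- tibble(
        kernel = kernel, repeat_id = r, seed = split_seeds[r],
        accuracy = report$accuracy
      )
      if (report$accuracy > best_acc) {
        best_acc <- report$accuracy
        best[[kernel]] <- list(model = model, report = report, repeat_id = r)
      }
    }
  }
  structure(
    list(
      reports = reports, best = best, summary = bind_rows(rows),
      n_repeats = n_repeats, seed = as.integer(seed), policy = policy
    ),
    class = "pa_holdout"
  )
}

#' @export
print.pa_holdout <- function(x, ...) {
  cat(sprintf(
    "<pa_holdout> %d repeats x %d kernel(s), policy '%s'\n",
    x$n_repeats, length(x$best), x$policy
  ))
  for (kernel in names(x$best)) {
    cat(sprintf(
      "  %-11s best accuracy %.1f%% (repeat %d)\n", kernel,
      x$best[[kernel]]$report$accuracy, x$best[[kernel]]$repeat_id
    ))
  }
  invisible(x)
}

#' @method tidy pa_holdout
#' @export
tidy.pa_holdout <- function(x, ...) {
  x$summary
}

#' @method glance pa_holdout
#' @export
glance.pa_holdout <- function(x, ...) {
  bind_rows(lapply(names(x$best), function(kernel) {
    tibble(
      kernel = kernel,
      best_accuracy = x$best[[kernel]]$report$accuracy,
      mean_accuracy = mean(x$summary$accuracy[x$summary$kernel == kernel]),
      n_repeats = x$n_repeats
    )
  }))
}

#' Per-class summary table of the best models
#'
#' A long table mirroring the usual staging-performance layout: one row per
#' (kernel, class) with the best model's per-class sensitivity and
#' specificity and its overall accuracy.
#'
#' @param holdout A [repeated_holdout()] result.
#' @return A tibble with columns `class`, `kernel`, `specificity`,
#'   `sensitivity`, `accuracy`.
#' @export
report_table <- function(holdout) {
  if (!inherits(holdout, "pa_holdout")) abort("`holdout` must be a `pa_holdout`.")
  bind_rows(lapply(names(holdout$best), function(kernel) {
    rep <- holdout$best[[kernel]]$report
    mutate(
      rep$metrics[, c("class", "sensitivity", "specificity")],
      kernel = kernel, accuracy = rep$accuracy
    )
  }))[, c("class", "kernel", "specificity", "sensitivity", "accuracy")]
}
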
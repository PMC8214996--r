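# Small labelled feature tables used across the classifier tests.
make_clouds <- function(n_per = 30, classes = c("day0", "day5", "day10"),
                        sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- seq_along(classes) * sep
  dplyr::bind_rows(lapply(seq_along(classes), function(i) {
    tibble::tibble(
      id = sprintf("%s_%d", classes[i], seq_len(n_per)),
      origin_id = sprintf("%s_o%d", classes[i], rep(1:5, length.out = n_per)),
      label = classes[i],
      aa2_001 = rnorm(n_per, centers[i], sd),
      aa2_002 = rnorm(n_per, -centers[i], sd)
    )
  }))
}

test_that("stratified splits preserve per-class proportions and determinism", {
  fm <- make_clouds(n_per = 50)
  sp <- stratified_split(fm, 0.8, seed = 5)
  expect_equal(as.vector(table(sp$train$label)), rep(40L, 3))
  expect_equal(as.vector(table(sp$test$label)), rep(10L, 3))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(fm))
  expect_length(intersect(sp$train$id, sp$test$id), 0L)

  again <- stratified_split(fm, 0.8, seed = 5)
  expect_identical(sp$train$id, again$train$id)
  other <- stratified_split(fm, 0.8, seed = 6)
  expect_false(identical(sp$train$id, other$train$id))
  expect_equal(as.vector(table(other$train$label)), rep(40L, 3))

  tiny <- make_clouds(n_per = 2)
  half <- stratified_split(tiny, 0.5, seed = 1)
  expect_equal(as.vector(table(half$train$label)), rep(1L, 3))
  expect_equal(as.vector(table(half$test$label)), rep(1L, 3))

  grouped <- stratified_split(fm, 0.8, seed = 5, policy = "grouped")
  expect_length(intersect(grouped$train$origin_id, grouped$test$origin_id), 0L)

  expect_error(stratified_split(fm, 1.2, seed = 1), "between 0 and 1")
  expect_error(stratified_split(fm[1, ], 0.5, seed = 1), "at least 2 rows")
})

test_that("decision scores evaluate the dual-form kernel expansion", {
  # single support vector, unit dual weight, zero bias, linear kernel
  m1 <- svm_binary_model(matrix(c(1, 2), 1), 1, 0, "linear")
  expect_equal(decision_score(m1, c(1, 2)), 5) # <x1, x1>

  # rbf kernel at the support vector itself: G(x, x) = 1
  mr <- svm_binary_model(matrix(c(1, 2), 1), 1, 0, "rbf", gamma = 0.7)
  expect_equal(decision_score(mr, c(1, 2)), 1)

  # two support vectors, hand arithmetic:
  # 0.5 * <(1,2),(2,1)> - 2 * <(3,-1),(2,1)> + 0.25 = 2 - 10 + 0.25
  m2 <- svm_binary_model(rbind(c(1, 2), c(3, -1)), c(0.5, -2), 0.25, "linear")
  expect_equal(decision_score(m2, c(2, 1)), -7.75)

  # polynomial kernel, hand arithmetic: (0.5 * 4 + 1)^2 = 9
  mp <- svm_binary_model(matrix(c(2, 0), 1), 1, 0, "polynomial",
                         gamma = 0.5, degree = 2, coef0 = 1)
  expect_equal(decision_score(mp, c(2, 0)), 9)

  expect_error(decision_score(m2, c(1, 2, 3)), "dimension")
})

test_that("the dual-form expansion reproduces libsvm decision values", {
  fm <- make_clouds(n_per = 40, classes = c("day0", "day20"), sep = 3, sd = 1)
  for (kernel in c("linear", "rbf", "polynomial")) {
    model <- train_svm(fm, kernel = kernel)
    fit <- model$fit
    hand <- svm_binary_model(
      fit$SV, fit$coefs[, 1], -fit$rho, kernel,
      gamma = model$hyper$gamma, degree = model$hyper$degree,
      coef0 = model$hyper$coef0
    )
    Xs <- scale(as.matrix(fm[, c("aa2_001", "aa2_002")]),
                center = model$center, scale = model$scale)
    ours <- apply(Xs[1:10, ], 1, function(x) decision_score(hand, x))
    libsvm <- attr(
      predict(fit, Xs[1:10, ], decision.values = TRUE), "decision.values"
    )[, 1]
    expect_equal(unname(ours), unname(libsvm), tolerance = 1e-8)
  }
})

test_that("training behaves on separable clouds and rejects degenerate input", {
  fm <- make_clouds(sep = 8, sd = 0.3)
  model <- train_svm(fm, kernel = "linear", cost = 100)
  expect_equal(mean(predict(model, fm) == fm$label), 1)

  expect_error(train_svm(dplyr::filter(fm, label == "day0")), "2 classes")
  bad <- fm
  bad$aa2_001[1] <- NA
  expect_error(train_svm(bad), "finite")

  # duplicating every training row leaves the boundary unchanged
  probe <- make_clouds(seed = 99)
  doubled <- train_svm(dplyr::bind_rows(fm, fm), kernel = "rbf")
  single <- train_svm(fm, kernel = "rbf")
  expect_identical(as.character(predict(doubled, probe)),
                   as.character(predict(single, probe)))
})

test_that("evaluation metrics match hand confusion-matrix arithmetic", {
  classes <- c("day0", "day10", "day20")
  test_set <- tibble::tibble(
    label = rep(classes, each = 4),
    aa2_001 = rnorm(12)
  )
  # perfect predictor: identity confusion, all metrics 100
  perfect <- evaluate_model(fixed_predictor(test_set$label), test_set)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$metrics$sensitivity, rep(100, 3))
  expect_equal(perfect$metrics$specificity, rep(100, 3))
  expect_equal(unname(diag(perfect$confusion)), rep(4L, 3))

  # constant predictor on a balanced set: accuracy forced to 1/k
  constant <- evaluate_model(fixed_predictor("day0"), test_set)
  expect_equal(constant$accuracy, 100 / 3)
  expect_equal(constant$metrics$sensitivity, c(100, 0, 0))
  expect_equal(constant$metrics$specificity, c(0, 100, 100))

  # fixed prediction pattern, metrics frozen from hand arithmetic:
  # truth (4 each): predictions below give confusion rows
  preds <- c("day0", "day0", "day10", "day0", # truth day0: 3 TP
             "day10", "day10", "day20", "day0", # truth day10: 2 TP
             "day20", "day20", "day20", "day10") # truth day20: 3 TP
  mixed <- evaluate_model(fixed_predictor(preds), test_set)
  expect_equal(mixed$accuracy, 100 * 8 / 12)
  expect_equal(mixed$metrics$sensitivity, 100 * c(3 / 4, 2 / 4, 3 / 4))
  # specificity hand counts: FP(day0)=1, FP(day10)=2, FP(day20)=1 against
  # 8 non-class rows each -> TN = 7/8, 6/8, 7/8
  expect_equal(mixed$metrics$specificity, 100 * c(7 / 8, 6 / 8, 7 / 8))

  # consistency: confusion row sums = per-class test counts, accuracy = trace
  expect_equal(unname(rowSums(mixed$confusion)), rep(4L, 3))
  expect_equal(100 * sum(diag(mixed$confusion)) / sum(mixed$confusion),
               mixed$accuracy)

  # a class missing from the test partition is flagged, not dropped
  missing_cls <- dplyr::filter(test_set, label != "day10")
  fake <- fixed_predictor(missing_cls$label)
  expect_warning(
    ev <- evaluate_model(fake, dplyr::mutate(missing_cls,
                                             label = factor(label, levels = classes))),
    "absent"
  )

  expect_error(evaluate_model(fixed_predictor("day0"), test_set[0, ]), "empty")
})

test_that("repeated hold-out pairs kernels on identical partitions", {
  fm <- make_clouds(n_per = 40, sep = 4, sd = 1)
  ho <- repeated_holdout(fm, kernels = c("linear", "rbf"), n_repeats = 3,
                         seed = 2)
  expect_length(ho$reports, 6L)
  expect_length(ho$best, 2L)
  sm <- generics::tidy(ho)
  expect_equal(nrow(sm), 6L)
  expect_identical(sm$seed[sm$kernel == "linear"], sm$seed[sm$kernel == "rbf"])
  best_acc <- generics::glance(ho)
  expect_true(all(best_acc$best_accuracy >= best_acc$mean_accuracy - 1e-9))

  one <- repeated_holdout(fm, kernels = "linear", n_repeats = 1, seed = 3)
  expect_length(one$reports, 1L)
  expect_equal(one$best$linear$report$accuracy, one$summary$accuracy)

  tbl <- report_table(ho)
  expect_setequal(names(tbl),
                  c("class", "kernel", "specificity", "sensitivity", "accuracy"))
  expect_equal(nrow(tbl), 6L) # 3 classes x 2 kernels
})

test_that("grouped splitting does not outperform row-wise splitting on average", {
  # Shape-identical templates: under row-wise ("paper") splits the model can
  # match held-out rows to their rescaled siblings, so accuracy reflects
  # memorization; grouped splits remove that route.
  tpl <- class_templates(amplitudes = seq(1, 1.8, length.out = 5),
                         shape_drift = 0)
  paper <- numeric(3)
  grouped <- numeric(3)
  for (s in 1:3) {
    sp <- generate_spectra(small_design(), tpl, seed = s)
    paper[s] <- downstream_accuracy(sp, seed = s, policy = "paper")
    grouped[s] <- downstream_accuracy(sp, seed = s, policy = "grouped")
  }
  expect_lt(mean(grouped), mean(paper))
})
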
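# Small synthetic labelled dataset generated through the full pipeline
# (6-antenna array keeps it light).
make_small_dataset <- function(n_per_class = 12, levels = -110, seed = 33) {
  ph <- fixture_phantom()
  op <- fixture_operator()
  Sb <- background_sparams(fixture_array())
  comp <- setNames(rep(n_per_class, 9), class_levels())
  generate_training_set(op, ph, Sb, composition = comp, levels = levels,
                        seed = seed)
}

# Full 24-antenna array on the small mesh: 600 features, richer spatial
# information than the 6-antenna fixture.
fixture_operator24 <- local({
  env <- new.env()
  function() {
    if (is.null(env$op)) {
      env$arr <- antenna_array()
      env$op <- system_operator(fixture_phantom(), env$arr)
      env$Sb <- background_sparams(env$arr)
    }
    list(op = env$op, Sb = env$Sb)
  }
})

test_that("classifier configs echo the documented hyperparameters", {
  expect_equal(classifier_config("svm")$hyperparameters$gamma, 0.059)
  expect_equal(classifier_config("svm")$hyperparameters$cost, 300)
  expect_equal(classifier_config("mlp")$hyperparameters$hidden,
               c(800, 400, 200, 100, 50))
  expect_equal(classifier_config("mlp")$hyperparameters$alpha, 1e-4)
  expect_equal(classifier_config("mlp")$hyperparameters$batch_size, 200)
  expect_equal(classifier_config("knn")$hyperparameters$k, 3)
  expect_equal(classifier_config("svm", gamma = 0.11)$hyperparameters$gamma,
               0.11)
})

test_that("k-NN with k = 3 predicts by majority of the three nearest", {
  # 10 separable points in 2-D, two classes
  x <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 5, 0.1), 5, 2))
  df <- tibble::tibble(f1 = x[, 1], f2 = x[, 2],
                       label = rep(c("N", "I_FL"), each = 5))
  m <- fit_classifier(df, classifier_config("knn", scale = "none"))
  pred <- predict(m, tibble::tibble(f1 = c(0.1, 5.1), f2 = c(0, 5)))
  expect_equal(as.character(pred), c("N", "I_FL"))
})

test_that("training is reproducible given the seed", {
  ds <- make_small_dataset(6)
  for (algo in c("knn", "mlp")) {
    cfg <- classifier_config(algo, seed = 5)
    if (algo == "mlp") cfg <- classifier_config(algo, seed = 5,
                                                hidden = c(32, 16),
                                                max_epochs = 20)
    m1 <- fit_classifier(ds, cfg)
    m2 <- fit_classifier(ds, cfg)
    expect_identical(as.character(predict(m1, ds)),
                     as.character(predict(m2, ds)))
  }
  expect_error(fit_classifier(ds[ds$label == "N", ], classifier_config("svm")),
               "single class")
})

test_that("all three classifiers learn the task on a clean low-noise dataset", {
  # deliberately small-sample smoke check (60 records/class); the
  # full-scale separation property (>= 95% macro accuracy at 10,000
  # records) runs with the acceptance suite
  fx <- fixture_operator24()
  comp <- setNames(rep(60L, 9), class_levels())
  ds <- generate_training_set(fx$op, fixture_phantom(), fx$Sb,
                              composition = comp, levels = -110, seed = 37)
  sp <- split_dataset(ds, 0.75, seed = 37)
  for (cfg in list(classifier_config("svm"),
                   classifier_config("knn"),
                   classifier_config("mlp", hidden = c(128, 64),
                                     max_epochs = 80))) {
    m <- fit_classifier(sp$train, cfg)
    cv <- evaluate_classifier(m, sp$validation)
    expect_gte(cv$macro_accuracy, 0.6)
    expect_gte(cv$accuracy, 0.35)          # chance level is 1/9
    expect_gte(cv$macro_accuracy, cv$accuracy)
  }
})

test_that("amplitude-only features do not clearly beat complex features", {
  fx <- fixture_operator24()
  comp <- setNames(rep(40L, 9), class_levels())
  dc <- generate_training_set(fx$op, fixture_phantom(), fx$Sb,
                              composition = comp, levels = -110, seed = 41,
                              mode = "complex")
  da <- generate_training_set(fx$op, fixture_phantom(), fx$Sb,
                              composition = comp, levels = -110, seed = 41,
                              mode = "amplitude")
  expect_equal(ncol(dc) - 1, 600)
  expect_equal(ncol(da) - 1, 300)
  acc <- sapply(list(dc, da), function(d) {
    sp <- split_dataset(d, 0.75, seed = 41)
    evaluate_classifier(fit_classifier(sp$train, classifier_config("knn")),
                        sp$validation)$accuracy
  })
  expect_gte(acc[1], acc[2] - 0.1)
})

test_that("grid search is exhaustive with first-in-grid tie breaking", {
  ds <- make_small_dataset(8)
  single <- classifier_config("knn", k = 3)
  gs <- grid_search(list(single), ds, folds = 3)
  expect_identical(gs$best, single)
  expect_equal(nrow(gs$results), 1)

  # a deliberately bad large k loses to the default; the better config wins
  grid <- list(classifier_config("knn", k = 25),
               classifier_config("knn", k = 3))
  gs2 <- grid_search(grid, ds, folds = 3, seed = 2)
  expect_gt(gs2$results$cv_accuracy[2], gs2$results$cv_accuracy[1])
  expect_equal(gs2$best$hyperparameters$k, 3)
})

test_that("confusion results tally correctly and aggregate to macro classes", {
  lv <- class_levels()
  set.seed(55)
  truth <- sample(lv, 200, replace = TRUE)

  # perfect predictor
  cr <- confusion_result(truth, truth)
  expect_equal(diag(cr$counts), as.vector(table(factor(truth, levels = lv))),
               ignore_attr = TRUE)
  expect_equal(cr$accuracy, 1)
  expect_true(all(diag(cr$normalized)[rowSums(cr$counts) > 0] == 1))

  # constant predictor: one non-zero column
  cr2 <- confusion_result(truth, rep("N", 200))
  expect_true(all(cr2$counts[, -1] == 0))
  expect_equal(sum(cr2$counts[, 1]), 200)

  # hand tally on random predictions
  pred <- sample(lv, 200, replace = TRUE)
  cr3 <- confusion_result(truth, pred)
  hand <- matrix(0L, 9, 9, dimnames = list(lv, lv))
  for (i in 1:200) {
    hand[truth[i], pred[i]] <- hand[truth[i], pred[i]] + 1L
  }
  expect_equal(unname(cr3$counts), unname(hand), ignore_attr = TRUE)

  # invariants: totals conserved, macro >= fine accuracy
  expect_equal(sum(cr3$counts), 200)
  expect_equal(sum(cr3$macro), 200)
  expect_gte(cr3$macro_accuracy, cr3$accuracy)
  # row sums survive macro aggregation
  expect_equal(sum(cr3$macro[2, ]), sum(cr3$counts[2:5, ]))
})

test_that("tidy/glance/autoplot methods return the documented shapes", {
  set.seed(57)
  truth <- sample(class_levels(), 100, replace = TRUE)
  pred <- sample(class_levels(), 100, replace = TRUE)
  cr <- confusion_result(truth, pred)
  td <- tidy(cr)
  expect_equal(nrow(td), 81)
  expect_equal(sum(td$count), 100)
  gl <- glance(cr)
  expect_equal(gl$misclassification, 100 * (1 - gl$accuracy))
  expect_s3_class(autoplot(cr), "ggplot")

  ds <- make_small_dataset(4)
  expect_s3_class(autoplot(ds), "ggplot")
  m <- fit_classifier(ds, classifier_config("knn"))
  expect_equal(glance(m)$algorithm, "knn")
})
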
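# Split plans, metric arithmetic against brute-force oracles, and the
# experiment loop with its leakage audit.

test_that("holdout splits 100 samples into disjoint 80/20 index sets", {
  y <- factor(rep(c("a", "b"), each = 50))
  sp <- make_splits(y, split_plan("holdout", seed = 1))
  expect_length(sp, 1)
  expect_equal(length(sp[[1]]$train), 80)
  expect_equal(length(sp[[1]]$test), 20)
  expect_length(intersect(sp[[1]]$train, sp[[1]]$test), 0)
  expect_setequal(c(sp[[1]]$train, sp[[1]]$test), 1:100)
})

test_that("k-fold test folds partition the indices exactly once", {
  y <- factor(rep(c("a", "b"), 50))
  sp <- make_splits(y, split_plan("kfold", k = 10, seed = 2))
  expect_length(sp, 10)
  all_test <- unlist(lapply(sp, `[[`, "test"))
  expect_equal(sort(all_test), 1:100)
  for (f in sp) {
    expect_setequal(c(f$train, f$test), 1:100)
    expect_length(intersect(f$train, f$test), 0)
  }
})

test_that("stratified splits preserve a 90/10 class mix within one sample", {
  y <- factor(rep(c("a", "b"), c(90, 10)))
  sp <- make_splits(y, split_plan("holdout", seed = 3))
  test_mix <- table(y[sp[[1]]$test])
  expect_equal(as.vector(test_mix), c(18, 2), tolerance = 1)
  kf <- make_splits(y, split_plan("kfold", k = 10, seed = 3))
  per_fold_b <- vapply(kf, function(f) sum(y[f$test] == "b"), 0L)
  expect_true(all(per_fold_b == 1))
  expect_error(make_splits(factor(rep(c("a", "b"), c(95, 5))),
                           split_plan("kfold", k = 10)),
               class = "painsense_config_error")
})

test_that("metric arithmetic matches the worked confusion matrix", {
  truth <- factor(rep(c("pain", "no_pain"), each = 10),
                  levels = c("no_pain", "pain"))
  pred <- truth
  pred[1] <- "no_pain"                    # one FN
  pred[11] <- "pain"                      # one FP
  m <- compute_metrics(truth, pred)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$f1, 0.9)
  cm <- attr(m, "confusion")
  expect_equal(as.vector(rowSums(cm)), c(10, 10))
})

test_that("perfect predictions give unit metrics and zero RMSE", {
  truth <- factor(c("low", "moderate", "high", "low"),
                  levels = c("low", "moderate", "high"))
  P <- matrix(0, 4, 3)
  P[cbind(1:4, as.integer(truth))] <- 1
  m <- compute_metrics(truth, truth, prob = P)
  expect_equal(unlist(m[c("accuracy", "precision", "recall", "f1")]),
               c(1, 1, 1, 1), ignore_attr = TRUE)
  expect_equal(m$rmse, 0)
})

test_that("macro metrics equal the explicit per-class loop on random vectors", {
  set.seed(30)
  for (i in 1:50) {
    lv <- c("low", "moderate", "high")
    truth <- factor(sample(lv, 60, replace = TRUE), levels = lv)
    pred <- factor(sample(lv, 60, replace = TRUE), levels = lv)
    m <- compute_metrics(truth, pred)
    o <- oracle_metrics(truth, pred)
    expect_equal(m$accuracy, o$accuracy)
    expect_equal(m$precision, o$precision, ignore_attr = TRUE)
    expect_equal(m$recall, o$recall, ignore_attr = TRUE)
    expect_equal(m$f1, o$f1, ignore_attr = TRUE)
  }
})

test_that("disagreeing label sets and mismatched lengths are refused", {
  truth <- factor(c("a", "b"))
  expect_error(compute_metrics(truth, factor(c("a", "c"))),
               class = "painsense_config_error")
  expect_error(compute_metrics(truth, factor(c("a", "b", "a"))),
               class = "painsense_config_error")
})

test_that("RMSE compares probability rows with one-hot labels", {
  truth <- factor(c("no_pain", "pain"), levels = c("no_pain", "pain"))
  P <- matrix(c(0.8, 0.2,
                0.4, 0.6), 2, 2, byrow = TRUE)
  m <- compute_metrics(truth, factor(c("no_pain", "pain"),
                                     levels = levels(truth)), prob = P)
  expect_equal(m$rmse, sqrt(mean(c(0.2, 0.2, 0.4, 0.4)^2)))
})

test_that("experiments are deterministic and stay inside their folds", {
  tab <- generate_feature_table(c(no_pain = 24, pain = 36), n_features = 10,
                                effect_size = 5, seed = 8)
  tab$rating <- ifelse(tab$label == "pain", 8L, 3L)
  plan <- split_plan("kfold", k = 5, seed = 4)
  a <- run_experiment(tab, c("svm", "rf"), plan,
                      augment = augment_config(seed = 2), scheme = "binary")
  b <- run_experiment(tab, c("svm", "rf"), plan,
                      augment = augment_config(seed = 2), scheme = "binary")
  expect_equal(a$metrics, b$metrics)
  expect_equal(a$summary, b$summary)
  # leakage audit: no test index ever enters augmentation
  expect_true(all(a$audit$test_in_augmentation == 0))
  # bookkeeping: 6x transform then SMOTE balancing
  expect_true(all(a$audit$n_transformed == 6 * a$audit$n_train))
  expect_true(all(a$audit$n_balanced >= a$audit$n_transformed))
  # confusion matrices accumulate the full test coverage
  expect_equal(sum(a$confusion$svm), nrow(tab))
})

test_that("reports compare augmentation on and off on scarce data", {
  tab <- generate_feature_table(c(no_pain = 40, pain = 40), n_features = 8,
                                effect_size = 2, seed = 9)
  plan <- split_plan("holdout", seed = 5)
  with_aug <- run_experiment(tab, "rf", plan,
                             augment = augment_config(seed = 3),
                             scheme = "binary")
  no_aug <- run_experiment(tab, "rf", plan, augment = NULL,
                           scheme = "binary")
  expect_equal(no_aug$audit$n_balanced, no_aug$audit$n_train)
  expect_gt(with_aug$audit$n_balanced, with_aug$audit$n_train)
  both <- dplyr::bind_rows(augmented = tidy(with_aug),
                           plain = tidy(no_aug), .id = "run")
  expect_equal(nrow(both), 2)
  expect_true(all(c("accuracy", "rmse") %in% names(both)))
})

test_that("report accessors expose fold metrics, summaries and plots", {
  tab <- generate_feature_table(c(no_pain = 20, pain = 20), n_features = 6,
                                effect_size = 5, seed = 10)
  rep <- run_experiment(tab, c("knn", "rf"),
                        split_plan("kfold", k = 4, seed = 6),
                        augment = NULL, scheme = "binary")
  td <- tidy(rep)
  expect_equal(nrow(td), 8)
  gl <- glance(rep)
  expect_equal(nrow(gl), 2)
  expect_equal(gl$accuracy[1], max(gl$accuracy))
  pl <- autoplot(rep)
  expect_s3_class(pl, "ggplot")
  hist_pl <- plot_training_history(
    train_model(model_spec("rnn", 2, seed = 1, lstm_units = 32, epochs = 2,
                           fold = c(3, 2)), tab))
  expect_s3_class(hist_pl, "ggplot")
})
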
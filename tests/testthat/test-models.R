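# Classifier families: contracts on separable data, probability outputs,
# architecture descriptions, gradient correctness and the grid search.

sep2 <- generate_feature_table(c(no_pain = 30, pain = 30), n_features = 12,
                               effect_size = 8, seed = 1)

test_that("svm, knn and rf reach training accuracy 1.0 on separable classes", {
  for (fam in c("svm", "knn", "rf")) {
    fit <- train_model(model_spec(fam, 2, seed = 1), sep2)
    pred <- predict(fit, sep2)
    expect_equal(mean(pred$.pred == sep2$label), 1, ignore_attr = TRUE)
  }
})

test_that("baseline fits are deterministic under a fixed seed", {
  for (fam in c("svm", "knn", "rf")) {
    a <- predict(train_model(model_spec(fam, 2, seed = 7), sep2), sep2)
    b <- predict(train_model(model_spec(fam, 2, seed = 7), sep2), sep2)
    expect_identical(a, b)
  }
})

test_that("knn returns vote-fraction probabilities and honours unanimity", {
  fit <- train_model(model_spec("knn", 2, seed = 1), sep2)
  pred <- predict(fit, sep2)
  expect_true(all(as.matrix(pred[-1]) %in% c(0, 1/3, 2/3, 1)))
  # a training point whose neighbourhood is label-unanimous keeps its label
  expect_equal(as.character(pred$.pred[1]), as.character(sep2$label[1]))
  # labels agree with the reference k-NN implementation
  fm <- feature_matrix(sep2)
  Xs <- scale(fm$x)
  ref <- class::knn(Xs, Xs, sep2$label, k = 3)
  expect_gte(mean(as.character(ref) == as.character(pred$.pred)), 0.98)
})

test_that("probability rows sum to one and permute with the input rows", {
  for (fam in c("svm", "rf", "knn")) {
    fit <- train_model(model_spec(fam, 2, seed = 2), sep2)
    pred <- predict(fit, sep2)
    expect_equal(rowSums(as.matrix(pred[-1])), rep(1, nrow(sep2)),
                 tolerance = 1e-6, ignore_attr = TRUE)
    perm <- c(10:1, 11:60)
    pred_p <- predict(fit, sep2[perm, ])
    expect_equal(pred_p$.pred, pred$.pred[perm])
  }
})

test_that("baseline predictions are invariant to consistent column permutation", {
  perm <- sample(paste0("f", 1:12))
  shuffled <- sep2[c("label", perm)]
  for (fam in c("svm", "knn", "rf")) {
    a <- predict(train_model(model_spec(fam, 2, seed = 3), sep2), sep2)
    b <- predict(train_model(model_spec(fam, 2, seed = 3), shuffled), shuffled)
    expect_equal(as.character(a$.pred), as.character(b$.pred))
  }
})

test_that("training rejects degenerate inputs", {
  one_class <- dplyr::filter(sep2, label == "pain")
  expect_error(train_model(model_spec("svm", 2), one_class),
               class = "painsense_training_error")
  bad <- sep2
  bad$f1[3] <- NA
  expect_error(train_model(model_spec("rf", 2), bad),
               class = "painsense_validation_error")
  expect_error(train_model(model_spec("knn", 2),
                           flag_partition(sep2, "test")),
               class = "painsense_leakage_error")
  fit <- train_model(model_spec("svm", 2, seed = 1), sep2)
  expect_error(predict(fit, sep2[c("label", paste0("f", 1:5))]),
               class = "painsense_shape_error")
})

test_that("the CNN description matches the layer contract", {
  a2 <- build_cnn(2)
  expect_equal(a2$n_classes, 2L)
  a3 <- build_cnn(3)
  expect_equal(a3$n_classes, 3L)
  expect_equal(a2$dropout_sequence, c(0.25, 0.25, 0.5, 0.3))
  expect_equal(a2$filters, c(32, 64))
  expect_equal(a2$hidden, c(128, 64))
})

test_that("the LSTM description keeps default widths in 64-256 and warns outside 32-512", {
  a <- build_rnn(3)
  expect_equal(a$n_classes, 3L)
  expect_true(all(a$lstm_units >= 64 & a$lstm_units <= 256))
  expect_true(all(diff(a$lstm_units) <= 0))
  expect_warning(build_rnn(2, lstm_units = 16),
                 class = "painsense_config_warning")
  expect_warning(build_rnn(2, lstm_units = 1024),
                 class = "painsense_config_warning")
})

test_that("neural output layers have n_classes softmax units and valid rows", {
  tab3 <- generate_feature_table(c(low = 15, moderate = 15, high = 15),
                                 n_features = 12, effect_size = 6, seed = 2)
  cnn3 <- train_model(model_spec("cnn", 3, seed = 1, filters = c(4, 8),
                                 hidden = c(16, 8), epochs = 2), tab3)
  p3 <- predict(cnn3, tab3)
  expect_equal(ncol(p3), 1 + 3)
  expect_equal(rowSums(as.matrix(p3[-1])), rep(1, 45), tolerance = 1e-6,
               ignore_attr = TRUE)
  rnn2 <- train_model(model_spec("rnn", 2, seed = 1, lstm_units = 32,
                                 epochs = 2, fold = c(4, 3)), sep2)
  p2 <- predict(rnn2, sep2)
  expect_equal(ncol(p2), 1 + 2)
  expect_equal(rowSums(as.matrix(p2[-1])), rep(1, 60), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("neural training is reproducible under a fixed seed", {
  a <- train_model(model_spec("cnn", 2, seed = 5, filters = c(4, 8),
                              hidden = c(16, 8), epochs = 2), sep2)
  b <- train_model(model_spec("cnn", 2, seed = 5, filters = c(4, 8),
                              hidden = c(16, 8), epochs = 2), sep2)
  expect_equal(a$fit$params, b$fit$params)
  expect_identical(predict(a, sep2), predict(b, sep2))
})

test_that("an all-zero sequence input yields one constant output distribution", {
  rnn <- train_model(model_spec("rnn", 2, seed = 1, lstm_units = 32,
                                epochs = 1, fold = c(4, 3)), sep2)
  zeros <- matrix(0, 7, 12)
  p <- predict(rnn, zeros)
  expect_equal(max(apply(as.matrix(p[-1]), 2, function(cc) diff(range(cc)))),
               0, tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  ns <- asNamespace("painsense")
  set.seed(42)
  X <- matrix(rnorm(6 * 40), 6, 40)
  y <- factor(c("a", "b", "a", "b", "a", "b"))
  Y1 <- ns$.onehot(y, 2)
  check_grads <- function(fwd_fn, bwd_fn, params, n_probe = 2) {
    fw <- fwd_fn(params)
    gr <- bwd_fn(params, fw)
    worst <- 0
    for (pi in seq_along(params)) {
      for (t in seq_len(n_probe)) {
        ii <- sample(length(params[[pi]]), 1)
        eps <- 1e-6
        up <- params; up[[pi]][ii] <- up[[pi]][ii] + eps
        dn <- params; dn[[pi]][ii] <- dn[[pi]][ii] - eps
        num <- (ns$.xent(fwd_fn(up)$P, Y1) - ns$.xent(fwd_fn(dn)$P, Y1)) /
          (2 * eps)
        rel <- abs(num - gr[[pi]][ii]) /
          max(1e-8, abs(num) + abs(gr[[pi]][ii]))
        worst <- max(worst, rel)
      }
    }
    worst
  }
  arch <- build_cnn(2, filters = c(3, 4), kernel = 3L, pool = 2L,
                    hidden = c(5, 4))
  params <- painsense:::with_local_seed(1, ns$.cnn_params(arch, 40))
  worst_cnn <- check_grads(
    function(p) ns$.cnn_forward(p, arch, X, training = FALSE),
    function(p, fw) ns$.cnn_backward(p, arch, fw, Y1), params)
  expect_lt(worst_cnn, 1e-4)
  archr <- suppressWarnings(build_rnn(2, lstm_units = c(6, 5), dropout = 0,
                                      fc_units = 4))
  Xarr <- ns$.fold_sequence(X, c(8, 5))
  paramsr <- painsense:::with_local_seed(1, ns$.rnn_params(archr, 5))
  worst_rnn <- check_grads(
    function(p) ns$.rnn_forward(p, archr, Xarr, training = FALSE),
    function(p, fw) ns$.rnn_backward(p, archr, fw, Y1), paramsr)
  expect_lt(worst_rnn, 1e-5)
})

test_that("training loss falls on separable data for most seeds", {
  drops <- vapply(1:10, function(s) {
    fit <- train_model(model_spec("rnn", 2, seed = s, lstm_units = 32,
                                  epochs = 6, fold = c(4, 3),
                                  learning_rate = 0.003), sep2)
    h <- fit$history
    h$loss[nrow(h)] < h$loss[1]
  }, TRUE)
  expect_gte(mean(drops), 0.9)
})

test_that("grid search returns the best member of the full product", {
  spec <- model_spec("cnn", 2, seed = 1, filters = c(4), hidden = c(8),
                     batch_size = 16)
  single <- grid_search(spec, sep2, dropout_rates = 0.2,
                        learning_rates = 0.005, epoch_counts = 3, folds = 2)
  expect_equal(nrow(single$results), 1)
  expect_equal(single$best$dropout, 0.2)
  g <- grid_search(spec, sep2, dropout_rates = c(0, 0.3),
                   learning_rates = 0.005, epoch_counts = c(2, 4), folds = 2)
  expect_equal(nrow(g$results), 4)
  expect_equal(g$best$mean_accuracy, max(g$results$mean_accuracy))
  expect_true(g$best$dropout %in% c(0, 0.3) && g$best$epochs %in% c(2, 4))
  expect_error(grid_search(spec, sep2, numeric(0), 0.005, 3),
               class = "painsense_parameter_error")
  expect_error(grid_search(spec, sep2, 1.5, 0.005, 3),
               class = "painsense_parameter_error")
  expect_error(grid_search(model_spec("svm"), sep2, 0.2, 0.005, 3),
               class = "painsense_config_error")
})

test_that("tidy and glance expose history and hyperparameters", {
  rnn <- train_model(model_spec("rnn", 2, seed = 1, lstm_units = 32,
                                epochs = 3, fold = c(4, 3)), sep2)
  h <- tidy(rnn)
  expect_named(h, c("epoch", "loss", "accuracy"))
  expect_equal(nrow(h), 3)
  g <- glance(rnn)
  expect_equal(g$family, "rnn")
  expect_equal(g$n_train, 60)
  svm_fit <- train_model(model_spec("svm", 2, seed = 1), sep2)
  expect_true("term" %in% names(tidy(svm_fit)))
})
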
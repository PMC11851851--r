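# The five classifier families behind one train/predict surface. Features
# are standardised with training-set statistics only; the scaler travels
# with the fitted model. SVM (rbf, C = 1, sklearn-style gamma = "scale"),
# k-NN (k = 3, Euclidean) and random forest (100 trees, Gini) are the
# baselines (RF via ranger's fast C++ forests); the CNN and stacked LSTM
# come from the in-package training engine (Adam, categorical
# cross-entropy).

#' Classifier specification
#'
#' @param family One of `"svm"`, `"knn"`, `"rf"`, `"cnn"`, `"rnn"`.
#' @param n_classes 2 (pain/no-pain) or 3 (severity).
#' @param seed Integer seed (weight init, shuffling, dropout, tree
#'   bootstraps).
#' @param ... Family-specific overrides: `cost`, `gamma` (svm); `k` (knn);
#'   `ntree` (rf); `filters`, `kernel`, `pool`, `hidden`, `learning_rate`,
#'   `epochs`, `batch_size`, `dropout` (cnn); `lstm_units`, `fc_units`,
#'   `learning_rate`, `epochs`, `batch_size`, `dropout`, `fold` (rnn).
#' @return A `model_spec` list. Neural defaults: CNN Adam at learning rate
#'   9e-05 for 100 epochs (both tasks); LSTM Adam at 1e-03 for 100 (binary)
#'   or 50 (ternary) epochs.
#' @export
model_spec <- function(family = c("svm", "knn", "rf", "cnn", "rnn"),
                       n_classes = 2L, seed = 1L, ...) {
  family <- match.arg(family)
  if (!n_classes %in% c(2L, 3L)) {
    abort("n_classes must be 2 or 3", class = "painsense_config_error")
  }
  dots <- list(...)
  defaults <- switch(family,
    svm = list(kernel = "radial", cost = 1, gamma = "scale"),
    knn = list(k = 3L),
    rf = list(ntree = 100L),
    cnn = list(filters = c(32, 64), kernel = 3L, pool = 2L,
               hidden = c(128, 64), dropout = NULL,
               learning_rate = 9e-05, epochs = 100L, batch_size = 32L),
    rnn = list(lstm_units = c(128, 64), fc_units = 32L, dropout = NULL,
               learning_rate = 1e-03,
               epochs = if (n_classes == 2L) 100L else 50L,
               batch_size = 32L, fold = NULL))
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown hyperparameter(s) for ", family, ": ",
                 paste(unknown, collapse = ", ")),
          class = "painsense_config_error")
  }
  hyper <- utils::modifyList(defaults, dots, keep.null = TRUE)
  structure(list(family = family, n_classes = as.integer(n_classes),
                 hyper = hyper, seed = as.integer(seed)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s, %d classes\n", x$family, x$n_classes))
  invisible(x)
}

.standardizer_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl < 1e-12] <- 1
  list(center = ctr, scale = scl)
}

.standardizer_apply <- function(scaler, X) {
  sweep(sweep(X, 2, scaler$center), 2, scaler$scale, `/`)
}

#' Train a classifier on a labelled feature table
#'
#' Standardises the features (statistics fitted on this table only — pass
#' training partitions), then fits the requested family. Tables flagged as
#' test partitions are refused.
#'
#' @param spec A [model_spec()].
#' @param data Tibble with a label column plus numeric feature columns.
#' @param label_col Label column name (default `"label"`).
#' @return A fitted `pain_model` (with `$history` for neural families).
#' @export
#' @examples
#' tab <- generate_feature_table(c(a = 25, b = 25), effect_size = 4, seed = 1)
#' fit <- train_model(model_spec("rf", seed = 1), tab)
#' predict(fit, tab)
train_model <- function(spec, data, label_col = "label") {
  stopifnot(inherits(spec, "model_spec"))
  .check_not_test(data, "train_model()")
  y <- data[[label_col]]
  if (is.null(y)) abort(paste0("label column '", label_col, "' not found"),
                        class = "painsense_config_error")
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) {
    abort("training labels contain a single class",
          class = "painsense_training_error")
  }
  if (nlevels(y) != spec$n_classes) {
    abort(sprintf("spec expects %d classes but labels have %d",
                  spec$n_classes, nlevels(y)),
          class = "painsense_training_error")
  }
  feat_cols <- setdiff(names(data), intersect(
    c("epoch", "rating", "label", "variant", label_col), names(data)))
  X <- as.matrix(data[feat_cols])
  if (anyNA(X) || any(!is.finite(X))) {
    abort("feature matrix contains NA/Inf values",
          class = "painsense_validation_error")
  }
  scaler <- .standardizer_fit(X)
  Xs <- .standardizer_apply(scaler, X)
  h <- spec$hyper
  fit <- history <- rnn_fold <- NULL
  if (spec$family == "svm") {
    gamma <- h$gamma
    if (identical(gamma, "scale")) gamma <- 1 / (ncol(Xs) * var(as.vector(Xs)))
    fit <- with_local_seed(spec$seed,
      e1071::svm(Xs, y, kernel = h$kernel, cost = h$cost, gamma = gamma,
                 probability = TRUE))
  } else if (spec$family == "knn") {
    fit <- list(X = Xs, y = y, k = h$k)
  } else if (spec$family == "rf") {
    fit <- ranger::ranger(x = Xs, y = y, num.trees = h$ntree,
                          probability = TRUE, seed = spec$seed,
                          num.threads = 1)
  } else if (spec$family == "cnn") {
    arch <- if (is.null(h$dropout)) {
      build_cnn(spec$n_classes, h$filters, h$kernel, h$pool, h$hidden)
    } else {
      build_cnn(spec$n_classes, h$filters, h$kernel, h$pool, h$hidden,
                conv_dropout = h$dropout,
                fc_dropout = rep(h$dropout, 2))
    }
    tr <- .nn_train(arch, Xs, y, spec$n_classes, h$learning_rate, h$epochs,
                    h$batch_size, spec$seed, kind = "cnn")
    fit <- list(kind = "cnn", params = tr$params, arch = arch)
    history <- tr$history
  } else if (spec$family == "rnn") {
    units <- h$lstm_units
    arch <- build_rnn(spec$n_classes, units,
                      dropout = if (is.null(h$dropout)) 0.2 else h$dropout,
                      fc_units = h$fc_units)
    rnn_fold <- if (is.null(h$fold)) default_sequence_fold(ncol(Xs)) else h$fold
    tr <- .nn_train(arch, Xs, y, spec$n_classes, h$learning_rate, h$epochs,
                    h$batch_size, spec$seed, kind = "rnn",
                    rnn_fold = rnn_fold)
    fit <- list(kind = "rnn", params = tr$params, arch = arch,
                rnn_fold = rnn_fold)
    history <- tr$history
  }
  structure(list(spec = spec, fit = fit, scaler = scaler,
                 levels = levels(y), feat_cols = feat_cols,
                 history = history, n_train = nrow(Xs)),
            class = "pain_model")
}

#' Predict labels and class probabilities
#'
#' @param object A fitted `pain_model`.
#' @param newdata Tibble (or matrix) with the training feature columns.
#' @param ... Unused.
#' @return Tibble with `.pred` (factor label, the argmax of the
#'   probabilities) and one `.prob_<class>` column per class; rows sum to 1.
#' @export
predict.pain_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(object$feat_cols, names(newdata))
    if (length(missing) > 0) {
      abort(sprintf("newdata lacks %d training feature column(s), e.g. %s",
                    length(missing), missing[1]),
            class = "painsense_shape_error")
    }
    X <- as.matrix(newdata[object$feat_cols])
  } else {
    X <- as.matrix(newdata)
    if (ncol(X) != length(object$feat_cols)) {
      abort(sprintf("newdata has %d features, model was trained on %d",
                    ncol(X), length(object$feat_cols)),
            class = "painsense_shape_error")
    }
  }
  Xs <- .standardizer_apply(object$scaler, X)
  lv <- object$levels
  fam <- object$spec$family
  P <- if (fam == "svm") {
    pr <- predict(object$fit, Xs, probability = TRUE)
    attr(pr, "probabilities")[, lv, drop = FALSE]
  } else if (fam == "knn") {
    .knn_prob(object$fit, Xs, lv)
  } else if (fam == "rf") {
    predict(object$fit, Xs, num.threads = 1)$predictions[, lv, drop = FALSE]
  } else {
    .nn_predict_prob(object$fit, Xs)
  }
  P <- matrix(P, nrow(Xs), length(lv))
  labels <- factor(lv[max.col(P, ties.method = "first")], levels = lv)
  out <- tibble(.pred = labels)
  for (j in seq_along(lv)) out[[paste0(".prob_", lv[j])]] <- P[, j]
  out
}

# k-NN vote fractions (Euclidean); ties go to the nearer neighbourhood.
.knn_prob <- function(fit, Xq, lv) {
  d2 <- outer(rowSums(Xq^2), rowSums(fit$X^2), `+`) - 2 * tcrossprod(Xq, fit$X)
  P <- matrix(0, nrow(Xq), length(lv))
  for (i in seq_len(nrow(Xq))) {
    nb <- order(d2[i, ])[seq_len(fit$k)]
    votes <- table(factor(fit$y[nb], levels = lv))
    P[i, ] <- as.numeric(votes) / fit$k
  }
  P
}

#' @export
print.pain_model <- function(x, ...) {
  cat(sprintf("<pain_model> %s, %d classes, trained on %d samples\n",
              x$spec$family, x$spec$n_classes, x$n_train))
  invisible(x)
}

#' Tidy a fitted classifier
#'
#' Returns per-epoch training history for neural families and the fitted
#' hyperparameters for the baselines.
#'
#' @param x A `pain_model`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy pain_model
#' @export
tidy.pain_model <- function(x, ...) {
  if (!is.null(x$history)) return(x$history)
  hyper <- purrr::keep(x$spec$hyper, ~ is.numeric(.x) || is.character(.x))
  tibble(term = names(hyper),
         value = vapply(hyper, function(v) paste(format(v), collapse = ","),
                        ""))
}

#' One-row summary of a fitted classifier
#'
#' @param x A `pain_model`.
#' @param ... Unused.
#' @return Tibble with family, class count, training size and (for neural
#'   families) final training loss/accuracy.
#' @method glance pain_model
#' @export
glance.pain_model <- function(x, ...) {
  out <- tibble(family = x$spec$family, n_classes = x$spec$n_classes,
                n_train = x$n_train)
  if (!is.null(x$history)) {
    last <- x$history[nrow(x$history), ]
    out$final_loss <- last$loss
    out$final_train_accuracy <- last$accuracy
  }
  out
}

#' Grid search over dropout rate, learning rate and epoch count
#'
#' Exhaustively evaluates the Cartesian product of the three axes by
#' internal cross-validation (or a single validation split) and returns the
#' member with the highest mean validation accuracy, together with the full
#' results table.
#'
#' @param spec A neural [model_spec()] (`cnn` or `rnn`).
#' @param data Labelled training tibble.
#' @param dropout_rates Values in `[0, 0.9]`.
#' @param learning_rates Candidate Adam learning rates; the canonical search
#'   set is `c(0.2, 0.5, 0.05, 0.005, 0.009, 0.0009, 0.00009)`.
#' @param epoch_counts Candidate epoch budgets; canonical set
#'   `c(50, 80, 100, 120, 200)`.
#' @param folds Internal fold count (default 3); set to 1 to use a single
#'   stratified 80:20 validation split.
#' @param label_col Label column name.
#' @param seed Integer seed for the internal splits.
#' @return List with `best` (one-row tibble) and `results` (full grid
#'   table, one row per member with mean validation accuracy).
#' @export
grid_search <- function(spec, data, dropout_rates, learning_rates,
                        epoch_counts, folds = 3L, label_col = "label",
                        seed = 1L) {
  if (!spec$family %in% c("cnn", "rnn")) {
    abort("grid_search tunes the neural families (cnn, rnn)",
          class = "painsense_config_error")
  }
  if (length(dropout_rates) == 0 || length(learning_rates) == 0 ||
      length(epoch_counts) == 0) {
    abort("empty grid axis", class = "painsense_parameter_error")
  }
  if (any(dropout_rates < 0 | dropout_rates > 0.9)) {
    abort("dropout_rates must lie in [0, 0.9]",
          class = "painsense_parameter_error")
  }
  grid <- tidyr::expand_grid(dropout = dropout_rates, lr = learning_rates,
                             epochs = epoch_counts)
  y <- data[[label_col]]
  plan <- if (folds >= 2) split_plan("kfold", k = folds, seed = seed)
          else split_plan("holdout", seed = seed)
  splits <- make_splits(y, plan)
  scores <- purrr::pmap_dbl(grid, function(dropout, lr, epochs) {
    accs <- purrr::map_dbl(splits, function(sp) {
      sp_spec <- spec
      sp_spec$hyper$dropout <- dropout
      sp_spec$hyper$learning_rate <- lr
      sp_spec$hyper$epochs <- as.integer(epochs)
      fit <- train_model(sp_spec, data[sp$train, , drop = FALSE], label_col)
      pred <- predict(fit, data[sp$test, , drop = FALSE])
      mean(pred$.pred == y[sp$test])
    })
    mean(accs)
  })
  results <- dplyr::mutate(grid, mean_accuracy = scores)
  best <- results[which.max(results$mean_accuracy), ]
  list(best = best, results = results)
}
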
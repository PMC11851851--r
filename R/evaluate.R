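# Evaluation protocols and metrics: stratified 80:20 holdout and stratified
# 10-fold cross-validation; accuracy, precision, recall, F1 (positive-class
# for the binary task, macro-averaged for the ternary task) and RMSE between
# class-probability rows and one-hot labels. Augmentation and balancing are
# re-run inside every fold on that fold's training portion only; an audit
# table in the report proves no test index reached them.

#' Evaluation split plan
#'
#' @param protocol `"holdout"` (single 80:20 split) or `"kfold"`.
#' @param test_fraction Test share for holdout (default 0.2).
#' @param k Fold count for k-fold (default 10).
#' @param stratified Preserve class proportions per split (default TRUE).
#' @param seed Integer seed.
#' @return A `split_plan` list.
#' @export
split_plan <- function(protocol = c("holdout", "kfold"), test_fraction = 0.2,
                       k = 10L, stratified = TRUE, seed = 1L) {
  protocol <- match.arg(protocol)
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("test_fraction must lie in (0, 1)", class = "painsense_config_error")
  }
  if (k < 2) abort("k must be >= 2", class = "painsense_config_error")
  structure(list(protocol = protocol, test_fraction = test_fraction,
                 k = as.integer(k), stratified = isTRUE(stratified),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Build train/test index sets
#'
#' Holdout yields one `(train, test)` pair; k-fold yields `k` pairs whose
#' test folds are disjoint and cover every index exactly once. Stratified
#' plans keep per-class proportions within one sample of the overall split.
#'
#' @param y Label vector (factor).
#' @param plan A [split_plan()].
#' @return List of `list(train, test)` integer index pairs.
#' @export
make_splits <- function(y, plan) {
  stopifnot(inherits(plan, "split_plan"))
  y <- as.factor(y)
  n <- length(y)
  with_local_seed(plan$seed, {
    if (plan$protocol == "holdout") {
      test_idx <- if (plan$stratified) {
        unlist(lapply(levels(y), function(cl) {
          idx <- which(y == cl)
          if (length(idx) < 2) {
            abort(sprintf("class '%s' has fewer than 2 samples", cl),
                  class = "painsense_config_error")
          }
          sample(idx, max(1L, round(plan$test_fraction * length(idx))))
        }))
      } else {
        sample.int(n, round(plan$test_fraction * n))
      }
      test_idx <- sort(test_idx)
      list(list(train = setdiff(seq_len(n), test_idx), test = test_idx))
    } else {
      fold_of <- integer(n)
      if (plan$stratified) {
        for (cl in levels(y)) {
          idx <- which(y == cl)
          if (length(idx) < plan$k) {
            abort(sprintf(
              "class '%s' (%d samples) is smaller than k = %d under stratified k-fold",
              cl, length(idx), plan$k), class = "painsense_config_error")
          }
          fold_of[sample(idx)] <- rep_len(seq_len(plan$k), length(idx))
        }
      } else {
        fold_of <- rep_len(seq_len(plan$k), n)[sample.int(n)]
      }
      lapply(seq_len(plan$k), function(f) {
        list(train = which(fold_of != f), test = which(fold_of == f))
      })
    }
  })
}

#' Classification metrics against true labels
#'
#' Accuracy plus precision/recall/F1 — positive-class for two classes
#' (positive = `"pain"` when present, else the second level), averaged over
#' classes otherwise — and, when probabilities are supplied, RMSE between
#' the probability rows and the one-hot true labels.
#'
#' @param truth Factor of true labels.
#' @param estimate Factor of predicted labels on the same level set.
#' @param prob Optional numeric matrix (rows = samples, columns = classes in
#'   level order).
#' @param average `"macro"` (default), `"micro"` or `"weighted"` averaging
#'   for 3+ classes.
#' @param positive Positive class for the binary case.
#' @return One-row tibble `accuracy`, `precision`, `recall`, `f1`, `rmse`
#'   with the confusion matrix (true rows x predicted columns) attached as
#'   attribute `"confusion"`.
#' @export
compute_metrics <- function(truth, estimate, prob = NULL,
                            average = c("macro", "micro", "weighted"),
                            positive = NULL) {
  average <- match.arg(average)
  truth <- as.factor(truth)
  lv <- levels(truth)
  if (!all(levels(as.factor(estimate)) %in% lv)) {
    abort("predicted label set disagrees with the true classes",
          class = "painsense_config_error")
  }
  estimate <- factor(estimate, levels = lv)
  if (length(truth) != length(estimate)) {
    abort("truth and estimate lengths differ", class = "painsense_config_error")
  }
  cm <- table(truth = truth, predicted = estimate)
  acc <- sum(diag(cm)) / sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec_c <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec_c <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1_c <- ifelse(prec_c + rec_c == 0, 0,
                 2 * prec_c * rec_c / (prec_c + rec_c))
  if (length(lv) == 2) {
    if (is.null(positive)) positive <- if ("pain" %in% lv) "pain" else lv[2]
    i <- match(positive, lv)
    prec <- prec_c[i]; rec <- rec_c[i]; f1 <- f1_c[i]
  } else if (average == "macro") {
    prec <- mean(prec_c); rec <- mean(rec_c); f1 <- mean(f1_c)
  } else if (average == "micro") {
    prec <- sum(tp) / (sum(tp) + sum(fp))
    rec <- sum(tp) / (sum(tp) + sum(fn))
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  } else {
    w <- rowSums(cm) / sum(cm)
    prec <- sum(w * prec_c); rec <- sum(w * rec_c); f1 <- sum(w * f1_c)
  }
  rmse <- NA_real_
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    Y1 <- matrix(0, length(truth), length(lv))
    Y1[cbind(seq_along(truth), as.integer(truth))] <- 1
    rmse <- sqrt(mean((prob - Y1)^2))
  }
  out <- tibble(accuracy = acc, precision = unname(prec),
                recall = unname(rec), f1 = unname(f1), rmse = rmse)
  attr(out, "confusion") <- cm
  out
}

#' Run a full classifier-evaluation experiment
#'
#' For each classifier and each split of the plan: the training portion is
#' (optionally) expanded with the transform operators and balanced with
#' SMOTE, a model is trained (standardisation fitted on that training data
#' only) and metrics are computed on the untouched test portion. Fold-level
#' metrics, aggregated means, confusion matrices, augmentation bookkeeping
#' and a leakage audit are collected in the returned report.
#'
#' @param features Feature tibble with either a `label` column or a
#'   `rating` column (labelled via `scheme`).
#' @param specs List of [model_spec()] objects, or a character vector of
#'   family names (specs are then built with default hyperparameters).
#' @param plan A [split_plan()].
#' @param augment An [augment_config()], or `NULL` to disable augmentation
#'   and balancing.
#' @param scheme `"binary"` or `"ternary"`; used when labels are derived
#'   from ratings and to set `n_classes` for auto-built specs.
#' @param seed Seed for auto-built specs.
#' @return A `pain_report`.
#' @export
run_experiment <- function(features, specs, plan = split_plan(),
                           augment = augment_config(),
                           scheme = c("binary", "ternary"), seed = 1L) {
  scheme <- match.arg(scheme)
  n_classes <- if (scheme == "binary") 2L else 3L
  data <- features
  if (!"label" %in% names(data)) {
    if (!"rating" %in% names(data)) {
      abort("features need a 'label' or 'rating' column",
            class = "painsense_config_error")
    }
    data$label <- if (scheme == "binary") label_binary(data$rating)
                  else label_ternary(data$rating)
  }
  if (is.character(specs)) {
    specs <- lapply(specs, function(f) model_spec(f, n_classes, seed = seed))
  }
  splits <- make_splits(data$label, plan)
  fold_rows <- list()
  audit_rows <- list()
  confusions <- list()
  for (fi in seq_along(splits)) {
    sp <- splits[[fi]]
    train <- flag_partition(data[sp$train, , drop = FALSE], "train")
    test <- flag_partition(data[sp$test, , drop = FALSE], "test")
    n_before <- nrow(train)
    if (!is.null(augment)) {
      # augmentation once per fold, shared by every classifier family
      train <- transform_training_set(train, augment)
      n_transformed <- nrow(train)
      train <- smote_balance(train, k = augment$smote_k,
                             seed = augment$seed + fi)
    } else {
      n_transformed <- n_before
    }
    n_after <- nrow(train)
    for (spec in specs) {
      fam <- spec$family
      fit <- train_model(spec, train)
      pred <- predict(fit, test)
      P <- as.matrix(pred[paste0(".prob_", fit$levels)])
      m <- compute_metrics(factor(test$label, levels = fit$levels),
                           pred$.pred, prob = P)
      confusion <- attr(m, "confusion")
      confusions[[fam]] <- if (is.null(confusions[[fam]])) confusion
                           else confusions[[fam]] + confusion
      fold_rows[[length(fold_rows) + 1]] <-
        dplyr::mutate(m, family = fam, fold = fi, n_train = n_before,
                      n_train_augmented = n_after, n_test = nrow(test),
                      .before = 1)
      audit_rows[[length(audit_rows) + 1]] <- tibble(
        family = fam, fold = fi,
        n_train = n_before, n_transformed = n_transformed,
        n_balanced = n_after, n_test = length(sp$test),
        test_in_augmentation = length(intersect(sp$train, sp$test)))
    }
  }
  metrics <- dplyr::bind_rows(fold_rows)
  summary <- metrics |>
    dplyr::group_by(.data$family) |>
    dplyr::summarise(dplyr::across(c("accuracy", "precision", "recall",
                                     "f1", "rmse"), mean),
                     n_folds = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$accuracy))
  structure(list(metrics = metrics, summary = summary,
                 confusion = confusions,
                 audit = dplyr::bind_rows(audit_rows),
                 scheme = scheme, plan = plan, augment = augment),
            class = "pain_report")
}

#' @export
print.pain_report <- function(x, ...) {
  cat(sprintf("<pain_report> %s scheme, %s protocol (%d split(s))\n",
              x$scheme, x$plan$protocol, length(unique(x$metrics$fold))))
  print(x$summary)
  invisible(x)
}

#' Fold-level metrics of an evaluation report
#' @param x A `pain_report`.
#' @param ... Unused.
#' @return Tibble with one row per classifier x fold.
#' @method tidy pain_report
#' @export
tidy.pain_report <- function(x, ...) x$metrics

#' Aggregated metrics of an evaluation report
#' @param x A `pain_report`.
#' @param ... Unused.
#' @return Tibble with one row per classifier (mean over folds), best first.
#' @method glance pain_report
#' @export
glance.pain_report <- function(x, ...) x$summary

#' Plot per-classifier accuracy of an evaluation report
#'
#' @param object A `pain_report`.
#' @param metric Metric column to plot (default `"accuracy"`).
#' @param ... Unused.
#' @return A ggplot: fold-level points over per-family mean bars.
#' @method autoplot pain_report
#' @export
autoplot.pain_report <- function(object, metric = "accuracy", ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$family, y = .data[[metric]])) +
    ggplot2::stat_summary(fun = mean, geom = "col", alpha = 0.6,
                          fill = "steelblue") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.7, size = 1) +
    ggplot2::labs(x = NULL, y = metric,
                  title = sprintf("%s classification (%s)", object$scheme,
                                  object$plan$protocol)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the training history of a neural classifier
#'
#' @param model A fitted neural `pain_model`.
#' @return A ggplot of loss and training accuracy per epoch.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history)) {
    abort("model has no training history (baseline family)",
          class = "painsense_config_error")
  }
  long <- tidyr::pivot_longer(model$history, c("loss", "accuracy"),
                              names_to = "series")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::theme_minimal()
}
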
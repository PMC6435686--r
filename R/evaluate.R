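#' Score predictions against reference labels
#'
#' Builds the class-by-class confusion matrix (rows: reference, columns:
#' predicted) and derives accuracy (trace / n), balanced accuracy (mean of
#' per-class recall over classes present in the reference), per-class
#' sensitivity (recall), specificity (one-vs-rest true-negative rate) and
#' precision. When the prediction table carries posterior columns the
#' macro one-vs-rest AUC is computed as well.
#'
#' Precision is reported alongside specificity because concordance tables
#' are read in both directions in practice: with the clinical routine as
#' reference, the assay's "specificity" quoted from the prediction side is
#' the precision of the positive class.
#'
#' @param predictions Tibble with `sample_id`, `predicted_class` and
#'   optionally one posterior column per class.
#' @param labels Reference label tibble covering every predicted sample.
#' @return An `ssp_eval` object; see [tidy.ssp_eval()] /
#'   [glance.ssp_eval()].
#' @export
score_predictions <- function(predictions, labels) {
  if (!all(c("sample_id", "predicted_class") %in% names(predictions))) {
    abort("`predictions` needs `sample_id` and `predicted_class` columns.")
  }
  labels <- as_labels(labels)
  miss <- setdiff(predictions$sample_id, labels$sample_id)
  if (length(miss)) {
    abort(paste0("Predictions without reference labels: ",
                 toString(head(miss, 5))))
  }
  truth <- setNames(labels$class, labels$sample_id)[predictions$sample_id]
  pred <- predictions$predicted_class
  classes <- sort(union(truth, pred))
  conf <- table(factor(truth, classes), factor(pred, classes))
  dimnames(conf) <- list(reference = classes, predicted = classes)
  n <- sum(conf)
  ref_classes <- classes[rowSums(conf) > 0]
  recalls <- vapply(ref_classes, function(cl) {
    conf[cl, cl] / sum(conf[cl, ])
  }, numeric(1))
  per_class <- dplyr::bind_rows(lapply(classes, function(cl) {
    tp <- conf[cl, cl]
    fn <- sum(conf[cl, ]) - tp
    fp <- sum(conf[, cl]) - tp
    tn <- n - tp - fn - fp
    tibble(
      class = cl, n = tp + fn,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_
    )
  }))
  post_cols <- intersect(classes, names(predictions))
  auc <- if (length(post_cols) >= 2) {
    macro_ovr_auc(predictions, labels)
  } else {
    NA_real_
  }
  structure(
    list(confusion = conf, n = n,
         accuracy = sum(diag(conf)) / n,
         balanced_accuracy = mean(recalls),
         macro_auc = auc,
         per_class = per_class),
    class = "ssp_eval"
  )
}

#' @export
print.ssp_eval <- function(x, ...) {
  cat("<ssp_eval> n =", x$n, "\n")
  print(x$confusion)
  cat(sprintf("accuracy %.3f | balanced accuracy %.3f | macro AUC %s\n",
              x$accuracy, x$balanced_accuracy,
              ifelse(is.na(x$macro_auc), "-", sprintf("%.3f", x$macro_auc))))
  invisible(x)
}

#' Tidy/summarize an evaluation
#'
#' `tidy()` returns the per-class sensitivity/specificity/precision
#' table; `glance()` the one-row overall metrics.
#'
#' @param x An `ssp_eval`.
#' @param ... Unused.
#' @method tidy ssp_eval
#' @export
tidy.ssp_eval <- function(x, ...) x$per_class

#' @rdname tidy.ssp_eval
#' @method glance ssp_eval
#' @export
glance.ssp_eval <- function(x, ...) {
  tibble(n = x$n, accuracy = x$accuracy,
         balanced_accuracy = x$balanced_accuracy, macro_auc = x$macro_auc)
}

#' Macro-averaged one-vs-rest AUC
#'
#' For each class with at least one positive and one negative in the
#' reference, the rank-based (Mann-Whitney, midrank ties) AUC of that
#' class's posterior score against all other classes; macro-averaged.
#' Classes with zero positives are skipped with a warning. Invariant to
#' strictly increasing transforms of the scores.
#'
#' @param predictions Tibble with `sample_id` and one score column per
#'   class.
#' @param labels Reference label tibble.
#' @return AUC in \[0, 1\].
#' @export
macro_ovr_auc <- function(predictions, labels) {
  labels <- as_labels(labels)
  truth <- setNames(labels$class, labels$sample_id)[predictions$sample_id]
  classes <- sort(unique(truth))
  aucs <- numeric(0)
  for (cl in classes) {
    if (!cl %in% names(predictions)) {
      warn(paste0("No posterior column for class '", cl, "'; skipped."))
      next
    }
    y <- truth == cl
    n1 <- sum(y)
    n0 <- sum(!y)
    if (n1 == 0) {
      warn(paste0("Class '", cl, "' has zero positives; skipped."))
      next
    }
    if (n0 == 0) next
    r <- rank(predictions[[cl]])  # midranks
    aucs <- c(aucs, (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(aucs) == 0) abort("No class with both positives and negatives.")
  mean(aucs)
}

# proportion-preserving stratified split; remainder goes to train
stratified_partition <- function(y, test_n) {
  classes <- sort(unique(y))
  n <- length(y)
  base <- floor(test_n * table(y)[classes] / n)
  frac <- test_n * table(y)[classes] / n - base
  short <- test_n - sum(base)
  if (short > 0) {
    bump <- order(-frac)[seq_len(short)]
    base[bump] <- base[bump] + 1
  }
  test_idx <- integer(0)
  for (i in seq_along(classes)) {
    idx <- which(y == classes[i])
    test_idx <- c(test_idx, idx[sample.int(length(idx), base[i])])
  }
  sort(test_idx)
}

#' Iterated stratified train/test evaluation
#'
#' The feasibility protocol: repeatedly partition the cohort into a
#' training and test set stratified by histology (proportion-preserving;
#' remainder samples go to train), train a fresh model on the training
#' split, then score both the training reclassification and the held-out
#' test predictions. Per-iteration metrics plus their mean and SD are
#' reported; the SD columns are present only when `n_iter > 1`.
#'
#' @param expr Expression tibble.
#' @param labels Label tibble.
#' @param n_iter Number of iterations (default 10).
#' @param train_n,test_n Split sizes; must sum to the labeled cohort size
#'   (defaults 48/20).
#' @param seed Integer seed; partition `i` and the model trained on it
#'   derive from `seed + i`.
#' @param panel,alpha,k_grid,folds,priors Passed to [train_ssp()].
#' @return An `ssp_holdout` object with `iterations`, `summary`,
#'   `n_iterations` and the last fitted model.
#' @export
iterated_holdout <- function(expr, labels, n_iter = 10, train_n = 48,
                             test_n = 20, seed = 1L,
                             panel = default_marker_panel(), alpha = 1,
                             k_grid = 1:25, folds = 5, priors = "uniform") {
  expr <- as_expression(expr, expr_platform(expr))
  labels <- as_labels(labels)
  labels <- labels[labels$sample_id %in% names(expr)[-1], ]
  n <- nrow(labels)
  if (train_n + test_n != n) {
    abort(paste0("train_n + test_n (", train_n + test_n,
                 ") must equal the labeled cohort size (", n, ")."))
  }
  y <- labels$class
  rows <- vector("list", n_iter)
  model <- NULL
  for (i in seq_len(n_iter)) {
    it_seed <- as.integer(seed) + i
    test_idx <- withr::with_seed(it_seed, stratified_partition(y, test_n))
    test_ids <- labels$sample_id[test_idx]
    train_ids <- setdiff(labels$sample_id, test_ids)
    model <- train_ssp(expr[, c("gene_id", train_ids)],
                       labels[labels$sample_id %in% train_ids, ],
                       panel = panel, alpha = alpha, k_grid = k_grid,
                       folds = folds, seed = it_seed, priors = priors)
    score_split <- function(ids, split) {
      sub <- expr[, c("gene_id", ids)]
      attr(sub, "platform") <- expr_platform(expr)
      ev <- score_predictions(predict_ssp(model, sub),
                              labels[labels$sample_id %in% ids, ])
      tibble(iteration = i, split = split, accuracy = ev$accuracy,
             balanced_accuracy = ev$balanced_accuracy,
             macro_auc = ev$macro_auc)
    }
    rows[[i]] <- dplyr::bind_rows(score_split(train_ids, "train"),
                                  score_split(test_ids, "test"))
  }
  iterations <- dplyr::bind_rows(rows)
  summary <- iterations |>
    tidyr::pivot_longer(cols = c("accuracy", "balanced_accuracy", "macro_auc"),
                        names_to = "metric", values_to = "value") |>
    dplyr::group_by(.data$split, .data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     .groups = "drop")
  if (n_iter == 1) summary$sd <- NULL
  structure(
    list(iterations = iterations, summary = summary, n_iterations = n_iter,
         train_n = train_n, test_n = test_n, seed = as.integer(seed),
         last_model = model),
    class = "ssp_holdout"
  )
}

#' @export
print.ssp_holdout <- function(x, ...) {
  cat("<ssp_holdout>", x$n_iterations, "iterations of",
      paste0(x$train_n, "/", x$test_n), "stratified splits\n")
  print(as.data.frame(x$summary))
  invisible(x)
}

#' @method tidy ssp_holdout
#' @export
tidy.ssp_holdout <- function(x, ...) x$iterations

#' @method glance ssp_holdout
#' @export
glance.ssp_holdout <- function(x, ...) {
  wide <- x$summary
  wide$key <- paste(wide$split, wide$metric, sep = "_")
  out <- as.list(setNames(wide$mean, paste0("mean_", wide$key)))
  as_tibble(c(list(n_iterations = x$n_iterations), out))
}

#' @method autoplot ssp_holdout
#' @export
autoplot.ssp_holdout <- function(object, ...) {
  long <- tidyr::pivot_longer(object$iterations,
                              cols = c("accuracy", "balanced_accuracy",
                                       "macro_auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value,
                                     fill = .data$split)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Metric over iterations") +
    ggplot2::theme_minimal()
}
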
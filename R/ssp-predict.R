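#' Predict histology for single samples
#'
#' Applies a trained model to an expression table. Each sample is scored
#' independently of every other column (the single-sample contract: the
#' posterior of a sample never changes when other columns are dropped,
#' duplicated or permuted), and scoring uses only within-sample value
#' ranks, so predictions are invariant under any strictly increasing
#' per-sample transform of the values — counts, FPKM and intensities are
#' all acceptable as-is.
#'
#' Posteriors come from the log-space naive Bayes layer
#' `log P(class | x) = log prior + sum_r [x_r log p + (1 - x_r) log(1 - p)]`
#' normalized across classes; ties in the argmax break to the first class
#' in alphabetical class order.
#'
#' @param model An `ssp_model` from [train_ssp()].
#' @param expr Expression tibble in which every rule gene resolves,
#'   directly or through the model panel's alias table.
#' @return Tibble: `sample_id`, `predicted_class`, then one posterior
#'   column per class (rows sum to 1).
#' @export
predict_ssp <- function(model, expr) {
  stopifnot(inherits(model, "ssp_model"))
  expr <- as_expression(expr, expr_platform(expr))
  need <- union(model$rules$gene_low, model$rules$gene_high)
  sub <- resolve_genes(expr, need, model$panel$aliases)
  b <- rule_matrix(expr_values(sub), model$rules)
  post <- nb_posterior(b, model$cond_prob, model$priors, model$classes)
  pred <- model$classes[apply(post, 2, which.max)]  # which.max: first on ties
  out <- dplyr::bind_cols(
    tibble(sample_id = colnames(b), predicted_class = pred),
    as_tibble(as.data.frame(t(post), check.names = FALSE))
  )
  class(out) <- c("ssp_prediction", class(out))
  out
}

#' Plot per-sample class posteriors
#'
#' Stacked-bar view of the class probabilities assigned to each sample,
#' in the spirit of per-tumor probability reporting.
#'
#' @param object A prediction tibble from [predict_ssp()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssp_prediction
#' @export
autoplot.ssp_prediction <- function(object, ...) {
  classes <- setdiff(names(object), c("sample_id", "predicted_class"))
  long <- tidyr::pivot_longer(as_tibble(object), cols = dplyr::all_of(classes),
                              names_to = "class", values_to = "posterior")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$posterior,
                                     fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Posterior probability", fill = "Histology") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the cross-validated rule-count curve
#'
#' @param object An `ssp_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ssp_model
#' @export
autoplot.ssp_model <- function(object, ...) {
  ggplot2::ggplot(object$cv_record,
                  ggplot2::aes(x = .data$k, y = .data$mean_balanced_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "Number of rules (k)",
                  y = "CV mean balanced accuracy") +
    ggplot2::theme_minimal()
}
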
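MODEL_SCHEMA_VERSION <- "1.0"

#' Save or load a trained model
#'
#' Models are serialized to a versioned, human-readable JSON file holding
#' the full rule list, smoothed conditional probabilities, class order,
#' priors and training provenance (seed, k-grid, CV record, panel). A
#' reloaded model produces numerically identical posteriors.
#'
#' @param model An `ssp_model`.
#' @param path File path (conventionally `.json`).
#' @return `path` invisibly ([write_ssp_model()]); an `ssp_model`
#'   ([read_ssp_model()]).
#' @export
write_ssp_model <- function(model, path) {
  stopifnot(inherits(model, "ssp_model"))
  payload <- list(
    schema_version = MODEL_SCHEMA_VERSION,
    classes = model$classes,
    rules = model$rules,
    cond_prob = as.data.frame(model$cond_prob, check.names = FALSE),
    priors = as.list(model$priors),
    alpha = model$alpha,
    k = model$k,
    k_grid = model$k_grid,
    cv_record = model$cv_record,
    folds = model$folds,
    seed = model$seed,
    priors_mode = model$priors_mode,
    n_train = model$n_train,
    panel = list(classes = model$panel$classes, aliases = model$panel$aliases)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ssp_model
#' @export
read_ssp_model <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$schema_version)) {
    abort(paste0("Model file lacks a schema_version field: ", path))
  }
  if (!identical(as.character(p$schema_version), MODEL_SCHEMA_VERSION)) {
    abort(paste0("Unsupported model schema version '", p$schema_version,
                 "' (expected ", MODEL_SCHEMA_VERSION, ")."))
  }
  need <- c("classes", "rules", "cond_prob", "priors", "alpha", "k", "panel")
  miss <- need[!need %in% names(p)]
  if (length(miss)) {
    abort(paste0("Model file missing fields: ", toString(miss)))
  }
  cond <- as.matrix(p$cond_prob)
  rownames(cond) <- p$rules$rule
  aliases <- p$panel$aliases
  if (is.null(aliases) || length(aliases) == 0) aliases <- list()
  structure(
    list(
      schema_version = as.character(p$schema_version),
      classes = as.character(p$classes),
      rules = as_tibble(p$rules),
      cond_prob = cond[, as.character(p$classes), drop = FALSE],
      priors = unlist(p$priors)[as.character(p$classes)],
      alpha = p$alpha,
      k = as.integer(p$k),
      k_grid = as.integer(p$k_grid),
      cv_record = if (!is.null(p$cv_record)) as_tibble(p$cv_record) else NULL,
      folds = p$folds,
      seed = as.integer(p$seed),
      priors_mode = p$priors_mode %||% "uniform",
      n_train = p$n_train,
      panel = marker_panel(p$panel$classes, aliases)
    ),
    class = "ssp_model"
  )
}

#' Write a calls or predictions table
#'
#' Writes a TSV with a stable column order. Prediction tables carry
#' `sample_id`, `predicted_class` and one posterior column per class;
#' fusion-call tables carry `sample_id`, `gene`, `status`, `best_variant`,
#' `imbalance_ratio`, `max_junction_count`, `qc_flag`, `qc_reason`. A table
#' mixing the two signatures (or matching neither) is rejected.
#'
#' @param calls A prediction tibble ([predict_ssp()]) or fusion-call
#'   tibble ([call_fusions()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_calls_table <- function(calls, path) {
  if (!is.data.frame(calls) || nrow(calls) == 0) {
    abort("`calls` must be a non-empty data frame.")
  }
  is_pred <- all(c("sample_id", "predicted_class") %in% names(calls))
  fusion_cols <- c("sample_id", "gene", "status", "best_variant",
                   "imbalance_ratio", "max_junction_count", "qc_flag")
  is_fusion <- all(fusion_cols %in% names(calls))
  if (is_pred == is_fusion) {
    abort("`calls` must be either a prediction table or a fusion-call table, not both/neither.")
  }
  if (is_pred) {
    classes <- sort(setdiff(names(calls), c("sample_id", "predicted_class")))
    out <- calls[, c("sample_id", "predicted_class", classes)]
  } else {
    out <- calls[, c(fusion_cols, intersect("qc_reason", names(calls)))]
  }
  readr::write_tsv(as_tibble(out), path)
  invisible(path)
}

#' @rdname write_calls_table
#' @export
read_calls_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE)
}
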
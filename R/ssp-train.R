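#' Background-correct NanoString counts
#'
#' Per sample, the background is estimated from the negative-control probes
#' as `mean + 2 * sd` of their counts; every remaining probe value becomes
#' `max(value - background, floor)`. Negative-control rows are removed from
#' the output. Correction only applies to raw NanoString counts; FPKM and
#' microarray tables are used as-is upstream.
#'
#' @param expr Expression tibble with platform `"nanostring_counts"`.
#' @param negative_probes Character vector of negative-control probe ids
#'   present in `expr`, or `NULL` to take them from `probe_classes`.
#' @param probe_classes Optional tibble (`probe_id`, `code_class`) as
#'   returned by [read_rcc_batch()]; rows with class `"Negative"` are used.
#' @param floor Positive floor applied after subtraction (default 1, so
#'   ratios computed downstream never divide by zero).
#' @return Expression tibble without the negative-control rows.
#' @export
background_correct <- function(expr, negative_probes = NULL,
                               probe_classes = NULL, floor = 1) {
  expr <- as_expression(expr, expr_platform(expr))
  if (expr_platform(expr) != "nanostring_counts") {
    abort("Background correction applies to platform 'nanostring_counts' only.")
  }
  if (is.null(negative_probes) && !is.null(probe_classes)) {
    negative_probes <- probe_classes$probe_id[probe_classes$code_class == "Negative"]
  }
  if (is.null(negative_probes) || length(negative_probes) == 0) {
    abort("No negative-control probes supplied for background correction.")
  }
  if (floor <= 0) abort("`floor` must be positive.")
  m <- expr_values(expr)
  negs <- intersect(negative_probes, rownames(m))
  if (length(negs) == 0) {
    abort("None of the negative-control probes are present in the table.")
  }
  nm <- m[negs, , drop = FALSE]
  b <- apply(nm, 2, mean) + 2 * apply(nm, 2, sd)
  b[is.na(b)] <- nm[1, ][is.na(b)]  # single negative probe: sd undefined, use its count
  keep <- setdiff(rownames(m), negs)
  out <- m[keep, , drop = FALSE]
  out <- pmax(sweep(out, 2, b, "-"), floor)
  expr_from_matrix(out, "nanostring_counts")
}

#' Enumerate candidate gene-pair rules
#'
#' All ordered pairs `(gene_low, gene_high)` over the panel genes. A rule
#' fires for a sample when `expression(gene_low) < expression(gene_high)`
#' strictly, within that sample. Order is deterministic: panel order,
#' low-gene index first, so 11 genes give 110 rules.
#'
#' @param panel A `marker_panel`.
#' @return Tibble with `rule`, `gene_low`, `gene_high`.
#' @export
enumerate_pair_rules <- function(panel) {
  genes <- panel_genes(panel)
  if (length(genes) < 2) abort("Need at least two panel genes.")
  grid <- expand.grid(j = seq_along(genes), i = seq_along(genes))
  grid <- grid[grid$i != grid$j, c("i", "j")]
  grid <- grid[order(grid$i, grid$j), ]
  tibble(
    rule = paste0(genes[grid$i], "<", genes[grid$j]),
    gene_low = genes[grid$i],
    gene_high = genes[grid$j]
  )
}

reverse_rule_id <- function(rules) paste0(rules$gene_high, "<", rules$gene_low)

# genes x samples value matrix -> rules x samples 0/1 matrix
rule_matrix <- function(vals, rules) {
  b <- (vals[rules$gene_low, , drop = FALSE] <
          vals[rules$gene_high, , drop = FALSE]) * 1
  rownames(b) <- rules$rule
  b
}

#' Binarize pair rules on an expression table
#'
#' Evaluates each rule on each sample: 1 when the low gene's value is
#' strictly below the high gene's, 0 otherwise (ties give 0 for both
#' orientations). The result depends only on within-sample value ranks, so
#' any strictly increasing per-sample transform leaves it unchanged —
#' which is what makes the predictor platform-portable.
#'
#' @param expr Expression tibble containing all rule genes.
#' @param rules Tibble with `gene_low`, `gene_high` (see
#'   [enumerate_pair_rules()]).
#' @return Tibble: `rule`, `gene_low`, `gene_high`, then one 0/1 column per
#'   sample.
#' @export
binarize_rules <- function(expr, rules) {
  expr <- as_expression(expr, expr_platform(expr))
  need <- union(rules$gene_low, rules$gene_high)
  missing <- setdiff(need, expr$gene_id)
  if (length(missing)) {
    abort(paste0("Rule genes missing from the table: ", toString(missing)))
  }
  b <- rule_matrix(expr_values(expr), rules)
  dplyr::bind_cols(
    tibble(rule = rules$rule, gene_low = rules$gene_low,
           gene_high = rules$gene_high),
    as_tibble(as.data.frame(b, check.names = FALSE))
  )
}

binary_values <- function(binary) {
  m <- as.matrix(binary[, setdiff(names(binary), c("rule", "gene_low", "gene_high")),
                        drop = FALSE])
  rownames(m) <- binary$rule
  storage.mode(m) <- "double"
  m
}

align_labels <- function(sample_ids, labels) {
  labels <- as_labels(labels)
  miss <- setdiff(sample_ids, labels$sample_id)
  if (length(miss)) {
    abort(paste0("Samples without labels: ", toString(head(miss, 5))))
  }
  setNames(labels$class, labels$sample_id)[sample_ids]
}

#' Rank rules by class discrimination
#'
#' For each class, rules are scored by the absolute gap between their
#' firing frequency inside the class and outside it,
#' `|freq(rule = 1 | class) - freq(rule = 1 | rest)|`, and sorted
#' descending with ties broken by enumeration order. Within a class list
#' the reverse orientation of an already-ranked rule is skipped, so a
#' class never lists both `A<B` and `B<A`.
#'
#' @param binary Binarized rule tibble from [binarize_rules()].
#' @param labels Label tibble covering every sample column.
#' @return Tibble: `class`, `rank`, `rule`, `gene_low`, `gene_high`,
#'   `score`.
#' @export
rank_rules <- function(binary, labels) {
  b <- binary_values(binary)
  y <- align_labels(colnames(b), labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("Need at least two classes.")
  small <- names(which(table(y) < 2))
  if (length(small)) {
    abort(paste0("Classes with fewer than 2 samples: ", toString(small)))
  }
  rev_id <- setNames(reverse_rule_id(binary), binary$rule)
  out <- lapply(classes, function(cl) {
    f1 <- rowMeans(b[, y == cl, drop = FALSE])
    f0 <- rowMeans(b[, y != cl, drop = FALSE])
    score <- abs(f1 - f0)
    ord <- order(-score)  # stable: ties keep enumeration order
    kept <- character(0)
    keep_idx <- integer(0)
    for (i in ord) {
      id <- binary$rule[i]
      if (rev_id[[id]] %in% kept) next
      kept <- c(kept, id)
      keep_idx <- c(keep_idx, i)
    }
    tibble(
      class = cl,
      rank = seq_along(keep_idx),
      rule = binary$rule[keep_idx],
      gene_low = binary$gene_low[keep_idx],
      gene_high = binary$gene_high[keep_idx],
      score = unname(score[keep_idx])
    )
  })
  dplyr::bind_rows(out)
}

# Round-robin over classes by rank until k distinct rules are selected;
# a rule already selected in either orientation is skipped.
select_top_rules <- function(ranked, k) {
  classes <- sort(unique(ranked$class))
  per_class <- split(ranked, ranked$class)
  per_class <- lapply(per_class, function(d) d[order(d$rank), ])
  sel <- ranked[0, c("rule", "gene_low", "gene_high")]
  max_rank <- max(ranked$rank)
  for (r in seq_len(max_rank)) {
    for (cl in classes) {
      d <- per_class[[cl]]
      if (r > nrow(d)) next
      cand <- d[r, c("rule", "gene_low", "gene_high")]
      rev <- paste0(cand$gene_high, "<", cand$gene_low)
      if (cand$rule %in% sel$rule || rev %in% sel$rule) next
      sel <- dplyr::bind_rows(sel, cand)
      if (nrow(sel) == k) return(sel)
    }
  }
  abort(paste0("Requested k = ", k, " exceeds the ", nrow(sel),
               " selectable candidate rules."))
}

#' Fit the naive Bayes layer on binarized rules
#'
#' Laplace-smoothed Bernoulli model:
#' `P(rule = 1 | class) = (count + alpha) / (n_class + 2 * alpha)`, which
#' keeps every conditional probability strictly inside (0, 1).
#'
#' @param binary Binarized rule tibble.
#' @param labels Label tibble.
#' @param alpha Positive smoothing pseudo-count (default 1).
#' @param priors `"uniform"` (default) or `"empirical"` class priors.
#' @return List with `classes`, `cond_prob` (rules x classes matrix) and
#'   `priors` (named, summing to 1).
#' @export
fit_naive_bayes <- function(binary, labels, alpha = 1,
                            priors = c("uniform", "empirical")) {
  priors <- match.arg(priors)
  if (!is.numeric(alpha) || alpha <= 0) abort("`alpha` must be positive.")
  b <- binary_values(binary)
  y <- align_labels(colnames(b), labels)
  classes <- sort(unique(y))
  if (any(table(y) == 0)) abort("Empty class.")
  cond <- vapply(classes, function(cl) {
    n_c <- sum(y == cl)
    (rowSums(b[, y == cl, drop = FALSE]) + alpha) / (n_c + 2 * alpha)
  }, numeric(nrow(b)))
  cond <- matrix(cond, nrow = nrow(b),
                 dimnames = list(rownames(b), classes))
  pri <- if (priors == "uniform") {
    rep(1 / length(classes), length(classes))
  } else {
    as.numeric(table(y)[classes] / length(y))
  }
  list(classes = classes, cond_prob = cond, priors = setNames(pri, classes))
}

# log-space NB posterior: classes x samples
nb_posterior <- function(b, cond_prob, priors, classes) {
  lp <- t(log(cond_prob)) %*% b + t(log1p(-cond_prob)) %*% (1 - b)
  lp <- lp + log(priors[classes])
  z <- apply(lp, 2, max)
  post <- exp(sweep(lp, 2, z, "-"))
  post <- sweep(post, 2, colSums(post), "/")
  rownames(post) <- classes
  post
}

balanced_accuracy_vec <- function(truth, pred) {
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) {
    mean(pred[truth == cl] == cl)
  }, numeric(1)))
}

# stratified fold ids, deterministic given seed
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Select the rule count by stratified cross-validation
#'
#' For each candidate `k`, rules are ranked inside each training fold,
#' the top `k` selected round-robin across classes, a naive Bayes layer
#' fitted, and held-out balanced accuracy recorded. The chosen `k*` is the
#' smallest `k` attaining the maximum mean CV balanced accuracy. Fully
#' deterministic given `seed`.
#'
#' @param expr Expression tibble (panel-resolved or resolvable).
#' @param labels Label tibble.
#' @param panel A `marker_panel`.
#' @param k_grid Integer vector of candidate rule counts (default 1:25).
#' @param folds Number of CV folds (default 5); silently reduced with a
#'   warning when a class has fewer samples than folds.
#' @param seed Integer seed for fold assignment.
#' @param alpha,priors Passed to [fit_naive_bayes()].
#' @return List: `k` (selected count), `cv_record` (tibble `k`,
#'   `mean_balanced_accuracy`, `sd_balanced_accuracy`), `folds`, `seed`.
#' @export
choose_rule_count <- function(expr, labels, panel = default_marker_panel(),
                              k_grid = 1:25, folds = 5, seed = 1L,
                              alpha = 1, priors = "uniform") {
  panel_expr <- resolve_panel(expr, panel)
  rules <- enumerate_pair_rules(panel)
  vals <- expr_values(panel_expr)
  b <- rule_matrix(vals, rules)
  y <- align_labels(colnames(b), labels)
  min_class <- min(table(y))
  if (folds < 2) abort("`folds` must be at least 2.")
  if (min_class < folds) {
    warn(paste0("Reducing folds from ", folds, " to ", min_class,
                " (smallest class size)."))
    folds <- min_class
  }
  if (folds < 2) abort("Smallest class has fewer than 2 samples.")
  k_grid <- sort(unique(as.integer(k_grid)))
  fold <- stratified_folds(y, folds, seed)
  binary_tbl <- function(cols) {
    dplyr::bind_cols(rules["rule"], rules["gene_low"], rules["gene_high"],
                     as_tibble(as.data.frame(b[, cols, drop = FALSE],
                                             check.names = FALSE)))
  }
  acc <- matrix(NA_real_, nrow = length(k_grid), ncol = folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    ranked <- rank_rules(binary_tbl(which(tr)),
                         tibble(sample_id = colnames(b)[tr], class = y[tr]))
    for (ki in seq_along(k_grid)) {
      sel <- select_top_rules(ranked, k_grid[ki])
      nb <- fit_naive_bayes(binary_tbl(which(tr))[match(sel$rule, rules$rule), ],
                            tibble(sample_id = colnames(b)[tr], class = y[tr]),
                            alpha = alpha, priors = priors)
      post <- nb_posterior(b[sel$rule, !tr, drop = FALSE],
                           nb$cond_prob, nb$priors, nb$classes)
      pred <- nb$classes[apply(post, 2, which.max)]
      acc[ki, f] <- balanced_accuracy_vec(y[!tr], pred)
    }
  }
  cv <- tibble(
    k = k_grid,
    mean_balanced_accuracy = rowMeans(acc),
    sd_balanced_accuracy = apply(acc, 1, sd)
  )
  best <- max(cv$mean_balanced_accuracy)
  k_star <- min(cv$k[cv$mean_balanced_accuracy >= best - 1e-12])
  list(k = k_star, cv_record = cv, folds = folds, seed = as.integer(seed))
}

#' Train the single-sample histology predictor
#'
#' End-to-end training: restrict the table to the marker panel, binarize
#' all candidate pair rules, select the rule count by stratified
#' cross-validation, rank rules on the full cohort, and fit the final
#' naive Bayes layer on all samples with the selected rules. The returned
#' model carries its full provenance (seed, k-grid, CV record, panel).
#'
#' @inheritParams choose_rule_count
#' @return An `ssp_model`.
#' @export
train_ssp <- function(expr, labels, panel = default_marker_panel(),
                      alpha = 1, k_grid = 1:25, folds = 5, seed = 1L,
                      priors = c("uniform", "empirical")) {
  priors <- match.arg(priors)
  expr <- as_expression(expr, expr_platform(expr))
  labels <- as_labels(labels)
  plat <- expr_platform(expr)
  common <- intersect(names(expr)[-1], labels$sample_id)
  if (length(common) == 0) abort("No labeled samples found in the table.")
  expr <- expr[, c("gene_id", common)]
  attr(expr, "platform") <- plat
  labels <- labels[labels$sample_id %in% common, ]
  tab <- table(labels$class)
  if (any(tab < 3)) {
    abort(paste0("Every class needs at least 3 samples; too small: ",
                 toString(names(tab)[tab < 3])))
  }
  panel_expr <- resolve_panel(expr, panel)
  cv <- choose_rule_count(panel_expr, labels, panel, k_grid = k_grid,
                          folds = folds, seed = seed, alpha = alpha,
                          priors = priors)
  rules <- enumerate_pair_rules(panel)
  binary <- binarize_rules(panel_expr, rules)
  ranked <- rank_rules(binary, labels)
  sel <- select_top_rules(ranked, cv$k)
  nb <- fit_naive_bayes(binary[match(sel$rule, rules$rule), ], labels,
                        alpha = alpha, priors = priors)
  structure(
    list(
      schema_version = "1.0",
      classes = nb$classes,
      rules = sel,
      cond_prob = nb$cond_prob[sel$rule, , drop = FALSE],
      priors = nb$priors,
      alpha = alpha,
      k = cv$k,
      k_grid = as.integer(sort(unique(k_grid))),
      cv_record = cv$cv_record,
      folds = cv$folds,
      seed = as.integer(seed),
      priors_mode = priors,
      n_train = length(common),
      panel = panel
    ),
    class = "ssp_model"
  )
}

#' @export
print.ssp_model <- function(x, ...) {
  cat("<ssp_model> ", length(x$classes), " classes (",
      toString(x$classes), "), ", x$k, " rules, trained on n = ",
      x$n_train, "\n", sep = "")
  cat("  CV: best mean balanced accuracy ",
      round(max(x$cv_record$mean_balanced_accuracy), 3),
      " at k = ", x$k, " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' @method tidy ssp_model
#' @export
tidy.ssp_model <- function(x, ...) {
  probs <- as_tibble(as.data.frame(x$cond_prob, check.names = FALSE))
  out <- dplyr::bind_cols(x$rules, probs)
  tidyr::pivot_longer(out, cols = dplyr::all_of(x$classes),
                      names_to = "class", values_to = "prob_fire")
}

#' @method glance ssp_model
#' @export
glance.ssp_model <- function(x, ...) {
  tibble(
    n_classes = length(x$classes),
    k = x$k,
    n_train = x$n_train,
    alpha = x$alpha,
    folds = x$folds,
    seed = x$seed,
    cv_balanced_accuracy = max(x$cv_record$mean_balanced_accuracy)
  )
}
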
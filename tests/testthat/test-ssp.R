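test_that("background correction applies the mean + 2 SD rule with a floor", {
  m <- matrix(c(100, 5, 8, 10, 12), ncol = 1,
              dimnames = list(c("E1", "E2", "NEG_A", "NEG_B", "NEG_C"), "s1"))
  expr <- toy_expr(m, "nanostring_counts")
  out <- background_correct(expr, negative_probes = c("NEG_A", "NEG_B", "NEG_C"))
  v <- expr_values(out)
  # negatives (8, 10, 12): b = 10 + 2*2 = 14
  expect_equal(v["E1", "s1"], 86)
  expect_equal(v["E2", "s1"], 1)  # 5 - 14 clamps to the floor
  expect_false("NEG_A" %in% rownames(v))

  # all-zero negatives: b = 0, values unchanged except flooring
  m0 <- matrix(c(100, 0, 0, 0, 0), ncol = 1,
               dimnames = list(c("E1", "E2", "NEG_A", "NEG_B", "NEG_C"), "s1"))
  out0 <- background_correct(toy_expr(m0, "nanostring_counts"),
                             negative_probes = c("NEG_A", "NEG_B", "NEG_C"))
  expect_equal(unname(expr_values(out0)[, 1]), c(100, 1))

  expect_error(background_correct(expr, negative_probes = character()),
               "negative-control")
  expect_error(background_correct(toy_expr(m, "rnaseq_fpkm"),
                                  negative_probes = "NEG_A"),
               "nanostring_counts")
})

test_that("rule enumeration covers all ordered pairs deterministically", {
  rules11 <- enumerate_pair_rules(default_marker_panel())
  expect_equal(nrow(rules11), 110)
  expect_true(all(c("KRT5<NAPSA", "NAPSA<KRT5") %in% rules11$rule))

  rules2 <- enumerate_pair_rules(marker_panel(list(A = "a", B = "b")))
  expect_equal(nrow(rules2), 2)
  expect_identical(rules2$rule, c("a<b", "b<a"))
})

test_that("binarization is strict, tie-zero, and monotone-transform invariant", {
  m <- matrix(c(5, 7, 7), ncol = 1, dimnames = list(c("a", "b", "c"), "s1"))
  rules <- tibble::tibble(rule = c("a<b", "b<a", "b<c", "c<b"),
                          gene_low = c("a", "b", "b", "c"),
                          gene_high = c("b", "a", "c", "b"))
  bin <- binarize_rules(toy_expr(m), rules)
  expect_equal(bin$s1, c(1, 0, 0, 0))  # ties (b, c) give 0 both ways

  # invariance under strictly increasing per-sample maps, random matrices
  full_rules <- enumerate_pair_rules(default_marker_panel())
  set.seed(101)
  for (i in 1:25) {
    expr <- random_expr()
    ref <- binarize_rules(expr, full_rules)
    for (mode in c("log_shift", "power", "affine_positive")) {
      tr <- platform_transform(expr, mode, seed = i)
      expect_identical(binary_values(binarize_rules(tr, full_rules)),
                       binary_values(ref))
    }
  }
})

test_that("rule ranking matches a brute-force frequency-gap oracle", {
  # 3 classes x 4 samples over 3 genes with hand-set orderings
  m <- cbind(
    matrix(c(1, 2, 3), 3, 4),  # class A: g1<g2<g3
    matrix(c(3, 1, 2), 3, 4),  # class B: g2<g3<g1
    matrix(c(2, 3, 1), 3, 4)   # class C: g3<g1<g2
  )
  dimnames(m) <- list(c("g1", "g2", "g3"), sprintf("s%02d", 1:12))
  labels <- tibble::tibble(sample_id = colnames(m),
                           class = rep(c("A", "B", "C"), each = 4))
  panel <- marker_panel(list(A = "g1", B = "g2", C = "g3"))
  rules <- enumerate_pair_rules(panel)
  bin <- binarize_rules(toy_expr(m), rules)
  ranked <- rank_rules(bin, labels)

  # independent oracle: direct frequency computation per rule and class
  b <- binary_values(bin)
  y <- labels$class
  for (cl in c("A", "B", "C")) {
    score <- abs(rowMeans(b[, y == cl, drop = FALSE]) -
                   rowMeans(b[, y != cl, drop = FALSE]))
    got <- ranked[ranked$class == cl, ]
    # every reported score matches the oracle for that rule
    expect_equal(got$score, unname(score[got$rule]))
    # descending order
    expect_true(all(diff(got$score) <= 1e-12))
    # no rule together with its reverse in one class list
    expect_false(any(paste0(got$gene_high, "<", got$gene_low) %in% got$rule))
  }

  # maximal-discrimination rule ranks first with score 1
  topA <- ranked[ranked$class == "A" & ranked$rank == 1, ]
  expect_equal(topA$score, 1)

  expect_error(
    rank_rules(bin, tibble::tibble(sample_id = colnames(m),
                                   class = c("A", rep("B", 11)))),
    "fewer than 2"
  )
})

test_that("naive Bayes conditional probabilities follow Laplace smoothing", {
  bin <- tibble::tibble(rule = "a<b", gene_low = "a", gene_high = "b",
                        s1 = 1, s2 = 1, s3 = 0, s4 = 0)
  labels <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                           class = c("c", "c", "d", "d"))
  nb <- fit_naive_bayes(bin, labels, alpha = 1)
  expect_equal(nb$cond_prob["a<b", "c"], 3 / 4)  # fires 2 of 2
  expect_equal(nb$cond_prob["a<b", "d"], 1 / 4)  # fires 0 of 2
  expect_equal(unname(nb$priors), c(0.5, 0.5))

  # smoothing limit: huge alpha pulls every probability to 1/2
  nb_inf <- fit_naive_bayes(bin, labels, alpha = 1e9)
  expect_equal(unname(nb_inf$cond_prob[1, ]), c(0.5, 0.5), tolerance = 1e-6)

  nb_emp <- fit_naive_bayes(bin, labels, alpha = 1, priors = "empirical")
  expect_equal(sum(nb_emp$priors), 1)
  expect_error(fit_naive_bayes(bin, labels, alpha = 0), "positive")
})

test_that("posteriors match the brute-force Bernoulli-product oracle", {
  sim <- simulate_histology_cohort(sim_config(seed = 9))
  corrected <- background_correct(sim$expression,
                                  probe_classes = sim$probe_classes)
  model <- train_ssp(corrected, sim$labels, k_grid = 1:6, seed = 2)
  expect_lte(model$k, 6)
  preds <- predict_ssp(model, corrected)
  sub <- resolve_panel(corrected, model$panel)
  b <- rule_matrix(expr_values(sub), model$rules)
  for (s in seq_len(ncol(b))) {
    oracle <- brute_force_posterior(b[, s], model$cond_prob, model$priors,
                                    model$classes)
    got <- unlist(preds[s, model$classes])
    expect_equal(unname(got), unname(oracle), tolerance = 1e-9)
  }
  # posteriors sum to 1 within 1e-9
  expect_true(all(abs(rowSums(as.matrix(preds[, model$classes])) - 1) < 1e-9))
})

test_that("rule-count selection is deterministic and finds the single informative rule", {
  toy <- separable_two_class(6)
  cv <- choose_rule_count(toy$expr, toy$labels, toy$panel, k_grid = 1:3,
                          folds = 3, seed = 7)
  # exactly one informative rule (g1 vs g2): k* = 1 beats or ties all k
  expect_equal(cv$k, 1)
  expect_equal(max(cv$cv_record$mean_balanced_accuracy),
               cv$cv_record$mean_balanced_accuracy[cv$cv_record$k == 1])
  expect_equal(cv$cv_record$mean_balanced_accuracy[1], 1.0)

  cv2 <- choose_rule_count(toy$expr, toy$labels, toy$panel, k_grid = 1:3,
                           folds = 3, seed = 7)
  expect_identical(cv$cv_record, cv2$cv_record)

  expect_error(choose_rule_count(toy$expr, toy$labels, toy$panel,
                                 k_grid = 1:50, folds = 3, seed = 7),
               "exceeds")
  expect_warning(choose_rule_count(toy$expr, toy$labels, toy$panel,
                                   k_grid = 1:2, folds = 10, seed = 7),
                 "Reducing folds")
})

test_that("training is seed-deterministic and rejects tiny classes", {
  sim <- simulate_histology_cohort(sim_config(seed = 5))
  m1 <- train_ssp(sim$expression, sim$labels, k_grid = 1:6, seed = 42)
  m2 <- train_ssp(sim$expression, sim$labels, k_grid = 1:6, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_ssp_model(m1, f1)
  write_ssp_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))

  bad_labels <- sim$labels
  bad_labels$class[1] <- "Solo"
  expect_error(train_ssp(sim$expression, bad_labels), "at least 3")
})

test_that("a trained model recovers generator truth with high reclassification accuracy", {
  sim <- simulate_histology_cohort(sim_config(seed = 13))
  corrected <- background_correct(sim$expression,
                                  probe_classes = sim$probe_classes)
  model <- train_ssp(corrected, sim$labels, k_grid = 1:15, seed = 13)
  ev <- score_predictions(predict_ssp(model, corrected), sim$labels)
  expect_gte(ev$balanced_accuracy, 0.95)

  # a sample with all SqCC markers above the rest is called SqCC confidently
  genes <- panel_genes(default_marker_panel())
  sq <- ifelse(genes %in% default_marker_panel()$classes$SqCC, 5000, 10)
  m <- matrix(sq, ncol = 1, dimnames = list(genes, "probe_case"))
  p <- predict_ssp(model, toy_expr(m))
  expect_identical(p$predicted_class, "SqCC")
  expect_gt(p$SqCC, 0.9)
})

test_that("predictions honor the single-sample contract and rank invariance", {
  sim <- simulate_histology_cohort(sim_config(seed = 21))
  model <- train_ssp(sim$expression, sim$labels, k_grid = 1:6, seed = 21)
  expr <- sim$expression
  all_preds <- predict_ssp(model, expr)

  # column deletion: scoring sample 5 alone gives the same posterior
  one <- expr[, c(1, 6)]
  p_one <- predict_ssp(model, one)
  expect_equal(as.data.frame(p_one), as.data.frame(all_preds[5, ]),
               tolerance = 1e-12, ignore_attr = TRUE)

  # duplicated column: both copies identical
  dup <- expr[, c(1, 2, 2)]
  names(dup)[3] <- "copy"
  p_dup <- predict_ssp(model, dup)
  expect_equal(unlist(p_dup[1, model$classes]), unlist(p_dup[2, model$classes]))

  # strictly increasing per-sample transforms leave predictions unchanged
  for (mode in c("log_shift", "power", "affine_positive")) {
    tr <- platform_transform(expr, mode, seed = 33)
    p_tr <- predict_ssp(model, tr)
    expect_equal(as.data.frame(p_tr), as.data.frame(all_preds),
                 tolerance = 1e-12)
  }
  # explicit cube transform
  m <- expr_values(expr)^3
  p_cube <- predict_ssp(model, toy_expr(m))
  expect_equal(as.data.frame(p_cube), as.data.frame(all_preds),
               tolerance = 1e-12)
})
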
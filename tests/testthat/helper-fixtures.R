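# Fixtures built in code: tiny expression tables, RCC file text, toy panels.

tiny_panel <- function() {
  marker_panel(
    classes = list(X = c("g1", "g2"), Y = c("g3")),
    aliases = list(g1 = "g1_alias")
  )
}

# deterministic small expression tibble, genes x samples
toy_expr <- function(m, platform = "unknown") {
  as_expression(
    dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)),
                     tibble::as_tibble(as.data.frame(m, check.names = FALSE))),
    platform
  )
}

# Two-class, perfectly separable toy cohort over 3 genes: class X samples
# always order g1 < g2, class Y the reverse, g3 always on top.
separable_two_class <- function(n_per_class = 6) {
  ids <- sprintf("T%02d", seq_len(2 * n_per_class))
  m <- matrix(0, nrow = 3, ncol = 2 * n_per_class,
              dimnames = list(c("g1", "g2", "g3"), ids))
  m["g1", ] <- rep(c(1, 3), each = n_per_class)
  m["g2", ] <- rep(c(3, 1), each = n_per_class)
  m["g3", ] <- 5
  labels <- tibble::tibble(sample_id = ids,
                           class = rep(c("X", "Y"), each = n_per_class))
  list(expr = toy_expr(m), labels = labels,
       panel = marker_panel(list(X = c("g1", "g2"), Y = "g3")))
}

write_rcc <- function(path, sample_id, probes, counts, classes,
                      crlf = FALSE, trailing_blank = FALSE,
                      drop_code_summary = FALSE) {
  lines <- c(
    "<Header>", "FileVersion,1.7", "SoftwareVersion,4.0.0.3", "</Header>",
    "<Sample_Attributes>", paste0("ID,", sample_id), "Owner,lab",
    "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,280", "</Lane_Attributes>"
  )
  if (!drop_code_summary) {
    lines <- c(lines,
               "<Code_Summary>",
               "CodeClass,Name,Accession,Count",
               paste(classes, probes, paste0("NM_", seq_along(probes)),
                     counts, sep = ","),
               "</Code_Summary>")
  }
  if (trailing_blank) lines <- c(lines, "", "")
  eol <- if (crlf) "\r\n" else "\n"
  writeLines(lines, path, sep = eol)
  invisible(path)
}

default_rcc_fixture <- function(dir, stem = "sample1", sample_id = "S_A",
                                counts = c(523, 12, 8, 15, 610, 9)) {
  path <- file.path(dir, paste0(stem, ".RCC"))
  write_rcc(path, sample_id,
            probes = c("CHGA", "NEG_A", "NEG_B", "NEG_C", "POS_A", "KRT5"),
            counts = counts,
            classes = c("Endogenous", "Negative", "Negative", "Negative",
                        "Positive", "Endogenous"))
  path
}

# Independent brute-force naive Bayes posterior oracle (direct Bernoulli
# product, no log space) for models with few rules.
brute_force_posterior <- function(x, cond_prob, priors, classes) {
  lik <- vapply(classes, function(cl) {
    p <- cond_prob[, cl]
    prod(ifelse(x == 1, p, 1 - p)) * priors[[cl]]
  }, numeric(1))
  lik / sum(lik)
}

# Independent pairwise-count AUC oracle.
brute_force_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

random_expr <- function(n_genes = 11, n_samples = 8,
                        genes = panel_genes(default_marker_panel())) {
  m <- matrix(runif(n_genes * n_samples, 0, 1000), nrow = n_genes,
              dimnames = list(genes[seq_len(n_genes)],
                              sprintf("R%02d", seq_len(n_samples))))
  toy_expr(m)
}
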
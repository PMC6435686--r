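#' Fusion probe panels
#'
#' A fusion probe panel is a tibble describing the role of every probe:
#' `gene`, `probe_id`, `role` in `five_prime`, `three_prime`, `junction`,
#' `exon_group`, and `group` naming the junction variant (e.g.
#' `EML4-ALK_E13:A20`, `exon14_skipping`) or the MET exon group
#' (`exons_3_4`, `exon_14`, `exons_20_21`). Probe ids must be unique
#' within a gene and role sets disjoint.
#'
#' @param x A data frame with columns `gene`, `probe_id`, `role`, `group`.
#' @return A validated `fusion_panel` tibble.
#' @export
fusion_panel <- function(x) {
  if (!is.data.frame(x)) abort("`x` must be a data frame.")
  x <- as_tibble(x)
  need <- c("gene", "probe_id", "role", "group")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("Panel missing columns: ", toString(miss)))
  ok_roles <- c("five_prime", "three_prime", "junction", "exon_group")
  bad <- setdiff(unique(x$role), ok_roles)
  if (length(bad)) abort(paste0("Unknown probe roles: ", toString(bad)))
  dup <- x |>
    dplyr::count(.data$gene, .data$probe_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("Probe assigned multiple roles within a gene: ",
                 toString(paste0(dup$gene, "/", dup$probe_id))))
  }
  class(x) <- c("fusion_panel", class(x))
  x
}

#' Default fusion probe panel
#'
#' Synthetic panel definition covering the assay's fusion targets: ALK,
#' RET, ROS1 and NRG1/NTRK1 with 5'/3' probe groups and variant junction
#' probes, plus MET with exon-group probes (exons 3-4, exon 14, exons
#' 20-21) and the exon 13-15 skip-junction probe. Probe ids are synthetic
#' stand-ins for a real codeset; the structure (roles and groups) is what
#' the calling logic consumes.
#'
#' @return A `fusion_panel`.
#' @export
default_fusion_panel <- function() {
  entry <- function(gene, role, group, ids) {
    tibble(gene = gene, probe_id = ids, role = role, group = group)
  }
  fusion_panel(dplyr::bind_rows(
    entry("ALK", "five_prime", NA, paste0("ALK_5p_", 1:3)),
    entry("ALK", "three_prime", NA, paste0("ALK_3p_", 1:3)),
    entry("ALK", "junction", "EML4-ALK_E6B:A20", "ALK_jx_E6B_A20"),
    entry("ALK", "junction", "EML4-ALK_E13:A20", "ALK_jx_E13_A20"),
    entry("ALK", "junction", "EML4-ALK_E20:A20", "ALK_jx_E20_A20"),
    entry("RET", "five_prime", NA, paste0("RET_5p_", 1:3)),
    entry("RET", "three_prime", NA, paste0("RET_3p_", 1:3)),
    entry("RET", "junction", "KIF5B-RET_K15:R12", "RET_jx_K15_R12"),
    entry("RET", "junction", "KIF5B-RET_K16:R12", "RET_jx_K16_R12"),
    entry("RET", "junction", "CCDC6-RET_C1:R12", "RET_jx_C1_R12"),
    entry("ROS1", "five_prime", NA, paste0("ROS1_5p_", 1:3)),
    entry("ROS1", "three_prime", NA, paste0("ROS1_3p_", 1:3)),
    entry("ROS1", "junction", "CD74-ROS1_C6:R34", "ROS1_jx_C6_R34"),
    entry("ROS1", "junction", "SLC34A2-ROS1_S4:R32", "ROS1_jx_S4_R32"),
    entry("NRG1", "five_prime", NA, paste0("NRG1_5p_", 1:3)),
    entry("NRG1", "three_prime", NA, paste0("NRG1_3p_", 1:3)),
    entry("NRG1", "junction", "CD74-NRG1_C8:N6", "NRG1_jx_C8_N6"),
    entry("NTRK1", "five_prime", NA, paste0("NTRK1_5p_", 1:3)),
    entry("NTRK1", "three_prime", NA, paste0("NTRK1_3p_", 1:3)),
    entry("NTRK1", "junction", "TPM3-NTRK1_T7:N10", "NTRK1_jx_T7_N10"),
    entry("MET", "exon_group", "exons_3_4", c("MET_ex3", "MET_ex4")),
    entry("MET", "exon_group", "exon_14", "MET_ex14"),
    entry("MET", "exon_group", "exons_20_21", c("MET_ex20", "MET_ex21")),
    entry("MET", "junction", "exon14_skipping", "MET_jx_ex13_15")
  ))
}

#' Read or write a fusion panel definition (YAML/JSON)
#'
#' @param path File path.
#' @return A `fusion_panel` or `path` invisibly.
#' @export
read_fusion_panel <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- purrr::map_dfr(raw, as_tibble)
  rows$group <- ifelse(rows$group %in% c("", "NA"), NA_character_, rows$group)
  fusion_panel(rows)
}

#' @rdname read_fusion_panel
#' @param panel A `fusion_panel`.
#' @export
write_fusion_panel <- function(panel, path) {
  df <- as.data.frame(panel)
  df$group[is.na(df$group)] <- ""
  yaml::write_yaml(purrr::transpose(df), path)
  invisible(path)
}

#' Default calling thresholds
#'
#' The quadrant geometry of the calls is fixed; the numeric cutoffs are
#' configuration. `ratio_min` bounds the 3'/5' imbalance ratio,
#' `junction_min` the (background-corrected) junction probe count,
#' `flank_ratio_min` the MET flank/exon-14 ratio. QC requires total
#' endogenous counts of at least `total_count_min` and a positive-control
#' geometric mean of at least `poscon_min`.
#'
#' @param ratio_min,junction_min,flank_ratio_min,total_count_min,poscon_min
#'   Numeric cutoffs.
#' @return A named list of thresholds.
#' @export
fusion_thresholds <- function(ratio_min = 2, junction_min = 50,
                              flank_ratio_min = 2, total_count_min = 100,
                              poscon_min = 32) {
  list(ratio_min = ratio_min, junction_min = junction_min,
       flank_ratio_min = flank_ratio_min, total_count_min = total_count_min,
       poscon_min = poscon_min)
}

counts_vector <- function(sample_counts) {
  if (is.data.frame(sample_counts)) {
    if (!all(c("probe_id", "count") %in% names(sample_counts))) {
      abort("Sample counts need `probe_id` and `count` columns.")
    }
    setNames(as.numeric(sample_counts$count),
             as.character(sample_counts$probe_id))
  } else if (is.numeric(sample_counts) && !is.null(names(sample_counts))) {
    sample_counts
  } else {
    abort("Sample counts must be a (probe_id, count) data frame or named vector.")
  }
}

group_counts <- function(v, panel, gene_, role_, group_ = NULL) {
  sel <- panel$gene == gene_ & panel$role == role_
  if (!is.null(group_)) sel <- sel & !is.na(panel$group) & panel$group == group_
  ids <- panel$probe_id[sel]
  v[intersect(ids, names(v))]
}

#' 3'/5' probe imbalance ratio
#'
#' Mean of the gene's 3'-side probe counts divided by the mean of its
#' 5'-side probe counts. In a fusion transcript driven by a partner
#' promoter the kinase-side (3') probes report elevated counts, so the
#' ratio rises above 1. Counts should be background-corrected with a
#' floor of at least 1 so the denominator is never 0.
#'
#' @param sample_counts One sample's probe counts: a tibble with
#'   `probe_id`, `count` or a named numeric vector.
#' @param panel A `fusion_panel`.
#' @param gene Gene symbol with 5' and 3' probe groups in the panel.
#' @param five_prime_trim Trim fraction for the 5' mean (`mean(trim = )`);
#'   0 (default) uses the plain mean. A small trim guards against a single
#'   5' probe with high background.
#' @return Non-negative ratio.
#' @export
compute_imbalance_ratio <- function(sample_counts, panel, gene,
                                    five_prime_trim = 0) {
  v <- counts_vector(sample_counts)
  p3 <- group_counts(v, panel, gene, "three_prime")
  p5 <- group_counts(v, panel, gene, "five_prime")
  if (length(p3) == 0) abort(paste0("No 3' probes for ", gene, " in the counts."))
  if (length(p5) == 0) abort(paste0("No 5' probes for ", gene, " in the counts."))
  mean(p3) / mean(p5, trim = five_prime_trim)
}

#' Conclusiveness QC for one sample
#'
#' Samples with degraded RNA give unreliable negative results, so calls
#' are gated: a sample fails QC (all its calls become inconclusive) when
#' its total endogenous counts fall below `total_count_min` or the
#' geometric mean of its positive-control probes falls below
#' `poscon_min`. Values exactly at a threshold pass.
#'
#' @inheritParams compute_imbalance_ratio
#' @param positive_control_ids Probe ids of the positive controls.
#' @param total_count_min,poscon_min QC cutoffs (see
#'   [fusion_thresholds()]).
#' @return Tibble with `pass` (logical) and `reason` (string, `"ok"` on
#'   pass).
#' @export
qc_conclusive <- function(sample_counts, positive_control_ids = character(),
                          total_count_min = 100, poscon_min = 32) {
  v <- counts_vector(sample_counts)
  endo <- v[setdiff(names(v), positive_control_ids)]
  reasons <- character()
  if (sum(endo) < total_count_min) reasons <- c(reasons, "low_total_counts")
  pc <- v[intersect(positive_control_ids, names(v))]
  if (length(pc)) {
    gm <- if (any(pc <= 0)) 0 else exp(mean(log(pc)))
    if (gm < poscon_min) reasons <- c(reasons, "low_positive_controls")
  }
  tibble(pass = length(reasons) == 0,
         reason = if (length(reasons)) paste(reasons, collapse = ";") else "ok")
}

#' Call a gene fusion for one sample
#'
#' Upper-right-quadrant rule: a sample is fusion positive for a gene when
#' its 3'/5' imbalance ratio reaches `ratio_min` AND its best
#' variant-junction probe count reaches `junction_min`. The best variant
#' is the junction probe with the highest count (ties break to panel
#' order). With a failed QC the status is `inconclusive`; otherwise
#' `negative`, with the measured ratio and counts reported either way.
#'
#' @inheritParams compute_imbalance_ratio
#' @param thresholds See [fusion_thresholds()].
#' @param qc_pass Logical QC verdict for the sample (from
#'   [qc_conclusive()]); default `TRUE`.
#' @param qc_reason QC reason string.
#' @return One-row tibble: `gene`, `status`, `best_variant`,
#'   `imbalance_ratio`, `max_junction_count`, `qc_flag`, `qc_reason`.
#' @export
call_gene_fusion <- function(sample_counts, panel, gene,
                             thresholds = fusion_thresholds(),
                             qc_pass = TRUE, qc_reason = "ok",
                             five_prime_trim = 0) {
  v <- counts_vector(sample_counts)
  ratio <- compute_imbalance_ratio(v, panel, gene, five_prime_trim)
  jx <- panel[panel$gene == gene & panel$role == "junction", ]
  jx_counts <- setNames(rep(0, nrow(jx)), jx$group)
  present <- intersect(jx$probe_id, names(v))
  jx_counts[jx$group[match(present, jx$probe_id)]] <- v[present]
  max_j <- if (length(jx_counts)) max(jx_counts) else 0
  best <- if (length(jx_counts)) names(jx_counts)[which.max(jx_counts)] else NA_character_
  if (!qc_pass) {
    status <- "inconclusive"
    best_variant <- NA_character_
  } else if (ratio >= thresholds$ratio_min && max_j >= thresholds$junction_min) {
    status <- "positive"
    best_variant <- best
  } else {
    status <- "negative"
    best_variant <- NA_character_
  }
  tibble(gene = gene, status = status, best_variant = best_variant,
         imbalance_ratio = ratio, max_junction_count = max_j,
         qc_flag = if (qc_pass) "pass" else "fail", qc_reason = qc_reason)
}

#' Call MET exon 14 skipping for one sample
#'
#' x-axis: mean of the flanking exon probes (exons 3-4 and 20-21) divided
#' by the exon-14 probe mean (denominator floored at `floor`); y-axis: the
#' exon 13-15 skip-junction probe count. Positive when `x >=
#' flank_ratio_min` and `y >= junction_min` (upper right quadrant), with
#' `best_variant = "exon14_skipping"`.
#'
#' @inheritParams call_gene_fusion
#' @param floor Denominator floor (default 1).
#' @return One-row tibble as in [call_gene_fusion()], `gene = "MET"`.
#' @export
call_met_exon14 <- function(sample_counts, panel,
                            thresholds = fusion_thresholds(),
                            qc_pass = TRUE, qc_reason = "ok", floor = 1) {
  v <- counts_vector(sample_counts)
  flank <- c(group_counts(v, panel, "MET", "exon_group", "exons_3_4"),
             group_counts(v, panel, "MET", "exon_group", "exons_20_21"))
  ex14 <- group_counts(v, panel, "MET", "exon_group", "exon_14")
  jx <- group_counts(v, panel, "MET", "junction", "exon14_skipping")
  if (length(flank) == 0 || length(ex14) == 0 || length(jx) == 0) {
    abort("MET panel entry needs exons_3_4/exons_20_21, exon_14 and the skip-junction probe.")
  }
  x <- mean(flank) / max(mean(ex14), floor)
  y <- max(jx)
  if (!qc_pass) {
    status <- "inconclusive"
    best_variant <- NA_character_
  } else if (x >= thresholds$flank_ratio_min && y >= thresholds$junction_min) {
    status <- "positive"
    best_variant <- "exon14_skipping"
  } else {
    status <- "negative"
    best_variant <- NA_character_
  }
  tibble(gene = "MET", status = status, best_variant = best_variant,
         imbalance_ratio = x, max_junction_count = y,
         qc_flag = if (qc_pass) "pass" else "fail", qc_reason = qc_reason)
}

#' Call fusions and MET exon 14 skipping across a cohort
#'
#' Batch driver: optionally background-corrects raw NanoString counts
#' (when negative-control probes are identifiable), runs per-sample QC
#' against the positive controls, then calls every panel gene with 5'/3'
#' probe groups through the imbalance + junction rule and MET through the
#' exon-skip rule. Calls are per-gene independent, so one sample may be
#' positive for several genes.
#'
#' @param counts Expression tibble of probe counts (probes x samples).
#' @param panel A `fusion_panel`.
#' @param probe_classes Optional tibble (`probe_id`, `code_class`) used to
#'   find Negative (background) and Positive (QC) control probes.
#' @param thresholds See [fusion_thresholds()].
#' @param qc Run the conclusiveness gate (default `TRUE`).
#' @param five_prime_trim Passed to [compute_imbalance_ratio()].
#' @return Tibble of calls, one row per sample x gene.
#' @export
call_fusions <- function(counts, panel = default_fusion_panel(),
                         probe_classes = NULL,
                         thresholds = fusion_thresholds(), qc = TRUE,
                         five_prime_trim = 0) {
  counts <- as_expression(counts, expr_platform(counts))
  pos_ids <- neg_ids <- character()
  if (!is.null(probe_classes)) {
    pos_ids <- probe_classes$probe_id[probe_classes$code_class == "Positive"]
    neg_ids <- probe_classes$probe_id[probe_classes$code_class == "Negative"]
  }
  raw <- expr_values(counts)
  corrected <- if (length(neg_ids) && expr_platform(counts) == "nanostring_counts") {
    expr_values(background_correct(counts, negative_probes = neg_ids))
  } else {
    pmax(raw[setdiff(rownames(raw), neg_ids), , drop = FALSE], 1)
  }
  imbalance_genes <- unique(panel$gene[panel$role %in% c("five_prime", "three_prime")])
  has_met <- any(panel$gene == "MET" & panel$role == "exon_group")
  out <- vector("list", ncol(raw))
  for (s in seq_len(ncol(raw))) {
    v_raw <- raw[, s]
    v <- corrected[, s]
    if (qc) {
      verdict <- qc_conclusive(v_raw, pos_ids,
                               total_count_min = thresholds$total_count_min,
                               poscon_min = thresholds$poscon_min)
    } else {
      verdict <- tibble(pass = TRUE, reason = "ok")
    }
    rows <- lapply(imbalance_genes, function(g) {
      call_gene_fusion(v, panel, g, thresholds, verdict$pass, verdict$reason,
                       five_prime_trim)
    })
    if (has_met) {
      rows <- c(rows, list(call_met_exon14(v, panel, thresholds,
                                           verdict$pass, verdict$reason)))
    }
    out[[s]] <- dplyr::bind_cols(tibble(sample_id = colnames(raw)[s]),
                                 dplyr::bind_rows(rows))
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("fusion_calls", class(res))
  res
}

#' Quadrant plot of fusion calls
#'
#' Scatter of the imbalance (or MET flank) ratio against the best junction
#' probe count per sample, with the decision thresholds drawn; positives
#' sit in the upper right quadrant.
#'
#' @param object A `fusion_calls` tibble.
#' @param thresholds See [fusion_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fusion_calls
#' @export
autoplot.fusion_calls <- function(object, thresholds = fusion_thresholds(), ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$imbalance_ratio,
                               y = .data$max_junction_count + 1,
                               colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = thresholds$ratio_min, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$junction_min + 1,
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~gene, scales = "free") +
    ggplot2::labs(x = "3'/5' (or flank/exon-14) ratio",
                  y = "Best junction probe count + 1") +
    ggplot2::theme_minimal()
}
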
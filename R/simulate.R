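#' Simulation configuration for histology cohorts
#'
#' Defaults emulate the structure of a 68-sample NanoString development
#' cohort: 29 AC, 28 SqCC and 11 LCNEC samples over the 11 marker genes,
#' with negative-binomial counts. A sample's own-class markers draw from
#' mean `marker_mean_on` (2000), all other markers from `marker_mean_off`
#' (50), both with size (inverse dispersion) `dispersion` (2) for
#' FFPE-like overdispersion. `marker_null_fraction` adds large-cell-like
#' "marker null" samples whose 11 genes all draw from the off mean.
#'
#' @param n_per_class Named integer vector of class sizes.
#' @param marker_mean_on,marker_mean_off Positive NB means for own-class
#'   and other-class markers.
#' @param dispersion Positive NB size parameter.
#' @param negative_control_mean Mean of the simulated negative-control
#'   probes.
#' @param positive_control_mean Mean of the simulated positive-control
#'   probes.
#' @param marker_null_fraction Fraction of samples (per class) re-drawn as
#'   marker-null; such samples keep label `"LCC"` in the truth record.
#' @param seed Integer seed.
#' @return A validated config list.
#' @export
sim_config <- function(n_per_class = c(AC = 29, SqCC = 28, LCNEC = 11),
                       marker_mean_on = 2000, marker_mean_off = 50,
                       dispersion = 2, negative_control_mean = 10,
                       positive_control_mean = 500,
                       marker_null_fraction = 0, seed = 1L) {
  stopifnot(all(n_per_class >= 0), !is.null(names(n_per_class)),
            marker_mean_on > 0, marker_mean_off > 0, dispersion > 0,
            negative_control_mean > 0, positive_control_mean > 0,
            marker_null_fraction >= 0, marker_null_fraction <= 1)
  list(n_per_class = n_per_class, marker_mean_on = marker_mean_on,
       marker_mean_off = marker_mean_off, dispersion = dispersion,
       negative_control_mean = negative_control_mean,
       positive_control_mean = positive_control_mean,
       marker_null_fraction = marker_null_fraction,
       seed = as.integer(seed))
}

#' Simulate a marker-gene histology cohort with known truth
#'
#' Draws a NanoString-like count matrix over the marker panel plus
#' negative/positive control probes, with class-specific marker elevation
#' as configured. Deterministic given the config seed.
#'
#' @param config From [sim_config()].
#' @param panel A `marker_panel` whose classes are drawn; classes in
#'   `config$n_per_class` must exist in the panel.
#' @return List: `expression` (platform `"nanostring_counts"`, including
#'   control probes), `labels`, `truth` (with `marker_null` flag) and
#'   `probe_classes`.
#' @export
simulate_histology_cohort <- function(config = sim_config(),
                                      panel = default_marker_panel()) {
  unknown <- setdiff(names(config$n_per_class), names(panel$classes))
  if (length(unknown)) {
    abort(paste0("Classes not in the panel: ", toString(unknown)))
  }
  genes <- panel_genes(panel)
  n_tot <- sum(config$n_per_class)
  classes <- rep(names(config$n_per_class), config$n_per_class)
  sample_ids <- sprintf("S%03d", seq_len(n_tot))
  negs <- paste0("NEG_", LETTERS[1:6])
  poss <- paste0("POS_", LETTERS[1:6])
  withr::with_seed(config$seed, {
    null_flag <- runif(n_tot) < config$marker_null_fraction
    m <- matrix(0, nrow = length(genes), ncol = n_tot,
                dimnames = list(genes, sample_ids))
    for (j in seq_len(n_tot)) {
      on_genes <- if (null_flag[j]) character() else panel$classes[[classes[j]]]
      mu <- ifelse(genes %in% on_genes, config$marker_mean_on,
                   config$marker_mean_off)
      m[, j] <- rnbinom(length(genes), size = config$dispersion, mu = mu)
    }
    ctrl <- rbind(
      matrix(rnbinom(length(negs) * n_tot, size = config$dispersion,
                     mu = config$negative_control_mean),
             nrow = length(negs), dimnames = list(negs, sample_ids)),
      matrix(rnbinom(length(poss) * n_tot, size = config$dispersion,
                     mu = config$positive_control_mean),
             nrow = length(poss), dimnames = list(poss, sample_ids))
    )
  })
  labels <- tibble(sample_id = sample_ids,
                   class = ifelse(null_flag, "LCC", classes))
  list(
    expression = expr_from_matrix(rbind(m, ctrl), "nanostring_counts"),
    labels = labels,
    truth = dplyr::bind_cols(labels, tibble(marker_null = null_flag)),
    probe_classes = tibble(
      probe_id = c(genes, negs, poss),
      code_class = c(rep("Endogenous", length(genes)),
                     rep("Negative", length(negs)),
                     rep("Positive", length(poss)))
    )
  )
}

#' Simulation configuration for fusion probe counts
#'
#' Defaults emulate a 131-sample fusion-tested cohort with event counts
#' matching the assay's observed prevalence: 5 EML4-ALK (1 E6B:A20, 3
#' E13:A20, 1 E20:A20), 4 KIF5B-RET (2 K15:R12, 2 K16:R12), 2 CD74-NRG1
#' and 3 MET exon 14 skipping events. Fusion-negative samples share a
#' baseline mean across 5' and 3' probes with junction probes at
#' background; positives multiply the 3' mean by `three_prime_fold` and
#' elevate the true variant's junction probe to `junction_mean`; MET-skip
#' positives suppress the exon-14 probe by `met_exon14_suppression` and
#' elevate the skip junction. Effect sizes default to the strong signals
#' seen in real positives (order-of-magnitude 3' imbalance, junction
#' probes in the thousands of counts).
#'
#' @param n_samples Cohort size.
#' @param n_positive Named integer vector: junction-variant name (or
#'   `"MET_exon14"`) -> number of positive samples.
#' @param baseline_mean NB mean of 5'/3'/exon probes in negatives.
#' @param junction_background_mean NB mean of junction probes in
#'   negatives.
#' @param three_prime_fold Fold-change applied to 3' probe means in
#'   fusion positives.
#' @param junction_mean NB mean of the true variant's junction probe in
#'   positives.
#' @param met_exon14_suppression Multiplier on the exon-14 probe mean in
#'   MET-skip positives.
#' @param dispersion,negative_control_mean,positive_control_mean,seed As
#'   in [sim_config()].
#' @return A validated config list.
#' @export
fusion_sim_config <- function(n_samples = 131,
                              n_positive = c("EML4-ALK_E6B:A20" = 1,
                                             "EML4-ALK_E13:A20" = 3,
                                             "EML4-ALK_E20:A20" = 1,
                                             "KIF5B-RET_K15:R12" = 2,
                                             "KIF5B-RET_K16:R12" = 2,
                                             "CD74-NRG1_C8:N6" = 2,
                                             "MET_exon14" = 3),
                              baseline_mean = 400,
                              junction_background_mean = 10,
                              three_prime_fold = 15,
                              junction_mean = 6000,
                              met_exon14_suppression = 0.05,
                              dispersion = 2,
                              negative_control_mean = 10,
                              positive_control_mean = 500,
                              seed = 1L) {
  stopifnot(n_samples >= sum(n_positive), all(n_positive >= 0),
            baseline_mean > 0, junction_background_mean > 0,
            three_prime_fold > 0, junction_mean > 0,
            met_exon14_suppression > 0, dispersion > 0)
  list(n_samples = as.integer(n_samples), n_positive = n_positive,
       baseline_mean = baseline_mean,
       junction_background_mean = junction_background_mean,
       three_prime_fold = three_prime_fold, junction_mean = junction_mean,
       met_exon14_suppression = met_exon14_suppression,
       dispersion = dispersion,
       negative_control_mean = negative_control_mean,
       positive_control_mean = positive_control_mean,
       seed = as.integer(seed))
}

#' Simulate fusion probe counts with known truth
#'
#' @param config From [fusion_sim_config()].
#' @param panel A `fusion_panel`; variant names in `config$n_positive`
#'   must exist as junction groups (except `"MET_exon14"`, which drives
#'   the MET exon-skip block).
#' @return List: `counts` (probe expression tibble incl. controls),
#'   `probe_classes`, `truth` (one row per positive: `sample_id`, `gene`,
#'   `variant`), `panel`.
#' @export
simulate_fusion_probes <- function(config = fusion_sim_config(),
                                   panel = default_fusion_panel()) {
  variants <- names(config$n_positive)
  known <- c(panel$group[panel$role == "junction"], "MET_exon14")
  unknown <- setdiff(variants, known)
  if (length(unknown)) {
    abort(paste0("Variants not in the panel: ", toString(unknown)))
  }
  n <- config$n_samples
  sample_ids <- sprintf("F%03d", seq_len(n))
  probes <- panel$probe_id
  negs <- paste0("NEG_", LETTERS[1:6])
  poss <- paste0("POS_", LETTERS[1:6])
  # baseline NB mean per probe
  base_mu <- ifelse(panel$role == "junction",
                    config$junction_background_mean, config$baseline_mean)
  names(base_mu) <- probes
  n_events <- sum(config$n_positive)
  withr::with_seed(config$seed, {
    event_samples <- sample(sample_ids, n_events)
    truth <- tibble(
      sample_id = event_samples,
      variant = rep(variants, config$n_positive)
    )
    truth$gene <- ifelse(
      truth$variant == "MET_exon14", "MET",
      panel$gene[match(truth$variant, panel$group)]
    )
    truth$variant <- ifelse(truth$variant == "MET_exon14",
                            "exon14_skipping", truth$variant)
    m <- matrix(0, nrow = length(probes), ncol = n,
                dimnames = list(probes, sample_ids))
    for (j in seq_len(n)) {
      mu <- base_mu
      hit <- truth[truth$sample_id == sample_ids[j], ]
      if (nrow(hit)) {
        g <- hit$gene
        if (g == "MET") {
          mu[panel$probe_id[panel$gene == "MET" & !is.na(panel$group) &
                              panel$group == "exon_14"]] <-
            config$baseline_mean * config$met_exon14_suppression
          mu[panel$probe_id[panel$gene == "MET" & panel$role == "junction"]] <-
            config$junction_mean
        } else {
          mu[panel$probe_id[panel$gene == g & panel$role == "three_prime"]] <-
            config$baseline_mean * config$three_prime_fold
          mu[panel$probe_id[panel$gene == g & !is.na(panel$group) &
                              panel$group == hit$variant]] <- config$junction_mean
        }
      }
      m[, j] <- rnbinom(length(probes), size = config$dispersion, mu = mu)
    }
    ctrl <- rbind(
      matrix(rnbinom(length(negs) * n, size = config$dispersion,
                     mu = config$negative_control_mean),
             nrow = length(negs), dimnames = list(negs, sample_ids)),
      matrix(rnbinom(length(poss) * n, size = config$dispersion,
                     mu = config$positive_control_mean),
             nrow = length(poss), dimnames = list(poss, sample_ids))
    )
  })
  list(
    counts = expr_from_matrix(rbind(m, ctrl), "nanostring_counts"),
    probe_classes = tibble(
      probe_id = c(probes, negs, poss),
      code_class = c(rep("Endogenous", length(probes)),
                     rep("Negative", length(negs)),
                     rep("Positive", length(poss)))
    ),
    truth = truth[, c("sample_id", "gene", "variant")],
    panel = panel
  )
}

#' Platform-shift transforms for robustness testing
#'
#' Re-expresses a matrix the way another measurement platform might:
#' `log_shift`, `power` and `affine_positive` apply a strictly increasing
#' map per sample (per-sample parameters drawn from the seed unless given),
#' under which rank-based predictions must be invariant. `gene_scale`
#' multiplies each gene by its own positive factor — this is NOT
#' rank-preserving within a sample (the FPKM-style length-bias failure
#' mode) and predictions may legitimately change.
#'
#' @param expr Expression tibble.
#' @param mode One of `"log_shift"`, `"power"`, `"affine_positive"`,
#'   `"gene_scale"`.
#' @param seed Seed for randomly drawn per-sample/per-gene parameters.
#' @param exponent Fixed exponent for `power` (must be > 0).
#' @param slope,intercept Fixed parameters for `affine_positive`
#'   (`slope > 0`, `intercept >= 0`).
#' @param factors Fixed per-gene factors for `gene_scale` (recycled; all 1
#'   is the identity).
#' @return A transformed expression tibble (platform tag `"unknown"`
#'   except for the identity cases).
#' @export
platform_transform <- function(expr,
                               mode = c("log_shift", "power",
                                        "affine_positive", "gene_scale"),
                               seed = 1L, exponent = NULL, slope = NULL,
                               intercept = NULL, factors = NULL) {
  mode <- match.arg(mode)
  expr <- as_expression(expr, expr_platform(expr))
  m <- expr_values(expr)
  ns <- ncol(m)
  out <- withr::with_seed(seed, {
    switch(mode,
      log_shift = {
        shift <- runif(ns, 1, 3)  # shift >= 1 keeps log values non-negative
        sweep_fun(m, function(x, j) log(x + shift[j]))
      },
      power = {
        if (!is.null(exponent) && exponent <= 0) {
          abort("`exponent` must be positive.")
        }
        p <- if (is.null(exponent)) runif(ns, 0.5, 2) else rep(exponent, ns)
        sweep_fun(m, function(x, j) x^p[j])
      },
      affine_positive = {
        if (!is.null(slope) && slope <= 0) abort("`slope` must be positive.")
        if (!is.null(intercept) && intercept < 0) {
          abort("`intercept` must be non-negative.")
        }
        a <- if (is.null(slope)) runif(ns, 0.5, 2) else rep(slope, ns)
        bb <- if (is.null(intercept)) runif(ns, 0, 10) else rep(intercept, ns)
        sweep_fun(m, function(x, j) a[j] * x + bb[j])
      },
      gene_scale = {
        f <- if (is.null(factors)) rlnorm(nrow(m), 0, 0.5) else
          rep_len(factors, nrow(m))
        m * f
      }
    )
  })
  expr_from_matrix(out, "unknown")
}

sweep_fun <- function(m, f) {
  for (j in seq_len(ncol(m))) m[, j] <- f(m[, j], j)
  m
}
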
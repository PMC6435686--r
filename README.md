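# nsclcssp

Single-sample histology prediction and fusion calling for non-small cell
lung cancer (NSCLC) expression panels.

Clinical NSCLC diagnostics must settle two questions from one small,
often degraded FFPE biopsy: the histological subtype — adenocarcinoma
(AC), squamous cell carcinoma (SqCC) or large-cell neuroendocrine
carcinoma (LCNEC) — and the presence of targetable fusion genes (ALK,
RET, ROS1, NRG1, NTRK1) or MET exon 14 skipping. `nsclcssp` provides the
analytics for a combined targeted-expression approach:

* a **single-sample predictor (SSP)** of histology built on 11
  immunomarker genes (AC: *SFTPG*, *NAPSA*, *TTF-1*; LCNEC: *CHGA*,
  *SYP*, *CD56*; SqCC: *TP73L*, *KRT6A*, *KRT5*, *KRT40*, *KRT16*).
  Classification uses binary within-sample gene-pair rules in the AIMS
  style — rule *r(a, b)* fires when *x(a) < x(b)* inside one sample — fed
  to a Laplace-smoothed naive Bayes layer,
  log *P*(*c* | **x**) ∝ log *π(c)* + Σᵣ [*xᵣ* log *p(r|c)* +
  (1 − *xᵣ*) log(1 − *p(r|c)*)],
  with the rule count chosen by stratified cross-validation. Because
  rules compare values only within a sample, predictions are invariant
  under any strictly increasing per-sample transform (NanoString counts,
  RNA-seq FPKM, microarray intensities) and never depend on other
  samples in the batch;
* a **fusion caller** combining the 3′/5′ probe imbalance ratio with
  fusion-specific junction probe counts (upper-right-quadrant rule), and
  a **MET exon 14 skipping caller** from the exon 13–15 junction probe
  against the flank/exon-14 expression ratio, both gated by a per-sample
  RNA-quality QC;
* **NanoString plumbing**: RCC file parsing, negative-control background
  correction (mean + 2 SD, floored), expression/label/calls tables;
* an **evaluation harness** (confusion matrices, accuracy, balanced
  accuracy, macro one-vs-rest AUC, iterated stratified train/test
  protocol) and a **synthetic-data generator** with known truth so the
  whole pipeline is testable without any external data.

## Worked example

```r
library(nsclcssp)

sim    <- simulate_histology_cohort(sim_config(seed = 1))   # 68 samples, known truth
counts <- background_correct(sim$expression, probe_classes = sim$probe_classes)

model <- train_ssp(counts, sim$labels, seed = 1)
model
#> <ssp_model> 3 classes (AC, LCNEC, SqCC), 9 rules, trained on n = 68
#>   CV: best mean balanced accuracy 1 at k = 9 (seed 1)

preds <- predict_ssp(model, counts)
head(preds, 3)
#> # A tibble: 3 × 5
#>   sample_id predicted_class    AC      LCNEC     SqCC
#> 1 S001      AC              1.000 0.00000730 5.45e-10
#> 2 S002      AC              1.000 0.00000730 5.45e-10
#> 3 S003      AC              1.000 0.00000730 5.45e-10

glance(score_predictions(preds, sim$labels))
#> # A tibble: 1 × 4
#>       n accuracy balanced_accuracy macro_auc
#> 1    68        1                 1         1
```

Each prediction row is one sample: the class posteriors sum to 1 and
`predicted_class` is their argmax. On this clean synthetic cohort the
cross-validated model selects 9 rules and reclassifies all 68 samples
correctly; real cohorts are noisier (see the methods vignette).

Fusion calling on a simulated 131-sample fusion cohort recovers exactly
the simulated events:

```r
fus   <- simulate_fusion_probes(fusion_sim_config(seed = 1))
calls <- call_fusions(fus$counts, fus$panel, probe_classes = fus$probe_classes)
dplyr::count(calls[calls$status == "positive", ], gene, best_variant)
#> # A tibble: 7 × 3
#>   gene  best_variant          n
#> 1 ALK   EML4-ALK_E13:A20      3
#> 2 ALK   EML4-ALK_E20:A20      1
#> 3 ALK   EML4-ALK_E6B:A20      1
#> 4 MET   exon14_skipping       3
#> 5 NRG1  CD74-NRG1_C8:N6       2
#> 6 RET   KIF5B-RET_K15:R12     2
#> 7 RET   KIF5B-RET_K16:R12     2
```

`autoplot()` methods exist for models (CV curve), predictions (posterior
bars), fusion calls (quadrant scatter) and hold-out reports (metric
boxplots); `tidy()`/`glance()` give broom-style summaries throughout.

A command-line wrapper is shipped at `inst/cli/nsclcssp` with
`simulate`, `train`, `predict`, `fusions` and `evaluate` subcommands.

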
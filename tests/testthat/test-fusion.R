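alk_counts <- function(p5 = c(10, 30, 20), p3 = c(100, 200, 150),
                       jx = c(0, 0, 0)) {
  tibble::tibble(
    probe_id = c(paste0("ALK_5p_", 1:3), paste0("ALK_3p_", 1:3),
                 "ALK_jx_E6B_A20", "ALK_jx_E13_A20", "ALK_jx_E20_A20"),
    count = c(p5, p3, jx)
  )
}

test_that("the imbalance ratio is the mean 3' over mean 5' count", {
  panel <- default_fusion_panel()
  counts <- tibble::tibble(probe_id = c("ALK_5p_1", "ALK_5p_2",
                                        "ALK_3p_1", "ALK_3p_2"),
                           count = c(10, 30, 100, 200))
  expect_equal(compute_imbalance_ratio(counts, panel, "ALK"), 150 / 20)  # 7.5

  sym <- tibble::tibble(probe_id = c("ALK_5p_1", "ALK_5p_2",
                                     "ALK_3p_1", "ALK_3p_2"),
                        count = c(50, 70, 50, 70))
  expect_equal(compute_imbalance_ratio(sym, panel, "ALK"), 1.0)

  # elevated 3' with low 5' (fusion-positive pattern) pushes the ratio over 1
  expect_gt(compute_imbalance_ratio(alk_counts(), panel, "ALK"), 1)

  expect_error(
    compute_imbalance_ratio(tibble::tibble(probe_id = "ALK_5p_1", count = 5),
                            panel, "ALK"),
    "No 3' probes")
})

test_that("gene fusion calls require both quadrant axes", {
  panel <- default_fusion_panel()
  th <- fusion_thresholds()

  pos <- call_gene_fusion(alk_counts(jx = c(5, 900, 2)), panel, "ALK", th)
  expect_identical(pos$status, "positive")
  expect_identical(pos$best_variant, "EML4-ALK_E13:A20")
  expect_equal(pos$imbalance_ratio, 7.5)

  no_jx <- call_gene_fusion(alk_counts(jx = c(0, 0, 0)), panel, "ALK", th)
  expect_identical(no_jx$status, "negative")
  expect_true(is.na(no_jx$best_variant))

  balanced <- call_gene_fusion(alk_counts(p3 = c(10, 30, 20), jx = c(0, 900, 0)),
                               panel, "ALK", th)
  expect_identical(balanced$status, "negative")  # ratio 1.0, high junction

  # variant tie-break: equal junction counts pick the first in panel order
  tie <- call_gene_fusion(alk_counts(jx = c(900, 900, 900)), panel, "ALK", th)
  expect_identical(tie$best_variant, "EML4-ALK_E6B:A20")

  # failed QC makes the call inconclusive
  inc <- call_gene_fusion(alk_counts(jx = c(5, 900, 2)), panel, "ALK", th,
                          qc_pass = FALSE, qc_reason = "low_total_counts")
  expect_identical(inc$status, "inconclusive")
  expect_identical(inc$qc_flag, "fail")
})

test_that("MET exon 14 skipping uses flank/exon-14 ratio and skip junction", {
  panel <- default_fusion_panel()
  th <- fusion_thresholds()
  met <- function(flank = 200, ex14 = 10, jx = 500) {
    tibble::tibble(
      probe_id = c("MET_ex3", "MET_ex4", "MET_ex14", "MET_ex20", "MET_ex21",
                   "MET_jx_ex13_15"),
      count = c(flank, flank, ex14, flank, flank, jx)
    )
  }
  pos <- call_met_exon14(met(), panel, th)
  expect_identical(pos$status, "positive")
  expect_identical(pos$best_variant, "exon14_skipping")
  expect_equal(pos$imbalance_ratio, 20)  # flank mean 200 / exon14 10
  expect_equal(pos$max_junction_count, 500)

  expect_identical(call_met_exon14(met(jx = 0), panel, th)$status, "negative")
  null <- call_met_exon14(met(ex14 = 200, jx = 0), panel, th)
  expect_identical(null$status, "negative")
  expect_equal(null$imbalance_ratio, 1)
})

test_that("QC gates on total counts and positive-control geometric mean", {
  pos_ids <- paste0("POS_", LETTERS[1:3])
  good <- c(setNames(c(500, 600, 700), c("E1", "E2", "E3")),
            setNames(c(200, 300, 250), pos_ids))
  expect_true(qc_conclusive(good, pos_ids)$pass)

  zero <- c(setNames(c(0, 0, 0), c("E1", "E2", "E3")),
            setNames(c(200, 300, 250), pos_ids))
  v <- qc_conclusive(zero, pos_ids)
  expect_false(v$pass)
  expect_match(v$reason, "low_total_counts")

  # geometric mean exactly at the threshold passes (>= convention)
  at <- c(setNames(c(500, 600), c("E1", "E2")),
          setNames(c(32, 32, 32), pos_ids))
  expect_true(qc_conclusive(at, pos_ids, poscon_min = 32)$pass)
  below <- c(setNames(c(500, 600), c("E1", "E2")),
             setNames(c(31, 32, 32), pos_ids))
  expect_false(qc_conclusive(below, pos_ids, poscon_min = 32)$pass)
})

test_that("calls are scale-equivariant in ratios and monotone in 3' counts", {
  panel <- default_fusion_panel()
  base <- alk_counts(jx = c(0, 120, 0))
  r1 <- compute_imbalance_ratio(base, panel, "ALK")
  scaled <- dplyr::mutate(base, count = count * 7)
  expect_equal(compute_imbalance_ratio(scaled, panel, "ALK"), r1)

  # junction thresholds are absolute: scaling down can flip the call
  th <- fusion_thresholds()
  expect_identical(call_gene_fusion(base, panel, "ALK", th)$status, "positive")
  tiny <- dplyr::mutate(base, count = count / 10)
  expect_identical(call_gene_fusion(tiny, panel, "ALK", th)$status, "negative")

  # increasing any 3' count never flips positive -> negative
  set.seed(4)
  for (i in 1:20) {
    bumped <- base
    j <- sample(which(grepl("ALK_3p", base$probe_id)), 1)
    bumped$count[j] <- bumped$count[j] + runif(1, 0, 5000)
    expect_identical(call_gene_fusion(bumped, panel, "ALK", th)$status,
                     "positive")
  }

  # increasing exon-14 count never flips a MET negative to positive
  met_neg <- tibble::tibble(
    probe_id = c("MET_ex3", "MET_ex4", "MET_ex14", "MET_ex20", "MET_ex21",
                 "MET_jx_ex13_15"),
    count = c(200, 200, 150, 200, 200, 500))
  expect_identical(call_met_exon14(met_neg, panel, th)$status, "negative")
  for (bump in c(10, 100, 1000)) {
    up <- met_neg
    up$count[3] <- up$count[3] + bump
    expect_identical(call_met_exon14(up, panel, th)$status, "negative")
  }
})

test_that("the synthetic fusion cohort is called with perfect sensitivity and specificity", {
  sim <- simulate_fusion_probes(fusion_sim_config(seed = 8))
  calls <- call_fusions(sim$counts, sim$panel, probe_classes = sim$probe_classes)
  pos <- calls[calls$status == "positive", ]
  truth_key <- paste(sim$truth$sample_id, sim$truth$gene)
  call_key <- paste(pos$sample_id, pos$gene)
  expect_setequal(call_key, truth_key)  # sensitivity = specificity = 1
  # called variants match the simulated ones
  merged <- dplyr::inner_join(pos, sim$truth, by = c("sample_id", "gene"))
  expect_identical(merged$best_variant, merged$variant)
})

test_that("shrinking the fusion effect size degrades sensitivity monotonically", {
  sens_at <- function(fold, jx_mean) {
    cfg <- fusion_sim_config(three_prime_fold = fold, junction_mean = jx_mean,
                             seed = 99)
    sim <- simulate_fusion_probes(cfg)
    calls <- call_fusions(sim$counts, sim$panel,
                          probe_classes = sim$probe_classes)
    pos <- calls[calls$status == "positive", ]
    hits <- paste(pos$sample_id, pos$gene)
    mean(paste(sim$truth$sample_id, sim$truth$gene) %in% hits)
  }
  s_hi <- sens_at(15, 6000)
  s_mid <- sens_at(2.5, 120)
  s_lo <- sens_at(1.1, 20)
  expect_gte(s_hi, s_mid)
  expect_gte(s_mid, s_lo)
  expect_lt(s_lo, 0.5)
})

test_that("fusion panels round-trip through YAML", {
  panel <- default_fusion_panel()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_fusion_panel(panel, path)
  back <- read_fusion_panel(path)
  expect_equal(as.data.frame(back), as.data.frame(panel))
})
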
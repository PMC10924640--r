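make_call <- function(pid = "P1", gene = "TP53", class = "SNV", vaf = 0.2,
                      alt = 20, bq = 35, mq = 50, bias = FALSE, nonsyn = TRUE) {
  data.frame(patient_id = pid, gene = gene, variant_class = class, vaf = vaf,
             alt_reads = alt, base_quality = bq, mapping_quality = mq,
             pe_bias = bias, nonsynonymous = nonsyn, stringsAsFactors = FALSE)
}

test_that("somatic filter applies the five QC rules with a first-fail ledger", {
  calls <- rbind(
    make_call(vaf = 0.015),                       # fails VAF (2% is not above)
    make_call(vaf = 0.02),                        # boundary: not above 2%
    make_call(vaf = 0.025, alt = 6, bq = 35, mq = 40),  # kept
    make_call(alt = 4),                           # fails alt reads
    make_call(bq = 29.5),                         # fails base quality
    make_call(mq = 29),                           # fails mapping quality
    make_call(bias = TRUE))                       # fails PE bias
  res <- filter_somatic(calls)
  expect_equal(nrow(res$kept), 1)
  expect_identical(res$rejected$reason,
                   c("VAF", "VAF", "alt reads", "base quality",
                     "mapping quality", "PE bias"))
  # idempotence: filtering the kept set changes nothing
  again <- filter_somatic(res$kept)
  expect_identical(again$kept, res$kept)
  expect_equal(nrow(again$rejected), 0)
})

test_that("a planted 100-call fixture matches the rule-application oracle", {
  set.seed(40)
  calls <- simulate_variants(
    data.frame(patient_id = sprintf("P%02d", 1:30),
               group = rep(c("low", "high"), 15), stringsAsFactors = FALSE),
    violation_fraction = 0.08, seed = 41)
  res <- filter_somatic(calls)
  keep_oracle <- with(calls, vaf > 0.02 & alt_reads >= 5 & base_quality >= 30 &
                        mapping_quality >= 30 & !pe_bias)
  expect_identical(sort(rownames(res$kept)),
                   sort(rownames(calls)[keep_oracle]))
  # planted violations and the ledger agree call by call
  expect_identical(res$rejected$reason, res$rejected$planted_violation)
  expect_true(all(res$kept$planted_violation == "none"))
})

test_that("TMB normalizes counts to a 0.7 Mb denominator", {
  p07 <- panel_spec("small", c("TP53", "EGFR"), 0.7)
  calls7 <- do.call(rbind, lapply(1:7, function(i) make_call()))
  expect_equal(compute_tmb(calls7, p07)$tmb, 7.0)
  p14 <- panel_spec("big", c("TP53", "EGFR"), 1.4)
  calls10 <- do.call(rbind, lapply(1:10, function(i) make_call()))
  expect_equal(compute_tmb(calls10, p14)$tmb, 5.0)
  expect_equal(compute_tmb(calls7[0, ], p07)$tmb, 0)
  # fusions/CNVs are excluded unless explicitly flagged in
  mixed <- rbind(calls7, make_call(class = "fusion"), make_call(class = "CNV_amp"))
  expect_equal(compute_tmb(mixed, p07)$tmb, 7.0)
  expect_equal(compute_tmb(mixed, p07, include_sv = TRUE)$tmb, 9.0)
  # homogeneity of degree -1 in panel size, additivity in calls
  expect_equal(compute_tmb(calls7, panel_spec("x", "TP53", 2.1))$tmb,
               compute_tmb(calls7, p07)$tmb / 3)
  expect_error(panel_spec("bad", "TP53", 0), "coding_region_mb")
})

test_that("per-gene group comparison flags the planted enrichment pattern", {
  # 61 patients: EGFR altered in 26/36 low vs 11/25 high; BRCA2 in 0/36 vs 4/25
  group <- factor(rep(c("low", "high"), c(36, 25)), levels = c("low", "high"))
  pids <- sprintf("P%02d", 1:61)
  calls <- rbind(
    do.call(rbind, lapply(pids[c(1:26, 37:47)], make_call, gene = "EGFR")),
    do.call(rbind, lapply(pids[48:51], make_call, gene = "BRCA2")),
    do.call(rbind, lapply(pids[c(5:20, 40:52)], make_call, gene = "TP53")))
  mat <- alteration_matrix(calls, patients = pids)
  cmp <- gene_frequency_compare(mat, group)
  egfr <- cmp[cmp$gene == "EGFR", ]
  expect_equal(egfr$freq_low, 26 / 36, tolerance = 1e-12)
  expect_equal(egfr$freq_high, 11 / 25, tolerance = 1e-12)
  expect_lt(egfr$p_value, 0.05)
  expect_lt(cmp[cmp$gene == "BRCA2", "p_value"], 0.05)
  # identical frequencies give p = 1
  bal <- alteration_matrix(make_call(pid = "Q1"), patients = c("Q1", "Q2"))
  bal["Q2", "TP53"] <- 1L
  expect_equal(gene_frequency_compare(bal, factor(c("low", "high")))$p_value, 1)
})

test_that("gene-set comparison marks a patient altered on any member gene", {
  group <- factor(rep(c("low", "high"), c(36, 25)), levels = c("low", "high"))
  pids <- sprintf("P%02d", 1:61)
  # planted: set genes altered in 8/36 low vs 13/25 high (22% vs 52%)
  calls <- rbind(
    do.call(rbind, lapply(pids[1:8], make_call, gene = "WNT5A")),
    do.call(rbind, lapply(pids[37:49], make_call, gene = "NOTCH1")),
    do.call(rbind, lapply(pids[10:20], make_call, gene = "TP53")))
  mat <- alteration_matrix(calls, patients = pids)
  sets <- list(cell_development = c("WNT5A", "NOTCH1", "ABSENT1"))
  cmp <- geneset_alteration_compare(mat, sets, group)
  expect_equal(cmp$freq_low, 8 / 36, tolerance = 1e-12)
  expect_equal(cmp$freq_high, 13 / 25, tolerance = 1e-12)
  expect_lt(cmp$p_value, 0.05)
  expect_error(geneset_alteration_compare(mat, list(empty = "NOPE"), group),
               "covers no panel gene")
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tTP53\tEGFR", "setB\tdesc\tKRAS"), path)
  sets <- read_gmt(path)
  expect_identical(sets$setA, c("TP53", "EGFR"))
  expect_identical(sets$setB, "KRAS")
})

test_that("VCF write/read round-trips one patient's calls", {
  set.seed(42)
  calls <- simulate_variants(
    data.frame(patient_id = "P01", group = "high", stringsAsFactors = FALSE),
    rate_high = 6, seed = 43)
  calls$planted_violation <- NULL
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(calls, path)
  back <- read_variant_vcf(path, "P01")
  expect_equal(nrow(back), nrow(calls))
  expect_identical(back$gene, calls$gene)
  expect_identical(back$variant_class, calls$variant_class)
  expect_close(back$vaf, calls$vaf, 1e-5)
  expect_identical(back$pe_bias, calls$pe_bias)
})
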
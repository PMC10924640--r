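test_that("the generator is deterministic from its seed", {
  a <- simulate_cohort(sim_config(n_patients = 40, seed = 50))
  b <- simulate_cohort(sim_config(n_patients = 40, seed = 50))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  l1 <- withr::local_tempfile(fileext = ".csv")
  l2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a$cohort, f1, l1)
  write_cohort(b$cohort, f2, l2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(l1), readLines(l2))
  expect_identical(a$truth, b$truth)
})

test_that("zero dispersion collapses every score to 0", {
  sim <- simulate_cohort(sim_config(n_patients = 25, tau_low = 0, tau_high = 0,
                                    seed = 51))
  sc <- thr_score_cohort(sim$cohort)
  # zero up to the float round-trip through realized diameters
  expect_true(all(sc$thrscore < 1e-12))
})

test_that("lesion counts follow the configured distribution", {
  sim <- simulate_cohort(sim_config(n_patients = 174, seed = 52))
  counts <- table(factor(vapply(sim$cohort$patients,
                                function(p) length(p$lesions), integer(1)),
                         levels = 3:6))
  probs <- c(.72, .24, .02, .02)
  # each bin within 3 binomial SDs of its expectation
  for (i in 1:4) {
    expect_lt(abs(counts[i] - 174 * probs[i]),
              3 * sqrt(174 * probs[i] * (1 - probs[i])) + 1)
  }
  # baseline diameters respect the measurability floors
  for (p in sim$cohort$patients) {
    for (l in p$lesions) {
      expect_gte(l$diameters_mm[["baseline"]], if (l$is_node) 15 else 10)
    }
  }
})

test_that("Cox on the true latent group recovers the planted log-HR", {
  set.seed(53)
  betas <- numeric(10)
  for (i in 1:10) {
    sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 530 + i))
    d <- merge(outcome_table(sim$cohort), sim$truth, by = "patient_id")
    betas[i] <- cox_fit(d$pfs_months, d$event,
                        data.frame(group = d$group))$coefficients$coef
  }
  expect_lt(abs(mean(betas) - log(3.4)), 0.05 * log(3.4))
})

test_that("scores are bimodal and concordant with the latent groups", {
  sim <- simulate_cohort(sim_config(n_patients = 2000, seed = 54))
  sc <- thr_score_cohort(sim$cohort)
  d <- merge(sc, sim$truth, by = "patient_id")
  # best separating cutoff achieves >= 95% concordance at default separation
  cand <- seq(0.05, 2, by = 0.01)
  acc <- vapply(cand, function(cc)
    mean((d$thrscore > cc) == (d$group == "high")), numeric(1))
  expect_gte(max(acc), 0.95)
  # bimodality on the log scale: the trough at the geometric midpoint of the
  # component medians carries far less mass than either mode
  s <- d$thrscore
  m_low <- median(s[d$group == "low"]); m_high <- median(s[d$group == "high"])
  near <- function(center) mean(abs(log(s / center)) < 0.3)
  expect_lt(near(sqrt(m_low * m_high)), 0.5 * near(m_low))
  expect_lt(near(sqrt(m_low * m_high)), 0.5 * near(m_high))
})

test_that("change-point cohorts carry the planted hazard structure", {
  null_stats <- alt_stats <- numeric(8)
  for (i in 1:8) {
    d0 <- simulate_changepoint_cohort(300, hr = 1, seed = 600 + i)
    d1 <- simulate_changepoint_cohort(300, hr = 3.4, seed = 700 + i)
    null_stats[i] <- maxsel_cutpoint(d0$time, d0$event, d0$score)$best_statistic
    alt_stats[i] <- maxsel_cutpoint(d1$time, d1$event, d1$score)$best_statistic
  }
  expect_gt(median(alt_stats), median(null_stats))
  # scores all on one side of the cutoff leave a single-hazard null
  d <- simulate_changepoint_cohort(200, true_cutoff = 1e9, hr = 3.4, seed = 55)
  expect_true(all(d$score <= 1e9))
})

test_that("variant generator hits the planted mutation rates and violations", {
  groups <- data.frame(patient_id = sprintf("P%04d", 1:1000),
                       group = rep("high", 1000), stringsAsFactors = FALSE)
  calls <- simulate_variants(groups, rate_high = 3, seed = 56)
  kept <- filter_somatic(calls)$kept
  per_patient <- table(factor(kept$patient_id, levels = groups$patient_id))
  expect_equal(median(as.integer(per_patient)), 3)
  # per-rule planted violation shares
  calls_v <- simulate_variants(groups, violation_fraction = 0.05, seed = 57)
  shares <- table(calls_v$planted_violation) / nrow(calls_v)
  for (rule in c("VAF", "alt reads", "base quality", "mapping quality",
                 "PE bias")) {
    expect_lt(abs(shares[[rule]] - 0.05), 0.015)
  }
  # EGFR enrichment by group
  set.seed(58)
  g2 <- data.frame(patient_id = sprintf("Q%04d", 1:2000),
                   group = rep(c("low", "high"), 1000),
                   stringsAsFactors = FALSE)
  calls2 <- simulate_variants(g2, seed = 59)
  egfr <- unique(calls2$patient_id[calls2$gene == "EGFR"])
  f_low <- mean(g2$patient_id[g2$group == "low"] %in% egfr)
  f_high <- mean(g2$patient_id[g2$group == "high"] %in% egfr)
  expect_lt(abs(f_low - 0.72), 0.05)
  expect_lt(abs(f_high - 0.44), 0.05)
})

test_that("VCF output is identical under a fixed seed", {
  groups <- data.frame(patient_id = "P1", group = "high",
                       stringsAsFactors = FALSE)
  p1 <- withr::local_tempfile(fileext = ".vcf")
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_variant_vcf(simulate_variants(groups, rate_high = 5, seed = 60), p1)
  write_variant_vcf(simulate_variants(groups, rate_high = 5, seed = 60), p2)
  expect_identical(readLines(p1), readLines(p2))
})
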
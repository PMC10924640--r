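test_that("sum of diameters is a plain sum with hard missing-value errors", {
  lesions <- list(make_lesion("P1", "L1", 20, 15), make_lesion("P1", "L2", 30, 22),
                  make_lesion("P1", "L3", 50, 40))
  expect_equal(sum_of_diameters(lesions, "baseline"), 100)
  expect_error(sum_of_diameters(list(), "baseline"), "empty")
  expect_error(sum_of_diameters(lesions, "week12"), "L1")
  set.seed(3)
  rand <- lapply(1:10, function(j)
    make_lesion("P1", paste0("R", j), runif(1, 10, 60), runif(1, 0, 60)))
  expected <- 0
  for (l in rand) expected <- expected + l$diameters_mm[["week6"]]
  expect_equal(sum_of_diameters(rand, "week6"), expected)
})

test_that("timepoint classification matches the rule table on the boundary grid", {
  # PR edge: nadir = baseline (no regrowth), sweep the -30% boundary
  baseline <- 100
  for (sum_mm in c(69, 70, 70.1, 100)) {
    got <- classify_timepoint(sum_mm, baseline, min(sum_mm, baseline))
    expect_identical(got,
                     oracle_recist(100 * (sum_mm - baseline) / baseline,
                                   0, 0, FALSE))
  }
  # PD edge: construct (nadir, sum) around the 20% / 5 mm corner; the oracle
  # sees the realized changes, which carry the same floating representation
  # as the implementation's inputs
  for (pct_nadir in c(19.9, 20, 20.1)) {
    for (abs_nadir in c(4.9, 5.0, 5.1)) {
      nadir <- abs_nadir / (pct_nadir / 100)
      sum_mm <- nadir + abs_nadir
      base <- max(nadir, sum_mm) * 1.05  # shrank first, then regrew
      got <- classify_timepoint(sum_mm, base, nadir)
      want <- oracle_recist(100 * (sum_mm - base) / base,
                            100 * (sum_mm - nadir) / nadir,
                            sum_mm - nadir, FALSE)
      expect_identical(got, want)
    }
  }
  # exact-arithmetic corner: 25 -> 30 over nadir 25 is exactly +20% and +5 mm
  expect_identical(classify_timepoint(30, 31.5, 25), "PD")
  expect_identical(classify_timepoint(29.9, 31.5, 25), "SD")
  # explicit anchor cases
  expect_identical(classify_timepoint(70, 100, 100), "PR")    # exactly -30%
  expect_identical(classify_timepoint(61, 100, 50), "PD")     # +22%, +11 mm
  expect_identical(classify_timepoint(24.5, 25, 20), "SD")    # +22.5% but +4.5 mm
  expect_identical(classify_timepoint(0, 100, 100), "CR")
  # new lesion forces PD even with deep shrinkage
  expect_identical(classify_timepoint(10, 100, 100, new_lesion = TRUE), "PD")
  # CR blocked while nodal short axes remain >= 10 mm; -88% is still PR
  expect_identical(classify_timepoint(12, 100, 100, nonnodal_disappeared = TRUE,
                                      nodes_normalized = FALSE), "PR")
})

test_that("classification is monotone in the current sum", {
  set.seed(11)
  for (rep in 1:50) {
    baseline <- runif(1, 30, 120)
    nadir <- runif(1, 0.4, 1) * baseline
    sums <- sort(runif(20, 0, 1.8 * baseline))
    rank <- c(CR = 1, PR = 2, SD = 3, PD = 4)
    cats <- rank[vapply(sums, classify_timepoint, "", baseline_sum = baseline,
                        nadir_sum = nadir)]
    expect_true(all(diff(cats) >= 0))
  }
})

test_that("best overall response follows CR > PR > SD with PD capping", {
  expect_identical(best_overall_response(c("SD", "PR", "SD"))$best, "PR")
  expect_identical(best_overall_response(c("PD"))$best, "PD")
  expect_true(best_overall_response(c("SD", "PR"))$orr_flag)
  expect_false(best_overall_response(c("SD", "SD"))$orr_flag)
  # responses after a PD visit are ignored
  expect_identical(best_overall_response(c("SD", "PD", "PR"))$best, "SD")
  expect_error(best_overall_response(character(0)), "empty")

  # 100 random sequences vs exhaustive rule application
  set.seed(5)
  rank <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  for (i in 1:100) {
    seq_i <- sample(c("CR", "PR", "SD", "PD"), sample(1:6, 1), replace = TRUE)
    pd <- match("PD", seq_i)
    upto <- if (is.na(pd)) seq_i else seq_i[seq_len(pd)]
    want <- names(rank)[min(rank[upto])]
    expect_identical(best_overall_response(seq_i)$best, want)
  }
})

test_that("confirmation mode needs a second qualifying visit", {
  expect_identical(best_overall_response(c("PR", "PR"), confirm = TRUE)$best, "PR")
  expect_identical(best_overall_response(c("PR", "SD"), confirm = TRUE)$best, "SD")
  expect_identical(best_overall_response(c("CR", "PR"), confirm = TRUE)$best, "PR")
})

test_that("PFS derivation uses first PD or death, else censors at last scan", {
  o <- derive_pfs(c(1.5, 3.0, 5.4), c("SD", "SD", "PD"), patient_id = "P1")
  expect_equal(o$pfs_months, 5.4); expect_true(o$event)
  o <- derive_pfs(c(1.5, 3.0), c("SD", "SD"), last_scan = 12.9)
  expect_equal(o$pfs_months, 12.9); expect_false(o$event)
  # death before any progression is an event at the death time
  o <- derive_pfs(c(1.5, 3.0), c("SD", "SD"), death_time = 3.0)
  expect_equal(o$pfs_months, 3.0); expect_true(o$event)
  expect_error(derive_pfs(c(1.5), c("SD")), "last_scan")
})

test_that("per-patient assessment table carries sums, nadir and categories", {
  lesions <- list(make_lesion("P1", "L1", 40, 20, week12 = 30),
                  make_lesion("P1", "L2", 60, 40, week12 = 50))
  tab <- recist_assess(lesions)
  expect_equal(tab$sum_mm, c(60, 80))
  expect_equal(tab$pct_baseline, c(-40, -20))
  # week12 grows +33% and +20 mm from the week6 nadir: PD
  expect_identical(tab$category, c("PR", "PD"))
})
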
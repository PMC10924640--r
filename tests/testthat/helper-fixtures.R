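# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (loops, enumeration) and never call the code paths they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

make_lesion <- function(pid = "P1", lid = "L1", baseline = 20, week6 = 14,
                        site = "lung", is_node = FALSE, ...) {
  extra <- c(...)
  d <- c(baseline = baseline, week6 = week6, extra)
  lesion_series(pid, lid, site = site, is_node = is_node, diameters_mm = d)
}

make_patient <- function(pid = "P1", lesions = NULL, ecog = 1,
                         treatment = "chemotherapy", local_therapy = FALSE,
                         n_lesions = 3, baseline = 20, week6 = 14) {
  if (is.null(lesions)) {
    lesions <- lapply(seq_len(n_lesions), function(j)
      make_lesion(pid, paste0("L", j), baseline, week6))
  }
  patient_record(pid, age = 60, sex = "male", smoking = FALSE,
                 ecog_ps = ecog, treatment = treatment,
                 local_therapy = local_therapy, lesions = lesions)
}

make_cohort <- function(n = 10, seed = 42) {
  set.seed(seed)
  patients <- lapply(seq_len(n), function(i) {
    k <- sample(3:5, 1)
    lesions <- lapply(seq_len(k), function(j) {
      b <- runif(1, 12, 60)
      make_lesion(sprintf("P%02d", i), paste0("L", j), baseline = b,
                  week6 = max(0, b * runif(1, 0.4, 1.3)))
    })
    make_patient(sprintf("P%02d", i), lesions = lesions)
  })
  outcomes <- lapply(seq_len(n), function(i)
    outcome_record(sprintf("P%02d", i), runif(1, 2, 30), runif(1) < 0.7))
  thr_cohort(patients, outcomes)
}

# direct two-pass THRscore oracle: population SD over |mean|
oracle_thrscore <- function(z) {
  m <- sum(z) / length(z)
  ss <- 0
  for (zi in z) ss <- ss + (zi - m)^2
  s <- sqrt(ss / length(z))
  if (s == 0) 0 else if (m == 0) Inf else s / abs(m)
}

# Nelson-Aalen log-rank scores by explicit loops
oracle_logrank_scores <- function(times, events) {
  n <- length(times)
  a <- numeric(n)
  for (i in seq_len(n)) {
    lam <- 0
    for (u in sort(unique(times[events]))) {
      if (u <= times[i]) lam <- lam + sum(times == u & events) / sum(times >= u)
    }
    a[i] <- as.numeric(events[i]) - lam
  }
  a
}

# exhaustive maximally-selected-statistic oracle over all admissible splits
oracle_maxsel <- function(x, a, minprop) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]; as_ <- a[ord]
  abar <- mean(as_); s2 <- mean((as_ - abar)^2)
  best <- list(stat = -Inf, cut = NA)
  for (k in seq_len(n - 1)) {
    if (xs[k] == xs[k + 1]) next
    if (k < minprop * n || (n - k) < minprop * n) next
    S <- abs(sum(as_[1:k]) - k * abar) / sqrt(k * (n - k) / (n - 1) * s2)
    if (S > best$stat + 1e-12) {
      best <- list(stat = S, cut = (xs[k] + xs[k + 1]) / 2)
    }
  }
  best
}

# RECIST truth table by literal rule transcription
oracle_recist <- function(pct_base, pct_nadir, abs_nadir, new_lesion,
                          all_gone = FALSE) {
  if (new_lesion || (pct_nadir >= 20 && abs_nadir >= 5)) return("PD")
  if (all_gone) return("CR")
  if (pct_base <= -30) return("PR")
  "SD"
}

# plain (uncensored) Pencina discrimination statistics
oracle_pencina <- function(risk_base, risk_new, is_case) {
  idi <- (mean(risk_new[is_case]) - mean(risk_new[!is_case])) -
    (mean(risk_base[is_case]) - mean(risk_base[!is_case]))
  d <- risk_new - risk_base
  nri <- (mean(d[is_case] > 0) - mean(d[is_case] < 0)) -
    (mean(d[!is_case] > 0) - mean(d[!is_case] < 0))
  list(idi = idi, nri = nri)
}

expect_close <- function(x, y, tol = 1e-8) {
  expect_true(all(abs(x - y) <= tol),
              label = sprintf("max|diff| = %.3g (tol %.3g)",
                              max(abs(x - y)), tol))
}
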
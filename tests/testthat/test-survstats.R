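test_that("KM median follows the smallest-t-with-S<=0.5 rule", {
  km <- km_estimate(1:5, rep(TRUE, 5))
  expect_equal(km$median, 3)
  km <- km_estimate(c(2, 4, 6), rep(FALSE, 3))
  expect_true(all(km$surv == 1))
  expect_false(km$median_defined)
  # KM with no censoring equals the empirical survival function
  set.seed(20)
  t <- rexp(200, 0.2)
  km <- km_estimate(t, rep(TRUE, 200))
  emp <- vapply(km$time, function(u) mean(t > u), numeric(1))
  expect_close(km$surv, emp, 1e-12)
})

test_that("KM median of an exponential law approaches log(2)/rate", {
  set.seed(21)
  lambda <- 0.15
  km <- km_estimate(rexp(5000, lambda), rep(TRUE, 5000))
  expect_lt(abs(km$median - log(2) / lambda) / (log(2) / lambda), 0.03)
})

test_that("log-rank test: null identity, symmetry, and a hand-computed toy", {
  t <- c(1, 2, 3, 4, 5, 6, 7, 8)
  e <- rep(TRUE, 8)
  g <- rep(c("a", "b"), 4)
  dup <- logrank_test(c(t, t), c(e, e), rep(c("a", "b"), each = 8))
  expect_lt(dup$statistic, 1e-9)
  expect_gt(dup$p_value, 0.999)
  swap <- logrank_test(t, e, rev(g))
  expect_equal(logrank_test(t, e, g)$statistic, swap$statistic,
               tolerance = 1e-12)
  # hand computation: O - E and hypergeometric variance summed over event times
  o_minus_e <- 0; v <- 0
  for (u in t) {
    at <- t >= u
    n1 <- sum(at & g == "a"); n_ <- sum(at); d <- 1
    o_minus_e <- o_minus_e + (u %in% t[g == "a"]) - n1 / n_
    if (n_ > 1) v <- v + d * (n1 / n_) * (1 - n1 / n_) * (n_ - d) / (n_ - 1)
  }
  expect_equal(logrank_test(t, e, g)$statistic, o_minus_e^2 / v,
               tolerance = 1e-9)
  expect_error(logrank_test(t, e, rep("a", 8)), "2 groups")
})

test_that("log-rank statistic equals the squared Cox score test on tie-free data", {
  set.seed(22)
  t <- rexp(60, 0.1) + runif(60) * 1e-4  # tie-free
  e <- rep(TRUE, 60)
  g <- rep(0:1, 30)
  lr <- logrank_test(t, e, g)
  fit <- survival::coxph(survival::Surv(t, e) ~ g, ties = "breslow")
  expect_equal(lr$statistic, unname(fit$score), tolerance = 1e-6)
})

test_that("Cox fit: null identity, guard rails, and grid-maximization oracle", {
  set.seed(23)
  t <- rexp(80, 0.1); e <- runif(80) < 0.8
  g <- rep(c("a", "b"), each = 40)
  null_fit <- cox_fit(c(t, t), c(e, e), data.frame(g = rep(c("a", "b"), each = 80)))
  expect_equal(null_fit$coefficients$hr, 1, tolerance = 1e-6)
  expect_true(null_fit$coefficients$ci_low <= 1 &&
                null_fit$coefficients$ci_high >= 1)
  expect_error(cox_fit(t, e, data.frame(x = rep(1, 80))), "constant")

  # n = 6 binary covariate, tie-free: brute-force partial likelihood grid
  t6 <- c(1, 2, 3, 4, 5, 6); e6 <- rep(TRUE, 6); x6 <- c(0, 1, 0, 1, 1, 0)
  loglik <- function(b) {
    ll <- 0
    for (i in order(t6)) {
      risk <- which(t6 >= t6[i])
      ll <- ll + b * x6[i] - log(sum(exp(b * x6[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  b_star <- grid[which.max(vapply(grid, loglik, numeric(1)))]
  fit6 <- cox_fit(t6, e6, data.frame(x = x6), ties = "breslow")
  expect_lt(abs(fit6$coefficients$coef - b_star), 1e-4)
})

test_that("restricted cubic spline basis has linear tails and continuity", {
  knots <- c(0.1, 0.4, 0.8, 1.5)
  # beyond the boundary knots the basis is linear: second differences vanish
  for (xs in list(seq(-2, 0.05, length.out = 20),
                  seq(1.6, 4, length.out = 20))) {
    b <- rcs_basis(xs, knots)
    for (j in seq_len(ncol(b))) {
      expect_close(diff(diff(b[, j])), 0, 1e-8)
    }
  }
  # continuity across a knot
  eps <- 1e-6
  b <- rcs_basis(c(0.8 - eps, 0.8, 0.8 + eps), knots)
  expect_close(b[1, ], b[2, ], 1e-4)
  expect_close(b[3, ], b[2, ], 1e-4)
  expect_error(rcs_basis(1:5, c(1, 1, 2)), "increasing")
})

test_that("spline dose-response recovers monotone risk and flags knot collisions", {
  set.seed(24)
  n <- 400
  x <- rlnorm(n, -0.9, 1)
  t <- rexp(n, 0.05 * exp(0.8 * log1p(x)))  # increasing risk in x
  cens <- runif(n, 5, 40)
  fit <- rcs_dose_response(pmin(t, cens), t <= cens, x)
  expect_true(fit$p_nonlinear >= 0 && fit$p_nonlinear <= 1)
  # fitted log-HR curve rises overall
  expect_gt(fit$curve$log_hr[nrow(fit$curve)], fit$curve$log_hr[1])
  expect_error(rcs_dose_response(pmin(t, cens), t <= cens,
                                 rep(c(0, 1), n / 2)),
               "distinct|collision")
})

test_that("nonlinearity test holds its size under a linear truth", {
  set.seed(25)
  rejections <- 0
  n_sims <- 120
  for (i in seq_len(n_sims)) {
    n <- 150
    x <- rnorm(n)
    t <- rexp(n, 0.08 * exp(0.5 * x))
    cens <- runif(n, 5, 40)
    p <- rcs_dose_response(pmin(t, cens), t <= cens, x)$p_nonlinear
    rejections <- rejections + (p < 0.05)
  }
  expect_gt(rejections / n_sims, 0.005)
  expect_lt(rejections / n_sims, 0.13)
})

test_that("time-dependent ROC: perfect marker, null marker, censoring correction", {
  set.seed(26)
  t <- rexp(300, 0.1)
  # marker = event-time rank reversed: earlier events have larger marker
  marker <- rank(-t)
  roc <- timedep_roc(t, rep(TRUE, 300), marker, horizons = c(6, 12))
  expect_equal(roc$auc, c(1, 1))
  # random marker at n = 2000 sits near 0.5
  t2 <- rexp(2000, 0.1)
  roc2 <- timedep_roc(t2, rep(TRUE, 2000), rnorm(2000), horizons = 12)
  expect_lt(abs(roc2$auc - 0.5), 0.03)
  expect_error(timedep_roc(t, rep(TRUE, 300), marker,
                           horizons = max(t) + 1), "beyond")

  # under censoring, the IPCW AUC stays closer to the uncensored truth than
  # an unweighted case/control AUC
  set.seed(27)
  n <- 1500
  m <- rnorm(n)
  t3 <- rexp(n, 0.08 * exp(0.9 * m))
  truth <- timedep_roc(t3, rep(TRUE, n), m, horizons = 12)$auc
  cens <- rexp(n, 0.04)  # ~30-40% censored
  obs <- pmin(t3, cens); ev <- t3 <= cens
  ipcw <- timedep_roc(obs, ev, m, horizons = 12)$auc
  case <- obs <= 12 & ev; ctrl <- obs > 12
  naive <- mean(outer(m[case], m[ctrl], ">") + 0.5 * outer(m[case], m[ctrl], "=="))
  expect_lt(abs(ipcw - truth), abs(naive - truth) + 0.005)
})

test_that("contingency tests reproduce printed two-set comparisons", {
  # discovery vs validation splits of a two-center cohort (counts as printed)
  tables <- list(
    brain = list(m = matrix(c(70, 15, 58, 31), 2), p = 0.017),
    bone = list(m = matrix(c(51, 34, 63, 26), 2), p = 0.181),
    liver = list(m = matrix(c(72, 13, 77, 12), 2), p = 0.901),
    ecog = list(m = matrix(c(75, 10, 87, 2), 2), p = 0.029),
    treatment = list(m = matrix(c(40, 45, 61, 28), 2), p = 0.007),
    smoking = list(m = matrix(c(58, 27, 58, 31), 2), p = 0.789))
  for (tb in tables) {
    got <- contingency_test(tb$m, mode = "chisq_yates")
    expect_equal(round(got$p_value, 3), tb$p)
  }
})

test_that("Fisher mode is exact and auto mode switches on small expecteds", {
  got <- contingency_test(matrix(c(5, 0, 0, 5), 2), mode = "fisher")
  expect_equal(got$p_value, 2 / choose(10, 5), tolerance = 1e-9)
  auto <- contingency_test(matrix(c(5, 0, 0, 5), 2))
  expect_identical(auto$test_used, "fisher")
  big <- contingency_test(matrix(c(30, 20, 25, 25), 2))
  expect_identical(big$test_used, "chisq_yates")
  expect_error(contingency_test(matrix(c(0, 0, 3, 5), 2)), "degenerate")
  expect_error(contingency_test(matrix(c(1.5, 2, 3, 5), 2)), "integer")
})

test_that("continuous comparisons route to Wilcoxon or Kruskal-Wallis", {
  set.seed(28)
  x <- rnorm(50); y <- rnorm(50)
  same <- group_compare_continuous(c(x, x), rep(c("a", "b"), each = 50))
  expect_identical(same$test_used, "wilcoxon")
  expect_gt(same$p_value, 0.9)
  shifted <- group_compare_continuous(c(x, x + 3), rep(c("a", "b"), each = 50))
  expect_lt(shifted$p_value, 0.001)
  three <- group_compare_continuous(c(x, y, rnorm(50)),
                                    rep(c("a", "b", "c"), each = 50))
  expect_identical(three$test_used, "kruskal_wallis")
  expect_error(group_compare_continuous(rep(1, 20), rep(c("a", "b"), 10)),
               "constant")
})

test_that("post-hoc power formula behaves at the null and scales monotonically", {
  expect_equal(schoenfeld_power(500, 1), 0.025, tolerance = 1e-9)
  expect_gt(schoenfeld_power(120, 3.4, 0.4), 0.99)
  d_grid <- schoenfeld_power(c(20, 50, 100, 200), 2)
  expect_true(all(diff(d_grid) > 0))
  hr_grid <- schoenfeld_power(80, c(1.2, 1.5, 2, 3))
  expect_true(all(diff(hr_grid) > 0))
  expect_equal(schoenfeld_power(80, 2), schoenfeld_power(80, 0.5),
               tolerance = 1e-12)
})
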
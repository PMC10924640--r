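#' Kaplan-Meier estimate with explicit median rule
#'
#' Product-limit estimator via \code{survival::survfit}. The median is the
#' smallest time t with S(t) <= 0.5; when S never reaches 0.5 the median is
#' undefined and returned as NA with \code{median_defined = FALSE}.
#'
#' @param times observed times.
#' @param events event indicators.
#' @return object of class \code{"thr_km"}: time grid, survival, n at risk,
#'   median, median_defined, and the underlying \code{survfit}.
#' @export
km_estimate <- function(times, events) {
  assert_that(length(times) >= 1, "need at least one subject")
  fit <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  hit <- which(fit$surv <= 0.5)
  median <- if (length(hit)) fit$time[min(hit)] else NA_real_
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, median = median,
                 median_defined = length(hit) > 0, fit = fit),
            class = "thr_km")
}

#' @export
print.thr_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: %d subjects, %d events, median %s\n",
              x$fit$n, sum(x$n_event),
              if (x$median_defined) sprintf("%.2f", x$median) else
                "not reached"))
  invisible(x)
}

#' Two-group log-rank test
#'
#' @param times,events survival data.
#' @param group two-level grouping vector.
#' @return list with \code{statistic} (chi-square, df 1) and \code{p_value}.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(group)
  assert_that(nlevels(droplevels(group)) == 2, "need exactly 2 groups")
  assert_that(any(as.logical(events)), "no events")
  sd <- survival::survdiff(survival::Surv(times, as.numeric(events)) ~ group)
  list(statistic = sd$chisq,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit through \code{survival::coxph} with Efron tie
#' handling by default (visit-grid times are heavily tied). Returns a tidy
#' coefficient table (term, hr, 95\% CI, Wald p) alongside the
#' likelihood-ratio p and the underlying fit.
#'
#' @param times,events survival data.
#' @param covariates data.frame of covariates (factors and numerics).
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return object of class \code{"thr_cox"}.
#' @export
cox_fit <- function(times, events, covariates, ties = "efron") {
  covariates <- as.data.frame(covariates)
  assert_that(ncol(covariates) >= 1, "need at least one covariate")
  for (j in seq_along(covariates)) {
    if (is.character(covariates[[j]]) || is.factor(covariates[[j]])) {
      covariates[[j]] <- droplevels(as.factor(covariates[[j]]))
    }
  }
  const <- vapply(covariates, function(v) length(unique(v)) < 2, logical(1))
  assert_that(!any(const), "constant covariate(s): %s",
              paste(names(covariates)[const], collapse = ", "))
  assert_that(sum(as.numeric(events)) >= ncol(covariates),
              "fewer events than covariates")
  dat <- cbind(data.frame(.time = times, .event = as.numeric(events)),
               covariates)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  # coxph's "coefficient may be infinite" warning is superseded by the
  # explicit linear-predictor divergence check below
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = ties),
    warning = function(w) {
      if (grepl("coefficient may be infinite", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  # separation shows as a diverging linear predictor, judged on each
  # covariate's own scale so small-scale basis columns do not false-trigger
  mm <- stats::model.matrix(fit)
  lp_spread <- abs(stats::coef(fit)) * apply(mm, 2, stats::sd)
  if (any(!is.finite(stats::coef(fit))) || any(lp_spread > 15)) {
    stop_thr("Cox fit did not converge (possible complete separation); max |coef|*sd = %.1f",
             max(lp_spread))
  }
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    ci_low = s$conf.int[, "lower .95"],
                    ci_high = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = tab, lr_p = s$logtest[["pvalue"]],
                 n = s$n, n_events = s$nevent, ties = ties, fit = fit,
                 data = dat),
            class = "thr_cox")
}

#' @export
print.thr_cox <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): %d subjects, %d events; LR p = %.3g\n",
              x$ties, x$n, x$n_events, x$lr_p))
  print(format(x$coefficients, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
coef.thr_cox <- function(object, ...) {
  stats::setNames(object$coefficients$coef, object$coefficients$term)
}

#' Univariate screen followed by a multivariable Cox model
#'
#' Each covariate is fit alone; those with a likelihood-ratio p below
#' \code{alpha} enter the joint multivariable model.
#'
#' @inheritParams cox_fit
#' @param alpha inclusion gate (default 0.05).
#' @return list with \code{univariate} (term, p), \code{selected}, and
#'   \code{multivariable} (a \code{"thr_cox"} or NULL when nothing passes).
#' @export
cox_screen <- function(times, events, covariates, alpha = 0.05,
                       ties = "efron") {
  covariates <- as.data.frame(covariates)
  uni_p <- vapply(names(covariates), function(nm) {
    cox_fit(times, events, covariates[, nm, drop = FALSE], ties = ties)$lr_p
  }, numeric(1))
  selected <- names(covariates)[uni_p < alpha]
  multi <- if (length(selected) >= 1) {
    cox_fit(times, events, covariates[, selected, drop = FALSE], ties = ties)
  } else NULL
  list(univariate = data.frame(term = names(covariates), p = unname(uni_p),
                               stringsAsFactors = FALSE),
       selected = selected, multivariable = multi)
}

#' Restricted cubic spline basis
#'
#' Harrell's truncated-power restricted cubic spline: linear beyond the
#' boundary knots, continuous second derivatives, k - 1 basis columns for k
#' knots (the linear term plus k - 2 nonlinear terms, scaled by the squared
#' knot span).
#'
#' @param x numeric vector.
#' @param knots increasing knot locations (length >= 3, distinct).
#' @return matrix with length(knots) - 1 columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  assert_that(k >= 3 && !is.unsorted(knots, strictly = TRUE),
              "knots must be >= 3 strictly increasing values")
  span2 <- (knots[k] - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    out[, j + 1] <- (cube(x - knots[j]) -
      cube(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
      cube(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) / span2
  }
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2)))
  out
}

#' Spline dose-response of a marker on survival
#'
#' Fits a Cox model on a 4-knot restricted cubic spline of the marker, with
#' knots at the 5/35/65/95th percentiles, and tests the nonlinear terms by a
#' joint Wald test. The returned curve is the log hazard ratio relative to
#' the marker value at the first knot.
#'
#' @param times,events survival data (>= 20 subjects).
#' @param x marker values with at least 4 distinct values.
#' @param nknots number of knots (default 4).
#' @param knot_quantiles percentile placement of the knots.
#' @param grid_length number of points on the returned curve.
#' @return object of class \code{"thr_rcs"}: \code{knots}, \code{fit}
#'   (a \code{"thr_cox"}), \code{curve} (data.frame x, log_hr), and
#'   \code{p_nonlinear}.
#' @export
rcs_dose_response <- function(times, events, x, nknots = 4,
                              knot_quantiles = c(.05, .35, .65, .95),
                              grid_length = 100) {
  assert_that(length(times) >= 20, "need >= 20 subjects")
  assert_that(length(unique(x)) >= nknots, "x needs >= %d distinct values",
              nknots)
  knots <- unname(stats::quantile(x, knot_quantiles[seq_len(nknots)], type = 7))
  assert_that(!anyDuplicated(knots) && !is.unsorted(knots, strictly = TRUE),
              "knot collision: duplicate percentile values of x")
  basis <- rcs_basis(x, knots)
  fit <- cox_fit(times, events, as.data.frame(basis))
  beta <- coef(fit)
  nl <- grep("^`?nl", names(beta))
  V <- stats::vcov(fit$fit)[nl, nl, drop = FALSE]
  w <- as.numeric(t(beta[nl]) %*% solve(V) %*% beta[nl])
  p_nl <- stats::pchisq(w, df = length(nl), lower.tail = FALSE)
  grid <- seq(min(x), max(x), length.out = grid_length)
  gb <- rcs_basis(grid, knots)
  ref <- rcs_basis(knots[1], knots)
  log_hr <- as.numeric((gb - matrix(ref, nrow(gb), ncol(gb),
                                    byrow = TRUE)) %*% beta)
  structure(list(knots = knots, fit = fit,
                 curve = data.frame(x = grid, log_hr = log_hr),
                 wald = w, p_nonlinear = p_nl),
            class = "thr_rcs")
}

#' @export
print.thr_rcs <- function(x, ...) {
  cat(sprintf(
    "Restricted cubic spline dose-response (%d knots at %s)\n  nonlinearity Wald chi2 = %.2f, p = %.3g\n",
    length(x$knots), paste(sprintf("%.3g", x$knots), collapse = ", "),
    x$wald, x$p_nonlinear))
  invisible(x)
}

# Censoring-distribution KM, returned as step functions G(t) and G(t-).
censoring_survfit <- function(times, events) {
  fit <- survival::survfit(
    survival::Surv(times, 1 - as.numeric(events)) ~ 1)
  sf <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  list(at = function(t) sf(t),
       at_minus = function(t) {
         vapply(t, function(u) if (any(fit$time < u))
           min(c(1, fit$surv)[seq_len(sum(fit$time < u) + 1L)]) else 1,
           numeric(1))
       })
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls, IPCW)
#'
#' At horizon t, cases are subjects with an observed event by t (weight
#' 1/G(T-)), controls are subjects still at risk beyond t (weight 1/G(t)),
#' where G is the Kaplan-Meier estimate of the censoring distribution.
#' Subjects censored before t carry weight 0. The AUC is the weighted
#' probability that a random case carries a larger marker than a random
#' control, ties counting one half.
#'
#' @param times,events survival data.
#' @param marker risk marker (larger = higher risk).
#' @param horizons months at which to evaluate (each must not exceed the last
#'   event time and must be preceded by at least one event).
#' @return data.frame: horizon, auc, n_cases, n_controls.
#' @export
timedep_roc <- function(times, events, marker, horizons) {
  events <- as.logical(events)
  G <- censoring_survfit(times, events)
  last_event <- max(times[events])
  out <- lapply(horizons, function(h) {
    assert_that(h <= last_event, "horizon %g beyond last event time %g",
                h, last_event)
    case <- times <= h & events
    ctrl <- times > h
    assert_that(any(case), "no events before horizon %g", h)
    wc <- 1 / G$at_minus(times[case])
    wk <- rep(1 / G$at(h), sum(ctrl))
    mc <- marker[case]; mk <- marker[ctrl]
    # weighted Mann-Whitney via outer comparison (cohort-scale n, fine)
    comp <- outer(mc, mk, ">") + 0.5 * outer(mc, mk, "==")
    auc <- sum((wc %o% wk) * comp) / (sum(wc) * sum(wk))
    data.frame(horizon = h, auc = auc, n_cases = sum(case),
               n_controls = sum(ctrl))
  })
  do.call(rbind, out)
}

#' Contingency table test (Yates chi-square or Fisher)
#'
#' 2x2 chi-square tests use the Yates continuity correction. In
#' \code{"auto"} mode the test switches to Fisher's exact test whenever any
#' expected cell count falls below 5. Fisher p-values are two-sided by the
#' point-probability rule.
#'
#' @param table non-negative integer matrix with non-degenerate margins.
#' @param mode \code{"auto"}, \code{"chisq_yates"} or \code{"fisher"}.
#' @return object of class \code{"thr_contingency"}: table, test_used,
#'   statistic (NA for Fisher), p_value, odds_ratio (2x2 only).
#' @export
contingency_test <- function(table, mode = c("auto", "chisq_yates", "fisher")) {
  mode <- match.arg(mode)
  table <- as.matrix(table)
  assert_that(all(table >= 0) && all(table == round(table)),
              "table must contain non-negative integers")
  assert_that(all(rowSums(table) > 0) && all(colSums(table) > 0),
              "degenerate margins: zero row or column")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (mode == "auto") {
    mode <- if (any(expected < 5)) "fisher" else "chisq_yates"
  }
  or <- if (all(dim(table) == c(2, 2))) {
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  } else NA_real_
  if (mode == "fisher") {
    ft <- stats::fisher.test(table)
    res <- list(statistic = NA_real_, p_value = ft$p.value,
                odds_ratio = if (all(dim(table) == c(2, 2)))
                  unname(ft$estimate) else NA_real_)
  } else {
    ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
    res <- list(statistic = unname(ct$statistic), p_value = ct$p.value,
                odds_ratio = or)
  }
  structure(c(list(table = table, test_used = mode), res),
            class = "thr_contingency")
}

#' @export
print.thr_contingency <- function(x, ...) {
  cat(sprintf("%s: p = %.4g%s\n",
              if (x$test_used == "fisher") "Fisher exact test" else
                "Chi-square (Yates)",
              x$p_value,
              if (!is.na(x$statistic)) sprintf(" (X2 = %.3f)", x$statistic)
              else ""))
  invisible(x)
}

#' Nonparametric comparison of a continuous variable across groups
#'
#' Two groups route to the Wilcoxon rank-sum test, three or more to
#' Kruskal-Wallis.
#'
#' @param values numeric vector.
#' @param group grouping vector (>= 2 subjects per group).
#' @return list with \code{test_used} and \code{p_value}.
#' @export
group_compare_continuous <- function(values, group) {
  group <- droplevels(as.factor(group))
  assert_that(all(table(group) >= 2), "need >= 2 subjects per group")
  assert_that(length(unique(values)) > 1, "constant data")
  if (nlevels(group) == 2) {
    lv <- levels(group)
    p <- suppressWarnings(stats::wilcox.test(values[group == lv[1]],
                                             values[group == lv[2]]))$p.value
    list(test_used = "wilcoxon", p_value = p)
  } else {
    list(test_used = "kruskal_wallis",
         p_value = stats::kruskal.test(values, group)$p.value)
  }
}

#' Post-hoc power for a two-group survival comparison
#'
#' Schoenfeld's formula: power = Phi(sqrt(d p (1-p)) |log hr| - z_{1-alpha/2})
#' for d events allocated in proportions p / (1-p).
#'
#' @param n_events observed number of events d.
#' @param hr hazard ratio (> 0).
#' @param allocation fraction in the index group (0 < p < 1).
#' @param alpha two-sided significance level.
#' @return power in [0, 1].
#' @export
schoenfeld_power <- function(n_events, hr, allocation = 0.5, alpha = 0.05) {
  assert_that(all(hr > 0), "hr must be > 0")
  assert_that(all(allocation > 0 & allocation < 1),
              "allocation must be in (0,1)")
  stats::pnorm(sqrt(n_events * allocation * (1 - allocation)) * abs(log(hr)) -
                 stats::qnorm(1 - alpha / 2))
}
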
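#' Absolute event risk at a horizon from a Cox model
#'
#' risk = 1 - S(t | x) from the fitted model's baseline hazard. With
#' \code{covariates = NULL} the marginal Kaplan-Meier risk is returned
#' (identical for every subject).
#'
#' @param times,events survival data used to fit the model.
#' @param covariates data.frame of model covariates, or NULL for the null
#'   model.
#' @param horizon months; must not exceed the last event time.
#' @param newdata covariates at which to evaluate (defaults to the fitting
#'   data).
#' @return numeric vector of event probabilities by the horizon.
#' @export
risk_at_horizon <- function(times, events, covariates = NULL, horizon,
                            newdata = covariates) {
  events <- as.numeric(events)
  assert_that(horizon <= max(times[events == 1]),
              "horizon %g beyond last event time", horizon)
  if (is.null(covariates)) {
    km <- km_estimate(times, events)
    s <- c(1, km$surv)[findInterval(horizon, km$time) + 1L]
    return(rep(1 - s, length(times)))
  }
  fit <- cox_fit(times, events, covariates)
  sf <- survival::survfit(fit$fit, newdata = as.data.frame(newdata))
  idx <- findInterval(horizon, sf$time)
  s <- if (idx == 0) rep(1, ncol(as.matrix(sf$surv))) else
    as.matrix(sf$surv)[idx, ]
  unname(1 - s)
}

# IPCW status and weights at a horizon: cases (event by t) weighted by
# 1/G(T-), controls (at risk beyond t) by 1/G(t), censored-before-t weight 0.
ipcw_at_horizon <- function(times, events, horizon) {
  events <- as.logical(events)
  G <- censoring_survfit(times, events)
  status <- ifelse(times <= horizon & events, "case",
                   ifelse(times > horizon, "control", "censored"))
  w <- numeric(length(times))
  w[status == "case"] <- 1 / G$at_minus(times[status == "case"])
  w[status == "control"] <- 1 / G$at(horizon)
  data.frame(status = status, weight = w, stringsAsFactors = FALSE)
}

#' Time-dependent IDI and continuous NRI at a horizon
#'
#' Compares the event risks of a base model and an extended model at a fixed
#' horizon under censoring, using inverse-probability-of-censoring weights.
#' IDI is the gain in discrimination slope:
#' \deqn{IDI = [\bar r_{new}^{case} - \bar r_{new}^{ctrl}] -
#'       [\bar r_{base}^{case} - \bar r_{base}^{ctrl}]}
#' with weighted means. The continuous NRI is
#' \eqn{E_w[sign(r_{new}-r_{base}) | case] - E_w[sign(...) | control]}; exact
#' ties contribute 0. Without censoring the weights are all 1 and both reduce
#' to the plain Pencina formulas.
#'
#' @param risk_base,risk_new event probabilities by the horizon under each
#'   model (in [0, 1]).
#' @param times,events survival data.
#' @param horizon months.
#' @return list with \code{idi}, \code{nri}, \code{n_cases},
#'   \code{n_controls}.
#' @export
idi_nri_at_horizon <- function(risk_base, risk_new, times, events, horizon) {
  assert_that(all(risk_base >= 0 & risk_base <= 1) &&
                all(risk_new >= 0 & risk_new <= 1),
              "risks must lie in [0, 1]")
  w <- ipcw_at_horizon(times, events, horizon)
  case <- w$status == "case"; ctrl <- w$status == "control"
  assert_that(any(case), "no cases by the horizon")
  assert_that(any(ctrl), "no controls beyond the horizon")
  wmean <- function(x, sel) sum(x[sel] * w$weight[sel]) / sum(w$weight[sel])
  idi <- (wmean(risk_new, case) - wmean(risk_new, ctrl)) -
    (wmean(risk_base, case) - wmean(risk_base, ctrl))
  sgn <- sign(risk_new - risk_base)
  nri <- wmean(sgn, case) - wmean(sgn, ctrl)
  list(idi = idi, nri = nri, n_cases = sum(case), n_controls = sum(ctrl))
}

#' Bootstrap percentile CI and p-value for a statistic
#'
#' Nonparametric bootstrap over patients (rows of \code{data}). The
#' two-sided p-value inverts the null-centered resampling distribution:
#' the resampled statistics are re-centered at zero and p is twice the
#' smaller tail probability of the observed value. Degenerate resamples
#' (statistic errors or returns NA) are dropped, with a warning when they
#' stay below 5\% of B and an error otherwise.
#'
#' @param statistic_fn function(data) -> scalar.
#' @param data data.frame resampled by rows.
#' @param B number of bootstrap replicates (>= 100).
#' @param seed integer seed, or NULL.
#' @param conf confidence level (default 0.95).
#' @return list with \code{estimate}, \code{ci} (length 2), \code{p_value},
#'   \code{B_effective}, \code{replicates}.
#' @export
resample_ci <- function(statistic_fn, data, B = 500, seed = NULL,
                        conf = 0.95) {
  assert_that(B >= 100, "B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  est <- statistic_fn(data)
  n <- nrow(data)
  reps <- rep(NA_real_, B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    reps[b] <- tryCatch(statistic_fn(data[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
  }
  bad <- sum(is.na(reps))
  if (bad > 0.05 * B) {
    stop_thr("%d/%d bootstrap replicates degenerate", bad, B)
  }
  if (bad > 0) warning(sprintf("%d/%d degenerate bootstrap replicates dropped",
                               bad, B))
  ok <- reps[!is.na(reps)]
  alpha <- 1 - conf
  ci <- unname(stats::quantile(ok, c(alpha / 2, 1 - alpha / 2), type = 7))
  centered <- ok - mean(ok)  # resampled null distribution centered at 0
  p <- 2 * min(mean(centered >= est), mean(centered <= est))
  p <- min(max(p, 1 / length(ok)), 1)
  list(estimate = est, ci = ci, p_value = p, B_effective = length(ok),
       replicates = ok)
}

#' Risk-model comparison report: base model vs base + THRscore group
#'
#' Fits both Cox models, evaluates risks at the horizon, computes IPCW IDI
#' and continuous NRI, and attaches bootstrap percentile CIs and p-values.
#'
#' @param times,events survival data.
#' @param base_covariates data.frame for the base model (e.g. the RECIST
#'   best-response category).
#' @param added_covariates data.frame of the additional marker columns (e.g.
#'   the THRscore group).
#' @param horizon months (default 12).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return object of class \code{"thr_reclass"} with idi/nri estimates, CIs,
#'   p-values and configuration; \code{as_report_json()} serializes it.
#' @export
idi_nri_compare <- function(times, events, base_covariates, added_covariates,
                            horizon = 12, B = 500, seed = NULL) {
  dat <- cbind(data.frame(.time = times, .event = as.numeric(events)),
               base_covariates, added_covariates)
  base_nm <- names(as.data.frame(base_covariates))
  new_nm <- c(base_nm, names(as.data.frame(added_covariates)))
  stat_pair <- function(d) {
    rb <- risk_at_horizon(d$.time, d$.event, d[, base_nm, drop = FALSE],
                          horizon)
    rn <- risk_at_horizon(d$.time, d$.event, d[, new_nm, drop = FALSE],
                          horizon)
    idi_nri_at_horizon(rb, rn, d$.time, d$.event, horizon)
  }
  idi_fn <- function(d) stat_pair(d)$idi
  nri_fn <- function(d) stat_pair(d)$nri
  idi_boot <- resample_ci(idi_fn, dat, B = B, seed = seed)
  nri_boot <- resample_ci(nri_fn, dat, B = B,
                          seed = if (is.null(seed)) NULL else seed + 1L)
  structure(list(horizon_months = horizon,
                 idi = idi_boot$estimate, idi_ci = idi_boot$ci,
                 idi_p = idi_boot$p_value,
                 nri = nri_boot$estimate, nri_ci = nri_boot$ci,
                 nri_p = nri_boot$p_value,
                 B = B, seed = seed,
                 base_model = base_nm, new_model = new_nm),
            class = "thr_reclass")
}

#' @export
print.thr_reclass <- function(x, ...) {
  cat(sprintf("Risk reclassification at %g months (base: %s; added: %s)\n",
              x$horizon_months, paste(x$base_model, collapse = "+"),
              paste(setdiff(x$new_model, x$base_model), collapse = "+")))
  cat(sprintf("  IDI %.3f (95%% CI %.3f to %.3f, p = %.3g)\n",
              x$idi, x$idi_ci[1], x$idi_ci[2], x$idi_p))
  cat(sprintf("  NRI %.3f (95%% CI %.3f to %.3f, p = %.3g)\n",
              x$nri, x$nri_ci[1], x$nri_ci[2], x$nri_p))
  invisible(x)
}
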
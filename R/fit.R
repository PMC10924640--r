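#' Fit the heterogeneity-response model to a cohort
#'
#' The end-to-end estimator: per-patient THRscores at the evaluation visit,
#' an outcome-driven cutoff (either supplied or discovered by the
#' subsampled maximally selected rank statistic), high/low group assignment,
#' and the group-level survival contrast (Kaplan-Meier per group, log-rank
#' test, Cox hazard ratio).
#'
#' @param cohort a [thr_cohort()] with outcomes.
#' @param eval_timepoint evaluation visit label (the 4-6 week scan).
#' @param cutoff numeric cutoff, or \code{"consensus"} to discover it via
#'   [consensus_cutoff()] on this cohort.
#' @param replicates subsample replicates for the consensus cutoff.
#' @param subsample,minprop see [consensus_cutoff()].
#' @param seed integer seed for the consensus subsampling.
#' @param sd_type THRscore standard-deviation convention, see [thr_score()].
#' @return object of class \code{"thr_fit"} with components \code{scores}
#'   (per-patient table with group and quintile), \code{cutoff},
#'   \code{consensus} (NULL when the cutoff was supplied), \code{km}
#'   (per-group [km_estimate()]s), \code{logrank}, \code{cox}
#'   (group hazard ratio), and \code{data}.
#' @export
thr_fit <- function(cohort, eval_timepoint = "week6", cutoff = "consensus",
                    replicates = 1000, subsample = 0.7, minprop = 0.3,
                    seed = NULL, sd_type = "population") {
  scores <- thr_score_cohort(cohort, eval_timepoint, sd_type)
  out <- outcome_table(cohort)
  dat <- merge(scores, out, by = "patient_id", sort = TRUE)
  assert_that(nrow(dat) == nrow(scores),
              "every scored patient needs an outcome record")
  consensus <- NULL
  if (identical(cutoff, "consensus")) {
    consensus <- consensus_cutoff(dat$pfs_months, dat$event, dat$thrscore,
                                  R = replicates, subsample = subsample,
                                  minprop = minprop, seed = seed)
    cutoff <- consensus$consensus
  }
  dat <- assign_groups(dat, cutoff)
  dat$quintile <- quintile_assign(dat$thrscore)
  km <- lapply(split(dat, dat$group), function(d)
    km_estimate(d$pfs_months, d$event))
  lr <- logrank_test(dat$pfs_months, dat$event, dat$group)
  cox <- cox_fit(dat$pfs_months, dat$event,
                 data.frame(group = dat$group))
  structure(list(scores = dat, cutoff = cutoff, consensus = consensus,
                 eval_timepoint = eval_timepoint, km = km, logrank = lr,
                 cox = cox, sd_type = sd_type),
            class = "thr_fit")
}

#' @export
print.thr_fit <- function(x, ...) {
  sz <- table(x$scores$group)
  cat("Intertumoral heterogeneity response model\n")
  cat(sprintf("  %d patients, cutoff %.2f%s: %d low / %d high\n",
              nrow(x$scores), x$cutoff,
              if (is.null(x$consensus)) " (fixed)" else
                sprintf(" (consensus of %d subsamples)",
                        length(x$consensus$replicate_cutoffs)),
              sz[["low"]], sz[["high"]]))
  med <- vapply(x$km, function(k)
    if (k$median_defined) k$median else NA_real_, numeric(1))
  cat(sprintf("  median PFS: low %s, high %s months\n",
              ifelse(is.na(med[["low"]]), "NR", sprintf("%.1f", med[["low"]])),
              ifelse(is.na(med[["high"]]), "NR", sprintf("%.1f", med[["high"]]))))
  co <- x$cox$coefficients
  cat(sprintf("  high vs low HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g\n",
              co$hr[1], co$ci_low[1], co$ci_high[1], x$logrank$p_value))
  invisible(x)
}

#' @export
summary.thr_fit <- function(object, ...) {
  q <- split(object$scores, object$scores$quintile)
  qmed <- vapply(q, function(d) {
    k <- km_estimate(d$pfs_months, d$event)
    if (k$median_defined) k$median else NA_real_
  }, numeric(1))
  out <- list(fit = object,
              quintile_median_pfs = qmed,
              score_summary = summary(object$scores$thrscore[
                is.finite(object$scores$thrscore)]))
  class(out) <- "summary.thr_fit"
  out
}

#' @export
print.summary.thr_fit <- function(x, ...) {
  print(x$fit)
  cat("  THRscore distribution (finite scores):\n")
  print(x$score_summary)
  cat("  median PFS by score quintile (months):\n")
  print(round(x$quintile_median_pfs, 1))
  invisible(x)
}

#' @export
coef.thr_fit <- function(object, ...) coef(object$cox)

#' Predict scores, groups or horizon risks for new patients
#'
#' @param object a \code{"thr_fit"}.
#' @param newdata a [thr_cohort()], or a list of per-patient z vectors
#'   (percentage changes).
#' @param type \code{"score"}, \code{"group"} or \code{"risk"} (event
#'   probability by \code{horizon} from the fitted group-level Cox model).
#' @param horizon months, for \code{type = "risk"}.
#' @param ... unused.
#' @return data.frame with patient_id (where known) and the requested column.
#' @export
predict.thr_fit <- function(object, newdata, type = c("score", "group", "risk"),
                            horizon = 12, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "thr_cohort")) {
    scores <- thr_score_cohort(newdata, object$eval_timepoint, object$sd_type)
  } else {
    scores <- data.frame(
      patient_id = names(newdata) %||% as.character(seq_along(newdata)),
      thrscore = vapply(newdata, function(z) thr_score(z, object$sd_type)$score,
                        numeric(1)),
      stringsAsFactors = FALSE)
  }
  scores$group <- factor(ifelse(scores$thrscore > object$cutoff,
                                "high", "low"), levels = c("low", "high"))
  if (type == "risk") {
    d <- object$scores
    scores$risk <- risk_at_horizon(d$pfs_months, d$event,
                                   data.frame(group = d$group), horizon,
                                   newdata = data.frame(group = scores$group))
  }
  cols <- c("patient_id", "thrscore",
            if (type %in% c("group", "risk")) "group",
            if (type == "risk") "risk")
  scores[, cols]
}

#' Kaplan-Meier plot of the fitted groups
#'
#' @param x a \code{"thr_fit"}.
#' @param ... passed to \code{plot.survfit}.
#' @export
plot.thr_fit <- function(x, ...) {
  d <- x$scores
  sf <- survival::survfit(
    survival::Surv(pfs_months, as.numeric(event)) ~ group, data = d)
  plot(sf, col = c("#2166AC", "#B2182B"), lwd = 2,
       xlab = "months", ylab = "progression-free survival", ...)
  graphics::legend("topright", bty = "n", lwd = 2,
                   col = c("#2166AC", "#B2182B"),
                   legend = sprintf("THRscore %s (n=%d)",
                                    levels(d$group), table(d$group)))
  invisible(x)
}

#' Write the per-patient score table to CSV
#'
#' @param fit a \code{"thr_fit"}.
#' @param path output CSV (patient_id, n_lesions, mean_z, sigma_z, thrscore,
#'   group, quintile).
#' @return the path, invisibly.
#' @export
write_score_table <- function(fit, path) {
  cols <- c("patient_id", "n_lesions", "mean_z", "sigma_z", "thrscore",
            "group", "quintile")
  utils::write.csv(fit$scores[, cols], path, row.names = FALSE)
  invisible(path)
}
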
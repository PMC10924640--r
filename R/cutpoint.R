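#' Log-rank scores for censored survival data
#'
#' Score a_i = delta_i - Lambda(t_i), where Lambda is the Nelson-Aalen
#' cumulative hazard evaluated at the subject's observed time (events at
#' exactly t_i included). The scores sum to zero exactly, up to floating
#' error, which makes the maximally selected statistic a centered linear rank
#' statistic.
#'
#' @param times observed times (months).
#' @param events logical/0-1 event indicators; at least one event required.
#' @return numeric vector of scores, one per subject.
#' @export
logrank_scores <- function(times, events) {
  events <- as.logical(events)
  n <- length(times)
  assert_that(n >= 2, "need at least 2 subjects")
  assert_that(any(events), "no events: log-rank scores undefined")
  ut <- sort(unique(times[events]))
  n_risk <- vapply(ut, function(u) sum(times >= u), numeric(1))
  d <- vapply(ut, function(u) sum(times == u & events), numeric(1))
  cumhaz <- cumsum(d / n_risk)
  # Lambda at each subject's own time (0 before the first event time)
  idx <- findInterval(times, ut)
  lam <- c(0, cumhaz)[idx + 1L]
  as.numeric(events) - lam
}

#' Maximally selected rank statistic scan
#'
#' Evaluates the standardized linear rank statistic at every admissible
#' cutpoint of \code{x}. Candidate cutpoints are midpoints between adjacent
#' distinct sorted values; a cutpoint is admissible when at least
#' \code{minprop} of the subjects fall on each side. For a split putting k
#' subjects at or below the cutpoint, the statistic is
#' \deqn{S = |sum_{x_i <= mu} a_i - k \bar a| / \sqrt{k (n-k)/(n-1) s^2_a}}
#' with \eqn{\bar a}, \eqn{s^2_a} the mean and population variance of all
#' scores. The best cutpoint maximizes S; ties go to the smallest cutpoint.
#'
#' @param x numeric marker values (e.g. THRscores; +Inf allowed).
#' @param scores per-subject scores, typically [logrank_scores()].
#' @param minprop minimum proportion of subjects per side (default 0.30; the
#'   upper admissibility bound is symmetric at 1 - minprop).
#' @return object of class \code{"maxsel_scan"}: candidate cutoffs,
#'   standardized statistics, best cutoff and statistic.
#' @export
maxsel_scan <- function(x, scores, minprop = 0.3) {
  n <- length(x)
  assert_that(n == length(scores), "x and scores must have equal length")
  ord <- order(x)
  xs <- x[ord]; as_ <- scores[ord]
  # k values at the boundary after each run of tied x values (except the last)
  distinct_end <- which(diff(xs) > 0)
  k <- distinct_end
  admissible <- k >= minprop * n & (n - k) >= minprop * n
  assert_that(any(admissible),
              "no admissible split under minprop = %g", minprop)
  k <- k[admissible]
  cand <- (xs[k] + xs[k + 1L]) / 2
  cand[!is.finite(cand)] <- xs[k][!is.finite(cand)]  # guard Inf neighbors
  abar <- mean(as_); s2 <- mean((as_ - abar)^2)
  csum <- cumsum(as_)
  stat <- abs(csum[k] - k * abar) / sqrt(k * (n - k) / (n - 1) * s2)
  best <- which.max(stat)  # first maximizer in sorted order
  structure(list(candidate_cutoffs = cand, statistics = stat,
                 best_cutoff = cand[best], best_statistic = stat[best],
                 minprop = minprop, n = n),
            class = "maxsel_scan")
}

#' @export
print.maxsel_scan <- function(x, ...) {
  cat(sprintf(
    "Maximally selected rank statistic (n=%d, minprop=%.2f)\n  best cutoff %.4g  (S = %.3f over %d candidates)\n",
    x$n, x$minprop, x$best_cutoff, x$best_statistic,
    length(x$candidate_cutoffs)))
  invisible(x)
}

#' @export
plot.maxsel_scan <- function(x, ...) {
  plot(x$candidate_cutoffs, x$statistics, type = "b", pch = 16,
       xlab = "candidate cutoff", ylab = "standardized statistic", ...)
  graphics::abline(v = x$best_cutoff, lty = 2)
  invisible(x)
}

#' Best survival cutpoint for a marker
#'
#' Convenience wrapper: log-rank scores for (times, events), then
#' [maxsel_scan()] over the marker.
#'
#' @inheritParams logrank_scores
#' @param x marker values.
#' @param minprop minimum proportion per side.
#' @return a \code{"maxsel_scan"} object.
#' @export
maxsel_cutpoint <- function(times, events, x, minprop = 0.3) {
  maxsel_scan(x, logrank_scores(times, events), minprop = minprop)
}

#' Consensus cutoff by repeated subsampling
#'
#' Draws R random subsamples (without replacement, default 70\% of subjects),
#' finds the maximally selected cutpoint in each, rounds the replicate
#' cutpoints (default 2 decimals), and returns the modal rounded value, with
#' ties broken toward the smaller cutoff. Replicates without an admissible
#' split (or without events) are dropped; more than 5\% failures is an error.
#' Fully reproducible from \code{seed}.
#'
#' @inheritParams maxsel_cutpoint
#' @param R number of subsample replicates (default 10000).
#' @param subsample subsample fraction (default 0.70).
#' @param rounding_decimals binning granularity for the consensus mode.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return object of class \code{"thr_consensus"}: \code{consensus},
#'   \code{replicate_cutoffs}, \code{histogram} (table of rounded values),
#'   \code{n_failed}, plus the configuration.
#' @export
consensus_cutoff <- function(times, events, x, R = 10000, subsample = 0.7,
                             minprop = 0.3, rounding_decimals = 2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(x)
  m <- max(2L, floor(subsample * n))
  reps <- rep(NA_real_, R)
  for (r in seq_len(R)) {
    idx <- sample.int(n, m)
    sc <- tryCatch(
      maxsel_cutpoint(times[idx], events[idx], x[idx], minprop = minprop),
      error = function(e) NULL)
    if (!is.null(sc)) reps[r] <- sc$best_cutoff
  }
  n_failed <- sum(is.na(reps))
  assert_that(n_failed <= 0.05 * R,
              "%.1f%% of replicates admit no split (max 5%% allowed)",
              100 * n_failed / R)
  ok <- reps[!is.na(reps)]
  rounded <- round(ok, rounding_decimals)
  structure(list(consensus = modal_value(ok, rounding_decimals),
                 replicate_cutoffs = ok, histogram = table(rounded),
                 n_failed = n_failed, R = R, subsample = subsample,
                 minprop = minprop, rounding_decimals = rounding_decimals,
                 seed = seed),
            class = "thr_consensus")
}

#' @export
print.thr_consensus <- function(x, ...) {
  cat(sprintf(
    "Consensus cutoff: %.2f  (mode of %d/%d subsample replicates at %.0f%%, minprop %.2f)\n",
    x$consensus, length(x$replicate_cutoffs), x$R, 100 * x$subsample,
    x$minprop))
  top <- sort(x$histogram, decreasing = TRUE)
  top <- utils::head(top, 5)
  cat("  top thresholds:",
      paste(sprintf("%s (%d)", names(top), as.integer(top)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write the replicate cutoff histogram to CSV
#'
#' @param consensus a \code{"thr_consensus"} object.
#' @param path output CSV (columns cutoff, count).
#' @return the path, invisibly.
#' @export
write_cutoff_histogram <- function(consensus, path) {
  df <- data.frame(cutoff = as.numeric(names(consensus$histogram)),
                   count = as.integer(consensus$histogram))
  utils::write.csv(df[order(df$cutoff), ], path, row.names = FALSE)
  invisible(path)
}
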
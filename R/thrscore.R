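#' Per-lesion percentage diameter changes
#'
#' z_i = 100 * (d_i(eval) - d_i(baseline)) / d_i(baseline) for every baseline
#' measurable lesion. The evaluation visit is the first follow-up scan, 4-6
#' weeks after the first treatment cycle. Lesions appearing after baseline
#' have no baseline diameter and never enter z.
#'
#' @param lesions list of [lesion_series()] for one patient.
#' @param eval_timepoint timepoint label of the evaluation visit.
#' @return numeric vector of percentage changes, one per lesion.
#' @export
lesion_percent_changes <- function(lesions, eval_timepoint) {
  assert_that(length(lesions) >= 1, "empty lesion list")
  vapply(lesions, function(l) {
    if (!eval_timepoint %in% names(l$diameters_mm)) {
      stop_thr("lesion %s/%s has no measurement at '%s'",
               l$patient_id, l$lesion_id, eval_timepoint)
    }
    b <- l$diameters_mm[["baseline"]]
    100 * (l$diameters_mm[[eval_timepoint]] - b) / b
  }, numeric(1))
}

#' Compute the intertumoral heterogeneity response score
#'
#' THRscore = sigma_z / |mean(z)|, the coefficient of variation of the
#' per-lesion percentage diameter changes taken against the absolute mean so
#' the score is non-negative whether lesions shrink or grow. sigma_z is the
#' population standard deviation (denominator n) by default; a sample
#' (denominator n-1) variant is available. Degenerate cases: zero dispersion
#' gives 0 (a perfectly homogeneous response, including all-zero z); positive
#' dispersion with a zero mean gives +Inf, which sorts above every finite
#' cutoff.
#'
#' @param z numeric vector of percentage changes (length >= 1).
#' @param sd_type \code{"population"} (default) or \code{"sample"}.
#' @return object of class \code{"thr_score"}: list with \code{n}, \code{z},
#'   \code{mean_z}, \code{sigma_z}, \code{score}.
#' @export
thr_score <- function(z, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  assert_that(length(z) >= 1 && all(is.finite(z)),
              "z must be a non-empty finite vector")
  m <- mean(z)
  s <- if (sd_type == "population") pop_sd(z) else stats::sd(z)
  if (length(z) == 1 && sd_type == "sample") s <- 0
  score <- if (s == 0) 0 else if (m == 0) Inf else s / abs(m)
  structure(list(n = length(z), z = z, mean_z = m, sigma_z = s,
                 score = score, sd_type = sd_type),
            class = "thr_score")
}

#' @export
print.thr_score <- function(x, ...) {
  cat(sprintf("THRscore: %s  (n=%d lesions, mean z=%.2f%%, sigma=%.2f%%)\n",
              formatC(x$score, digits = 4, format = "g"), x$n, x$mean_z,
              x$sigma_z))
  invisible(x)
}

#' THRscore table for a cohort
#'
#' @param cohort a [thr_cohort()].
#' @param eval_timepoint evaluation visit label (first follow-up scan).
#' @param sd_type passed to [thr_score()].
#' @return data.frame: patient_id, n_lesions, mean_z, sigma_z, thrscore.
#' @export
thr_score_cohort <- function(cohort, eval_timepoint = "week6",
                             sd_type = "population") {
  rows <- lapply(cohort$patients, function(p) {
    z <- lesion_percent_changes(p$lesions, eval_timepoint)
    r <- thr_score(z, sd_type)
    data.frame(patient_id = p$patient_id, n_lesions = r$n, mean_z = r$mean_z,
               sigma_z = r$sigma_z, thrscore = r$score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign high/low THRscore groups at a cutoff
#'
#' A patient is \code{high} iff score > cutoff (strict inequality; a score
#' exactly at the cutoff is \code{low}); +Inf scores are always high. The
#' boundary rule is recorded in the result's attributes.
#'
#' @param scores numeric vector of THRscores, or the data.frame from
#'   [thr_score_cohort()].
#' @param cutoff finite positive cutoff.
#' @return if given a data.frame, the data.frame with a \code{group} column;
#'   otherwise a factor with levels \code{low}, \code{high}. Attributes:
#'   \code{cutoff}, \code{boundary} ("score > cutoff is high"),
#'   \code{group_sizes}.
#' @export
assign_groups <- function(scores, cutoff) {
  assert_that(is.finite(cutoff) && cutoff > 0, "cutoff must be finite and > 0")
  df <- NULL
  if (is.data.frame(scores)) { df <- scores; scores <- scores$thrscore }
  grp <- factor(ifelse(scores > cutoff, "high", "low"),
                levels = c("low", "high"))
  if (!is.null(df)) {
    df$group <- grp
    out <- df
  } else out <- grp
  attr(out, "cutoff") <- cutoff
  attr(out, "boundary") <- "score > cutoff is high"
  attr(out, "group_sizes") <- table(grp)
  out
}

#' Assign THRscore quintiles
#'
#' Quintile boundaries sit at the 20/40/60/80th empirical percentiles of the
#' scores; values tied at a boundary share the lower quintile. Requires at
#' least 5 distinct finite scores.
#'
#' @param scores numeric vector (may include +Inf, which lands in quintile 5).
#' @return integer vector of quintiles 1-5.
#' @export
quintile_assign <- function(scores) {
  finite <- scores[is.finite(scores)]
  assert_that(length(scores) >= 5 && length(unique(finite)) >= 5,
              "need >= 5 patients with distinct finite scores")
  qs <- stats::quantile(finite, probs = c(.2, .4, .6, .8), names = FALSE)
  as.integer(cut(scores, breaks = c(-Inf, qs, Inf), labels = FALSE,
                 right = TRUE))
}
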
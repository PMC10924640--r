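#' Sum of diameters at a timepoint
#'
#' Arithmetic sum over the target lesions, each measured on its designated
#' axis (longest diameter for non-nodal lesions, short axis for nodes).
#'
#' @param lesions list of [lesion_series()].
#' @param timepoint timepoint label; every lesion must carry a measurement.
#' @return sum in mm.
#' @export
sum_of_diameters <- function(lesions, timepoint) {
  assert_that(length(lesions) >= 1, "empty lesion list")
  vals <- vapply(lesions, function(l) {
    if (!timepoint %in% names(l$diameters_mm)) {
      stop_thr("lesion %s/%s has no measurement at '%s'",
               l$patient_id, l$lesion_id, timepoint)
    }
    l$diameters_mm[[timepoint]]
  }, numeric(1))
  sum(vals)
}

recist_levels <- c("CR", "PR", "SD", "PD")

#' Classify one RECIST 1.1 assessment
#'
#' Category precedence is PD > CR > PR > SD. PD requires a >= 20\% increase
#' from the nadir sum AND a >= 5 mm absolute increase, or any new lesion.
#' CR requires disappearance of all non-nodal target lesions with all nodal
#' short axes below 10 mm. PR requires a >= 30\% decrease from the baseline
#' sum. Thresholds are compared inclusively at full floating precision
#' (-30.0\% is PR; +20.0\% with +5.0 mm is PD).
#'
#' @param sum_mm current sum of diameters.
#' @param baseline_sum baseline sum (> 0).
#' @param nadir_sum smallest sum observed up to and including the current
#'   assessment.
#' @param new_lesion any unequivocal new lesion at this assessment.
#' @param nonnodal_disappeared all non-nodal target lesions measure 0 mm;
#'   defaults to \code{sum_mm == 0}, which is exact when no lesion is nodal.
#' @param nodes_normalized all nodal short axes < 10 mm (vacuously TRUE
#'   without nodes). Nodal normalization for CR is applied via this flag.
#' @return one of \code{"CR"}, \code{"PR"}, \code{"SD"}, \code{"PD"}.
#' @export
classify_timepoint <- function(sum_mm, baseline_sum, nadir_sum,
                               new_lesion = FALSE,
                               nonnodal_disappeared = sum_mm == 0,
                               nodes_normalized = TRUE) {
  assert_that(baseline_sum > 0, "baseline_sum must be > 0")
  assert_that(nadir_sum <= baseline_sum + 1e-9,
              "nadir_sum cannot exceed baseline_sum")
  pct_nadir <- if (nadir_sum > 0) 100 * (sum_mm - nadir_sum) / nadir_sum else
    ifelse(sum_mm > 0, Inf, 0)
  abs_nadir <- sum_mm - nadir_sum
  if (isTRUE(new_lesion) || (pct_nadir >= 20 && abs_nadir >= 5)) return("PD")
  if (isTRUE(nonnodal_disappeared) && isTRUE(nodes_normalized)) return("CR")
  pct_base <- 100 * (sum_mm - baseline_sum) / baseline_sum
  if (pct_base <= -30) return("PR")
  "SD"
}

#' Assess a patient's lesion series over all follow-up visits
#'
#' Builds the per-timepoint assessment table: sum of diameters, percent
#' change from baseline, percent and absolute change from the nadir (the
#' running minimum sum including the current visit), and the RECIST category.
#'
#' @param lesions list of [lesion_series()] for one patient; all series must
#'   share the same timepoint grid.
#' @param new_lesion_timepoints timepoint labels at which a new lesion was
#'   detected (new lesions set PD but never enter the sums).
#' @return data.frame with one row per post-baseline timepoint: patient_id,
#'   timepoint, sum_mm, pct_baseline, pct_nadir, abs_nadir, new_lesion,
#'   category.
#' @export
recist_assess <- function(lesions, new_lesion_timepoints = character(0)) {
  assert_that(length(lesions) >= 1, "empty lesion list")
  tps <- names(lesions[[1]]$diameters_mm)
  assert_that(length(tps) >= 2, "need at least one post-baseline timepoint")
  node <- vapply(lesions, function(l) l$is_node, logical(1))
  sums <- vapply(tps, function(tp) sum_of_diameters(lesions, tp), numeric(1))
  baseline_sum <- sums[[1]]
  out <- vector("list", length(tps) - 1L)
  for (i in 2:length(tps)) {
    tp <- tps[i]
    nadir <- min(sums[1:i])
    d_now <- vapply(lesions, function(l) l$diameters_mm[[tp]], numeric(1))
    newly <- tp %in% new_lesion_timepoints
    cat_i <- classify_timepoint(sums[i], baseline_sum, nadir,
                                new_lesion = newly,
                                nonnodal_disappeared = all(d_now[!node] == 0),
                                nodes_normalized = all(d_now[node] < 10))
    out[[i - 1L]] <- data.frame(
      patient_id = lesions[[1]]$patient_id, timepoint = tp,
      sum_mm = sums[i], pct_baseline = 100 * (sums[i] - baseline_sum) / baseline_sum,
      pct_nadir = if (nadir > 0) 100 * (sums[i] - nadir) / nadir else 0,
      abs_nadir = sums[i] - nadir, new_lesion = newly, category = cat_i,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Best overall response and ORR flag
#'
#' The best category across visits with ordering CR > PR > SD, where a PD
#' visit caps the sequence: categories after the first PD are ignored, and a
#' patient whose first assessment is PD is PD. By default a single qualifying
#' visit confirms a response; \code{confirm = TRUE} additionally requires the
#' category (or better) on a second, later visit.
#'
#' @param categories character vector of per-visit categories in visit order.
#' @param confirm require a second qualifying visit for CR/PR.
#' @return list with \code{best} and \code{orr_flag} (TRUE iff best is CR/PR).
#' @export
best_overall_response <- function(categories, confirm = FALSE) {
  assert_that(length(categories) >= 1, "empty assessment list")
  assert_that(all(categories %in% recist_levels),
              "categories must be CR/PR/SD/PD")
  pd_at <- match("PD", categories)
  upto <- if (is.na(pd_at)) categories else categories[seq_len(pd_at)]
  rank <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  qualifies <- function(cat) {
    hits <- which(rank[upto] <= rank[[cat]])
    if (!confirm) length(hits) >= 1 else length(hits) >= 2
  }
  best <- "PD"
  for (cat in c("CR", "PR", "SD")) {
    if (cat %in% upto && qualifies(cat)) { best <- cat; break }
  }
  # an unconfirmed response without any PD visit falls back to SD, not PD
  if (best == "PD" && is.na(pd_at)) best <- "SD"
  list(best = best, orr_flag = best %in% c("CR", "PR"))
}

#' Derive the PFS outcome from assessments
#'
#' The event time is the earlier of the first progression and death from any
#' cause; patients with neither are censored at the last scan.
#'
#' @param assess_times months of each assessment, in visit order.
#' @param categories RECIST category at each assessment.
#' @param death_time months, or NA if alive.
#' @param last_scan months of the last scan; required when no event occurred.
#' @param patient_id identifier carried into the outcome.
#' @return an [outcome_record()].
#' @export
derive_pfs <- function(assess_times, categories, death_time = NA,
                       last_scan = NA, patient_id = "?") {
  assert_that(length(assess_times) == length(categories),
              "assess_times and categories must align")
  pd_at <- match("PD", categories)
  pd_time <- if (is.na(pd_at)) NA_real_ else assess_times[pd_at]
  cand <- c(pd_time, death_time)
  if (all(is.na(cand))) {
    assert_that(!is.na(last_scan),
                "patient %s: last_scan required when no event observed",
                patient_id)
    return(outcome_record(patient_id, last_scan, event = FALSE))
  }
  outcome_record(patient_id, min(cand, na.rm = TRUE), event = TRUE)
}

#' Assessment tables for a whole cohort
#'
#' @param cohort a [thr_cohort()].
#' @return data.frame stacking [recist_assess()] over patients, plus a
#'   \code{best} and \code{orr_flag} column per patient row via
#'   [best_overall_response()].
#' @export
recist_assess_cohort <- function(cohort) {
  tabs <- lapply(cohort$patients, function(p) recist_assess(p$lesions))
  assess <- do.call(rbind, tabs)
  rownames(assess) <- NULL
  best <- vapply(tabs, function(tb) best_overall_response(tb$category)$best,
                 character(1))
  summary <- data.frame(patient_id = names(tabs), best = best,
                        orr_flag = best %in% c("CR", "PR"),
                        stringsAsFactors = FALSE, row.names = NULL)
  list(assessments = assess, best = summary)
}
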
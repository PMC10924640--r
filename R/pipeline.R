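#' Run the full analysis pipeline on a synthetic or supplied cohort
#'
#' Orchestrates: cohort simulation (or ingestion), RECIST assessment,
#' THRscore computation, consensus cutoff discovery, group survival analysis
#' (Kaplan-Meier, log-rank, Cox with univariate screen, quintiles,
#' time-dependent ROC), risk reclassification (IPCW NRI/IDI at a horizon),
#' and group-wise genomic comparison on simulated panel calls. All tables are
#' written as CSV next to a JSON + Markdown report; the run manifest records
#' the seed and a configuration hash, and a rerun with the same seed and
#' configuration writes byte-identical reports.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()]; its seed drives every random draw.
#' @param cohort optionally, a pre-built [thr_cohort()] (skips simulation;
#'   genomics are still simulated from the fitted groups).
#' @param cutoff \code{"consensus"} or a fixed numeric cutoff.
#' @param replicates consensus subsample replicates.
#' @param horizons months for the time-dependent ROC.
#' @param nri_horizon months for the NRI/IDI comparison.
#' @param nri_B bootstrap replicates for the NRI/IDI CIs.
#' @param with_genomics simulate and analyze panel variants.
#' @return invisibly, the report list (also written to
#'   \code{out_dir/report.json} and \code{report.md}).
#' @export
run_thr_pipeline <- function(out_dir, config = sim_config(), cohort = NULL,
                             cutoff = "consensus", replicates = 1000,
                             horizons = c(6, 12, 18), nri_horizon = 12,
                             nri_B = 200, with_genomics = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  if (is.null(cohort)) {
    sim <- simulate_cohort(config)
    cohort <- sim$cohort
  }
  fit <- thr_fit(cohort, cutoff = cutoff, replicates = replicates,
                 seed = config$seed + 1L)
  d <- fit$scores

  recist <- recist_assess_cohort(cohort)
  utils::write.csv(recist$assessments, file.path(out_dir, "assessments.csv"),
                   row.names = FALSE)
  best <- recist$best[match(d$patient_id, recist$best$patient_id), ]
  orr_by_group <- table(d$group, best$orr_flag)

  write_score_table(fit, file.path(out_dir, "scores.csv"))
  if (!is.null(fit$consensus)) {
    write_cutoff_histogram(fit$consensus, file.path(out_dir, "cutoff_histogram.csv"))
  }

  # covariate screen: clinical covariates + group, univariate gate p < 0.05
  clin <- do.call(rbind, lapply(cohort$patients, function(p) {
    data.frame(patient_id = p$patient_id, age = p$age, sex = p$sex,
               smoking = p$smoking, ecog_ps = p$ecog_ps,
               brain_met = p$brain_met, bone_met = p$bone_met,
               adrenal_met = p$adrenal_met, liver_met = p$liver_met,
               driver_status = p$driver_status, treatment = p$treatment,
               stringsAsFactors = FALSE)
  }))
  clin <- clin[match(d$patient_id, clin$patient_id), ]
  covs <- data.frame(group = d$group, age = clin$age,
                     sex = factor(clin$sex), smoking = clin$smoking,
                     ecog_ps = clin$ecog_ps, treatment = factor(clin$treatment))
  screen <- cox_screen(d$pfs_months, d$event, covs)
  forest <- fit$cox$coefficients
  if (!is.null(screen$multivariable)) {
    forest <- rbind(forest, screen$multivariable$coefficients)
  }
  utils::write.csv(forest, file.path(out_dir, "cox_forest.csv"),
                   row.names = FALSE)

  roc <- timedep_roc(d$pfs_months, d$event,
                     ifelse(is.finite(d$thrscore), d$thrscore,
                            max(d$thrscore[is.finite(d$thrscore)]) * 10),
                     horizons = horizons)
  utils::write.csv(roc, file.path(out_dir, "timedep_roc.csv"),
                   row.names = FALSE)

  reclass <- idi_nri_compare(
    d$pfs_months, d$event,
    base_covariates = data.frame(response = factor(best$best)),
    added_covariates = data.frame(group = d$group),
    horizon = nri_horizon, B = nri_B, seed = config$seed + 2L)

  genomics <- NULL
  if (with_genomics) {
    calls <- simulate_variants(d[, c("patient_id", "group")],
                               seed = config$seed + 3L)
    kept <- filter_somatic(calls)$kept
    panel <- panel_spec("synthetic-20", default_panel_genes(), 0.7)
    tmb <- tmb_by_patient(kept, panel)
    tmb <- merge(tmb, d[, c("patient_id", "group")], by = "patient_id")
    mat <- alteration_matrix(kept, patients = d$patient_id)
    gene_cmp <- gene_frequency_compare(mat, d$group)
    utils::write.csv(gene_cmp, file.path(out_dir, "gene_comparison.csv"),
                     row.names = FALSE)
    med_by <- tapply(tmb$tmb, tmb$group, stats::median)
    genomics <- list(
      n_calls = nrow(calls), n_kept = nrow(kept),
      median_tmb = as.list(med_by),
      tmb_p = if (length(unique(tmb$group)) == 2 &&
                  length(unique(tmb$tmb)) > 1)
        group_compare_continuous(tmb$tmb, tmb$group)$p_value else NA,
      n_significant_genes = sum(gene_cmp$p_value < 0.05))
  }

  quint <- summary(fit)$quintile_median_pfs
  med <- vapply(fit$km, function(k)
    if (k$median_defined) k$median else NA_real_, numeric(1))
  co <- fit$cox$coefficients
  report <- list(
    n_patients = nrow(d),
    eval_timepoint = fit$eval_timepoint,
    cutoff = fit$cutoff,
    cutoff_source = if (is.null(fit$consensus)) "fixed" else "consensus",
    group_sizes = as.list(table(d$group)),
    median_pfs_months = as.list(med),
    hr_high_vs_low = co$hr[1],
    hr_ci = c(co$ci_low[1], co$ci_high[1]),
    logrank_p = fit$logrank$p_value,
    power = schoenfeld_power(fit$cox$n_events, co$hr[1],
                             mean(d$group == "high")),
    orr = list(low = unname(orr_by_group["low", "TRUE"] /
                              sum(orr_by_group["low", ])),
               high = unname(orr_by_group["high", "TRUE"] /
                               sum(orr_by_group["high", ]))),
    quintile_median_pfs = as.list(quint),
    timedep_auc = stats::setNames(as.list(roc$auc),
                                  paste0("m", roc$horizon)),
    reclassification = list(horizon_months = reclass$horizon_months,
                            idi = reclass$idi, idi_ci = reclass$idi_ci,
                            nri = reclass$nri, nri_ci = reclass$nri_ci,
                            B = reclass$B),
    genomics = genomics)

  manifest <- list(seed = config$seed,
                   config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("thrscore")))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(report_markdown(report), file.path(out_dir, "report.md"))
  message(sprintf("pipeline finished in %.1f s -> %s",
                  as.numeric(difftime(Sys.time(), t0, units = "secs")),
                  out_dir))
  invisible(report)
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

report_markdown <- function(r) {
  fmt <- function(x, d = 2) ifelse(is.na(x), "NR", sprintf(paste0("%.", d, "f"), x))
  lines <- c(
    "# Heterogeneity response analysis report", "",
    sprintf("- patients: %d (evaluation visit: %s)", r$n_patients,
            r$eval_timepoint),
    sprintf("- cutoff: %.2f (%s); groups: %d low / %d high", r$cutoff,
            r$cutoff_source, r$group_sizes$low, r$group_sizes$high),
    sprintf("- median PFS: low %s, high %s months",
            fmt(r$median_pfs_months$low, 1), fmt(r$median_pfs_months$high, 1)),
    sprintf("- high vs low HR %.2f (95%% CI %.2f-%.2f), log-rank p = %.3g, post-hoc power %.3f",
            r$hr_high_vs_low, r$hr_ci[1], r$hr_ci[2], r$logrank_p, r$power),
    sprintf("- ORR: low %.0f%%, high %.0f%%", 100 * r$orr$low, 100 * r$orr$high),
    sprintf("- median PFS by score quintile: %s",
            paste(fmt(unlist(r$quintile_median_pfs), 1), collapse = ", ")),
    sprintf("- time-dependent AUC: %s",
            paste(sprintf("%s = %.3f", names(r$timedep_auc),
                          unlist(r$timedep_auc)), collapse = ", ")),
    sprintf("- reclassification at %g months: IDI %.3f (%.3f to %.3f), NRI %.3f (%.3f to %.3f)",
            r$reclassification$horizon_months, r$reclassification$idi,
            r$reclassification$idi_ci[1], r$reclassification$idi_ci[2],
            r$reclassification$nri, r$reclassification$nri_ci[1],
            r$reclassification$nri_ci[2]))
  if (!is.null(r$genomics)) {
    lines <- c(lines, sprintf(
      "- genomics: %d/%d calls pass QC; median TMB low %.1f, high %.1f (p = %.3g); %d gene(s) differ at p < 0.05",
      r$genomics$n_kept, r$genomics$n_calls, r$genomics$median_tmb$low,
      r$genomics$median_tmb$high, r$genomics$tmb_p,
      r$genomics$n_significant_genes))
  }
  lines
}
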
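#' Simulation configuration
#'
#' Defaults emulate the data structure of an advanced lung adenocarcinoma
#' cohort with multiple measurable lesions: 3-6 lesions per patient
#' (probabilities 0.72/0.24/0.02/0.02 for 3/4/5/6), log-normal baseline
#' diameters floored at the measurability thresholds (10 mm non-nodal, 15 mm
#' nodal), per-lesion percentage changes z_i ~ Normal(mu_p, tau_p) around a
#' patient mean mu_p ~ Normal(m_treat, s_between), with the patient
#' dispersion tau_p drawn from a two-component (low/high heterogeneity)
#' mixture that drives the THRscore, proportional-hazards PFS with hazard
#' ratio exp(beta) for the high-dispersion group, independent uniform
#' censoring, and a 1.5-month visit grid.
#'
#' @param n_patients cohort size.
#' @param lesion_count_probs named probabilities over lesion counts.
#' @param baseline_meanlog,baseline_sdlog log-normal law of baseline
#'   diameters (mm).
#' @param nodal_fraction fraction of lesions that are lymph nodes.
#' @param m_treat mean percentage change across patients (negative =
#'   shrinkage).
#' @param s_between SD of the patient-level mean percentage change.
#' @param tau_low,tau_high per-lesion dispersion (percentage points) of the
#'   two mixture components.
#' @param p_high probability of the high-heterogeneity component.
#' @param h0 baseline hazard (per month) of the low-heterogeneity group.
#' @param beta log hazard ratio of the high group (default log(3.4)).
#' @param c_min,c_max support of the uniform censoring law (months).
#' @param visit_every visit-grid spacing (months).
#' @param seed integer seed.
#' @return list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_patients = 174,
                       lesion_count_probs = c(`3` = .72, `4` = .24,
                                              `5` = .02, `6` = .02),
                       baseline_meanlog = log(25), baseline_sdlog = 0.45,
                       nodal_fraction = 0.15,
                       m_treat = -30, s_between = 8,
                       tau_low = 2.5, tau_high = 45, p_high = 0.40,
                       h0 = log(2) / 15.6, beta = log(3.4),
                       c_min = 6, c_max = 36, visit_every = 1.5,
                       seed = 1L) {
  assert_that(abs(sum(lesion_count_probs) - 1) < 1e-8,
              "lesion_count_probs must sum to 1")
  assert_that(all(lesion_count_probs >= 0), "probabilities must be >= 0")
  assert_that(tau_low >= 0 && tau_high >= 0 && h0 > 0 && c_max > c_min,
              "scales must be positive and c_max > c_min")
  structure(as.list(environment()), class = "sim_config")
}

snap_to_grid <- function(t, step) ceiling(pmax(t, step / 2) / step) * step

#' Simulate a cohort with planted heterogeneity structure
#'
#' Percentage changes are generated directly in z-space and back-converted
#' into follow-up diameters (d_eval = d_base * (1 + z/100), truncated at 0),
#' so the generator's truth is exact for the THRscore. PFS follows an
#' exponential proportional-hazards model keyed to the latent
#' high/low-dispersion group; observed times are composed onto the visit
#' grid. Clinical covariates are drawn from marginal frequencies typical of
#' such cohorts and are independent of the lesion model.
#'
#' @param config a [sim_config()].
#' @return list with \code{cohort} (a [thr_cohort()]) and \code{truth}
#'   (data.frame: patient_id, mu_p, tau_p, group, true_time, censor_time).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_patients
  counts <- as.integer(names(config$lesion_count_probs))
  n_les <- sample(counts, n, replace = TRUE, prob = config$lesion_count_probs)
  mu_p <- stats::rnorm(n, config$m_treat, config$s_between)
  high <- stats::runif(n) < config$p_high
  tau_p <- ifelse(high, config$tau_high, config$tau_low)
  true_t <- stats::rexp(n, rate = config$h0 * exp(config$beta * high))
  cens_t <- stats::runif(n, config$c_min, config$c_max)
  obs_t <- snap_to_grid(pmin(true_t, cens_t), config$visit_every)
  event <- true_t <= cens_t

  patients <- vector("list", n)
  outcomes <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("P%03d", i)
    L <- n_les[i]
    is_node <- stats::runif(L) < config$nodal_fraction
    floor_mm <- ifelse(is_node, 15, 10)
    d0 <- pmax(stats::rlnorm(L, config$baseline_meanlog,
                             config$baseline_sdlog), floor_mm)
    z <- stats::rnorm(L, mu_p[i], tau_p[i])
    d1 <- pmax(d0 * (1 + z / 100), 0)
    sites <- ifelse(is_node, "node",
                    sample(c("lung", "liver", "adrenal", "bone", "brain"),
                           L, replace = TRUE,
                           prob = c(.55, .12, .11, .12, .10)))
    lesions <- lapply(seq_len(L), function(j) {
      lesion_series(id, sprintf("L%d", j), site = sites[j],
                    is_node = is_node[j],
                    diameters_mm = c(baseline = d0[j], week6 = d1[j]))
    })
    patients[[i]] <- patient_record(
      id, age = round(stats::rnorm(1, 59, 10)),
      sex = sample(c("male", "female"), 1, prob = c(.60, .40)),
      smoking = stats::runif(1) < .33,
      ecog_ps = sample(0:2, 1, prob = c(.05, .88, .07)),
      brain_met = stats::runif(1) < .26, bone_met = stats::runif(1) < .35,
      adrenal_met = stats::runif(1) < .14, liver_met = stats::runif(1) < .14,
      driver_status = sample(c("mutation", "wild_type", "unknown"), 1,
                             prob = c(.58, .34, .08)),
      treatment = sample(c("chemotherapy", "targeted"), 1,
                         prob = c(.58, .42)),
      local_therapy = FALSE, lesions = lesions)
    outcomes[[i]] <- outcome_record(id, obs_t[i], event[i])
  }
  truth <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                      mu_p = mu_p, tau_p = tau_p,
                      group = factor(ifelse(high, "high", "low"),
                                     levels = c("low", "high")),
                      true_time = true_t, censor_time = cens_t,
                      stringsAsFactors = FALSE)
  list(cohort = thr_cohort(patients, outcomes, provenance = "synthetic"),
       truth = truth)
}

#' Simulate survival data with a planted score change-point
#'
#' Scores are drawn from a log-normal law (median matched to a typical
#' observed cohort median of 0.40); the hazard jumps by the factor \code{hr}
#' for scores above \code{true_cutoff}. Supports validation of the
#' maximally-selected-cutpoint machinery.
#'
#' @param n subjects.
#' @param true_cutoff planted change-point (within the score support).
#' @param hr hazard ratio above the cutoff.
#' @param seed integer seed, or NULL.
#' @param median_score median of the log-normal score law.
#' @param sdlog log-scale SD of the score law.
#' @param h0 baseline hazard below the cutoff (per month).
#' @param c_min,c_max uniform censoring support (months).
#' @return data.frame: time, event, score; the planted parameters are
#'   attached as attributes.
#' @export
simulate_changepoint_cohort <- function(n, true_cutoff = 0.46, hr = 3.4,
                                        seed = NULL, median_score = 0.40,
                                        sdlog = 1, h0 = log(2) / 15.6,
                                        c_min = 6, c_max = 36) {
  if (!is.null(seed)) set.seed(seed)
  score <- stats::rlnorm(n, meanlog = log(median_score), sdlog = sdlog)
  rate <- h0 * ifelse(score > true_cutoff, hr, 1)
  t <- stats::rexp(n, rate)
  cens <- stats::runif(n, c_min, c_max)
  out <- data.frame(time = pmin(t, cens), event = t <= cens, score = score)
  attr(out, "true_cutoff") <- true_cutoff
  attr(out, "hr") <- hr
  out
}

default_panel_genes <- function() {
  c("TP53", "KRAS", "ALK", "ROS1", "RET", "BRAF", "MET", "ERBB2", "STK11",
    "KEAP1", "PIK3CA", "SMAD4", "CDKN2A", "RB1", "NF1", "ATM", "BRCA2",
    "CTNNB1", "SMARCA4", "ARID1A")
}

#' Simulate panel-sequencing somatic calls for grouped patients
#'
#' Per patient: an EGFR mutation with a group-dependent probability
#' (emulating the enrichment of targetable drivers in homogeneous
#' responders), plus a Poisson (group-rate) number of further mutations drawn
#' from a panel gene list. QC fields of "clean" calls pass every somatic
#' filter rule; a configurable fraction of calls per rule is planted to
#' violate exactly that rule (ledger bookkeeping via the
#' \code{planted_violation} column).
#'
#' @param groups data.frame with patient_id and group ("low"/"high").
#' @param rate_low,rate_high Poisson rates of the non-EGFR mutation count.
#' @param egfr_prob_low,egfr_prob_high EGFR mutation probabilities.
#' @param genes non-EGFR gene pool.
#' @param violation_fraction per-rule fraction of calls planted to fail that
#'   rule (5 rules; their sum must stay below 1).
#' @param seed integer seed, or NULL.
#' @return calls data.frame ([variant_calls()] dialect) with an extra
#'   \code{planted_violation} column ("none" or the rule name).
#' @export
simulate_variants <- function(groups, rate_low = 1.5, rate_high = 3,
                              egfr_prob_low = 0.72, egfr_prob_high = 0.44,
                              genes = default_panel_genes(),
                              violation_fraction = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rules <- c("VAF", "alt reads", "base quality", "mapping quality", "PE bias")
  assert_that(5 * violation_fraction < 1,
              "violation_fraction too large (5 rules must sum below 1)")
  rows <- list()
  clean_call <- function(id, gene, class = "SNV") {
    data.frame(patient_id = id, gene = gene, variant_class = class,
               vaf = stats::runif(1, 0.05, 0.5),
               alt_reads = sample(5:200, 1),
               base_quality = stats::runif(1, 30, 40),
               mapping_quality = stats::runif(1, 30, 60),
               pe_bias = FALSE, nonsynonymous = TRUE,
               planted_violation = "none", stringsAsFactors = FALSE)
  }
  violate <- function(call, rule) {
    switch(rule,
           "VAF" = { call$vaf <- stats::runif(1, 0.001, 0.02) },
           "alt reads" = { call$alt_reads <- sample(0:4, 1) },
           "base quality" = { call$base_quality <- stats::runif(1, 10, 29.9) },
           "mapping quality" = { call$mapping_quality <- stats::runif(1, 10, 29.9) },
           "PE bias" = { call$pe_bias <- TRUE })
    call$planted_violation <- rule
    call
  }
  for (i in seq_len(nrow(groups))) {
    id <- groups$patient_id[i]
    hi <- groups$group[i] == "high"
    calls <- list()
    if (stats::runif(1) < (if (hi) egfr_prob_high else egfr_prob_low)) {
      calls[[length(calls) + 1L]] <- clean_call(id, "EGFR")
    }
    k <- stats::rpois(1, if (hi) rate_high else rate_low)
    for (j in seq_len(k)) {
      cls <- sample(c("SNV", "ins", "del", "indel"), 1,
                    prob = c(.75, .1, .1, .05))
      calls[[length(calls) + 1L]] <- clean_call(id, sample(genes, 1), cls)
    }
    if (violation_fraction > 0) {
      for (call_i in seq_along(calls)) {
        u <- stats::runif(1)
        hit <- findInterval(u, cumsum(rep(violation_fraction, 5)),
                            left.open = TRUE) + 1L
        if (u < 5 * violation_fraction) {
          calls[[call_i]] <- violate(calls[[call_i]], rules[hit])
        }
      }
    }
    rows <- c(rows, calls)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
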
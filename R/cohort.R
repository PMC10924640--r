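#' Lesion measurement series
#'
#' One target lesion's diameter measurements over follow-up. Diameters are
#' recorded on the RECIST 1.1 measurement axis: longest diameter for
#' non-nodal lesions, short axis for lymph nodes. The first timepoint must be
#' \code{"baseline"} with a strictly positive diameter; follow-up diameters of
#' exactly 0 encode complete disappearance of the lesion.
#'
#' @param patient_id,lesion_id opaque identifiers.
#' @param site one of \code{"lung"}, \code{"node"}, \code{"liver"},
#'   \code{"adrenal"}, \code{"bone"}, \code{"brain"}, \code{"other"}; unknown
#'   labels map to \code{"other"}.
#' @param is_node logical; nodes are measured on the short axis and carry a
#'   15 mm baseline measurability threshold (10 mm otherwise).
#' @param diameters_mm named numeric vector of diameters in mm, in visit
#'   order, starting at \code{"baseline"}.
#' @return An object of class \code{"lesion_series"}.
#' @export
lesion_series <- function(patient_id, lesion_id, site = "other",
                          is_node = identical(site, "node"), diameters_mm) {
  assert_that(length(diameters_mm) >= 1 && !is.null(names(diameters_mm)),
              "diameters_mm must be a named vector (patient %s lesion %s)",
              patient_id, lesion_id)
  assert_that(names(diameters_mm)[1] == "baseline",
              "first timepoint must be 'baseline' (patient %s lesion %s)",
              patient_id, lesion_id)
  assert_that(all(is.finite(diameters_mm)) && all(diameters_mm >= 0),
              "diameters must be finite and >= 0 (patient %s lesion %s)",
              patient_id, lesion_id)
  assert_that(diameters_mm[["baseline"]] > 0,
              "baseline diameter must be > 0 (patient %s lesion %s)",
              patient_id, lesion_id)
  site <- as.character(site)
  if (!site %in% lesion_sites()) site <- "other"
  structure(list(patient_id = as.character(patient_id),
                 lesion_id = as.character(lesion_id),
                 site = site, is_node = isTRUE(is_node),
                 diameters_mm = diameters_mm),
            class = "lesion_series")
}

#' @export
print.lesion_series <- function(x, ...) {
  cat(sprintf("<lesion %s/%s site=%s%s> %s\n", x$patient_id, x$lesion_id,
              x$site, if (x$is_node) " (node, short axis)" else "",
              paste(sprintf("%s=%gmm", names(x$diameters_mm), x$diameters_mm),
                    collapse = " ")))
  invisible(x)
}

lesion_sites <- function() {
  c("lung", "node", "liver", "adrenal", "bone", "brain", "other")
}

#' RECIST 1.1 baseline measurability
#'
#' A lesion is measurable when its baseline diameter reaches 10 mm (longest
#' diameter, non-nodal) or 15 mm (short axis, nodal). Pure function of the
#' nodal flag and the baseline diameter; later shrinkage below the threshold
#' does not remove a lesion from the target set.
#'
#' @param is_node logical vector.
#' @param baseline_mm numeric vector of baseline diameters (mm).
#' @return logical vector.
#' @export
is_measurable <- function(is_node, baseline_mm) {
  ifelse(is_node, baseline_mm >= 15, baseline_mm >= 10)
}

#' Patient record
#'
#' Clinical covariates plus the patient's lesion series. Parsing is permissive
#' (an ECOG of 3 is stored; eligibility is enforced later by
#' [apply_inclusion_criteria()]), but categorical labels are closed.
#'
#' @param patient_id identifier.
#' @param age years.
#' @param sex \code{"male"} or \code{"female"}.
#' @param smoking,local_therapy,brain_met,bone_met,adrenal_met,liver_met logicals.
#' @param ecog_ps integer 0-5.
#' @param driver_status \code{"mutation"}, \code{"wild_type"} or \code{"unknown"}.
#' @param treatment \code{"chemotherapy"} or \code{"targeted"}.
#' @param lesions list of [lesion_series()] objects, non-empty, unique lesion ids.
#' @return An object of class \code{"patient_record"}.
#' @export
patient_record <- function(patient_id, age, sex, smoking, ecog_ps,
                           brain_met = FALSE, bone_met = FALSE,
                           adrenal_met = FALSE, liver_met = FALSE,
                           driver_status = "unknown", treatment,
                           local_therapy = FALSE, lesions = list()) {
  treatment <- normalize_treatment(treatment)
  driver_status <- normalize_driver_status(driver_status)
  assert_that(length(lesions) >= 1, "patient %s: lesion list must be non-empty",
              patient_id)
  ids <- vapply(lesions, function(l) l$lesion_id, character(1))
  assert_that(!anyDuplicated(ids), "patient %s: duplicate lesion ids", patient_id)
  assert_that(ecog_ps %in% 0:5, "patient %s: ecog_ps must be 0-5", patient_id)
  structure(list(patient_id = as.character(patient_id), age = as.numeric(age),
                 sex = as.character(sex), smoking = isTRUE(smoking),
                 ecog_ps = as.integer(ecog_ps), brain_met = isTRUE(brain_met),
                 bone_met = isTRUE(bone_met), adrenal_met = isTRUE(adrenal_met),
                 liver_met = isTRUE(liver_met), driver_status = driver_status,
                 treatment = treatment, local_therapy = isTRUE(local_therapy),
                 lesions = lesions),
            class = "patient_record")
}

normalize_treatment <- function(x) {
  key <- gsub("[ _-]*therapy$", "", tolower(trimws(as.character(x))))
  key <- gsub("[ _-]+", "", key)
  map <- c(chemotherapy = "chemotherapy", chemo = "chemotherapy",
           targeted = "targeted", target = "targeted")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop_thr("unknown treatment label '%s' (allowed: chemotherapy, targeted)",
             paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

normalize_driver_status <- function(x) {
  key <- gsub("[ -]+", "_", tolower(trimws(as.character(x))))
  map <- c(mutation = "mutation", mutant = "mutation", mut = "mutation",
           wild_type = "wild_type", wildtype = "wild_type", wt = "wild_type",
           unknown = "unknown")
  out <- unname(map[key])
  if (anyNA(out)) {
    stop_thr("unknown driver status '%s' (allowed: mutation, wild_type, unknown)",
             paste(unique(x[is.na(out)]), collapse = ", "))
  }
  out
}

#' Outcome record (progression-free survival)
#'
#' PFS runs from the start of treatment to progression or death from any
#' cause; patients without an event are censored at their last scan.
#'
#' @param patient_id identifier.
#' @param pfs_months positive, finite time in months.
#' @param event logical; TRUE for observed progression/death.
#' @return An object of class \code{"outcome_record"}.
#' @export
outcome_record <- function(patient_id, pfs_months, event) {
  assert_that(is.finite(pfs_months) && pfs_months > 0,
              "patient %s: pfs_months must be finite and positive", patient_id)
  structure(list(patient_id = as.character(patient_id),
                 pfs_months = as.numeric(pfs_months), event = isTRUE(event)),
            class = "outcome_record")
}

#' Cohort container
#'
#' @param patients list of [patient_record()]s with unique ids.
#' @param outcomes list of [outcome_record()]s; every outcome's patient must
#'   exist in \code{patients}.
#' @param provenance free-text source tag.
#' @return An object of class \code{"thr_cohort"}.
#' @export
thr_cohort <- function(patients, outcomes = list(), provenance = "") {
  pid <- vapply(patients, function(p) p$patient_id, character(1))
  assert_that(!anyDuplicated(pid), "duplicate patient ids: %s",
              paste(unique(pid[duplicated(pid)]), collapse = ", "))
  oid <- vapply(outcomes, function(o) o$patient_id, character(1))
  orphan <- setdiff(oid, pid)
  assert_that(length(orphan) == 0, "outcomes reference unknown patients: %s",
              paste(orphan, collapse = ", "))
  names(patients) <- pid
  names(outcomes) <- oid
  structure(list(patients = patients, outcomes = outcomes,
                 provenance = provenance),
            class = "thr_cohort")
}

#' @export
print.thr_cohort <- function(x, ...) {
  cat(sprintf("<thr_cohort: %d patients, %d outcomes%s>\n",
              length(x$patients), length(x$outcomes),
              if (nzchar(x$provenance)) paste0(", ", x$provenance) else ""))
  invisible(x)
}

#' Extract the outcome table of a cohort
#'
#' @param cohort a [thr_cohort()].
#' @return data.frame with patient_id, pfs_months, event.
#' @export
outcome_table <- function(cohort) {
  data.frame(
    patient_id = vapply(cohort$outcomes, `[[`, character(1), "patient_id"),
    pfs_months = vapply(cohort$outcomes, `[[`, numeric(1), "pfs_months"),
    event = vapply(cohort$outcomes, `[[`, logical(1), "event"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the study inclusion criteria
#'
#' Retains patients with 3-10 RECIST-measurable lesions at baseline
#' (non-nodal >= 10 mm longest diameter, nodal >= 15 mm short axis), ECOG
#' performance status 0-2, first-line chemotherapy or targeted therapy, and no
#' local therapy during first-line treatment. A filter, not a validator: it
#' never errors, and reports the first failed criterion per excluded patient.
#'
#' @param cohort a [thr_cohort()].
#' @return list with \code{cohort} (the retained subset) and
#'   \code{exclusions}, a data.frame (patient_id, reason).
#' @export
apply_inclusion_criteria <- function(cohort) {
  reasons <- character(0); excluded <- character(0)
  keep <- logical(length(cohort$patients))
  for (i in seq_along(cohort$patients)) {
    p <- cohort$patients[[i]]
    base <- vapply(p$lesions, function(l) l$diameters_mm[["baseline"]], numeric(1))
    node <- vapply(p$lesions, function(l) l$is_node, logical(1))
    n_meas <- sum(is_measurable(node, base))
    reason <- if (!p$treatment %in% c("chemotherapy", "targeted")) "treatment"
      else if (p$ecog_ps > 2) "ecog"
      else if (n_meas < 3 || n_meas > 10) "lesion count"
      else if (p$local_therapy) "local therapy"
      else NA_character_
    keep[i] <- is.na(reason)
    if (!keep[i]) {
      excluded <- c(excluded, p$patient_id)
      reasons <- c(reasons, reason)
    }
  }
  kept <- cohort$patients[keep]
  kept_ids <- names(kept)
  out <- cohort$outcomes[intersect(names(cohort$outcomes), kept_ids)]
  list(cohort = thr_cohort(kept, out, provenance = cohort$provenance),
       exclusions = data.frame(patient_id = excluded, reason = reasons,
                               stringsAsFactors = FALSE))
}

# ---- file IO ---------------------------------------------------------------

lesion_cols <- c("patient_id", "lesion_id", "site", "is_node", "timepoint",
                 "order", "diameter_mm")

clinical_cols <- c("patient_id", "age", "sex", "smoking", "ecog_ps",
                   "brain_met", "bone_met", "adrenal_met", "liver_met",
                   "driver_status", "treatment", "local_therapy",
                   "pfs_months", "event")

apply_dialect <- function(df, canonical, dialect) {
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      j <- match(dialect[[canon]], names(df))
      if (!is.na(j)) names(df)[j] <- canon
    }
  }
  missing <- setdiff(canonical, names(df))
  assert_that(length(missing) == 0, "missing column(s): %s",
              paste(missing, collapse = ", "))
  df
}

#' Read a long-format lesion table
#'
#' Expects one row per (patient, lesion, timepoint) with columns
#' \code{patient_id, lesion_id, site, is_node, timepoint, order, diameter_mm};
#' \code{order} is an integer giving the visit order (baseline = 0). Rows are
#' never silently dropped: every row becomes part of a returned series or the
#' reader stops with an error naming the offending patient and lesion.
#'
#' @param path CSV file.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, e.g. \code{c(diameter_mm = "diam")}.
#' @return list of [lesion_series()], grouped and visit-ordered.
#' @export
read_lesion_table <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_dialect(df, lesion_cols, dialect)
  if (any(!is.finite(df$diameter_mm) | df$diameter_mm < 0)) {
    bad <- df[!is.finite(df$diameter_mm) | df$diameter_mm < 0, ][1, ]
    stop_thr("negative or missing diameter for patient %s lesion %s at %s",
             bad$patient_id, bad$lesion_id, bad$timepoint)
  }
  df$is_node <- parse_flag(df$is_node, "is_node")
  out <- list()
  for (key in unique(paste(df$patient_id, df$lesion_id, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    rows <- df[df$patient_id == parts[1] & df$lesion_id == parts[2], ]
    rows <- rows[order(rows$order), ]
    if (rows$timepoint[1] != "baseline") {
      stop_thr("no baseline row for patient %s lesion %s", parts[1], parts[2])
    }
    d <- rows$diameter_mm
    names(d) <- rows$timepoint
    out[[length(out) + 1L]] <- lesion_series(parts[1], parts[2],
                                             site = rows$site[1],
                                             is_node = rows$is_node[1],
                                             diameters_mm = d)
  }
  out
}

#' Write lesion series to a long-format CSV
#'
#' @param lesions list of [lesion_series()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_lesion_table <- function(lesions, path) {
  rows <- do.call(rbind, lapply(lesions, function(l) {
    data.frame(patient_id = l$patient_id, lesion_id = l$lesion_id,
               site = l$site, is_node = as.integer(l$is_node),
               timepoint = names(l$diameters_mm),
               order = seq_along(l$diameters_mm) - 1L,
               diameter_mm = unname(l$diameters_mm),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read a clinical + outcome table
#'
#' One row per patient with columns \code{patient_id, age, sex, smoking,
#' ecog_ps, brain_met, bone_met, adrenal_met, liver_met, driver_status,
#' treatment, local_therapy, pfs_months, event}. Booleans accept
#' 0/1/yes/no/true/false; treatment and driver labels are case- and
#' space-tolerant but closed (unknown labels are a hard error). Eligibility
#' (e.g. ECOG > 2) is not enforced at parse time.
#'
#' @param path CSV file.
#' @param dialect optional column-name mapping as in [read_lesion_table()].
#' @return data.frame of typed per-patient covariates and outcomes.
#' @export
read_clinical_table <- function(path, dialect = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df <- apply_dialect(df, clinical_cols, dialect)
  for (col in c("smoking", "brain_met", "bone_met", "adrenal_met",
                "liver_met", "local_therapy", "event")) {
    df[[col]] <- parse_flag(df[[col]], col)
  }
  df$treatment <- normalize_treatment(df$treatment)
  df$driver_status <- normalize_driver_status(df$driver_status)
  df$patient_id <- as.character(df$patient_id)
  df
}

#' Assemble a cohort from clinical and lesion CSVs
#'
#' @param clinical_path,lesion_path CSV files in the dialects of
#'   [read_clinical_table()] and [read_lesion_table()].
#' @param provenance free-text source tag.
#' @return a [thr_cohort()].
#' @export
read_cohort <- function(clinical_path, lesion_path, provenance = "") {
  clin <- read_clinical_table(clinical_path)
  lesions <- read_lesion_table(lesion_path)
  lesion_pid <- vapply(lesions, function(l) l$patient_id, character(1))
  patients <- lapply(seq_len(nrow(clin)), function(i) {
    r <- clin[i, ]
    patient_record(r$patient_id, r$age, r$sex, r$smoking, r$ecog_ps,
                   r$brain_met, r$bone_met, r$adrenal_met, r$liver_met,
                   r$driver_status, r$treatment, r$local_therapy,
                   lesions = lesions[lesion_pid == r$patient_id])
  })
  outcomes <- lapply(seq_len(nrow(clin)), function(i) {
    r <- clin[i, ]
    outcome_record(r$patient_id, r$pfs_months, r$event)
  })
  thr_cohort(patients, outcomes, provenance = provenance)
}

#' Write a cohort to clinical and lesion CSVs
#'
#' Inverse of [read_cohort()]; \code{read_cohort(write_cohort(x))} round-trips.
#'
#' @param cohort a [thr_cohort()].
#' @param clinical_path,lesion_path output CSV paths.
#' @return invisibly, a list of the two paths.
#' @export
write_cohort <- function(cohort, clinical_path, lesion_path) {
  rows <- do.call(rbind, lapply(cohort$patients, function(p) {
    o <- cohort$outcomes[[p$patient_id]]
    assert_that(!is.null(o), "patient %s has no outcome record", p$patient_id)
    data.frame(patient_id = p$patient_id, age = p$age, sex = p$sex,
               smoking = as.integer(p$smoking), ecog_ps = p$ecog_ps,
               brain_met = as.integer(p$brain_met),
               bone_met = as.integer(p$bone_met),
               adrenal_met = as.integer(p$adrenal_met),
               liver_met = as.integer(p$liver_met),
               driver_status = p$driver_status, treatment = p$treatment,
               local_therapy = as.integer(p$local_therapy),
               pfs_months = o$pfs_months, event = as.integer(o$event),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, clinical_path, row.names = FALSE)
  write_lesion_table(unlist(lapply(cohort$patients, `[[`, "lesions"),
                            recursive = FALSE), lesion_path)
  invisible(list(clinical = clinical_path, lesions = lesion_path))
}
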
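variant_classes <- c("SNV", "ins", "del", "indel", "fusion", "CNV_amp")

#' Validate a table of somatic variant calls
#'
#' Canonical columns: patient_id, gene, variant_class (SNV/ins/del/indel/
#' fusion/CNV_amp), vaf (fraction in [0,1]), alt_reads, base_quality,
#' mapping_quality (Phred), pe_bias (paired-end read bias flag),
#' nonsynonymous.
#'
#' @param calls data.frame of calls.
#' @return the validated data.frame (flags coerced to logical).
#' @export
variant_calls <- function(calls) {
  need <- c("patient_id", "gene", "variant_class", "vaf", "alt_reads",
            "base_quality", "mapping_quality", "pe_bias", "nonsynonymous")
  missing <- setdiff(need, names(calls))
  assert_that(length(missing) == 0, "missing variant column(s): %s",
              paste(missing, collapse = ", "))
  assert_that(all(calls$variant_class %in% variant_classes),
              "unknown variant_class (allowed: %s)",
              paste(variant_classes, collapse = ", "))
  assert_that(all(calls$vaf >= 0 & calls$vaf <= 1), "vaf must be in [0, 1]")
  assert_that(all(calls$alt_reads >= 0), "alt_reads must be >= 0")
  calls$pe_bias <- parse_flag(calls$pe_bias, "pe_bias")
  calls$nonsynonymous <- parse_flag(calls$nonsynonymous, "nonsynonymous")
  calls$patient_id <- as.character(calls$patient_id)
  calls
}

#' Somatic variant QC filter
#'
#' Keeps calls with VAF above 2\% supported by at least five high-quality
#' reads: base quality Phred >= 30, mapping quality >= 30, and no paired-end
#' read bias. The rejection ledger records the first failed rule per call, in
#' the order VAF, alt reads, base quality, mapping quality, PE bias. The
#' filter is idempotent.
#'
#' @param calls data.frame accepted by [variant_calls()].
#' @return list with \code{kept} (data.frame) and \code{rejected}
#'   (data.frame with a \code{reason} column).
#' @export
filter_somatic <- function(calls) {
  calls <- variant_calls(calls)
  reason <- rep(NA_character_, nrow(calls))
  reason[is.na(reason) & !(calls$vaf > 0.02)] <- "VAF"
  reason[is.na(reason) & calls$alt_reads < 5] <- "alt reads"
  reason[is.na(reason) & calls$base_quality < 30] <- "base quality"
  reason[is.na(reason) & calls$mapping_quality < 30] <- "mapping quality"
  reason[is.na(reason) & calls$pe_bias] <- "PE bias"
  rejected <- calls[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  list(kept = calls[is.na(reason), , drop = FALSE], rejected = rejected)
}

#' Targeted sequencing panel specification
#'
#' @param name panel label.
#' @param genes character vector of panel genes.
#' @param coding_region_mb targeted coding region size in megabases (> 0).
#' @return object of class \code{"panel_spec"}.
#' @export
panel_spec <- function(name, genes, coding_region_mb) {
  assert_that(coding_region_mb > 0, "coding_region_mb must be > 0")
  structure(list(name = name, genes = genes,
                 coding_region_mb = coding_region_mb),
            class = "panel_spec")
}

#' Tumor mutation burden for one patient
#'
#' TMB = (number of nonsynonymous mutations) per 0.7 Mb of the panel's
#' targeted coding region, i.e. count * 0.7 / panel size in Mb. Fusions and
#' copy-number events are excluded from the count unless
#' \code{include_sv = TRUE}. Apply [filter_somatic()] first.
#'
#' @param calls kept calls for a single patient.
#' @param panel a [panel_spec()].
#' @param include_sv count fusions/CNV_amp flagged nonsynonymous.
#' @return list: patient_id, n_nonsynonymous, tmb (mutations per 0.7 Mb).
#' @export
compute_tmb <- function(calls, panel, include_sv = FALSE) {
  assert_that(inherits(panel, "panel_spec"), "panel must be a panel_spec")
  assert_that(length(unique(calls$patient_id)) <= 1,
              "compute_tmb takes one patient's calls")
  point <- calls$variant_class %in% c("SNV", "ins", "del", "indel")
  counted <- calls$nonsynonymous & (point | include_sv)
  n <- sum(counted)
  list(patient_id = if (nrow(calls)) calls$patient_id[1] else NA_character_,
       n_nonsynonymous = n, tmb = n * 0.7 / panel$coding_region_mb)
}

#' TMB per patient over a cohort of calls
#'
#' @param calls kept calls (any number of patients).
#' @param panel a [panel_spec()] applied to every patient, or a named list of
#'   panels keyed by patient_id (mixed-panel cohorts are flagged with a
#'   message).
#' @param include_sv see [compute_tmb()].
#' @return data.frame: patient_id, n_nonsynonymous, tmb.
#' @export
tmb_by_patient <- function(calls, panel, include_sv = FALSE) {
  ids <- unique(calls$patient_id)
  mixed <- is.list(panel) && !inherits(panel, "panel_spec")
  if (mixed) message("mixed-panel cohort: per-patient TMB uses each patient's own panel")
  rows <- lapply(ids, function(id) {
    p <- if (mixed) panel[[id]] else panel
    r <- compute_tmb(calls[calls$patient_id == id, , drop = FALSE], p,
                     include_sv)
    data.frame(patient_id = id, n_nonsynonymous = r$n_nonsynonymous,
               tmb = r$tmb, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Binary alteration matrix (patients x genes)
#'
#' @param calls kept calls.
#' @param patients patient ids to include (default: those with calls).
#' @param genes genes to include (default: those observed).
#' @return 0/1 integer matrix with patient rownames and gene colnames.
#' @export
alteration_matrix <- function(calls, patients = NULL, genes = NULL) {
  patients <- patients %||% unique(calls$patient_id)
  genes <- genes %||% sort(unique(calls$gene))
  m <- matrix(0L, length(patients), length(genes),
              dimnames = list(patients, genes))
  hit <- calls[calls$patient_id %in% patients & calls$gene %in% genes, ]
  m[cbind(match(hit$patient_id, patients), match(hit$gene, genes))] <- 1L
  m
}

#' Per-gene alteration frequency comparison between groups
#'
#' Two-sided Fisher's exact test per gene on the 2x2 table of altered vs not
#' by group. Genes altered in no patient are skipped (listed in the
#' \code{skipped} attribute).
#'
#' @param mat binary patients x genes matrix ([alteration_matrix()]).
#' @param group two-level factor aligned with the matrix rows.
#' @return data.frame: gene, n and frequency per group, p_value; skipped
#'   genes in \code{attr(, "skipped")}.
#' @export
gene_frequency_compare <- function(mat, group) {
  group <- droplevels(as.factor(group))
  assert_that(nlevels(group) == 2, "need exactly 2 groups")
  assert_that(nrow(mat) == length(group), "group must align with matrix rows")
  lv <- levels(group)
  skipped <- colnames(mat)[colSums(mat) == 0]
  keep <- colnames(mat)[colSums(mat) > 0]
  rows <- lapply(keep, function(g) {
    tab <- table(factor(mat[, g], levels = c(1, 0)), group)
    data.frame(gene = g,
               n_1 = sum(mat[group == lv[1], g]),
               n_2 = sum(mat[group == lv[2], g]),
               freq_1 = mean(mat[group == lv[1], g]),
               freq_2 = mean(mat[group == lv[2], g]),
               p_value = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("gene", paste0("n_", lv), paste0("freq_", lv), "p_value")
  if (length(skipped)) {
    message(sprintf("skipped %d gene(s) altered in no patient", length(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Gene-set alteration comparison between groups
#'
#' A patient is set-altered when at least one gene of the set is altered.
#' Per set, a two-sided Fisher test compares the set-altered fractions of the
#' two groups. Sets covering no gene of the matrix are an error.
#'
#' @param mat binary patients x genes matrix.
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param group two-level factor aligned with the matrix rows.
#' @return data.frame: set, frequency per group, p_value.
#' @export
geneset_alteration_compare <- function(mat, gene_sets, group) {
  group <- droplevels(as.factor(group))
  lv <- levels(group)
  rows <- lapply(names(gene_sets), function(nm) {
    genes <- gene_sets[[nm]]
    assert_that(length(genes) >= 1, "gene set '%s' is empty", nm)
    hit <- intersect(genes, colnames(mat))
    assert_that(length(hit) >= 1, "gene set '%s' covers no panel gene", nm)
    altered <- as.integer(rowSums(mat[, hit, drop = FALSE]) > 0)
    tab <- table(factor(altered, levels = c(1, 0)), group)
    data.frame(set = nm,
               freq_1 = mean(altered[group == lv[1]]),
               freq_2 = mean(altered[group == lv[2]]),
               p_value = stats::fisher.test(tab)$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- c("set", paste0("freq_", lv), "p_value")
  out
}

#' Read gene sets from a GMT file
#'
#' @param path GMT file (one set per line: name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

# ---- VCF ingestion ---------------------------------------------------------

default_vcf_keys <- function() {
  c(gene = "GENE", variant_class = "VC", vaf = "VAF", alt_reads = "ALTC",
    base_quality = "BQ", mapping_quality = "MQ", pe_bias = "PEB",
    nonsynonymous = "NONSYN")
}

#' Read somatic calls from a single-patient VCF
#'
#' Maps INFO fields onto the canonical call columns via a configurable key
#' map (panel vendors differ); the default expects the dialect written by
#' [write_variant_vcf()].
#'
#' @param path VCF (v4.2) file.
#' @param patient_id patient the file belongs to.
#' @param key_map named character vector mapping canonical columns to INFO
#'   keys; see \code{thrscore:::default_vcf_keys()}.
#' @return validated calls data.frame.
#' @export
read_variant_vcf <- function(path, patient_id, key_map = default_vcf_keys()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop_thr("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  info <- function(key) vcfR::extract.info(v, element = key)
  calls <- data.frame(
    patient_id = patient_id,
    gene = info(key_map[["gene"]]),
    variant_class = info(key_map[["variant_class"]]),
    vaf = as.numeric(info(key_map[["vaf"]])),
    alt_reads = as.integer(info(key_map[["alt_reads"]])),
    base_quality = as.numeric(info(key_map[["base_quality"]])),
    mapping_quality = as.numeric(info(key_map[["mapping_quality"]])),
    pe_bias = as.integer(info(key_map[["pe_bias"]])),
    nonsynonymous = as.integer(info(key_map[["nonsynonymous"]])),
    stringsAsFactors = FALSE)
  variant_calls(calls)
}

#' Write somatic calls as a minimal VCF 4.2 file
#'
#' One file per patient; call attributes are carried in INFO fields matching
#' [read_variant_vcf()]'s default key map. Positions are synthetic
#' placeholders (the data model is gene-level).
#'
#' @param calls one patient's calls.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(calls, path) {
  calls <- variant_calls(calls)
  assert_that(length(unique(calls$patient_id)) <= 1,
              "write_variant_vcf takes one patient's calls")
  km <- default_vcf_keys()
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=thrscore",
    sprintf("##INFO=<ID=%s,Number=1,Type=%s,Description=\"%s\">",
            c(km[["gene"]], km[["variant_class"]], km[["vaf"]],
              km[["alt_reads"]], km[["base_quality"]], km[["mapping_quality"]],
              km[["pe_bias"]], km[["nonsynonymous"]]),
            c("String", "String", "Float", "Integer", "Float", "Float",
              "Integer", "Integer"),
            c("Gene symbol", "Variant class", "Variant allele fraction",
              "Alt-supporting reads", "Base quality (Phred)",
              "Mapping quality (Phred)", "Paired-end read bias",
              "Nonsynonymous flag")),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    r <- calls[i, ]
    info <- paste(
      sprintf("%s=%s", km,
              c(r$gene, r$variant_class, format(r$vaf, digits = 6),
                r$alt_reads, format(r$base_quality, digits = 6),
                format(r$mapping_quality, digits = 6),
                as.integer(r$pe_bias), as.integer(r$nonsynonymous))),
      collapse = ";")
    sprintf("chr1\t%d\t.\tN\tA\t.\tPASS\t%s", 1000L + i, info)
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}
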
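# Per-patient tumor-specificity calling: a transcript is tumor-specific in
# a patient when it is expressed above `tumor_hi` in the tumor sample,
# below `normal_lo` in the matched normal, and not expressed (median above
# `panel_max_median`) in any nonreproductive healthy-panel tissue. Testis /
# ovary expression never gates the call (germinal cells lack HLA-I) but is
# recorded, as is thymus expression (relevant to central tolerance).

#' Matched tumor/normal cutoff test
#'
#' @param tumor_fpkm,normal_fpkm expression of one transcript in the
#'   patient's tumor and matched normal sample.
#' @param cutoffs a `cohort_cutoffs` object.
#' @return logical: `tumor_fpkm > tumor_hi & normal_fpkm < normal_lo`
#'   (both inequalities strict). Vectorised.
#' @export
call_matched <- function(tumor_fpkm, normal_fpkm, cutoffs = cohort_cutoffs()) {
  assert_that(all(tumor_fpkm >= 0) && all(normal_fpkm >= 0),
              "expression values must be non-negative")
  tumor_fpkm > cutoffs$tumor_hi & normal_fpkm < cutoffs$normal_lo
}

#' Build a normal-tissue panel
#'
#' @param medians numeric matrix transcript x tissue of median expression.
#' @param reproductive character vector naming the reproductive tissues
#'   (exempt from gating). Default `c("testis", "ovary")`.
#' @return a `normal_panel` object.
#' @export
normal_panel <- function(medians, reproductive = c("testis", "ovary")) {
  assert_that(is.matrix(medians) && !is.null(colnames(medians)) &&
                !is.null(rownames(medians)), "medians must be a named matrix")
  assert_that(all(medians >= 0), "panel medians must be non-negative")
  structure(list(medians = medians,
                 reproductive = intersect(reproductive, colnames(medians)),
                 nonreproductive = setdiff(colnames(medians), reproductive)),
            class = "normal_panel")
}

#' Healthy-panel filter for one transcript
#'
#' @param transcript_id transcript to test.
#' @param panel a `normal_panel`.
#' @param max_median maximum tolerated median in any nonreproductive
#'   tissue (inclusive). Default 0.5 (same-unit threshold: callers must
#'   supply panel medians in the unit their expression tables use).
#' @return list with `pass` (TRUE iff every nonreproductive median is at or
#'   below `max_median`) and `testis_expressed` (median in testis above
#'   `max_median`; annotation only). Transcripts absent from the panel are
#'   treated as unexpressed there, with a warning.
#' @export
call_panel <- function(transcript_id, panel, max_median = 0.5) {
  if (!transcript_id %in% rownames(panel$medians)) {
    warning("transcript ", transcript_id,
            " absent from the normal panel; treated as unexpressed",
            call. = FALSE)
    return(list(pass = TRUE, testis_expressed = FALSE))
  }
  row <- panel$medians[transcript_id, ]
  testis <- if ("testis" %in% names(row)) row[["testis"]] > max_median else FALSE
  list(pass = all(row[panel$nonreproductive] <= max_median),
       testis_expressed = testis)
}

#' Thymus expression flag
#'
#' Annotation only (central-tolerance caveat for candidate shortlists);
#' never gates a tumor-specificity call.
#'
#' @param median_expr median expression of the transcript across thymic
#'   samples.
#' @param cutoff strict threshold. Default 0.5.
#' @return logical, vectorised.
#' @export
thymus_flag <- function(median_expr, cutoff = 0.5) {
  assert_that(all(median_expr >= 0), "medians must be non-negative")
  median_expr > cutoff
}

#' Classify tumor-specific transcripts per patient
#'
#' Runs the full filter cascade for every (patient, transcript) pair and
#' returns the calls that pass the matched tumor/normal test, with the
#' panel outcome and annotation flags attached. `tumor_specific` is
#' `pass_matched & pass_panel`; the testis and thymus flags never affect it.
#'
#' @param mat an `expression_matrix`.
#' @param panel a `normal_panel` (or `NULL` to skip panel gating).
#' @param cutoffs a `cohort_cutoffs` object.
#' @param thymus_medians optional named vector of thymic median expression.
#' @return data frame with columns `patient_id`, `transcript_id`,
#'   `tumor_fpkm`, `normal_fpkm`, `pass_matched`, `pass_panel`,
#'   `testis_expressed`, `thymus_expressed`, `tumor_specific`.
#' @export
classify_tumor_specific <- function(mat, panel = NULL,
                                    cutoffs = cohort_cutoffs(),
                                    thymus_medians = NULL) {
  patients <- unique(mat$sample_meta$patient_id)
  tids <- rownames(mat$values)
  panel_pass <- rep(TRUE, length(tids))
  testis <- rep(FALSE, length(tids))
  if (!is.null(panel)) {
    known <- tids %in% rownames(panel$medians)
    if (any(known)) {
      sub <- panel$medians[tids[known], , drop = FALSE]
      panel_pass[known] <- apply(
        sub[, panel$nonreproductive, drop = FALSE] <=
          cutoffs$panel_max_median, 1, all)
      if ("testis" %in% colnames(sub))
        testis[known] <- sub[, "testis"] > cutoffs$panel_max_median
    }
  }
  names(panel_pass) <- names(testis) <- tids
  thym <- rep(FALSE, length(tids))
  names(thym) <- tids
  if (!is.null(thymus_medians)) {
    hit <- intersect(tids, names(thymus_medians))
    thym[hit] <- thymus_flag(thymus_medians[hit])
  }
  rows <- lapply(patients, function(p) {
    tu <- mat$values[, sample_of(mat, p, "tumor")]
    no <- mat$values[, sample_of(mat, p, "normal")]
    pm <- call_matched(tu, no, cutoffs)
    sel <- which(pm)
    if (!length(sel)) return(NULL)
    data.frame(patient_id = p, transcript_id = tids[sel],
               tumor_fpkm = unname(tu[sel]), normal_fpkm = unname(no[sel]),
               pass_matched = TRUE, pass_panel = unname(panel_pass[sel]),
               testis_expressed = unname(testis[sel]),
               thymus_expressed = unname(thym[sel]),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(patient_id = character(0), transcript_id = character(0),
               tumor_fpkm = numeric(0), normal_fpkm = numeric(0),
               pass_matched = logical(0), pass_panel = logical(0),
               testis_expressed = logical(0), thymus_expressed = logical(0))
  out$tumor_specific <- out$pass_matched & out$pass_panel
  rownames(out) <- NULL
  out
}

#' Normal-specific transcript set of one patient
#'
#' The mirror of the tumor-specific matched test: transcripts expressed
#' above `tumor_hi` in the normal sample and below `normal_lo` in the tumor.
#'
#' @param patient patient id.
#' @param mat an `expression_matrix`.
#' @param cutoffs a `cohort_cutoffs` object.
#' @return character vector of transcript ids.
#' @export
normal_specific_set <- function(patient, mat, cutoffs = cohort_cutoffs()) {
  tu <- mat$values[, sample_of(mat, patient, "tumor")]
  no <- mat$values[, sample_of(mat, patient, "normal")]
  rownames(mat$values)[call_matched(no, tu, cutoffs)]
}

#' Paired test of noncoding enrichment among tumor-specific transcripts
#'
#' For each patient computes the noncoding:coding count ratio among
#' tumor-specific and among normal-specific transcripts, then compares the
#' paired ratios with a Wilcoxon signed-rank test. Patients whose ratios
#' are undefined (zero coding count on either side) are dropped with a
#' warning.
#'
#' @param calls tumor-specific calls from [classify_tumor_specific()].
#' @param mat an `expression_matrix`.
#' @param biotypes named character vector transcript_id -> biotype.
#' @param cutoffs a `cohort_cutoffs` object.
#' @return list with per-patient ratio data frame, the Wilcoxon `statistic`
#'   and `p_value`.
#' @export
specificity_ratio_test <- function(calls, mat, biotypes,
                                   cutoffs = cohort_cutoffs()) {
  patients <- unique(mat$sample_meta$patient_id)
  assert_that(length(patients) >= 2,
              "at least two patients are required for the paired test")
  ratio_of <- function(ids) {
    b <- biotypes[ids]
    nc <- sum(b %in% c("lncRNA", "novel"))
    co <- sum(b == "coding")
    if (co == 0) NA_real_ else nc / co
  }
  df <- do.call(rbind, lapply(patients, function(p) {
    ts_ids <- calls$transcript_id[calls$patient_id == p & calls$tumor_specific]
    ns_ids <- normal_specific_set(p, mat, cutoffs)
    data.frame(patient_id = p, ratio_tumor = ratio_of(ts_ids),
               ratio_normal = ratio_of(ns_ids), stringsAsFactors = FALSE)
  }))
  ok <- stats::complete.cases(df[, c("ratio_tumor", "ratio_normal")])
  if (any(!ok)) {
    warning(sum(!ok), " patient(s) dropped: undefined noncoding:coding ratio",
            call. = FALSE)
  }
  assert_that(sum(ok) >= 2, "fewer than two patients with defined ratios")
  wt <- suppressWarnings(stats::wilcox.test(df$ratio_tumor[ok],
                                            df$ratio_normal[ok],
                                            paired = TRUE))
  list(ratios = df, statistic = unname(wt$statistic),
       p_value = wt$p.value)
}

#' Sharing table of tumor-specific transcripts
#'
#' @param calls tumor-specific calls from [classify_tumor_specific()].
#' @param n_patients total patients in the cohort (denominator of the
#'   fraction); defaults to the number of distinct patients in `calls`.
#' @return data frame `transcript_id`, `n_patients_specific`,
#'   `fraction_patients`, sorted by decreasing count.
#' @export
sharing_table <- function(calls, n_patients = NULL) {
  ts <- calls[calls$tumor_specific, , drop = FALSE]
  if (is.null(n_patients)) n_patients <- length(unique(calls$patient_id))
  if (!nrow(ts)) {
    return(data.frame(transcript_id = character(0),
                      n_patients_specific = integer(0),
                      fraction_patients = numeric(0)))
  }
  tab <- table(ts$transcript_id)
  out <- data.frame(transcript_id = names(tab),
                    n_patients_specific = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$fraction_patients <- out$n_patients_specific / n_patients
  out <- out[order(-out$n_patients_specific, out$transcript_id), ]
  rownames(out) <- NULL
  out
}
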
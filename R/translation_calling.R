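# Translation calling from P-site-resolved ribosome-profiling profiles.
#
# Each ORF is scored with a transparent periodicity-and-homogeneity score:
# f1 is the fraction of P-site counts falling in the ORF's reading frame,
# h the normalised Shannon entropy of the per-codon count distribution
# (1 for perfectly even coverage, -> 0 for a single-codon pileup), and the
# score s = f1 * h. An ORF is called translated when it has at least
# `min_reads` footprints and s >= `score_cutoff` (defaults 5 and 0.5, the
# published operating point for this class of classifier).

#' Score one ORF against a footprint profile
#'
#' @param orf one-row ORF data frame (see [orf_catalog()]).
#' @param profile integer vector of P-site counts per transcript position
#'   (length = transcript spliced length).
#' @param min_reads minimum footprints for a translated call. Default 5.
#' @param score_cutoff minimum score for a translated call. Default 0.5.
#' @return one-row data frame: `orf_id`, `n_reads`, `f1`, `h`, `score`,
#'   `translated`. Zero reads give f1 = h = score = 0 and no call.
#' @export
score_orf <- function(orf, profile, min_reads = 5, score_cutoff = 0.5) {
  assert_that(orf$start >= 0 && orf$end <= length(profile),
              paste0("ORF ", orf$orf_id %||% "?",
                     " lies outside the footprint profile"))
  assert_that(all(profile >= 0), "footprint counts must be non-negative")
  region <- profile[(orf$start + 1L):orf$end]
  n <- sum(region)
  if (n == 0) {
    f1 <- 0; h <- 0; s <- 0
  } else {
    len <- orf$end - orf$start
    f1 <- sum(region[seq(1L, len, 3L)]) / n
    codon <- rep(seq_len(len %/% 3L), each = 3L)
    cs <- as.vector(rowsum(region, codon))
    p <- cs[cs > 0] / n
    h <- if (length(cs) <= 1L) 1 else -sum(p * log(p)) / log(length(cs))
    s <- f1 * h
  }
  data.frame(orf_id = orf$orf_id %||% NA_character_, n_reads = n, f1 = f1,
             h = h, score = s,
             translated = (n >= min_reads) && (s >= score_cutoff),
             stringsAsFactors = FALSE)
}

#' Call translated ORFs over a catalog
#'
#' @param catalog ORF catalog data frame.
#' @param profiles named list of per-transcript P-site count vectors.
#' @inheritParams score_orf
#' @return data frame of translation calls, one row per scored ORF; ORFs on
#'   transcripts without a profile are skipped with a warning.
#' @export
call_translated <- function(catalog, profiles, min_reads = 5,
                            score_cutoff = 0.5) {
  empty <- data.frame(orf_id = character(0), n_reads = numeric(0),
                      f1 = numeric(0), h = numeric(0), score = numeric(0),
                      translated = logical(0))
  if (!nrow(catalog)) return(empty)
  missing <- setdiff(unique(catalog$transcript_id), names(profiles))
  if (length(missing)) {
    warning("no footprint profile for ",
            length(missing), " transcript(s): ",
            paste(utils::head(missing, 5), collapse = ", "),
            "; their ORFs were skipped", call. = FALSE)
    catalog <- catalog[!catalog$transcript_id %in% missing, , drop = FALSE]
  }
  if (!nrow(catalog)) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(catalog)), function(i) {
    score_orf(catalog[i, ], profiles[[catalog$transcript_id[i]]],
              min_reads = min_reads, score_cutoff = score_cutoff)
  }))
  rownames(out) <- NULL
  out
}

#' Remove redundant translated ORFs
#'
#' Among translated ORFs of the same transcript overlapping in the same
#' frame, only the longest is kept (ties broken by the 5'-most start, then
#' by orf_id). Non-translated calls pass through untouched in the returned
#' id set's complement.
#'
#' @param calls translation-call data frame from [call_translated()].
#' @param catalog the matching ORF catalog.
#' @return character vector of orf_ids forming the nonredundant translated
#'   set.
#' @export
deduplicate_translated <- function(calls, catalog) {
  tr_ids <- calls$orf_id[calls$translated]
  cat_t <- catalog[catalog$orf_id %in% tr_ids, , drop = FALSE]
  keep <- character(0)
  for (grp in split(cat_t, list(cat_t$transcript_id, cat_t$frame),
                    drop = TRUE)) {
    o <- order(-grp$length_nt, grp$start, grp$orf_id)
    grp <- grp[o, , drop = FALSE]
    sel_start <- integer(0); sel_end <- integer(0)
    for (i in seq_len(nrow(grp))) {
      if (!any(grp$start[i] < sel_end & grp$end[i] > sel_start)) {
        keep <- c(keep, grp$orf_id[i])
        sel_start <- c(sel_start, grp$start[i])
        sel_end <- c(sel_end, grp$end[i])
      }
    }
  }
  sort(keep)
}

#' Transcripts expressed in (almost) every patient
#'
#' Translation is only assessed on transcripts expressed in at least
#' `fraction` of the cohort's tumor samples, so that footprint evidence
#' from a separate ribosome-profiling cohort is informative.
#'
#' @param mat an `expression_matrix`.
#' @param cutoffs a `cohort_cutoffs` object (the `expr_cutoff` is used).
#' @param fraction minimum fraction of patients. Default 0.9; the patient
#'   threshold is `ceiling(fraction * n_patients)`.
#' @return character vector of transcript ids.
#' @export
widely_expressed_filter <- function(mat, cutoffs = cohort_cutoffs(),
                                    fraction = 0.9) {
  ts <- tumor_samples(mat)
  assert_that(length(ts) >= 1, "at least one patient is required")
  need <- ceiling(fraction * length(ts))
  n_expr <- rowSums(mat$values[, ts, drop = FALSE] > cutoffs$expr_cutoff)
  rownames(mat$values)[n_expr >= need]
}

#' Class-level translation index
#'
#' The translation index of a transcript class is the length-weighted
#' fraction of candidate ncORF sequence called translated:
#' sum of translated ORF lengths / sum of tested ORF lengths. The plain
#' count fraction is reported alongside.
#'
#' @param catalog ORF catalog restricted to the tested ORFs of one class.
#' @param translated_ids orf_ids called translated (after deduplication).
#' @return list with `transcript_class`, `value` (length-weighted),
#'   `count_fraction`, `n_orfs_tested`, `n_orfs_translated`.
#' @export
compute_translation_index <- function(catalog, translated_ids) {
  cls <- unique(catalog$biotype)
  assert_that(length(cls) <= 1,
              "catalog must be restricted to a single transcript class")
  n_tested <- nrow(catalog)
  is_tr <- catalog$orf_id %in% translated_ids
  if (n_tested == 0) {
    warning("no tested ORFs; translation index reported as 0", call. = FALSE)
    return(list(transcript_class = if (length(cls)) cls else NA_character_,
                value = 0, count_fraction = 0, n_orfs_tested = 0L,
                n_orfs_translated = 0L))
  }
  list(transcript_class = cls,
       value = sum(catalog$length_nt[is_tr]) / sum(catalog$length_nt),
       count_fraction = mean(is_tr),
       n_orfs_tested = n_tested,
       n_orfs_translated = sum(is_tr))
}
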
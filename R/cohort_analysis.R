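# Cohort-level analyses: shortlisting of frequent, highly tumor-specific
# transcripts; transposable-element (TE/HERV) overlap and enrichment among
# tumor-specific noncoding transcripts; pairwise expression correlation of
# the candidate set.

TE_CLASSES <- c("LINE", "SINE", "LTR", "retrotransposon", "RNA")

#' Shortlist frequent tumor-specific candidates
#'
#' Retains transcripts that are tumor-specific in at least
#' `ceiling(min_fraction * n_patients)` patients, exceed `min_max_fpkm` in
#' at least one tumor sample, and are expressed (above the expression
#' cutoff) in less than `max_normal_prevalence` of all normal samples.
#'
#' @param sharing sharing table from [sharing_table()].
#' @param mat an `expression_matrix` over the same cohort.
#' @param cutoffs a `cohort_cutoffs` object (the `expr_cutoff` defines
#'   normal-sample expression).
#' @param min_fraction minimum fraction of patients. Default 0.10.
#' @param min_max_fpkm strict minimum of the max tumor FPKM. Default 5.
#' @param max_normal_prevalence strict maximum fraction of normal samples
#'   expressing the transcript. Default 0.01.
#' @return data frame of candidates: `transcript_id`,
#'   `n_patients_specific`, `fraction_patients`, `max_tumor_fpkm`,
#'   `normal_prevalence`.
#' @export
select_candidates <- function(sharing, mat, cutoffs = cohort_cutoffs(),
                              min_fraction = 0.10, min_max_fpkm = 5,
                              max_normal_prevalence = 0.01) {
  n_patients <- length(unique(mat$sample_meta$patient_id))
  need <- ceiling(min_fraction * n_patients)
  sh <- sharing[order(sharing$transcript_id), , drop = FALSE]
  sh <- sh[sh$n_patients_specific >= need, , drop = FALSE]
  if (!nrow(sh)) {
    return(data.frame(transcript_id = character(0),
                      n_patients_specific = integer(0),
                      fraction_patients = numeric(0),
                      max_tumor_fpkm = numeric(0),
                      normal_prevalence = numeric(0)))
  }
  tu <- mat$values[sh$transcript_id, tumor_samples(mat), drop = FALSE]
  no <- mat$values[sh$transcript_id, normal_samples(mat), drop = FALSE]
  sh$max_tumor_fpkm <- apply(tu, 1, max)
  sh$normal_prevalence <- rowMeans(no > cutoffs$expr_cutoff)
  out <- sh[sh$max_tumor_fpkm > min_max_fpkm &
              sh$normal_prevalence < max_normal_prevalence, , drop = FALSE]
  out <- out[order(-out$n_patients_specific, out$transcript_id), ]
  rownames(out) <- NULL
  out
}

#' Load a TE annotation, keeping stranded features only
#'
#' @param te `GRanges` with a `name` (or `te_class`) metadata column giving
#'   the TE class; features with unknown strand are dropped.
#' @return a `GRanges` with a `te_class` column and strands in `{+, -}`.
#' @export
te_annotation <- function(te) {
  assert_that(methods::is(te, "GRanges"), "te must be a GRanges")
  cls <- S4Vectors::mcols(te)$te_class %||% S4Vectors::mcols(te)$name
  assert_that(!is.null(cls), "te needs a te_class (or name) column")
  keep <- as.character(GenomicRanges::strand(te)) %in% c("+", "-")
  te <- te[keep]
  S4Vectors::mcols(te)$te_class <- cls[keep]
  te
}

#' TE overlap of one transcript
#'
#' Per TE class, features on the transcript's strand are merged (union)
#' before intersecting with the transcript's exons, so a region covered by
#' several TE copies is counted once. The fraction is overlap bp divided by
#' spliced length.
#'
#' @param ts a `transcript_set`.
#' @param transcript_id transcript to assess (must be stranded).
#' @param te TE annotation from [te_annotation()].
#' @return data frame per TE class present in `te`: `te_class`,
#'   `overlap_bp`, `overlap_fraction`, `overlaps` (>= 1 bp).
#' @export
te_overlap <- function(ts, transcript_id, te) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  assert_that(nrow(tr) == 1, paste("unknown transcript:", transcript_id))
  assert_that(tr$strand %in% c("+", "-"),
              "transcript must be stranded for TE overlap")
  ex <- ts$exons[S4Vectors::mcols(ts$exons)$transcript_id == transcript_id]
  classes <- sort(unique(S4Vectors::mcols(te)$te_class))
  bp <- vapply(classes, function(cl) {
    sub <- te[S4Vectors::mcols(te)$te_class == cl &
                as.character(GenomicRanges::strand(te)) == tr$strand &
                as.character(GenomicRanges::seqnames(te)) == tr$chrom]
    if (!length(sub)) return(0L)
    merged <- GenomicRanges::reduce(sub, ignore.strand = FALSE)
    sum(GenomicRanges::width(GenomicRanges::intersect(
      GenomicRanges::reduce(ex, ignore.strand = FALSE), merged,
      ignore.strand = FALSE)))
  }, integer(1))
  data.frame(transcript_id = transcript_id, te_class = classes,
             overlap_bp = as.integer(bp),
             overlap_fraction = as.numeric(bp) / tr$spliced_length,
             overlaps = bp >= 1, stringsAsFactors = FALSE)
}

#' TE overlap flags for many transcripts
#'
#' @inheritParams te_overlap
#' @param transcript_ids transcripts to assess.
#' @param te_class single TE class of interest (e.g. `"LTR"` for HERVs).
#' @return named logical vector: transcript overlaps the class by >= 1 bp.
#' @export
te_overlap_flags <- function(ts, transcript_ids, te, te_class = "LTR") {
  sub <- te[S4Vectors::mcols(te)$te_class == te_class]
  ex <- ts$exons[S4Vectors::mcols(ts$exons)$transcript_id %in% transcript_ids]
  hits <- GenomicRanges::findOverlaps(ex, sub, ignore.strand = FALSE)
  hit_ids <- unique(
    S4Vectors::mcols(ex)$transcript_id[S4Vectors::queryHits(hits)])
  stats::setNames(transcript_ids %in% hit_ids, transcript_ids)
}

#' HERV (or other TE class) enrichment among tumor-specific transcripts
#'
#' Builds the 2x2 table {tumor-specific, other tumor-expressed} x
#' {overlaps class, does not} and reports the two-sided Fisher's exact
#' p-value and odds ratio.
#'
#' @param tumor_expressed_set transcript ids expressed in tumors (the
#'   background; must contain `tumor_specific_set`).
#' @param tumor_specific_set transcript ids tumor-specific in >= 1 patient.
#' @param overlaps named logical vector (from [te_overlap_flags()]) over at
#'   least the background set.
#' @param alternative passed to [stats::fisher.test()]. Default two-sided.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p_value`.
#' @export
herv_enrichment <- function(tumor_expressed_set, tumor_specific_set,
                            overlaps, alternative = "two.sided") {
  assert_that(all(tumor_specific_set %in% tumor_expressed_set),
              "tumor_specific_set must be a subset of tumor_expressed_set")
  other <- setdiff(tumor_expressed_set, tumor_specific_set)
  tab <- rbind(
    tumor_specific = c(overlap = sum(overlaps[tumor_specific_set]),
                       no_overlap = sum(!overlaps[tumor_specific_set])),
    other_expressed = c(overlap = sum(overlaps[other]),
                        no_overlap = sum(!overlaps[other])))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("empty margin in the enrichment table; p = 1", call. = FALSE)
    return(list(table = tab, odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  list(table = tab, odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Pairwise expression correlations among candidate transcripts
#'
#' Pearson correlation of tumor-sample expression for every candidate
#' pair, and the mean off-diagonal correlation per biotype class. Pairs
#' involving a zero-variance transcript are reported as missing.
#'
#' @param candidate_ids transcript ids (>= 2 for a meaningful result).
#' @param mat an `expression_matrix`.
#' @param biotypes named character vector transcript_id -> biotype.
#' @return list with `correlations` (matrix) and `class_means` (named
#'   numeric of mean off-diagonal correlations per class).
#' @export
candidate_correlations <- function(candidate_ids, mat, biotypes) {
  assert_that(length(candidate_ids) >= 2,
              "at least two candidates are required")
  x <- t(mat$values[candidate_ids, tumor_samples(mat), drop = FALSE])
  zero_var <- apply(x, 2, stats::var) == 0
  cc <- suppressWarnings(stats::cor(x))
  cc[zero_var, ] <- NA_real_
  cc[, zero_var] <- NA_real_
  diag(cc) <- 1
  cls <- biotypes[candidate_ids]
  means <- vapply(sort(unique(cls)), function(cl) {
    ids <- candidate_ids[cls == cl]
    if (length(ids) < 2) return(NA_real_)
    m <- cc[ids, ids]
    mean(m[upper.tri(m)], na.rm = TRUE)
  }, numeric(1))
  list(correlations = cc, class_means = means)
}
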
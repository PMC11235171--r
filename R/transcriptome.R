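# Transcript models, expression quantification and the structural filters
# applied before ORF calling: FPKM conversion, expression cutoffs, novel
# transcript length bounds, strand imputation against a reference catalog
# and cross-patient merging of novel transcripts.
#
# Genomic intervals are held as GRanges (1-based closed, the Bioconductor
# convention); transcript-internal ORF coordinates are 0-based half-open.

#' Construct a transcript set
#'
#' Bundles transcript-level metadata, exon structures and (optionally)
#' spliced sequences into a validated container used throughout the
#' pipeline.
#'
#' @param transcripts data frame with columns `transcript_id`, `biotype`
#'   (one of coding, lncRNA, novel), `chrom`, `strand` (`+`, `-` or `*` for
#'   unknown), `spliced_length`, and for coding transcripts `cds_start` /
#'   `cds_end` in 0-based half-open transcript coordinates.
#' @param exons `GRanges` with a `transcript_id` metadata column; exons of
#'   one transcript must be non-overlapping.
#' @param sequences optional named character vector (or `DNAStringSet`) of
#'   spliced sequences keyed by transcript id.
#' @return an object of class `transcript_set`.
#' @export
transcript_set <- function(transcripts, exons, sequences = NULL) {
  req <- c("transcript_id", "biotype", "chrom", "strand", "spliced_length")
  assert_that(is.data.frame(transcripts) && all(req %in% names(transcripts)),
              paste("transcripts needs columns:", paste(req, collapse = ", ")))
  assert_that(!anyDuplicated(transcripts$transcript_id),
              "transcript_id values must be unique")
  assert_that(all(transcripts$biotype %in% c("coding", "lncRNA", "novel")),
              "biotype must be coding, lncRNA or novel")
  if (!"cds_start" %in% names(transcripts)) transcripts$cds_start <- NA_integer_
  if (!"cds_end" %in% names(transcripts)) transcripts$cds_end <- NA_integer_
  assert_that(methods::is(exons, "GRanges") &&
                "transcript_id" %in% names(S4Vectors::mcols(exons)),
              "exons must be a GRanges with a transcript_id column")
  w <- tapply(GenomicRanges::width(exons),
              S4Vectors::mcols(exons)$transcript_id, sum)
  got <- as.integer(w[transcripts$transcript_id])
  assert_that(all(got == transcripts$spliced_length, na.rm = FALSE),
              "spliced_length must equal the sum of exon widths")
  if (!is.null(sequences)) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
    assert_that(all(transcripts$transcript_id %in% names(sequences)),
                "every transcript needs a sequence when sequences are given")
    assert_that(all(nchar(sequences[transcripts$transcript_id]) ==
                      transcripts$spliced_length),
                "sequence length must equal spliced_length")
  }
  cds_len <- transcripts$cds_end - transcripts$cds_start
  assert_that(all(is.na(cds_len) | cds_len %% 3 == 0),
              "CDS length must be divisible by 3")
  structure(list(transcripts = transcripts, exons = exons,
                 sequences = sequences),
            class = "transcript_set")
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x$transcripts), "transcripts (",
      paste(names(table(x$transcripts$biotype)),
            table(x$transcripts$biotype), collapse = ", "),
      ")\n")
  invisible(x)
}

#' Subset a transcript set by transcript id
#' @param ts a `transcript_set`.
#' @param ids transcript ids to keep.
#' @return a `transcript_set` restricted to `ids`.
#' @export
subset_transcripts <- function(ts, ids) {
  keep <- ts$transcripts$transcript_id %in% ids
  ex <- ts$exons[S4Vectors::mcols(ts$exons)$transcript_id %in% ids]
  seqs <- if (!is.null(ts$sequences))
    ts$sequences[ts$transcripts$transcript_id[keep]] else NULL
  transcript_set(ts$transcripts[keep, , drop = FALSE], ex, seqs)
}

#' Cohort-level expression cutoffs
#'
#' @param expr_cutoff FPKM above which a transcript counts as expressed in a
#'   sample (strict `>`). Default 1 (one cohort in the source study used 2).
#' @param tumor_hi FPKM the tumor sample must exceed for a tumor-specific
#'   call (strict `>`). Default 1.
#' @param normal_lo FPKM the matched normal must stay below (strict `<`).
#'   Default 0.1.
#' @param panel_max_median maximum tolerated median expression in any
#'   nonreproductive healthy-panel tissue. Default 0.5.
#' @return a `cohort_cutoffs` list.
#' @export
cohort_cutoffs <- function(expr_cutoff = 1, tumor_hi = 1, normal_lo = 0.1,
                           panel_max_median = 0.5) {
  assert_that(normal_lo < tumor_hi, "normal_lo must be below tumor_hi")
  assert_that(all(c(expr_cutoff, tumor_hi, normal_lo, panel_max_median) >= 0),
              "cutoffs must be non-negative")
  structure(list(expr_cutoff = expr_cutoff, tumor_hi = tumor_hi,
                 normal_lo = normal_lo, panel_max_median = panel_max_median),
            class = "cohort_cutoffs")
}

#' Build an expression matrix with sample metadata
#'
#' @param values numeric matrix, transcripts x samples, of non-negative
#'   FPKM values; dimnames required.
#' @param sample_meta data frame with columns `sample_id`, `patient_id`,
#'   `tissue` (tumor/normal) and optionally `cohort_id`; each patient must
#'   contribute exactly one tumor and one normal sample.
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, sample_meta) {
  assert_that(is.matrix(values) && !is.null(rownames(values)) &&
                !is.null(colnames(values)), "values must be a named matrix")
  assert_that(all(values >= 0), "FPKM values must be non-negative")
  req <- c("sample_id", "patient_id", "tissue")
  assert_that(is.data.frame(sample_meta) && all(req %in% names(sample_meta)),
              "sample_meta needs sample_id, patient_id, tissue")
  assert_that(setequal(colnames(values), sample_meta$sample_id),
              "matrix columns must match sample_meta$sample_id")
  assert_that(all(sample_meta$tissue %in% c("tumor", "normal")),
              "tissue must be tumor or normal")
  tab <- table(sample_meta$patient_id, sample_meta$tissue)
  assert_that(all(tab == 1),
              "each patient needs exactly one tumor and one normal sample")
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample_id), ]
  if (is.null(sample_meta$cohort_id)) sample_meta$cohort_id <- "cohort1"
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "samples (", length(unique(x$sample_meta$patient_id)),
      "patients )\n")
  invisible(x)
}

sample_of <- function(mat, patient, tissue) {
  m <- mat$sample_meta
  m$sample_id[m$patient_id == patient & m$tissue == tissue]
}

tumor_samples <- function(mat) {
  mat$sample_meta$sample_id[mat$sample_meta$tissue == "tumor"]
}

normal_samples <- function(mat) {
  mat$sample_meta$sample_id[mat$sample_meta$tissue == "normal"]
}

#' Convert read counts to FPKM
#'
#' fpkm = count * 1e9 / (transcript length * library size), i.e. fragments
#' per kilobase of transcript per million mapped reads.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths transcript lengths in nt, named by transcript or in row
#'   order.
#' @param library_sizes mapped reads per sample, named by sample or in
#'   column order.
#' @param sample_meta passed to [expression_matrix()].
#' @return an `expression_matrix` of FPKM values.
#' @examples
#' counts <- matrix(100, 1, 1, dimnames = list("t1", "s1"))
#' meta <- data.frame(sample_id = "s1", patient_id = "p1", tissue = "tumor")
#' # a single-sample matrix violates the paired-design invariant, so use the
#' # bare conversion: 100 * 1e9 / (1000 * 1e7) = 10 FPKM
#' ncorfTSA:::fpkm_values(counts, 1000, 1e7)
#' @export
counts_to_fpkm <- function(counts, lengths, library_sizes, sample_meta) {
  expression_matrix(fpkm_values(counts, lengths, library_sizes), sample_meta)
}

fpkm_values <- function(counts, lengths, library_sizes) {
  assert_that(is.matrix(counts), "counts must be a matrix")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (!is.null(names(library_sizes)) && !is.null(colnames(counts)))
    library_sizes <- library_sizes[colnames(counts)]
  assert_that(length(lengths) == nrow(counts) && all(lengths > 0),
              "lengths must be positive, one per transcript")
  assert_that(length(library_sizes) == ncol(counts) && all(library_sizes > 0),
              "library_sizes must be positive, one per sample")
  sweep(sweep(counts * 1e9, 1, lengths, "/"), 2, library_sizes, "/")
}

#' Transcripts expressed in a sample
#'
#' Returns the transcripts with FPKM strictly above the expression cutoff
#' in one sample.
#'
#' @param mat an `expression_matrix`.
#' @param sample sample id.
#' @param cutoffs a `cohort_cutoffs` object.
#' @return character vector of transcript ids.
#' @export
filter_expressed <- function(mat, sample, cutoffs = cohort_cutoffs()) {
  assert_that(sample %in% colnames(mat$values),
              paste("unknown sample:", sample))
  rownames(mat$values)[mat$values[, sample] > cutoffs$expr_cutoff]
}

#' Length filter for novel transcripts
#'
#' Novel transcripts shorter than `min_len` or longer than `max_len` are
#' removed (bounds inclusive); the default upper bound is the length of the
#' longest annotated tumor lncRNA (KCNQ1OT1, 91666 nt). Annotated
#' transcripts are untouched.
#'
#' @param ts a `transcript_set`.
#' @param min_len,max_len inclusive spliced-length bounds for novel
#'   transcripts.
#' @return a filtered `transcript_set`.
#' @export
filter_novel_length <- function(ts, min_len = 300, max_len = 91666) {
  tr <- ts$transcripts
  drop <- tr$biotype == "novel" &
    (tr$spliced_length < min_len | tr$spliced_length > max_len)
  subset_transcripts(ts, tr$transcript_id[!drop])
}

#' Impute the strand of unstranded novel transcripts
#'
#' Novel transcripts assembled from unstranded libraries carry no
#' orientation; the strand is imputed from a reference catalog of stranded
#' intervals overlapping the transcript's exons by at least 1 bp. With
#' conflicting matches the strand of the largest-overlap reference wins
#' (ties broken by lexicographic reference id); transcripts with no match
#' are discarded.
#'
#' @param ts a `transcript_set` (only transcripts with strand `*` are
#'   touched).
#' @param reference `GRanges` of stranded reference intervals with a
#'   `ref_id` metadata column.
#' @return list with elements `transcripts` (the updated, possibly reduced
#'   `transcript_set`) and `discarded` (ids dropped for lack of a match).
#' @export
impute_strand <- function(ts, reference) {
  assert_that(methods::is(reference, "GRanges") &&
                "ref_id" %in% names(S4Vectors::mcols(reference)),
              "reference must be a GRanges with a ref_id column")
  assert_that(all(as.character(GenomicRanges::strand(reference)) %in%
                    c("+", "-")), "reference intervals must be stranded")
  tr <- ts$transcripts
  todo <- tr$transcript_id[tr$strand == "*"]
  if (!length(todo)) return(list(transcripts = ts, discarded = character(0)))
  ex <- ts$exons[S4Vectors::mcols(ts$exons)$transcript_id %in% todo]
  hits <- GenomicRanges::findOverlaps(ex, reference, ignore.strand = TRUE)
  ov <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(ex)[S4Vectors::queryHits(hits)],
    GenomicRanges::ranges(reference)[S4Vectors::subjectHits(hits)]))
  df <- data.frame(
    transcript_id = S4Vectors::mcols(ex)$transcript_id[S4Vectors::queryHits(hits)],
    ref_id = S4Vectors::mcols(reference)$ref_id[S4Vectors::subjectHits(hits)],
    strand = as.character(GenomicRanges::strand(reference))[S4Vectors::subjectHits(hits)],
    overlap = ov, stringsAsFactors = FALSE)
  # aggregate overlap per (transcript, reference interval set member)
  if (nrow(df)) {
    agg <- stats::aggregate(overlap ~ transcript_id + ref_id + strand, df, sum)
    agg <- agg[order(agg$transcript_id, -agg$overlap, agg$ref_id), ]
    best <- agg[!duplicated(agg$transcript_id), ]
  } else {
    best <- data.frame(transcript_id = character(0), strand = character(0))
  }
  matched <- best$transcript_id
  discarded <- setdiff(todo, matched)
  tr$strand[match(matched, tr$transcript_id)] <- best$strand
  keep <- setdiff(tr$transcript_id, discarded)
  out <- ts
  out$transcripts <- tr
  out <- subset_transcripts(out, keep)
  # propagate imputed strand onto exons
  idx <- match(S4Vectors::mcols(out$exons)$transcript_id,
               out$transcripts$transcript_id)
  GenomicRanges::strand(out$exons) <- out$transcripts$strand[idx]
  list(transcripts = out, discarded = discarded)
}

#' Merge novel transcripts across patients
#'
#' Single-linkage clustering of novel transcripts sharing at least 1 bp of
#' exonic overlap on the same chromosome and strand; each cluster is
#' represented by its longest member (ties broken by transcript id).
#'
#' @param ts a `transcript_set` of stranded novel transcripts (one entry
#'   per patient-level transcript).
#' @return list with `representatives` (a `transcript_set`) and
#'   `membership` (data frame transcript_id -> representative_id).
#' @export
merge_novel_across_patients <- function(ts) {
  tr <- ts$transcripts
  assert_that(all(tr$strand %in% c("+", "-")),
              "all transcripts must be stranded before merging")
  n <- nrow(tr)
  if (n == 0) {
    return(list(representatives = ts,
                membership = data.frame(transcript_id = character(0),
                                        representative_id = character(0))))
  }
  hits <- GenomicRanges::findOverlaps(ts$exons, ts$exons,
                                      ignore.strand = FALSE)
  qi <- match(S4Vectors::mcols(ts$exons)$transcript_id[S4Vectors::queryHits(hits)],
              tr$transcript_id)
  si <- match(S4Vectors::mcols(ts$exons)$transcript_id[S4Vectors::subjectHits(hits)],
              tr$transcript_id)
  # union-find over the transcript overlap graph (single linkage)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_along(qi)) {
    a <- find(qi[k]); b <- find(si[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  reps <- vapply(split(seq_len(n), comp), function(members) {
    o <- order(-tr$spliced_length[members], tr$transcript_id[members])
    members[o[1]]
  }, integer(1))
  rep_of <- tr$transcript_id[reps[match(comp, sort(unique(comp)))]]
  membership <- data.frame(transcript_id = tr$transcript_id,
                           representative_id = rep_of,
                           stringsAsFactors = FALSE)
  list(representatives = subset_transcripts(ts, unique(rep_of)),
       membership = membership)
}
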
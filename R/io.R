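# Readers and writers for the plain-text interchange formats: GTF + FASTA
# transcript models (via rtracklayer / Biostrings), per-sample expression
# TSVs, P-site footprint TSVs, normal-panel / thymus / HLA / variant
# tables, BED6 TE annotations and the ground-truth JSON.
#
# CDS annotations travel as `cds_start` / `cds_end` GTF attributes on the
# transcript feature (0-based half-open transcript coordinates, stop codon
# included), which keeps the GTF <-> transcript_set round trip lossless
# without projecting CDS intervals through the exon chain.

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write / read transcript models as GTF
#'
#' @param ts a `transcript_set`.
#' @param path GTF file path.
#' @return the path (writer) or a `transcript_set` without sequences
#'   (reader).
#' @export
write_transcripts_gtf <- function(ts, path) {
  tr <- ts$transcripts
  ex <- ts$exons
  tx_ranges <- unlist(range(GenomicRanges::split(
    ex, S4Vectors::mcols(ex)$transcript_id)))
  tx <- GenomicRanges::GRanges(
    tr$chrom,
    IRanges::ranges(tx_ranges)[match(tr$transcript_id, names(tx_ranges))],
    strand = tr$strand)
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    source = "ncorfTSA", type = "transcript", gene_id = tr$transcript_id,
    transcript_id = tr$transcript_id, gene_biotype = tr$biotype,
    cds_start = tr$cds_start, cds_end = tr$cds_end)
  exg <- ex
  idx <- match(S4Vectors::mcols(ex)$transcript_id, tr$transcript_id)
  S4Vectors::mcols(exg) <- S4Vectors::DataFrame(
    source = "ncorfTSA", type = "exon",
    gene_id = tr$transcript_id[idx],
    transcript_id = tr$transcript_id[idx],
    gene_biotype = tr$biotype[idx])
  o <- order(match(S4Vectors::mcols(exg)$transcript_id, tr$transcript_id),
             GenomicRanges::start(exg))
  all <- c(tx, exg[o])
  rtracklayer::export(all, path, format = "gtf")
  path
}

#' @rdname write_transcripts_gtf
#' @param fasta_path optional FASTA of spliced transcript sequences.
#' @export
read_transcripts_gtf <- function(path, fasta_path = NULL) {
  g <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(g)
  tx <- g[m$type == "transcript"]
  ex <- g[m$type == "exon"]
  mtx <- S4Vectors::mcols(tx)
  exons <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(ex), GenomicRanges::ranges(ex),
    strand = GenomicRanges::strand(ex),
    transcript_id = S4Vectors::mcols(ex)$transcript_id)
  w <- tapply(GenomicRanges::width(exons),
              S4Vectors::mcols(exons)$transcript_id, sum)
  to_int <- function(x) {
    if (is.null(x)) rep(NA_integer_, length(tx)) else as.integer(x)
  }
  transcripts <- data.frame(
    transcript_id = mtx$transcript_id,
    biotype = mtx$gene_biotype,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    strand = as.character(GenomicRanges::strand(tx)),
    spliced_length = as.integer(w[mtx$transcript_id]),
    cds_start = to_int(mtx$cds_start),
    cds_end = to_int(mtx$cds_end),
    stringsAsFactors = FALSE)
  seqs <- NULL
  if (!is.null(fasta_path)) {
    x <- Biostrings::readDNAStringSet(fasta_path)
    seqs <- stats::setNames(as.character(x), names(x))
  }
  transcript_set(transcripts, exons, seqs)
}

#' Write spliced transcript sequences as FASTA
#' @param ts a `transcript_set` with sequences.
#' @param path FASTA path.
#' @return the path.
#' @export
write_transcripts_fasta <- function(ts, path) {
  assert_that(!is.null(ts$sequences), "transcript_set carries no sequences")
  x <- Biostrings::DNAStringSet(ts$sequences[ts$transcripts$transcript_id])
  Biostrings::writeXStringSet(x, path)
  path
}

#' Write / read per-sample expression tables
#'
#' One TSV per sample (columns `transcript_id`, `fpkm`) plus a samples.tsv
#' with the sample metadata.
#'
#' @param mat an `expression_matrix`.
#' @param dir directory receiving `samples.tsv` and `expr/<sample>.tsv`.
#' @return invisible vector of written paths (writer); an
#'   `expression_matrix` (reader).
#' @export
write_expression_tables <- function(mat, dir) {
  dir.create(file.path(dir, "expr"), showWarnings = FALSE, recursive = TRUE)
  paths <- write_tsv_plain(mat$sample_meta, file.path(dir, "samples.tsv"))
  for (s in colnames(mat$values)) {
    df <- data.frame(transcript_id = rownames(mat$values),
                     fpkm = mat$values[, s], stringsAsFactors = FALSE)
    paths <- c(paths, write_tsv_plain(df, file.path(dir, "expr",
                                                    paste0(s, ".tsv"))))
  }
  invisible(paths)
}

#' @rdname write_expression_tables
#' @export
read_expression_tables <- function(dir) {
  meta <- read_tsv_plain(file.path(dir, "samples.tsv"))
  cols <- lapply(meta$sample_id, function(s) {
    df <- read_tsv_plain(file.path(dir, "expr", paste0(s, ".tsv")))
    stats::setNames(df$fpkm, df$transcript_id)
  })
  ids <- names(cols[[1]])
  values <- vapply(cols, function(x) x[ids], numeric(length(ids)))
  dimnames(values) <- list(ids, meta$sample_id)
  expression_matrix(values, meta)
}

#' Write / read P-site footprint profiles
#'
#' Long TSV with columns `transcript_id`, `position_0based`, `count`
#' (nonzero positions only).
#'
#' @param profiles named list of per-transcript count vectors.
#' @param path TSV path.
#' @param lengths named integer vector of transcript spliced lengths
#'   (needed by the reader to restore full-length vectors).
#' @return the path (writer); a named list of count vectors (reader).
#' @export
write_footprints <- function(profiles, path) {
  rows <- lapply(names(profiles), function(id) {
    v <- profiles[[id]]
    nz <- which(v > 0)
    if (!length(nz)) return(NULL)
    data.frame(transcript_id = id, position_0based = nz - 1L,
               count = v[nz], stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), position_0based = integer(0),
               count = integer(0))
  write_tsv_plain(df, path)
}

#' @rdname write_footprints
#' @export
read_footprints <- function(path, lengths) {
  df <- read_tsv_plain(path)
  out <- lapply(stats::setNames(names(lengths), names(lengths)),
                function(id) integer(lengths[[id]]))
  for (id in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == id, ]
    v <- out[[id]]
    if (is.null(v)) next
    v[sub$position_0based + 1L] <- sub$count
    out[[id]] <- v
  }
  out
}

#' Write / read the normal-tissue panel
#'
#' Long TSV: `transcript_id`, `tissue`, `median_expr`, `tissue_class`
#' (reproductive / nonreproductive).
#'
#' @param panel a `normal_panel`.
#' @param path TSV path.
#' @return the path (writer); a `normal_panel` (reader).
#' @export
write_panel <- function(panel, path) {
  m <- panel$medians
  df <- data.frame(
    transcript_id = rep(rownames(m), times = ncol(m)),
    tissue = rep(colnames(m), each = nrow(m)),
    median_expr = as.vector(m),
    tissue_class = ifelse(rep(colnames(m), each = nrow(m)) %in%
                            panel$reproductive,
                          "reproductive", "nonreproductive"),
    stringsAsFactors = FALSE)
  write_tsv_plain(df, path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read_tsv_plain(path)
  tissues <- unique(df$tissue)
  ids <- unique(df$transcript_id)
  m <- matrix(0, length(ids), length(tissues), dimnames = list(ids, tissues))
  m[cbind(match(df$transcript_id, ids), match(df$tissue, tissues))] <-
    df$median_expr
  rep_t <- unique(df$tissue[df$tissue_class == "reproductive"])
  normal_panel(m, reproductive = rep_t)
}

#' Write / read a TE annotation as BED6
#'
#' The BED name column carries the TE class; on reading, features with
#' unknown strand are dropped (per [te_annotation()]).
#'
#' @param te `GRanges` with a `te_class` column.
#' @param path BED path.
#' @return the path (writer); a `GRanges` (reader).
#' @export
write_te_bed <- function(te, path) {
  g <- te
  S4Vectors::mcols(g) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(te)$te_class, score = 0L)
  rtracklayer::export(g, path, format = "bed")
  path
}

#' @rdname write_te_bed
#' @export
read_te_bed <- function(path) {
  te_annotation(rtracklayer::import(path, format = "bed"))
}

read_hla_table <- function(path) read_tsv_plain(path)

read_variant_table <- function(path) read_tsv_plain(path)

read_thymus_table <- function(path) {
  df <- read_tsv_plain(path)
  stats::setNames(df$median_expr, df$transcript_id)
}
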
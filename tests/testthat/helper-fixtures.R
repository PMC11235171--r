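# Shared fixtures and independent oracles used across the test files.

# random expression matrix with mass around the decision boundaries
random_expression_matrix <- function(n_transcripts = 200, n_patients = 12,
                                     seed = 1) {
  set.seed(seed)
  pats <- sprintf("P%02d", seq_len(n_patients))
  meta <- data.frame(
    sample_id = c(paste0(pats, "_T"), paste0(pats, "_N")),
    patient_id = rep(pats, 2),
    tissue = rep(c("tumor", "normal"), each = n_patients),
    stringsAsFactors = FALSE)
  pool <- c(0, 0.05, 0.08, 0.1, 0.12, 0.5, 1, 1.2, 2, 5)
  values <- matrix(sample(pool, n_transcripts * 2 * n_patients,
                          replace = TRUE),
                   n_transcripts, 2 * n_patients,
                   dimnames = list(sprintf("T%04d", seq_len(n_transcripts)),
                                   meta$sample_id))
  expression_matrix(values, meta)
}

random_peptide <- function(n = 1, len = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(ncorfTSA:::AA_ALPHABET20, len, replace = TRUE),
          collapse = "")
  }, character(1))
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent brute-force ORF enumeration: every start-stop pair per frame,
# keep the longest (5'-most start) per (frame, stop)
oracle_orfs <- function(s, min_len = 30) {
  s <- toupper(s)
  L <- nchar(s)
  starts_set <- c("ATG", "ACG", "CTG", "GTG", "TTG")
  stops_set <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (frame in 0:2) {
    pos <- seq(frame + 1, L - 2, by = 3)
    if (L - 2 < frame + 1) next
    codons <- substring(s, pos, pos + 2)
    start_pos <- pos[codons %in% starts_set]
    stop_pos <- pos[codons %in% stops_set]
    for (stp in stop_pos) {
      prev <- suppressWarnings(max(stop_pos[stop_pos < stp]))
      cand <- start_pos[start_pos < stp & start_pos > prev]
      if (!length(cand)) next
      st <- min(cand)
      len <- stp + 3 - st
      if (len < min_len) next
      rows[[length(rows) + 1L]] <- data.frame(
        start = as.integer(st - 1), end = as.integer(stp + 2),
        frame = as.integer((st - 1) %% 3),
        start_codon = substr(s, st, st + 2), length_nt = as.integer(len),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), start_codon = character(0),
                      length_nt = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$frame), ]
  rownames(out) <- NULL
  out
}

# exact two-sided Fisher p by hypergeometric tail enumeration
oracle_fisher_p <- function(tab) {
  x <- tab[1, 1]
  n1 <- sum(tab[1, ])
  n2 <- sum(tab[2, ])
  k <- sum(tab[, 1])
  support <- max(0, k - n2):min(k, n1)
  d <- stats::dhyper(support, n1, n2, k)
  sum(d[d <= stats::dhyper(x, n1, n2, k) * (1 + 1e-7)])
}

# two-exon toy transcript set on one chromosome for interval tests
toy_transcript_set <- function() {
  transcripts <- data.frame(
    transcript_id = c("A", "B"), biotype = c("lncRNA", "lncRNA"),
    chrom = "chr1", strand = c("+", "-"),
    spliced_length = c(200L, 150L), stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(101, 301, 1001), width = c(100, 100, 150)),
    strand = c("+", "+", "-"),
    transcript_id = c("A", "A", "B"))
  transcript_set(transcripts, exons)
}
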
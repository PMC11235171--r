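# Candidate ORF enumeration. Noncanonical ORFs start at ATG or a
# near-cognate codon (ACG, CTG, GTG, TTG), end at the first in-frame stop,
# and must span at least 30 nt (stop codon included). When several
# candidate starts share a stop in the same frame only the 5'-most (the
# longest ORF) is kept. Protein-coding transcripts contribute only their
# annotated CDS.

NC_START_CODONS <- c("ATG", "ACG", "CTG", "GTG", "TTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_nt <- function(sequence) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "sequence must be a single string")
  s <- toupper(sequence)
  assert_that(!grepl("[^ACGTN]", s),
              "sequence may only contain A, C, G, T or N")
  s
}

#' Translate an ORF nucleotide sequence
#'
#' Standard genetic code; the initiator codon is rendered as methionine
#' regardless of identity when `initiator_as_met` is `TRUE` (near-cognate
#' starts are decoded by initiator tRNA), codons containing N translate to
#' X, the terminal stop is required and excluded from the peptide, and an
#' internal stop is an error.
#'
#' @param orf_nt_sequence nucleotide sequence of the ORF, stop included.
#' @param initiator_as_met render the first codon as M. Default `TRUE`.
#' @return the peptide as a single string.
#' @examples
#' translate_orf("ATGGCTTAA")  # "MA"
#' translate_orf("CTGGCTTAA")  # also "MA": near-cognate initiator
#' @export
translate_orf <- function(orf_nt_sequence, initiator_as_met = TRUE) {
  s <- validate_nt(orf_nt_sequence)
  n <- nchar(s)
  assert_that(n %% 3 == 0 && n >= 6, "ORF length must be a multiple of 3")
  pos <- seq(1, n, 3)
  codons <- substring(s, pos, pos + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"  # ambiguous (N-containing) codons
  last <- length(aa)
  assert_that(codons[last] %in% STOP_CODONS,
              "ORF must end with a stop codon")
  assert_that(!any(aa[-last] == "*"),
              "internal stop codon in ORF sequence")
  if (initiator_as_met) aa[1] <- "M"
  paste(aa[-last], collapse = "")
}

#' Enumerate candidate noncanonical ORFs on a transcript sequence
#'
#' Scans all three frames for ORFs beginning at a candidate start codon and
#' ending at the first in-frame stop. Per (frame, stop) pair at most one ORF
#' is reported: the one with the 5'-most start, i.e. the longest of the
#' same-frame overlapping set. ORFs without a stop inside the transcript
#' are not reported; codons containing N never match a start or stop.
#'
#' @param sequence transcript nucleotide sequence (A/C/G/T/N).
#' @param min_len_nt minimum ORF length in nt, stop codon included.
#'   Default 30 (nine amino acids and the stop).
#' @param start_codons candidate start codons. Default ATG plus the four
#'   near-cognate codons.
#' @param initiator_as_met passed to [translate_orf()].
#' @return data frame with columns `start` (0-based, first base of the
#'   start codon), `end` (half-open, past the stop codon), `frame`
#'   (`start %% 3`), `start_codon`, `length_nt` and `peptide`, sorted by
#'   (start, frame).
#' @export
enumerate_ncorfs <- function(sequence, min_len_nt = 30,
                             start_codons = NC_START_CODONS,
                             initiator_as_met = TRUE) {
  s <- validate_nt(sequence)
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3
    if (n_codons < 2) next
    pos <- as.integer(frame) + 3L * seq_len(n_codons) - 2L  # 1-based codon starts
    codons <- substring(s, pos, pos + 2)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% start_codons
    cur <- NA_integer_
    for (i in seq_len(n_codons)) {
      if (is_stop[i]) {
        if (!is.na(cur)) {
          len <- (i - cur + 1L) * 3L
          if (len >= min_len_nt) {
            start0 <- pos[cur] - 1L
            out[[length(out) + 1L]] <- data.frame(
              start = start0, end = pos[i] + 2L, frame = start0 %% 3L,
              start_codon = codons[cur], length_nt = len,
              stringsAsFactors = FALSE)
          }
          cur <- NA_integer_
        }
      } else if (is_start[i] && is.na(cur)) {
        cur <- i
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), start_codon = character(0),
                      length_nt = integer(0), peptide = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$peptide <- vapply(seq_len(nrow(res)), function(i) {
    translate_orf(substr(s, res$start[i] + 1L, res$end[i]),
                  initiator_as_met = initiator_as_met)
  }, character(1))
  res <- res[order(res$start, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotated CDS of a coding transcript as an ORF record
#'
#' @param ts a `transcript_set` with sequences.
#' @param transcript_id id of a coding transcript whose `cds_start` /
#'   `cds_end` (0-based half-open, stop codon included) are set.
#' @return one-row ORF data frame matching [enumerate_ncorfs()] plus
#'   `orf_id`, `transcript_id` and `is_canonical = TRUE`.
#' @export
canonical_cds_orf <- function(ts, transcript_id) {
  tr <- ts$transcripts[ts$transcripts$transcript_id == transcript_id, ]
  assert_that(nrow(tr) == 1, paste("unknown transcript:", transcript_id))
  assert_that(tr$biotype == "coding",
              "canonical CDS is only defined for coding transcripts")
  assert_that(!is.na(tr$cds_start) && !is.na(tr$cds_end),
              paste("missing CDS annotation for", transcript_id))
  len <- tr$cds_end - tr$cds_start
  assert_that(len %% 3 == 0 && len >= 6 && tr$cds_start >= 0 &&
                tr$cds_end <= tr$spliced_length,
              paste("invalid CDS annotation for", transcript_id))
  s <- ts$sequences[[transcript_id]]
  assert_that(!is.null(s), "transcript sequences are required")
  nt <- substr(s, tr$cds_start + 1L, tr$cds_end)
  pep <- translate_orf(nt, initiator_as_met = TRUE)
  data.frame(orf_id = paste0(transcript_id, ":", tr$cds_start, "-", tr$cds_end),
             transcript_id = transcript_id, start = tr$cds_start,
             end = tr$cds_end, frame = tr$cds_start %% 3L,
             start_codon = substr(nt, 1, 3), length_nt = len, peptide = pep,
             is_canonical = TRUE, stringsAsFactors = FALSE)
}

#' Build the ORF catalog for a transcript set
#'
#' Noncoding transcripts (lncRNA, novel) contribute all enumerated ncORFs;
#' coding transcripts contribute only their annotated CDS.
#'
#' @inheritParams canonical_cds_orf
#' @inheritParams enumerate_ncorfs
#' @return data frame with one row per ORF: `orf_id`, `transcript_id`,
#'   `biotype`, `start`, `end`, `frame`, `start_codon`, `length_nt`,
#'   `peptide`, `is_canonical`.
#' @export
orf_catalog <- function(ts, min_len_nt = 30, start_codons = NC_START_CODONS,
                        initiator_as_met = TRUE) {
  assert_that(!is.null(ts$sequences), "transcript sequences are required")
  tr <- ts$transcripts
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    id <- tr$transcript_id[i]
    if (tr$biotype[i] == "coding") {
      df <- canonical_cds_orf(ts, id)
    } else {
      df <- enumerate_ncorfs(ts$sequences[[id]], min_len_nt = min_len_nt,
                             start_codons = start_codons,
                             initiator_as_met = initiator_as_met)
      if (!nrow(df)) return(NULL)
      df$orf_id <- paste0(id, ":", df$start, "-", df$end)
      df$transcript_id <- id
      df$is_canonical <- FALSE
    }
    df$biotype <- tr$biotype[i]
    df[, c("orf_id", "transcript_id", "biotype", "start", "end", "frame",
           "start_codon", "length_nt", "peptide", "is_canonical")]
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(orf_id = character(0), transcript_id = character(0),
                      biotype = character(0), start = integer(0),
                      end = integer(0), frame = integer(0),
                      start_codon = character(0), length_nt = integer(0),
                      peptide = character(0), is_canonical = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
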
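# HLA-I antigen-load modelling: 9-mer enumeration from tumor-specific
# sources (canonical CDS, ncORFs, missense mutations), strong-binder
# prediction (IC50 < 50 nM on at least one of the patient's alleles),
# self-peptide cross-matching, translation-index correction of the
# noncoding classes, and shared/private accounting across patients.

STRONG_BINDER_NM <- 50

#' Enumerate all 9-mers of a peptide
#'
#' @param peptide amino-acid string; windows containing X (ambiguous
#'   residues) are dropped.
#' @param k window length. Default 9 (the HLA-I core length modelled here).
#' @return character vector of the `L - k + 1` contiguous windows, in
#'   order; empty for peptides shorter than `k`.
#' @export
enumerate_9mers <- function(peptide, k = 9L) {
  assert_that(is.character(peptide) && length(peptide) == 1L,
              "peptide must be a single string")
  L <- nchar(peptide)
  if (L < k) return(character(0))
  w <- substring(peptide, 1:(L - k + 1L), k:L)
  w[!grepl("X", w, fixed = TRUE)]
}

#' Mutant 9-mers around a missense variant
#'
#' Substitutes the alternate residue and returns every 9-mer window of the
#' mutant protein containing the mutated position (at most nine, fewer near
#' the termini); windows identical to the corresponding wild-type window
#' are excluded.
#'
#' @param protein wild-type protein sequence.
#' @param protein_pos 1-based mutated residue index.
#' @param ref_aa,alt_aa reference and alternate residues; `ref_aa` must
#'   match the protein at `protein_pos`.
#' @param k window length. Default 9.
#' @return character vector of mutant 9-mers.
#' @export
mutation_windows <- function(protein, protein_pos, ref_aa, alt_aa, k = 9L) {
  L <- nchar(protein)
  assert_that(protein_pos >= 1 && protein_pos <= L,
              "protein_pos outside the protein")
  assert_that(substr(protein, protein_pos, protein_pos) == ref_aa,
              paste0("reference residue mismatch at position ", protein_pos,
                     ": protein has ",
                     substr(protein, protein_pos, protein_pos),
                     ", variant says ", ref_aa))
  mutant <- protein
  substr(mutant, protein_pos, protein_pos) <- alt_aa
  first <- max(1L, protein_pos - k + 1L)
  last <- min(protein_pos, L - k + 1L)
  if (last < first) return(character(0))
  starts <- first:last
  mw <- substring(mutant, starts, starts + k - 1L)
  ww <- substring(protein, starts, starts + k - 1L)
  mw <- mw[mw != ww]
  mw[!grepl("X", mw, fixed = TRUE)]
}

#' Filter somatic variant records
#'
#' High-confidence missense variants: total depth strictly above 10, at
#' least 3 reads supporting the alternative allele, consequence missense.
#'
#' @param records data frame with columns `depth`, `alt_reads`,
#'   `consequence` (plus identifying columns passed through).
#' @param min_depth depth must exceed this (strict). Default 10.
#' @param min_alt_reads minimum alt-supporting reads (inclusive). Default 3.
#' @return the passing rows.
#' @export
filter_variants <- function(records, min_depth = 10, min_alt_reads = 3) {
  req <- c("depth", "alt_reads", "consequence")
  assert_that(is.data.frame(records) && all(req %in% names(records)),
              paste("variant records need columns:",
                    paste(req, collapse = ", ")))
  bad <- !is.finite(records$depth) | !is.finite(records$alt_reads)
  if (any(bad)) {
    stop("malformed variant record at row(s): ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  records[records$depth > min_depth & records$alt_reads >= min_alt_reads &
            records$consequence == "missense", , drop = FALSE]
}

#' Predict strong HLA-I binders for a patient
#'
#' One binding call is made per (peptide, allele) pair; a peptide is a
#' patient-level strong binder when its predicted IC50 is below 50 nM for
#' at least one of the patient's alleles. Duplicated allele entries and
#' allele order do not affect the result.
#'
#' @param peptides data frame with columns `peptide`, `source_class`
#'   (coding/lncRNA/novel/mutation) and `source_id`.
#' @param patient_alleles character vector of the patient's HLA-I alleles.
#' @param predictor function `(peptide, allele) -> ic50_nm`, e.g. from
#'   [affinity_predictor_surrogate()] or [affinity_predictor_table()].
#' @param patient_id attached to the output.
#' @return data frame of binding calls: `patient_id`, `peptide`,
#'   `source_class`, `source_id`, `allele`, `ic50_nm`, `strong`.
#' @export
predict_binders <- function(peptides, patient_alleles, predictor,
                            patient_id = NA_character_) {
  assert_that(is.data.frame(peptides) &&
                all(c("peptide", "source_class", "source_id") %in%
                      names(peptides)),
              "peptides needs columns peptide, source_class, source_id")
  alleles <- sort(unique(patient_alleles))
  if (!nrow(peptides) || !length(alleles)) {
    return(data.frame(patient_id = character(0), peptide = character(0),
                      source_class = character(0), source_id = character(0),
                      allele = character(0), ic50_nm = numeric(0),
                      strong = logical(0)))
  }
  idx <- rep(seq_len(nrow(peptides)), times = length(alleles))
  al <- rep(alleles, each = nrow(peptides))
  ic50 <- predictor(peptides$peptide[idx], al)
  assert_that(all(is.finite(ic50)) && all(ic50 > 0),
              "predictor must return positive finite IC50 values")
  data.frame(patient_id = patient_id, peptide = peptides$peptide[idx],
             source_class = peptides$source_class[idx],
             source_id = peptides$source_id[idx], allele = al,
             ic50_nm = ic50, strong = ic50 < STRONG_BINDER_NM,
             stringsAsFactors = FALSE)
}

#' Patient-level strong-binder peptide sets by class
#'
#' @param calls binding calls from [predict_binders()] (possibly several
#'   patients bound together).
#' @return data frame of unique (patient_id, source_class, peptide) rows
#'   for peptides strong on >= 1 allele.
#' @export
strong_binder_sets <- function(calls) {
  st <- calls[calls$strong, c("patient_id", "source_class", "peptide")]
  unique(st)
}

#' Self-peptide cross-match filter
#'
#' Removes strong-binder peptides whose exact sequence occurs in the self
#' set (the annotated proteome plus ORF translations of transcripts that
#' are not tumor-specific anywhere in the cohort): such peptides are not
#' tumor-restricted and could cross-react.
#'
#' @param strong_calls data frame with at least `peptide` and
#'   `source_class` columns.
#' @param self_9mer_set character vector of self 9-mers.
#' @return list with `filtered` (retained rows) and `removed_fraction`
#'   (named per-class fraction removed).
#' @export
self_filter <- function(strong_calls, self_9mer_set) {
  hit <- strong_calls$peptide %in% self_9mer_set
  removed <- vapply(split(hit, strong_calls$source_class), mean, numeric(1))
  list(filtered = strong_calls[!hit, , drop = FALSE],
       removed_fraction = removed)
}

#' Build the self 9-mer set
#'
#' @param catalog full ORF catalog of the cohort.
#' @param tumor_specific_ids transcripts tumor-specific in >= 1 patient.
#' @return character vector: all 9-mers of canonical proteins plus all
#'   9-mers of ORFs on transcripts never called tumor-specific.
#' @export
self_peptide_set <- function(catalog, tumor_specific_ids) {
  keep <- !catalog$transcript_id %in% tumor_specific_ids
  unique(unlist(lapply(catalog$peptide[keep], enumerate_9mers),
                use.names = FALSE))
}

#' Translation-index-corrected antigen load
#'
#' Corrected load: unique self-filtered strong binders per class,
#' multiplied by the class translation index for lncRNA and novel sources
#' (the fraction of ncORF sequence space expected to be translated);
#' coding and mutation counts are used as-is.
#'
#' @param strong_sets patient-level strong-binder sets (data frame
#'   `patient_id`, `source_class`, `peptide`) after self-filtering.
#' @param raw_sets the same sets before self-filtering (for bookkeeping);
#'   defaults to `strong_sets`.
#' @param translation_indices named numeric, e.g.
#'   `c(lncRNA = 0.116, novel = 0.0053)`; values in `[0, 1]`.
#' @param patients patient ids to report (defaults to those present).
#' @return data frame per (patient_id, source_class): `n_strong_raw`,
#'   `n_strong_selffiltered`, `translation_index_used`, `n_corrected`.
#' @export
antigen_load <- function(strong_sets, raw_sets = strong_sets,
                         translation_indices = c(lncRNA = 0.116,
                                                 novel = 0.0053),
                         patients = NULL) {
  assert_that(is_prob(translation_indices),
              "translation indices must lie in [0, 1]")
  if (is.null(patients)) patients <- unique(raw_sets$patient_id)
  classes <- c("coding", "lncRNA", "novel", "mutation")
  grid <- expand.grid(patient_id = patients, source_class = classes,
                      stringsAsFactors = FALSE)
  cnt <- function(sets, p, cl) {
    length(unique(sets$peptide[sets$patient_id == p &
                                 sets$source_class == cl]))
  }
  grid$n_strong_raw <- mapply(cnt, list(raw_sets),
                              grid$patient_id, grid$source_class)
  grid$n_strong_selffiltered <- mapply(cnt, list(strong_sets),
                                       grid$patient_id, grid$source_class)
  assert_that(all(grid$n_strong_selffiltered <= grid$n_strong_raw),
              "self-filtered counts exceed raw counts")
  idx <- translation_indices[grid$source_class]
  idx[is.na(idx)] <- 1  # coding and mutation classes are not deflated
  grid$translation_index_used <- unname(idx)
  grid$n_corrected <- grid$n_strong_selffiltered * grid$translation_index_used
  grid
}

#' Per-class contribution fractions of the corrected antigen load
#'
#' @param loads output of [antigen_load()].
#' @return named numeric: each class's summed corrected load divided by the
#'   cohort total.
#' @export
class_contributions <- function(loads) {
  tot <- tapply(loads$n_corrected, loads$source_class, sum)
  tot <- tot[!is.na(tot)]
  if (sum(tot) == 0) return(tot * 0)
  tot / sum(tot)
}

#' Shared vs private strong binders per class
#'
#' A peptide is shared when the identical 9-mer is a patient-level strong
#' binder in at least two distinct patients; fractions are computed over
#' the unique peptides of each class and satisfy shared + private = 1.
#'
#' @param strong_sets data frame `patient_id`, `source_class`, `peptide`.
#' @return data frame per class: `n_peptides`, `shared_fraction`,
#'   `private_fraction`.
#' @export
shared_private_summary <- function(strong_sets) {
  classes <- sort(unique(strong_sets$source_class))
  out <- do.call(rbind, lapply(classes, function(cl) {
    sub <- unique(strong_sets[strong_sets$source_class == cl,
                              c("patient_id", "peptide")])
    npat <- table(sub$peptide)
    shared <- mean(npat >= 2)
    data.frame(source_class = cl, n_peptides = length(npat),
               shared_fraction = shared, private_fraction = 1 - shared,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(source_class = character(0), n_peptides = integer(0),
                      shared_fraction = numeric(0),
                      private_fraction = numeric(0))
  }
  out
}
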
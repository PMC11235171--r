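# Synthetic cohort generator.
#
# Emits a fully labelled cohort (transcript models, spliced sequences,
# per-sample FPKM tables, P-site footprint profiles, a healthy-tissue
# panel, thymus medians, TE annotations, patient HLA alleles and somatic
# variants) with the statistical structure the analysis assumes: noncoding
# transcripts expressed below coding ones, patient-specific tumor
# activation events with a truncated-geometric prevalence, 3-nt-periodic
# footprints over translated ORFs versus uniform noise elsewhere, HERV
# overlap enriched among tumor-specific noncoding loci, and essentially
# private somatic mutations. Every record maps to a ground-truth label so
# each downstream stage can be tested for recovery.

rate_by_class <- function(x, field) {
  classes <- c("coding", "lncRNA", "novel")
  if (length(x) == 1L && is.null(names(x))) x <- stats::setNames(rep(x, 3), classes)
  assert_that(is.numeric(x) && all(classes %in% names(x)) && is_prob(x),
              paste0("invalid config field '", field,
                     "': need probabilities for coding, lncRNA, novel"))
  x[classes]
}

#' Configuration of the synthetic cohort
#'
#' All probabilities must lie in `[0, 1]` and all counts be at least 1; the
#' seed fixes every downstream draw, so two bundles generated from the same
#' configuration are identical.
#'
#' @param n_patients number of patients (each contributes one tumor and one
#'   matched normal sample).
#' @param n_coding,n_lncrna,n_novel transcript counts per class.
#' @param tumor_specific_rate probability per class that a transcript is a
#'   tumor-activation event; scalar or named vector.
#' @param normal_specific_rate probability per class of a normal-activation
#'   event (high in the normal, silent in the tumor); scalar or named.
#' @param prevalence_geom_p success probability of the truncated geometric
#'   distribution of the number of carrier patients per event: most events
#'   are private, a minority is shared by several patients.
#' @param translated_fraction_lncrna,translated_fraction_novel target
#'   length-weighted fraction of ncORF sequence that is translated, per
#'   class. Defaults 0.116 and 0.0053, the values reported for
#'   hepatocellular tumors.
#' @param inframe_read_fraction probability that a footprint of a
#'   translated ORF falls in frame 0. Default 0.58, the observed in-frame
#'   periodicity of 28-nt footprints.
#' @param mean_depth mean footprints per translated ORF (Poisson).
#' @param noise_depth mean footprints of uniform noise per untranslated
#'   ORF; defaults to `mean_depth / 10`.
#' @param herv_background_rate HERV (LTR) overlap probability of a
#'   noncoding transcript that is not tumor-specific.
#' @param herv_enrichment_odds odds multiplier of HERV overlap for
#'   tumor-specific noncoding transcripts.
#' @param testis_fraction fraction of tumor-specific transcripts also
#'   expressed in testis (annotation only; never gates calls).
#' @param thymus_fraction fraction of tumor-specific transcripts expressed
#'   in thymus.
#' @param n_alleles_per_patient HLA-I alleles drawn per patient. Default 6.
#' @param mutation_rate expected somatic missense mutations per patient.
#' @param mutation_recurrence_rate probability that a mutation recurs in a
#'   second patient. Default 0 (private mutations).
#' @param self_overlap_rate per-class fraction of a tumor-specific source's
#'   peptide sequence copied from non-tumor-specific proteins, creating
#'   self-matching 9-mers for the cross-match filter.
#' @param strong_binder_target calibration quantile of the surrogate
#'   affinity predictor.
#' @param fpkm_meanlog,fpkm_sdlog log-normal location (per class) and scale
#'   of baseline expression; coding > lncRNA > novel by default.
#' @param noise_sdlog per-sample multiplicative log-normal noise.
#' @param fpkm_scale global multiplier of all expression values (0 gives
#'   all-zero tables).
#' @param cutoffs a `cohort_cutoffs` object the simulation respects.
#' @param min_orf_len minimum ncORF length (nt, stop included).
#' @param seed random seed.
#' @return a validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 12, n_coding = 60, n_lncrna = 80,
                          n_novel = 40,
                          tumor_specific_rate = c(coding = 0.08,
                                                  lncRNA = 0.2, novel = 0.2),
                          normal_specific_rate = 0.08,
                          prevalence_geom_p = 0.45,
                          translated_fraction_lncrna = 0.116,
                          translated_fraction_novel = 0.0053,
                          inframe_read_fraction = 0.58,
                          mean_depth = 300, noise_depth = NULL,
                          herv_background_rate = 0.15,
                          herv_enrichment_odds = 4,
                          testis_fraction = 0.3, thymus_fraction = 0.05,
                          n_alleles_per_patient = 6,
                          mutation_rate = 3,
                          mutation_recurrence_rate = 0,
                          self_overlap_rate = c(coding = 0.25,
                                                lncRNA = 0.015,
                                                novel = 0.015),
                          strong_binder_target = 0.09,
                          fpkm_meanlog = c(coding = log(20), lncRNA = log(4),
                                           novel = log(2.5)),
                          fpkm_sdlog = 0.6, noise_sdlog = 0.4,
                          fpkm_scale = 1,
                          cutoffs = cohort_cutoffs(),
                          min_orf_len = 30, seed = 1) {
  for (f in c("n_patients", "n_coding", "n_lncrna", "n_novel",
              "n_alleles_per_patient")) {
    assert_that(is_count(get(f)), paste0("invalid config field '", f,
                                         "': must be a count >= 1"))
  }
  for (f in c("prevalence_geom_p", "translated_fraction_lncrna",
              "translated_fraction_novel", "inframe_read_fraction",
              "herv_background_rate", "testis_fraction", "thymus_fraction",
              "mutation_recurrence_rate", "strong_binder_target")) {
    assert_that(is_prob(get(f)) && length(get(f)) == 1L,
                paste0("invalid config field '", f,
                       "': must be a probability"))
  }
  for (f in c("mean_depth", "mutation_rate", "herv_enrichment_odds",
              "fpkm_sdlog", "noise_sdlog", "fpkm_scale")) {
    v <- get(f)
    assert_that(is.numeric(v) && length(v) == 1L && v >= 0,
                paste0("invalid config field '", f,
                       "': must be non-negative"))
  }
  assert_that(prevalence_geom_p > 0,
              "invalid config field 'prevalence_geom_p': must be positive")
  if (is.null(noise_depth)) noise_depth <- mean_depth / 10
  assert_that(is.numeric(noise_depth) && noise_depth >= 0,
              "invalid config field 'noise_depth': must be non-negative")
  assert_that(is.numeric(seed) && length(seed) == 1L && seed == floor(seed),
              "invalid config field 'seed': must be an integer")
  structure(list(
    n_patients = as.integer(n_patients), n_coding = as.integer(n_coding),
    n_lncrna = as.integer(n_lncrna), n_novel = as.integer(n_novel),
    tumor_specific_rate = rate_by_class(tumor_specific_rate,
                                        "tumor_specific_rate"),
    normal_specific_rate = rate_by_class(normal_specific_rate,
                                         "normal_specific_rate"),
    prevalence_geom_p = prevalence_geom_p,
    translated_fraction_lncrna = translated_fraction_lncrna,
    translated_fraction_novel = translated_fraction_novel,
    inframe_read_fraction = inframe_read_fraction,
    mean_depth = mean_depth, noise_depth = noise_depth,
    herv_background_rate = herv_background_rate,
    herv_enrichment_odds = herv_enrichment_odds,
    testis_fraction = testis_fraction, thymus_fraction = thymus_fraction,
    n_alleles_per_patient = as.integer(n_alleles_per_patient),
    mutation_rate = mutation_rate,
    mutation_recurrence_rate = mutation_recurrence_rate,
    self_overlap_rate = rate_by_class(self_overlap_rate,
                                      "self_overlap_rate"),
    strong_binder_target = strong_binder_target,
    fpkm_meanlog = fpkm_meanlog, fpkm_sdlog = fpkm_sdlog,
    noise_sdlog = noise_sdlog, fpkm_scale = fpkm_scale,
    cutoffs = cutoffs, min_orf_len = as.integer(min_orf_len),
    seed = as.integer(seed)), class = "cohort_config")
}

patient_ids <- function(config) sprintf("P%02d", seq_len(config$n_patients))

HLA_POOL <- c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02",
              "HLA-B*07:02", "HLA-B*08:01", "HLA-B*35:01", "HLA-B*44:02",
              "HLA-C*04:01", "HLA-C*05:01", "HLA-C*07:01", "HLA-C*07:02")

# truncated geometric over 1..n (number of carrier patients per event)
draw_prevalence <- function(n, p) {
  sample.int(n, 1L, prob = (1 - p)^(0:(n - 1L)))
}

# --- event layer (cheap; no sequences) ------------------------------------

sim_events <- function(config) {
  ids <- c(sprintf("COD%03d", seq_len(config$n_coding)),
           sprintf("LNC%03d", seq_len(config$n_lncrna)),
           sprintf("NOV%03d", seq_len(config$n_novel)))
  biotype <- rep(c("coding", "lncRNA", "novel"),
                 c(config$n_coding, config$n_lncrna, config$n_novel))
  n <- length(ids)
  ts <- stats::runif(n) < config$tumor_specific_rate[biotype]
  ns <- !ts & stats::runif(n) < config$normal_specific_rate[biotype]
  carriers <- vector("list", n)
  ns_carriers <- vector("list", n)
  pats <- patient_ids(config)
  for (i in seq_len(n)) {
    if (ts[i]) {
      k <- draw_prevalence(config$n_patients, config$prevalence_geom_p)
      carriers[[i]] <- sort(sample(pats, k))
    } else carriers[[i]] <- character(0)
    if (ns[i]) {
      k <- draw_prevalence(config$n_patients, config$prevalence_geom_p)
      ns_carriers[[i]] <- sort(sample(pats, k))
    } else ns_carriers[[i]] <- character(0)
  }
  noncoding <- biotype != "coding"
  p0 <- config$herv_background_rate
  odds <- config$herv_enrichment_odds
  p1 <- if (p0 == 0) 0 else (odds * p0) / (1 - p0 + odds * p0)
  herv <- noncoding & stats::runif(n) < ifelse(ts, p1, p0)
  testis <- ts & stats::runif(n) < config$testis_fraction
  thymus <- ts & stats::runif(n) < config$thymus_fraction
  data.frame(transcript_id = ids, biotype = biotype, tumor_specific = ts,
             normal_specific = ns, herv_overlap = herv,
             testis_expressed = testis, thymus_expressed = thymus,
             carriers = I(carriers), normal_carriers = I(ns_carriers),
             stringsAsFactors = FALSE)
}

#' Draw the cohort's tumor-activation events
#'
#' The cheap label layer of the generator: per-transcript class,
#' tumor/normal-specific status with carrier patients (truncated-geometric
#' prevalence), HERV overlap, testis and thymus flags. Used standalone for
#' calibration checks and internally by [generate_cohort()].
#'
#' @param config a `cohort_config`.
#' @return data frame with one row per transcript; `carriers` and
#'   `normal_carriers` are list columns of patient ids.
#' @export
simulate_specificity_events <- function(config) {
  set.seed(config$seed)
  sim_events(config)
}

# --- sequence layer --------------------------------------------------------

NONSTOP_CODONS <- setdiff(
  apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                    c("A","C","G","T")), 1, paste, collapse = ""),
  STOP_CODONS)

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Noncoding transcripts are built from ORF cassettes separated by stop-rich
# spacers. Spacer codons carry no start codon in any frame, and every
# seventh cassette codon block embeds the CTA-AAT-AAG motif, which places a
# stop in both shifted frames; together these keep candidate ORFs
# essentially non-overlapping, so a chosen set of cassettes can be marked
# translated without their footprint signals diluting each other's
# periodicity.
SPACER_CODONS <- c("TAA", "TGA", "TAG", "CTA", "AAT", "AAG")

make_spacer <- function(n_codons = sample(8:16, 1)) {
  paste(sample(SPACER_CODONS, n_codons, replace = TRUE), collapse = "")
}

make_cassette <- function(n_codons) {
  inner <- n_codons - 2L
  phase <- seq_len(inner) %% 7L
  codons <- character(inner)
  codons[phase == 3L] <- "CTA"
  codons[phase == 4L] <- "AAT"
  codons[phase == 5L] <- "AAG"
  free <- !phase %in% 3:5
  codons[free] <- sample(NONSTOP_CODONS, sum(free), replace = TRUE)
  paste0(sample(NC_START_CODONS, 1), paste(codons, collapse = ""),
         sample(STOP_CODONS, 1))
}

make_noncoding_sequence <- function(biotype) {
  if (biotype == "lncRNA") {
    k <- sample(3:6, 1)
    sizes <- sample(12:80, k, replace = TRUE)
  } else {
    k <- sample(2:4, 1)
    sizes <- sample(11:60, k, replace = TRUE)
  }
  pieces <- character(2L * k + 1L)
  pieces[1] <- make_spacer()
  for (j in seq_len(k)) {
    pieces[2L * j] <- make_cassette(sizes[j])
    pieces[2L * j + 1L] <- make_spacer()
  }
  s <- paste0(sample(c("", "T", "CT"), 1), paste(pieces, collapse = ""))
  min_len <- if (biotype == "novel") 305L else 200L
  while (nchar(s) < min_len) s <- paste0(s, make_spacer())
  s
}

sim_transcript_models <- function(config, events) {
  n <- nrow(events)
  chroms <- paste0("chr", 1:4)
  chrom <- chroms[(seq_len(n) - 1L) %% 4L + 1L]
  cursor <- stats::setNames(rep(1L, 4), chroms)
  seqs <- character(n)
  cds_start <- rep(NA_integer_, n)
  cds_end <- rep(NA_integer_, n)
  spliced_len <- integer(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  exon_rows <- vector("list", n)
  for (i in seq_len(n)) {
    if (events$biotype[i] == "coding") {
      utr5 <- sample(20:80, 1)
      cds_aa <- sample(80:300, 1)
      utr3 <- sample(20:100, 1)
      cds_len <- 3L * (cds_aa + 1L)
      L <- utr5 + cds_len + utr3
      body <- paste0("ATG",
                     paste(sample(NONSTOP_CODONS, cds_aa - 1L, replace = TRUE),
                           collapse = ""),
                     sample(STOP_CODONS, 1))
      seqs[i] <- paste0(random_nt(utr5), body, random_nt(utr3))
      cds_start[i] <- utr5
      cds_end[i] <- utr5 + cds_len
    } else {
      seqs[i] <- make_noncoding_sequence(events$biotype[i])
      L <- nchar(seqs[i])
    }
    spliced_len[i] <- L
    n_ex <- sample(1:3, 1)
    lens <- if (n_ex == 1) L else {
      cuts <- sort(sample(seq(60L, L - 60L, by = 1L), n_ex - 1L))
      diff(c(0L, cuts, L))
    }
    if (any(lens < 30L)) { n_ex <- 1L; lens <- L }
    introns <- if (n_ex > 1) sample(100:800, n_ex - 1L, replace = TRUE) else
      integer(0)
    gap <- sample(500:2000, 1)
    start <- cursor[chrom[i]] + gap
    st <- integer(n_ex); en <- integer(n_ex)
    pos <- start
    for (e in seq_len(n_ex)) {
      st[e] <- pos
      en[e] <- pos + lens[e] - 1L
      pos <- en[e] + 1L + if (e < n_ex) introns[e] else 0L
    }
    cursor[chrom[i]] <- en[n_ex]
    exon_rows[[i]] <- data.frame(chrom = chrom[i], start = st, end = en,
                                 strand = strand[i],
                                 transcript_id = events$transcript_id[i],
                                 stringsAsFactors = FALSE)
  }
  exdf <- do.call(rbind, exon_rows)
  exons <- GenomicRanges::GRanges(exdf$chrom,
                                  IRanges::IRanges(exdf$start, exdf$end),
                                  strand = exdf$strand,
                                  transcript_id = exdf$transcript_id)
  transcripts <- data.frame(transcript_id = events$transcript_id,
                            biotype = events$biotype, chrom = chrom,
                            strand = strand, spliced_length = spliced_len,
                            cds_start = cds_start, cds_end = cds_end,
                            stringsAsFactors = FALSE)
  transcript_set(transcripts,
                 exons, stats::setNames(seqs, events$transcript_id))
}

# Copy in-frame chunks from non-tumor-specific CDSs into tumor-specific
# sources so that a controlled fraction of their 9-mers self-matches.
plant_self_overlap <- function(ts, events, config) {
  rates <- config$self_overlap_rate
  donors <- events$transcript_id[events$biotype == "coding" &
                                   !events$tumor_specific]
  if (!length(donors) || all(rates == 0)) return(ts)
  seqs <- ts$sequences
  tr <- ts$transcripts
  donor_chunk <- function(c_aa) {
    d <- sample(donors, 1)
    row <- tr[tr$transcript_id == d, ]
    aa_len <- (row$cds_end - row$cds_start) / 3 - 1
    if (aa_len < c_aa + 2) return(NULL)
    at <- sample(seq(2L, aa_len - c_aa), 1)  # interior, codon-aligned
    nt0 <- row$cds_start + 3L * (at - 1L)
    substr(seqs[[d]], nt0 + 1L, nt0 + 3L * c_aa)
  }
  for (i in which(events$tumor_specific)) {
    bt <- events$biotype[i]
    id <- events$transcript_id[i]
    if (bt == "coding") {
      r <- rates["coding"]
      if (r == 0) next
      row <- tr[tr$transcript_id == id, ]
      P <- (row$cds_end - row$cds_start) / 3 - 1
      c_aa <- min(round(r * (P - 8)) + 8L, P - 4L)
      chunk <- donor_chunk(c_aa)
      if (is.null(chunk)) next
      at <- sample(seq(2L, P - c_aa), 1)
      nt0 <- row$cds_start + 3L * (at - 1L)
      substr(seqs[[id]], nt0 + 1L, nt0 + 3L * c_aa) <- chunk
    } else {
      if (rates[bt] == 0 || stats::runif(1) > 20 * rates[bt]) next
      orfs <- enumerate_ncorfs(seqs[[id]], min_len_nt = 60)
      if (!nrow(orfs)) next
      o <- orfs[sample(nrow(orfs), 1), ]
      c_aa <- 10L
      inner <- o$length_nt / 3 - 2  # codons between start and stop
      if (inner < c_aa + 1) next
      chunk <- donor_chunk(c_aa)
      if (is.null(chunk)) next
      at <- sample(seq_len(inner - c_aa), 1)
      nt0 <- o$start + 3L * at
      substr(seqs[[id]], nt0 + 1L, nt0 + 3L * c_aa) <- chunk
    }
  }
  ts$sequences <- seqs
  ts
}

# Greedy selection of translated ORFs hitting a length-weighted target
# fraction; overlapping ORFs (any frame) are avoided while possible so
# translated signals do not dilute each other's periodicity.
select_translated_orfs <- function(catalog, q) {
  if (!nrow(catalog) || q == 0) return(character(0))
  total <- sum(catalog$length_nt)
  ord <- sample(nrow(catalog))
  sel <- logical(nrow(catalog))
  cum <- 0
  overlaps_sel <- function(i) {
    j <- which(sel & catalog$transcript_id == catalog$transcript_id[i])
    any(catalog$start[i] < catalog$end[j] & catalog$end[i] > catalog$start[j])
  }
  for (i in ord) {
    if (cum / total >= q) break
    if (overlaps_sel(i)) next
    sel[i] <- TRUE
    cum <- cum + catalog$length_nt[i]
  }
  if (cum / total < q) {  # target unreachable without overlaps
    for (i in ord) {
      if (cum / total >= q) break
      if (sel[i]) next
      sel[i] <- TRUE
      cum <- cum + catalog$length_nt[i]
    }
  }
  # drop the last pick if that lands closer to the target
  picked <- which(sel)
  if (length(picked)) {
    last <- picked[length(picked)]
    if (abs((cum - catalog$length_nt[last]) / total - q) < abs(cum / total - q))
      sel[last] <- FALSE
  }
  catalog$orf_id[sel]
}

# --- expression layer ------------------------------------------------------

#' Simulate per-sample FPKM values
#'
#' Log-normal baselines with class-dependent location (coding > lncRNA >
#' novel) and per-sample multiplicative noise. Tumor-specific transcripts
#' are forced above `tumor_hi` in carrier tumors and below `normal_lo`
#' everywhere else; normal-specific events are the mirror image. Expression
#' of non-event transcripts is clipped so that no non-event pair satisfies
#' the tumor-specificity cutoffs, making ground-truth recovery exact.
#'
#' @param config a `cohort_config`.
#' @param events event table from [simulate_specificity_events()].
#' @return an `expression_matrix`. Uses the current RNG state; call within
#'   a seeded context (as [generate_cohort()] does).
#' @export
simulate_expression <- function(config, events) {
  pats <- patient_ids(config)
  samples <- data.frame(
    sample_id = c(paste0(pats, "_T"), paste0(pats, "_N")),
    patient_id = rep(pats, 2),
    tissue = rep(c("tumor", "normal"), each = length(pats)),
    cohort_id = "SIM1", stringsAsFactors = FALSE)
  n <- nrow(events)
  cut <- config$cutoffs
  baseline <- stats::rlnorm(n, config$fpkm_meanlog[events$biotype],
                            config$fpkm_sdlog)
  values <- matrix(0, n, nrow(samples),
                   dimnames = list(events$transcript_id, samples$sample_id))
  for (p in pats) {
    tu <- baseline * stats::rlnorm(n, 0, config$noise_sdlog)
    no <- baseline * stats::rlnorm(n, 0, config$noise_sdlog)
    for (i in seq_len(n)) {
      if (events$tumor_specific[i]) {
        if (p %in% events$carriers[[i]]) {
          tu[i] <- cut$tumor_hi * (1.5 + stats::rlnorm(1, log(2), 0.8))
          no[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
        } else {
          tu[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
          no[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
        }
      } else if (events$normal_specific[i]) {
        if (p %in% events$normal_carriers[[i]]) {
          no[i] <- cut$tumor_hi * (1.5 + stats::rlnorm(1, log(2), 0.8))
          tu[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
        } else {
          tu[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
          no[i] <- stats::runif(1, 0, 0.8 * cut$normal_lo)
        }
      }
    }
    # clip non-events away from the tumor-specific acceptance region
    nonev <- !events$tumor_specific & !events$normal_specific
    hit <- nonev & tu > cut$tumor_hi & no < cut$normal_lo
    no[hit] <- cut$normal_lo
    values[, paste0(p, "_T")] <- tu
    values[, paste0(p, "_N")] <- no
  }
  expression_matrix(values * config$fpkm_scale, samples)
}

sim_panel <- function(config, events, baseline) {
  nonrep <- c("brain", "heart", "kidney", "liver", "lung", "colon")
  rep_t <- c("testis", "ovary")
  tissues <- c(nonrep, rep_t)
  n <- nrow(events)
  cutoff <- config$cutoffs$panel_max_median
  m <- matrix(0, n, length(tissues),
              dimnames = list(events$transcript_id, tissues))
  for (tt in tissues) {
    m[, tt] <- baseline * stats::rlnorm(n, 0, 0.3)
  }
  ev <- events$tumor_specific
  for (tt in nonrep) m[ev, tt] <- stats::runif(sum(ev), 0, 0.8 * cutoff)
  m[ev, "ovary"] <- stats::runif(sum(ev), 0, 0.8 * cutoff)
  m[ev, "testis"] <- ifelse(events$testis_expressed[ev],
                            stats::runif(sum(ev), 5, 50),
                            stats::runif(sum(ev), 0, 0.8 * cutoff))
  normal_panel(m * config$fpkm_scale, reproductive = rep_t)
}

sim_thymus <- function(config, events) {
  v <- stats::runif(nrow(events), 0, 0.3)
  v[events$thymus_expressed] <-
    stats::runif(sum(events$thymus_expressed), 1, 5)
  stats::setNames(v * config$fpkm_scale, events$transcript_id)
}

# --- footprint layer -------------------------------------------------------

#' Simulate the footprint profile of one ORF
#'
#' Translated ORFs receive `Poisson(mean_depth)` P-site counts distributed
#' uniformly over codons, with each count landing in frame 0 with
#' probability `inframe_read_fraction` (remainder split between frames 1
#' and 2); untranslated ORFs receive uniform noise over all ORF positions
#' (expected in-frame fraction 1/3) at the same mean depth.
#'
#' @param orf one-row ORF data frame (`start`, `end` in transcript
#'   coordinates).
#' @param translated logical.
#' @param config a `cohort_config` (`mean_depth`, `inframe_read_fraction`).
#' @param transcript_length profile length; defaults to `orf$end`.
#' @param depth override of the Poisson mean (used internally for noise).
#' @return integer vector of per-position counts of length
#'   `transcript_length`.
#' @export
simulate_footprints <- function(orf, translated, config,
                                transcript_length = orf$end, depth = NULL) {
  assert_that(orf$start >= 0 && orf$end <= transcript_length &&
                orf$start < orf$end,
              "ORF lies outside its transcript")
  if (is.null(depth)) depth <- config$mean_depth
  profile <- integer(transcript_length)
  n <- stats::rpois(1, depth)
  if (n == 0) return(profile)
  len <- orf$end - orf$start
  if (translated) {
    ncod <- len %/% 3L
    codon <- sample.int(ncod, n, replace = TRUE)
    frac <- config$inframe_read_fraction
    offset <- sample(0:2, n, replace = TRUE,
                     prob = c(frac, (1 - frac) / 2, (1 - frac) / 2))
    pos <- orf$start + 3L * (codon - 1L) + offset
  } else {
    pos <- orf$start + sample.int(len, n, replace = TRUE) - 1L
  }
  tab <- tabulate(pos + 1L, nbins = transcript_length)
  profile + tab
}

sim_profiles <- function(config, ts, catalog, translated_ids) {
  lens <- stats::setNames(ts$transcripts$spliced_length,
                          ts$transcripts$transcript_id)
  profiles <- lapply(lens, integer)
  for (i in seq_len(nrow(catalog))) {
    id <- catalog$transcript_id[i]
    tr <- catalog$is_canonical[i] || catalog$orf_id[i] %in% translated_ids
    depth <- if (tr) config$mean_depth else config$noise_depth
    profiles[[id]] <- profiles[[id]] +
      simulate_footprints(catalog[i, ], tr, config,
                          transcript_length = lens[[id]], depth = depth)
  }
  profiles
}

# --- patient layer ---------------------------------------------------------

sim_hla <- function(config) {
  pats <- patient_ids(config)
  k <- min(config$n_alleles_per_patient, length(HLA_POOL))
  do.call(rbind, lapply(pats, function(p) {
    data.frame(patient_id = p, allele = sort(sample(HLA_POOL, k)),
               stringsAsFactors = FALSE)
  }))
}

sim_mutations <- function(config, events, catalog) {
  pats <- patient_ids(config)
  genes <- catalog[catalog$is_canonical &
                     !catalog$transcript_id %in%
                     events$transcript_id[events$tumor_specific], ,
                   drop = FALSE]
  if (!nrow(genes)) {
    return(data.frame(patient_id = character(0), gene_id = character(0),
                      protein_pos = integer(0), ref_aa = character(0),
                      alt_aa = character(0), depth = integer(0),
                      alt_reads = integer(0), consequence = character(0)))
  }
  one <- function(p, passing) {
    g <- genes[sample(nrow(genes), 1), ]
    pos <- sample(nchar(g$peptide), 1)
    ref <- substr(g$peptide, pos, pos)
    alt <- sample(setdiff(AA_ALPHABET20, ref), 1)
    if (passing) {
      depth <- 11L + stats::rpois(1, 30)
      alt_reads <- 3L + stats::rpois(1, 8)
      csq <- "missense"
    } else {
      mode <- sample(c("depth", "alt", "synonymous"), 1)
      depth <- if (mode == "depth") sample(1:10, 1) else 11L + stats::rpois(1, 30)
      alt_reads <- if (mode == "alt") sample(0:2, 1) else 3L + stats::rpois(1, 8)
      csq <- if (mode == "synonymous") "synonymous" else "missense"
    }
    data.frame(patient_id = p, gene_id = g$transcript_id, protein_pos = pos,
               ref_aa = ref, alt_aa = alt, depth = depth,
               alt_reads = alt_reads, consequence = csq,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (p in pats) {
    n_pass <- stats::rpois(1, config$mutation_rate)
    n_fail <- stats::rpois(1, config$mutation_rate / 4)
    for (i in seq_len(n_pass)) rows[[length(rows) + 1L]] <- one(p, TRUE)
    for (i in seq_len(n_fail)) rows[[length(rows) + 1L]] <- one(p, FALSE)
  }
  df <- do.call(rbind, rows)
  if (config$mutation_recurrence_rate > 0 && nrow(df)) {
    pass <- which(df$depth > 10 & df$alt_reads >= 3 &
                    df$consequence == "missense")
    rec <- pass[stats::runif(length(pass)) < config$mutation_recurrence_rate]
    for (i in rec) {
      other <- sample(setdiff(pats, df$patient_id[i]), 1)
      copy <- df[i, ]
      copy$patient_id <- other
      df <- rbind(df, copy)
    }
  }
  rownames(df) <- NULL
  df
}

# --- bundle ----------------------------------------------------------------

sim_te <- function(config, events, ts) {
  ex <- ts$exons
  rows <- list()
  for (i in which(events$herv_overlap)) {
    id <- events$transcript_id[i]
    sub <- ex[S4Vectors::mcols(ex)$transcript_id == id]
    e <- sub[sample(length(sub), 1)]
    w <- min(200L, GenomicRanges::width(e))
    off <- sample.int(GenomicRanges::width(e) - w + 1L, 1) - 1L
    rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(e),
      IRanges::IRanges(GenomicRanges::start(e) + off, width = w),
      strand = GenomicRanges::strand(e), te_class = "LTR")
  }
  # decoy elements away from any transcript (beyond each chromosome cursor)
  for (ch in paste0("chr", 1:4)) {
    base <- max(GenomicRanges::end(ex[GenomicRanges::seqnames(ex) == ch]), 0) +
      10000L
    for (k in 1:5) {
      rows[[length(rows) + 1L]] <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(base + k * 1000L, width = sample(100:400, 1)),
        strand = sample(c("+", "-"), 1),
        te_class = sample(c("LINE", "SINE", "retrotransposon", "RNA"), 1))
    }
  }
  te <- suppressWarnings(do.call(c, rows))
  te_annotation(te)
}

#' Generate a synthetic cohort bundle
#'
#' Draws the full labelled cohort and, when `dir` is given, writes every
#' interchange file (GTF, FASTA, expression TSVs, footprints, panel,
#' thymus, TE BED, HLA, variants, affinity table, ground-truth JSON).
#' Regenerating with the same configuration yields byte-identical files.
#'
#' @param config a `cohort_config`.
#' @param dir optional output directory.
#' @return a `cohort_bundle`: the in-memory objects (`transcripts`,
#'   `matrix`, `panel`, `thymus`, `profiles`, `te`, `hla`, `variants`,
#'   `catalog`), the `ground_truth` labels, the `config` and (if written)
#'   the file `paths`.
#' @export
generate_cohort <- function(config, dir = NULL) {
  assert_that(inherits(config, "cohort_config"),
              "config must be built with cohort_config()")
  set.seed(config$seed)
  events <- sim_events(config)
  ts <- sim_transcript_models(config, events)
  ts <- plant_self_overlap(ts, events, config)
  catalog <- orf_catalog(ts, min_len_nt = config$min_orf_len)
  translated <- character(0)
  for (cls in c("lncRNA", "novel")) {
    q <- if (cls == "lncRNA") config$translated_fraction_lncrna else
      config$translated_fraction_novel
    for (is_ts in c(FALSE, TRUE)) {
      sub <- catalog[catalog$biotype == cls &
                       (catalog$transcript_id %in%
                          events$transcript_id[events$tumor_specific]) == is_ts, ,
                     drop = FALSE]
      translated <- c(translated, select_translated_orfs(sub, q))
    }
  }
  mat <- simulate_expression(config, events)
  baseline_for_panel <- stats::rlnorm(nrow(events),
                                      config$fpkm_meanlog[events$biotype],
                                      config$fpkm_sdlog)
  panel <- sim_panel(config, events, baseline_for_panel)
  thymus <- sim_thymus(config, events)
  profiles <- sim_profiles(config, ts, catalog, translated)
  hla <- sim_hla(config)
  variants <- sim_mutations(config, events, catalog)
  te <- sim_te(config, events, ts)
  passing <- filter_variants(variants)
  ground_truth <- list(
    transcripts = events[, c("transcript_id", "biotype", "tumor_specific",
                             "normal_specific", "herv_overlap",
                             "testis_expressed", "thymus_expressed")],
    carriers = stats::setNames(events$carriers, events$transcript_id),
    normal_carriers = stats::setNames(events$normal_carriers,
                                      events$transcript_id),
    orfs = data.frame(orf_id = catalog$orf_id,
                      transcript_id = catalog$transcript_id,
                      biotype = catalog$biotype,
                      length_nt = catalog$length_nt,
                      is_canonical = catalog$is_canonical,
                      translated = catalog$is_canonical |
                        catalog$orf_id %in% translated,
                      stringsAsFactors = FALSE),
    mutations = passing)
  bundle <- structure(list(config = config, transcripts = ts, matrix = mat,
                           panel = panel, thymus = thymus,
                           profiles = profiles, te = te, hla = hla,
                           variants = variants, catalog = catalog,
                           ground_truth = ground_truth, dir = dir,
                           paths = NULL),
                      class = "cohort_bundle")
  if (!is.null(dir)) bundle <- write_cohort_bundle(bundle, dir)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle:", x$config$n_patients, "patients,",
      nrow(x$transcripts$transcripts), "transcripts,",
      nrow(x$catalog), "ORFs",
      if (!is.null(x$dir)) paste0("(written to ", x$dir, ")") else "", "\n")
  invisible(x)
}

#' Write a cohort bundle to disk
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return the bundle with `dir` and `paths` filled in.
#' @export
write_cohort_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- list()
  p$gtf <- write_transcripts_gtf(bundle$transcripts,
                                 file.path(dir, "transcripts.gtf"))
  p$fasta <- write_transcripts_fasta(bundle$transcripts,
                                     file.path(dir, "transcripts.fa"))
  write_expression_tables(bundle$matrix, dir)
  p$samples <- file.path(dir, "samples.tsv")
  p$footprints <- write_footprints(bundle$profiles,
                                   file.path(dir, "footprints.tsv"))
  p$panel <- write_panel(bundle$panel, file.path(dir, "panel.tsv"))
  p$thymus <- write_tsv_plain(
    data.frame(transcript_id = names(bundle$thymus),
               median_expr = unname(bundle$thymus)),
    file.path(dir, "thymus.tsv"))
  p$te <- write_te_bed(bundle$te, file.path(dir, "te.bed"))
  p$hla <- write_tsv_plain(bundle$hla, file.path(dir, "hla.tsv"))
  p$variants <- write_tsv_plain(bundle$variants,
                                file.path(dir, "variants.tsv"))
  # affinity table for the mutation-derived peptides under carrier alleles
  aff <- affinity_table_for_mutations(bundle)
  p$affinity <- write_tsv_plain(aff, file.path(dir, "affinity.tsv"))
  gt <- bundle$ground_truth
  gt_json <- list(
    transcripts = gt$transcripts,
    carriers = lapply(gt$carriers, as.list),
    normal_carriers = lapply(gt$normal_carriers, as.list),
    orfs = gt$orfs, mutations = gt$mutations,
    seed = bundle$config$seed)
  p$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(gt_json, p$ground_truth, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  bundle$dir <- dir
  bundle$paths <- p
  bundle
}

affinity_table_for_mutations <- function(bundle) {
  passing <- bundle$ground_truth$mutations
  catalog <- bundle$catalog
  rows <- list()
  for (i in seq_len(nrow(passing))) {
    v <- passing[i, ]
    prot <- catalog$peptide[catalog$is_canonical &
                              catalog$transcript_id == v$gene_id]
    if (!length(prot)) next
    win <- tryCatch(mutation_windows(prot, v$protein_pos, v$ref_aa, v$alt_aa),
                    error = function(e) character(0))
    if (!length(win)) next
    al <- bundle$hla$allele[bundle$hla$patient_id == v$patient_id]
    rows[[length(rows) + 1L]] <- expand.grid(peptide = win, allele = al,
                                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(peptide = character(0), allele = character(0),
                      ic50_nm = numeric(0)))
  }
  df <- unique(do.call(rbind, rows))
  df$ic50_nm <- surrogate_affinity(df$peptide, df$allele,
                                   target = bundle$config$strong_binder_target)
  rownames(df) <- NULL
  df
}
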
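# End-to-end orchestration: quantify -> orfs -> translate -> tumorspec ->
# antigens -> cohort, reading the interchange files of a cohort directory
# and writing one output directory per stage plus a JSON manifest with a
# content checksum for every file. Re-running with identical inputs
# reproduces identical checksums (no stage uses random numbers).

PIPELINE_STAGES <- c("quantify", "orfs", "translate", "tumorspec",
                     "antigens", "cohort")

#' Pipeline run configuration
#'
#' @param input_dir directory holding a cohort bundle (see
#'   [generate_cohort()] for the file layout).
#' @param output_dir directory for stage outputs and the manifest.
#' @param cutoffs a `cohort_cutoffs` object (per-cohort overrides, e.g. the
#'   2 / 0.2 FPKM variant for cohorts with globally higher noncoding
#'   expression, are supplied here).
#' @param stages character vector of stages to run (dependency order is
#'   enforced; later stages require the outputs of earlier ones).
#' @param min_orf_len,min_reads,score_cutoff,widely_expressed_fraction
#'   stage parameters (see the stage functions).
#' @param affinity `"surrogate"` or the path to an affinity TSV (peptide,
#'   allele, ic50_nm); table lookups fall back to the surrogate for missing
#'   pairs.
#' @param strong_binder_target surrogate calibration quantile.
#' @param min_fraction,min_max_fpkm,max_normal_prevalence candidate
#'   shortlist thresholds (see [select_candidates()]).
#' @return a `run_config` list.
#' @export
run_config <- function(input_dir, output_dir,
                       cutoffs = cohort_cutoffs(),
                       stages = PIPELINE_STAGES,
                       min_orf_len = 30, min_reads = 5, score_cutoff = 0.5,
                       widely_expressed_fraction = 0.9,
                       affinity = "surrogate", strong_binder_target = 0.09,
                       min_fraction = 0.10, min_max_fpkm = 5,
                       max_normal_prevalence = 0.01) {
  assert_that(all(stages %in% PIPELINE_STAGES),
              paste("unknown stage(s):",
                    paste(setdiff(stages, PIPELINE_STAGES), collapse = ", ")))
  structure(list(input_dir = input_dir, output_dir = output_dir,
                 cutoffs = cutoffs,
                 stages = PIPELINE_STAGES[PIPELINE_STAGES %in% stages],
                 min_orf_len = min_orf_len, min_reads = min_reads,
                 score_cutoff = score_cutoff,
                 widely_expressed_fraction = widely_expressed_fraction,
                 affinity = affinity,
                 strong_binder_target = strong_binder_target,
                 min_fraction = min_fraction, min_max_fpkm = min_max_fpkm,
                 max_normal_prevalence = max_normal_prevalence),
            class = "run_config")
}

log_stage <- function(stage, what, n_in, n_out) {
  message(sprintf("stage=%s filter=%s in=%d out=%d", stage, what,
                  as.integer(n_in), as.integer(n_out)))
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' @param config a `run_config`.
#' @return the manifest (invisibly written to
#'   `output_dir/manifest.json`): per-file md5 checksums, stage status and
#'   headline counts.
#' @export
run_all <- function(config) {
  assert_that(inherits(config, "run_config"),
              "config must be built with run_config()")
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages
  state <- new.env(parent = emptyenv())
  written <- character(0)
  status <- list()
  emit <- function(df, rel) {
    path <- file.path(out, rel)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    write_tsv_plain(df, path)
    written <<- c(written, path)
    path
  }
  emit_json <- function(x, rel) {
    path <- file.path(out, rel)
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    written <<- c(written, path)
    path
  }

  if ("quantify" %in% stages) {
    with_stage("quantify", {
      state$ts <- read_transcripts_gtf(
        file.path(config$input_dir, "transcripts.gtf"),
        file.path(config$input_dir, "transcripts.fa"))
      state$mat <- read_expression_tables(config$input_dir)
      n0 <- nrow(state$ts$transcripts)
      state$ts <- filter_novel_length(state$ts)
      log_stage("quantify", "novel_length", n0, nrow(state$ts$transcripts))
      keep <- intersect(rownames(state$mat$values),
                        state$ts$transcripts$transcript_id)
      state$mat$values <- state$mat$values[keep, , drop = FALSE]
      expressed <- unique(unlist(lapply(tumor_samples(state$mat),
                                        function(s) filter_expressed(
                                          state$mat, s, config$cutoffs))))
      state$tumor_expressed <- expressed
      log_stage("quantify", "tumor_expressed", nrow(state$mat$values),
                length(expressed))
      emit(data.frame(transcript_id = sort(expressed)),
           "quantify/tumor_expressed.tsv")
    })
    status$quantify <- "ok"
  }

  if ("orfs" %in% stages) {
    with_stage("orfs", {
      state$catalog <- orf_catalog(state$ts,
                                   min_len_nt = config$min_orf_len)
      log_stage("orfs", "catalog", nrow(state$ts$transcripts),
                nrow(state$catalog))
      emit(state$catalog[, setdiff(names(state$catalog), "peptide")],
           "orfs/orf_catalog.tsv")
      pep <- Biostrings::AAStringSet(stats::setNames(state$catalog$peptide,
                                                     state$catalog$orf_id))
      path <- file.path(out, "orfs", "peptides.fa")
      Biostrings::writeXStringSet(pep, path)
      written <<- c(written, path)
    })
    status$orfs <- "ok"
  }

  if ("translate" %in% stages) {
    with_stage("translate", {
      lens <- stats::setNames(state$ts$transcripts$spliced_length,
                              state$ts$transcripts$transcript_id)
      state$profiles <- read_footprints(
        file.path(config$input_dir, "footprints.tsv"), lens)
      wide <- widely_expressed_filter(state$mat, config$cutoffs,
                                      config$widely_expressed_fraction)
      nc <- state$catalog[!state$catalog$is_canonical &
                            state$catalog$transcript_id %in% wide, ,
                          drop = FALSE]
      log_stage("translate", "widely_expressed_ncorfs",
                sum(!state$catalog$is_canonical), nrow(nc))
      calls <- call_translated(nc, state$profiles,
                               min_reads = config$min_reads,
                               score_cutoff = config$score_cutoff)
      dedup <- deduplicate_translated(calls, nc)
      log_stage("translate", "translated", nrow(calls), length(dedup))
      state$translation_calls <- calls
      state$translated_ids <- dedup
      idx <- lapply(c(lncRNA = "lncRNA", novel = "novel"), function(cl) {
        compute_translation_index(nc[nc$biotype == cl, , drop = FALSE],
                                  dedup)
      })
      state$translation_indices <- vapply(idx, `[[`, numeric(1), "value")
      emit(calls, "translate/calls.tsv")
      emit_json(idx, "translate/translation_index.json")
    })
    status$translate <- "ok"
  }

  if ("tumorspec" %in% stages) {
    with_stage("tumorspec", {
      panel <- read_panel(file.path(config$input_dir, "panel.tsv"))
      thymus <- read_thymus_table(file.path(config$input_dir, "thymus.tsv"))
      calls <- classify_tumor_specific(state$mat, panel, config$cutoffs,
                                       thymus)
      log_stage("tumorspec", "tumor_specific", nrow(calls),
                sum(calls$tumor_specific))
      state$ts_calls <- calls
      state$sharing <- sharing_table(
        calls, length(unique(state$mat$sample_meta$patient_id)))
      biotypes <- stats::setNames(state$ts$transcripts$biotype,
                                  state$ts$transcripts$transcript_id)
      state$biotypes <- biotypes
      rt <- tryCatch(specificity_ratio_test(calls, state$mat, biotypes,
                                            config$cutoffs),
                     error = function(e) list(ratios = NULL,
                                              statistic = NA, p_value = NA,
                                              note = conditionMessage(e)))
      emit(calls, "tumorspec/calls.tsv")
      emit(state$sharing, "tumorspec/sharing.tsv")
      emit_json(list(statistic = rt$statistic, p_value = rt$p_value),
                "tumorspec/ratio_test.json")
    })
    status$tumorspec <- "ok"
  }

  if ("antigens" %in% stages) {
    with_stage("antigens", {
      hla <- read_hla_table(file.path(config$input_dir, "hla.tsv"))
      variants <- read_variant_table(file.path(config$input_dir,
                                               "variants.tsv"))
      predictor <- if (identical(config$affinity, "surrogate")) {
        affinity_predictor_surrogate(config$strong_binder_target)
      } else {
        affinity_predictor_table(
          read_tsv_plain(config$affinity),
          fallback = affinity_predictor_surrogate(config$strong_binder_target))
      }
      res <- antigen_stage(state, hla, variants, predictor, config)
      state$strong_sets <- res$filtered_sets
      emit(res$raw_sets, "antigens/strong_binders_raw.tsv")
      emit(res$filtered_sets, "antigens/strong_binders.tsv")
      emit(res$loads, "antigens/antigen_load.tsv")
      emit(res$shared, "antigens/shared_private.tsv")
      emit_json(list(removed_fraction = as.list(res$removed_fraction),
                     class_contributions = as.list(res$contributions)),
                "antigens/summary.json")
    })
    status$antigens <- "ok"
  }

  if ("cohort" %in% stages) {
    with_stage("cohort", {
      te <- read_te_bed(file.path(config$input_dir, "te.bed"))
      cand <- select_candidates(state$sharing, state$mat, config$cutoffs,
                                config$min_fraction, config$min_max_fpkm,
                                config$max_normal_prevalence)
      log_stage("cohort", "candidates", nrow(state$sharing), nrow(cand))
      enr <- lapply(c(lncRNA = "lncRNA", novel = "novel"), function(cl) {
        expressed <- intersect(state$tumor_expressed,
                               names(state$biotypes)[state$biotypes == cl])
        specific <- intersect(
          unique(state$ts_calls$transcript_id[state$ts_calls$tumor_specific]),
          expressed)
        flags <- te_overlap_flags(state$ts, expressed, te, "LTR")
        h <- herv_enrichment(expressed, specific, flags)
        data.frame(biotype = cl,
                   n_specific = length(specific),
                   n_expressed = length(expressed),
                   specific_overlap = h$table["tumor_specific", "overlap"],
                   other_overlap = h$table["other_expressed", "overlap"],
                   odds_ratio = h$odds_ratio, p_value = h$p_value)
      })
      enr <- do.call(rbind, enr)
      emit(cand, "cohort/candidates.tsv")
      emit(enr, "cohort/te_enrichment.tsv")
      if (nrow(cand) >= 2) {
        cc <- candidate_correlations(cand$transcript_id, state$mat,
                                     state$biotypes)
        emit(data.frame(biotype = names(cc$class_means),
                        mean_correlation = unname(cc$class_means)),
             "cohort/correlation_means.tsv")
      }
      state$candidates <- cand
      state$te_enrichment <- enr
    })
    status$cohort <- "ok"
  }

  manifest <- list(
    stages = status,
    files = data.frame(
      path = sub(paste0("^", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", out),
                        "/?"), "", written),
      md5 = unname(tools::md5sum(written)),
      stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# strong binders, self filter, loads and sharing for every patient
antigen_stage <- function(state, hla, variants, predictor, config) {
  calls <- state$ts_calls
  ts_ids_all <- unique(calls$transcript_id[calls$tumor_specific])
  self_set <- self_peptide_set(state$catalog, ts_ids_all)
  passing <- filter_variants(variants)
  log_stage("antigens", "variants_pass", nrow(variants), nrow(passing))
  patients <- unique(state$mat$sample_meta$patient_id)
  all_calls <- list()
  for (p in patients) {
    ts_ids <- calls$transcript_id[calls$patient_id == p & calls$tumor_specific]
    src <- state$catalog[state$catalog$transcript_id %in% ts_ids, ,
                         drop = FALSE]
    peps <- list()
    if (nrow(src)) {
      for (i in seq_len(nrow(src))) {
        w <- enumerate_9mers(src$peptide[i])
        if (!length(w)) next
        peps[[length(peps) + 1L]] <- data.frame(
          peptide = w, source_class = src$biotype[i],
          source_id = src$orf_id[i], stringsAsFactors = FALSE)
      }
    }
    pv <- passing[passing$patient_id == p, , drop = FALSE]
    if (nrow(pv)) {
      tu <- state$mat$values[, sample_of(state$mat, p, "tumor")]
      for (i in seq_len(nrow(pv))) {
        g <- pv$gene_id[i]
        if (!g %in% names(tu) || tu[[g]] <= config$cutoffs$expr_cutoff) next
        prot <- state$catalog$peptide[state$catalog$is_canonical &
                                        state$catalog$transcript_id == g]
        if (!length(prot)) next
        w <- tryCatch(mutation_windows(prot, pv$protein_pos[i],
                                       pv$ref_aa[i], pv$alt_aa[i]),
                      error = function(e) character(0))
        if (!length(w)) next
        peps[[length(peps) + 1L]] <- data.frame(
          peptide = w, source_class = "mutation",
          source_id = paste0(g, ":", pv$ref_aa[i], pv$protein_pos[i],
                             pv$alt_aa[i]),
          stringsAsFactors = FALSE)
      }
    }
    if (!length(peps)) next
    pep_df <- do.call(rbind, peps)
    pep_df <- pep_df[!duplicated(pep_df[, c("peptide", "source_class")]), ]
    alleles <- hla$allele[hla$patient_id == p]
    all_calls[[p]] <- predict_binders(pep_df, alleles, predictor,
                                      patient_id = p)
  }
  bc <- if (length(all_calls)) do.call(rbind, all_calls) else
    data.frame(patient_id = character(0), peptide = character(0),
               source_class = character(0), source_id = character(0),
               allele = character(0), ic50_nm = numeric(0),
               strong = logical(0))
  raw_sets <- strong_binder_sets(bc)
  sf <- self_filter(raw_sets, self_set)
  log_stage("antigens", "self_filter", nrow(raw_sets), nrow(sf$filtered))
  loads <- antigen_load(sf$filtered, raw_sets,
                        translation_indices =
                          state$translation_indices %||%
                          c(lncRNA = 0.116, novel = 0.0053),
                        patients = patients)
  shared <- shared_private_summary(sf$filtered)
  list(binding_calls = bc, raw_sets = raw_sets, filtered_sets = sf$filtered,
       removed_fraction = sf$removed_fraction, loads = loads,
       shared = shared, contributions = class_contributions(loads))
}

# minimal command-line front end: simulate | run
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: ncorftsa simulate --out DIR [--seed N] [--patients N]",
    "       ncorftsa run --in DIR --out DIR [--stages a,b,...]", sep = "\n")
  if (!length(args)) { cat(usage, "\n"); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list()
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  if (cmd == "simulate") {
    cfg <- cohort_config(seed = as.integer(opt$seed %||% 1),
                         n_patients = as.integer(opt$patients %||% 12))
    generate_cohort(cfg, dir = opt$out)
    message("cohort written to ", opt$out)
  } else if (cmd == "run") {
    stages <- if (is.null(opt$stages)) PIPELINE_STAGES else
      strsplit(opt$stages, ",", fixed = TRUE)[[1]]
    rc <- run_config(opt[["in"]], opt$out, stages = stages)
    run_all(rc)
    message("pipeline outputs written to ", opt$out)
  } else {
    cat(usage, "\n"); return(invisible(1L))
  }
  invisible(0L)
}
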
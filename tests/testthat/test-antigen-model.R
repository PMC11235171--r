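test_that("9-mer enumeration covers all windows and drops ambiguity", {
  p9 <- random_peptide(1, 9)
  expect_equal(enumerate_9mers(p9), p9)
  expect_equal(enumerate_9mers(random_peptide(1, 8)), character(0))
  p20 <- random_peptide(1, 20)
  wins <- enumerate_9mers(p20)
  expect_equal(length(wins), 12L)
  # brute-force slicing oracle
  expect_equal(wins, vapply(1:12, function(i) substr(p20, i, i + 8),
                            character(1)))
  expect_equal(enumerate_9mers("AAAAXAAAAA"), character(0))
})

test_that("mutation windows follow sliding-window combinatorics", {
  set.seed(12)
  prot <- random_peptide(1, 100)
  pos <- 50
  ref <- substr(prot, pos, pos)
  alt <- setdiff(c("A", "W"), ref)[1]
  w <- mutation_windows(prot, pos, ref, alt)
  expect_equal(length(w), 9L)
  mut_res <- substr(alt, 1, 1)
  expect_true(all(vapply(seq_along(w), function(i) {
    grepl(mut_res, w[i], fixed = TRUE)
  }, logical(1))))
  # terminus: a mutation at residue 1 has exactly one window
  ref1 <- substr(prot, 1, 1)
  alt1 <- setdiff(c("A", "W"), ref1)[1]
  expect_equal(length(mutation_windows(prot, 1, ref1, alt1)), 1L)
  expect_error(mutation_windows(prot, 50, setdiff(LETTERS[1:3], ref)[1], "W"),
               "mismatch")
})

test_that("mutation windows equal the mutant-minus-wildtype 9-mer oracle", {
  set.seed(13)
  for (rep in 1:25) {
    L <- sample(9:60, 1)
    prot <- random_peptide(1, L)
    pos <- sample(L, 1)
    ref <- substr(prot, pos, pos)
    alt <- sample(setdiff(ncorfTSA:::AA_ALPHABET20, ref), 1)
    mutant <- prot
    substr(mutant, pos, pos) <- alt
    oracle <- setdiff(enumerate_9mers(mutant), enumerate_9mers(prot))
    expect_setequal(mutation_windows(prot, pos, ref, alt), oracle)
  }
})

test_that("variant filters are strict on depth and inclusive on alt reads", {
  rec <- data.frame(patient_id = "P1", gene_id = "g",
                    depth = c(10, 11, 50, 50),
                    alt_reads = c(5, 3, 2, 3),
                    consequence = c("missense", "missense", "missense",
                                    "synonymous"))
  pass <- filter_variants(rec)
  expect_equal(nrow(pass), 1L)
  expect_equal(pass$depth, 11)
  rec$depth[1] <- NA
  expect_error(filter_variants(rec), "malformed")
})

test_that("strong binders require IC50 strictly below 50 nM", {
  peps <- data.frame(peptide = random_peptide(3), source_class = "lncRNA",
                     source_id = "o1", stringsAsFactors = FALSE)
  fixed <- function(values) function(peptide, allele) {
    values[match(peptide, peps$peptide)]
  }
  calls <- predict_binders(peps, "HLA-A*02:01", fixed(c(49.9, 50.0, 500)),
                           patient_id = "P1")
  expect_equal(calls$strong, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(predict_binders(peps[0, ], "HLA-A*02:01",
                                    fixed(1), "P1")), 0L)
})

test_that("patient-level strong sets ignore allele order and duplicates", {
  peps <- data.frame(peptide = random_peptide(20), source_class = "coding",
                     source_id = "c1", stringsAsFactors = FALSE)
  pred <- affinity_predictor_surrogate()
  a <- c("HLA-A*02:01", "HLA-B*07:02")
  s1 <- strong_binder_sets(predict_binders(peps, a, pred, "P1"))
  s2 <- strong_binder_sets(predict_binders(peps, rev(c(a, a)), pred, "P1"))
  expect_equal(s1[order(s1$peptide), ], s2[order(s2$peptide), ],
               ignore_attr = TRUE)
})

test_that("self filter removes exact matches and reports fractions", {
  calls <- data.frame(peptide = c("AAAAAAAAA", "WWWWWWWWW", "KKKKKKKKK"),
                      source_class = c("coding", "coding", "lncRNA"),
                      patient_id = "P1", stringsAsFactors = FALSE)
  res <- self_filter(calls, c("AAAAAAAAA", "YYYYYYYYY"))
  expect_equal(res$filtered$peptide, c("WWWWWWWWW", "KKKKKKKKK"))
  expect_equal(res$removed_fraction[["coding"]], 0.5)
  expect_equal(res$removed_fraction[["lncRNA"]], 0)
})

test_that("self-filter removal is far larger for coding than noncoding
           sources on a cohort with planted overlap", {
  cfg <- cohort_config(seed = 19, n_patients = 8)
  b <- generate_cohort(cfg)
  gt <- b$ground_truth$transcripts
  ts_ids <- gt$transcript_id[gt$tumor_specific]
  self_set <- self_peptide_set(b$catalog, ts_ids)
  src <- b$catalog[b$catalog$transcript_id %in% ts_ids, ]
  peps <- do.call(rbind, lapply(seq_len(nrow(src)), function(i) {
    w <- enumerate_9mers(src$peptide[i])
    if (!length(w)) return(NULL)
    data.frame(peptide = w, source_class = src$biotype[i],
               patient_id = "all", stringsAsFactors = FALSE)
  }))
  res <- self_filter(peps, self_set)
  rf <- res$removed_fraction
  expect_gt(rf[["coding"]], 0.1)
  expect_lt(rf[["lncRNA"]], 0.05)
  expect_gt(rf[["coding"]], 5 * max(rf[["lncRNA"]], 0.005))
})

test_that("antigen load applies the translation index to noncoding only", {
  sets <- data.frame(
    patient_id = "P1",
    source_class = rep(c("lncRNA", "coding", "mutation", "novel"),
                       c(100, 20, 10, 50)),
    peptide = random_peptide(180), stringsAsFactors = FALSE)
  loads <- antigen_load(sets, sets,
                        translation_indices = c(lncRNA = 0.116,
                                                novel = 0.0053))
  g <- function(cl) loads[loads$source_class == cl, ]
  expect_equal(g("lncRNA")$n_corrected, 100 * 0.116)
  expect_equal(g("novel")$n_corrected, 50 * 0.0053)
  expect_equal(g("coding")$n_corrected, 20)
  expect_equal(g("mutation")$n_corrected, 10)
  # a zero index erases the class regardless of raw count
  z <- antigen_load(sets, sets, translation_indices = c(lncRNA = 0,
                                                        novel = 0))
  expect_equal(z$n_corrected[z$source_class == "lncRNA"], 0)
  # coding untouched by any index value
  expect_equal(z$n_corrected[z$source_class == "coding"], 20)
  # self-filtered counts can never exceed raw ones
  expect_error(antigen_load(sets, sets[1:10, ]), "exceed")
})

test_that("shared and private fractions are complementary and exact", {
  sets <- data.frame(
    patient_id = c("P1", "P2", "P1", "P2", "P3"),
    source_class = c("lncRNA", "lncRNA", "mutation", "mutation", "lncRNA"),
    peptide = c("AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD",
                "EEEEEEEEE"), stringsAsFactors = FALSE)
  sp <- shared_private_summary(sets)
  expect_equal(sp$shared_fraction + sp$private_fraction, rep(1, nrow(sp)))
  expect_equal(sp$shared_fraction[sp$source_class == "lncRNA"], 0.5)
  expect_equal(sp$shared_fraction[sp$source_class == "mutation"], 0)
  # one peptide strong in all patients and nothing else: fully shared
  all_shared <- data.frame(patient_id = c("P1", "P2", "P3"),
                           source_class = "coding",
                           peptide = "AAAAAAAAA", stringsAsFactors = FALSE)
  expect_equal(shared_private_summary(all_shared)$shared_fraction, 1)
  # disjoint peptides per patient: fully private
  disjoint <- data.frame(patient_id = c("P1", "P2"), source_class = "coding",
                         peptide = c("AAAAAAAAA", "CCCCCCCCC"),
                         stringsAsFactors = FALSE)
  expect_equal(shared_private_summary(disjoint)$shared_fraction, 0)
})
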
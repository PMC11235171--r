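small_config <- function(...) {
  cohort_config(n_patients = 6, n_coding = 15, n_lncrna = 20, n_novel = 10,
                ...)
}

test_that("configuration errors name the offending field", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(inframe_read_fraction = 1.5),
               "inframe_read_fraction")
  expect_error(cohort_config(tumor_specific_rate = c(coding = 0.1)),
               "tumor_specific_rate")
  expect_error(cohort_config(mean_depth = -1), "mean_depth")
})

test_that("the same seed reproduces a byte-identical bundle", {
  cfg <- small_config(seed = 4)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, dir = d1)
  generate_cohort(cfg, dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f1))))
})

test_that("a zero tumor-specific rate yields no events and rate 0.2 the
           binomial expectation", {
  cfg0 <- small_config(tumor_specific_rate = 0, seed = 2)
  ev <- simulate_specificity_events(cfg0)
  expect_equal(sum(ev$tumor_specific), 0L)
  # expected count of tumor-specific lncRNA events: 50 * 0.2 = 10
  counts <- vapply(1:200, function(s) {
    cfg <- cohort_config(n_patients = 12, n_lncrna = 50,
                         tumor_specific_rate = 0.2, seed = s)
    ev <- simulate_specificity_events(cfg)
    sum(ev$tumor_specific & ev$biotype == "lncRNA")
  }, numeric(1))
  expect_lt(abs(mean(counts) - 10), 0.7)  # +/- 3.5 SE of the mean
  expect_gt(stats::var(counts), 0)
})

test_that("bundle files are mutually consistent with the ground truth", {
  cfg <- small_config(seed = 8)
  d <- withr::local_tempdir()
  b <- generate_cohort(cfg, dir = d)
  ts <- read_transcripts_gtf(file.path(d, "transcripts.gtf"),
                             file.path(d, "transcripts.fa"))
  # every GTF transcript has a FASTA sequence of matching spliced length
  expect_setequal(ts$transcripts$transcript_id,
                  b$transcripts$transcripts$transcript_id)
  expect_equal(nchar(ts$sequences[ts$transcripts$transcript_id]),
               stats::setNames(ts$transcripts$spliced_length,
                               ts$transcripts$transcript_id))
  # two samples per patient, one of each tissue
  mat <- read_expression_tables(d)
  expect_equal(ncol(mat$values), 2L * cfg$n_patients)
  tab <- table(mat$sample_meta$patient_id, mat$sample_meta$tissue)
  expect_true(all(tab == 1))
  # every ground-truth ORF belongs to an emitted transcript
  expect_true(all(b$ground_truth$orfs$transcript_id %in%
                    ts$transcripts$transcript_id))
})

test_that("expression honours class ordering and the specificity cutoffs", {
  cfg <- cohort_config(n_patients = 4, n_coding = 334, n_lncrna = 333,
                       n_novel = 333, seed = 14)
  ev <- simulate_specificity_events(cfg)
  mat <- simulate_expression(cfg, ev)
  med <- tapply(rowMeans(mat$values), ev$biotype, stats::median)
  expect_gt(med[["coding"]], med[["lncRNA"]])
  expect_gt(med[["lncRNA"]], med[["novel"]])
  # tumor-specific transcripts respect the cutoffs by construction
  cut <- cfg$cutoffs
  for (i in which(ev$tumor_specific)) {
    for (p in ev$carriers[[i]]) {
      expect_gt(mat$values[i, paste0(p, "_T")], cut$tumor_hi)
      expect_lt(mat$values[i, paste0(p, "_N")], cut$normal_lo)
    }
  }
  # zero expression floor produces all-zero tables
  cfg0 <- small_config(fpkm_scale = 0, seed = 3)
  ev0 <- simulate_specificity_events(cfg0)
  expect_true(all(simulate_expression(cfg0, ev0)$values == 0))
})

test_that("footprint simulation matches the periodicity model", {
  cfg <- cohort_config(mean_depth = 300, seed = 1)
  orf <- data.frame(orf_id = "o", start = 0L, end = 300L)
  set.seed(101)
  inframe <- function(profile) {
    sum(profile[seq(1, 300, 3)]) / sum(profile)
  }
  f_tr <- replicate(30, inframe(simulate_footprints(orf, TRUE, cfg)))
  expect_lt(abs(mean(f_tr) - 0.58), 0.05)
  f_null <- replicate(30, inframe(simulate_footprints(orf, FALSE, cfg)))
  expect_lt(abs(mean(f_null) - 1 / 3), 0.05)
  # zero depth gives an all-zero profile
  cfg0 <- cohort_config(mean_depth = 0, seed = 1)
  expect_true(all(simulate_footprints(orf, TRUE, cfg0) == 0))
  expect_error(simulate_footprints(data.frame(orf_id = "o", start = 0L,
                                              end = 400L),
                                   TRUE, cfg, transcript_length = 300),
               "outside")
})

test_that("the empirical in-frame fraction converges at high depth", {
  cfg <- cohort_config(mean_depth = 1e4, seed = 1)
  orf <- data.frame(orf_id = "o", start = 0L, end = 900L)
  set.seed(55)
  profile <- simulate_footprints(orf, TRUE, cfg)
  f <- sum(profile[seq(1, 900, 3)]) / sum(profile)
  expect_lt(abs(f - cfg$inframe_read_fraction), 0.02)
})

test_that("HERV flags are enriched among tumor-specific noncoding loci", {
  cfg <- cohort_config(n_lncrna = 400, herv_enrichment_odds = 4, seed = 23)
  ev <- simulate_specificity_events(cfg)
  lnc <- ev[ev$biotype == "lncRNA", ]
  p_ts <- mean(lnc$herv_overlap[lnc$tumor_specific])
  p_bg <- mean(lnc$herv_overlap[!lnc$tumor_specific])
  expect_gt(p_ts, p_bg)
})
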
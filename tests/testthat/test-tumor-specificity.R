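test_that("matched tumor/normal cutoffs are strict on both sides", {
  cut <- cohort_cutoffs()
  expect_true(call_matched(1.5, 0.05, cut))
  expect_false(call_matched(1.5, 0.1, cut))   # normal at the boundary
  expect_false(call_matched(1.0, 0.05, cut))  # tumor at the boundary
  expect_false(call_matched(0, 0, cut))
  # the HCC1-style override shifts both boundaries
  cut2 <- cohort_cutoffs(expr_cutoff = 2, tumor_hi = 2, normal_lo = 0.2)
  expect_false(call_matched(1.5, 0.05, cut2))
  expect_true(call_matched(2.5, 0.15, cut2))
})

test_that("panel filter gates on nonreproductive tissues only", {
  m <- matrix(0, 2, 4, dimnames = list(c("t1", "t2"),
                                       c("liver", "brain", "testis",
                                         "ovary")))
  m["t1", "liver"] <- 0.6
  m["t2", "testis"] <- 50
  panel <- normal_panel(m)
  r1 <- call_panel("t1", panel)
  expect_false(r1$pass)            # liver median above 0.5
  r2 <- call_panel("t2", panel)
  expect_true(r2$pass)             # testis exemption
  expect_true(r2$testis_expressed)
  expect_true(call_panel("t1", normal_panel(m * 0))$pass)
  expect_warning(r3 <- call_panel("absent", panel), "absent")
  expect_true(r3$pass)
})

test_that("thymus flag is a strict annotation-only threshold", {
  expect_true(thymus_flag(0.6))
  expect_false(thymus_flag(0.5))
  expect_false(thymus_flag(0))
})

test_that("testis and thymus flags never change the tumor-specific call", {
  mat <- random_expression_matrix(100, 6, seed = 21)
  ids <- rownames(mat$values)
  m <- matrix(0, length(ids), 3,
              dimnames = list(ids, c("liver", "testis", "ovary")))
  m[, "testis"] <- 50  # everything testis-expressed
  panel <- normal_panel(m)
  thym <- stats::setNames(rep(10, length(ids)), ids)
  calls <- classify_tumor_specific(mat, panel, thymus_medians = thym)
  expect_true(all(calls$tumor_specific ==
                    (calls$pass_matched & calls$pass_panel)))
  no_flags <- classify_tumor_specific(mat, panel)
  expect_equal(calls$tumor_specific, no_flags$tumor_specific)
})

test_that("tumor- and normal-specific sets match brute-force comprehensions", {
  cut <- cohort_cutoffs()
  for (seed in 1:5) {
    mat <- random_expression_matrix(200, 12, seed = seed)
    calls <- classify_tumor_specific(mat, panel = NULL, cut)
    for (p in unique(mat$sample_meta$patient_id)) {
      tu <- mat$values[, paste0(p, "_T")]
      no <- mat$values[, paste0(p, "_N")]
      oracle_ts <- rownames(mat$values)[tu > 1 & no < 0.1]
      oracle_ns <- rownames(mat$values)[no > 1 & tu < 0.1]
      got <- calls$transcript_id[calls$patient_id == p & calls$tumor_specific]
      expect_setequal(got, oracle_ts)
      expect_setequal(normal_specific_set(p, mat, cut), oracle_ns)
    }
  }
})

test_that("tumor- and normal-specific calls mirror under value swap", {
  mat <- random_expression_matrix(100, 4, seed = 33)
  p <- "P01"
  swapped <- mat
  swapped$values[, paste0(p, "_T")] <- mat$values[, paste0(p, "_N")]
  swapped$values[, paste0(p, "_N")] <- mat$values[, paste0(p, "_T")]
  calls <- classify_tumor_specific(mat, panel = NULL)
  ts_p <- calls$transcript_id[calls$patient_id == p & calls$tumor_specific]
  expect_setequal(normal_specific_set(p, swapped), ts_p)
})

test_that("sharing table counts conserve total tumor-specific calls", {
  for (seed in 1:3) {
    mat <- random_expression_matrix(150, 8, seed = 40 + seed)
    calls <- classify_tumor_specific(mat, panel = NULL)
    sh <- sharing_table(calls, 8)
    expect_equal(sum(sh$n_patients_specific), sum(calls$tumor_specific))
    expect_equal(sh$fraction_patients, sh$n_patients_specific / 8)
  }
  empty <- classify_tumor_specific(
    expression_matrix(matrix(0, 2, 4,
                             dimnames = list(c("a", "b"),
                                             c("P1_T", "P2_T", "P1_N",
                                               "P2_N"))),
                      data.frame(sample_id = c("P1_T", "P2_T", "P1_N", "P2_N"),
                                 patient_id = c("P1", "P2", "P1", "P2"),
                                 tissue = c("tumor", "tumor", "normal",
                                            "normal"))),
    panel = NULL)
  expect_equal(nrow(sharing_table(empty, 2)), 0L)
})

test_that("the paired ratio test recovers noncoding-biased tumor activation", {
  cfg <- cohort_config(n_patients = 20, n_coding = 80, n_lncrna = 80,
                       n_novel = 40, seed = 5, prevalence_geom_p = 0.2,
                       tumor_specific_rate = c(coding = 0.2, lncRNA = 0.45,
                                               novel = 0.45),
                       normal_specific_rate = 0.15)
  b <- generate_cohort(cfg)
  biotypes <- stats::setNames(b$transcripts$transcripts$biotype,
                              b$transcripts$transcripts$transcript_id)
  calls <- classify_tumor_specific(b$matrix, b$panel, cfg$cutoffs)
  res <- suppressWarnings(specificity_ratio_test(calls, b$matrix, biotypes,
                                                 cfg$cutoffs))
  expect_lt(res$p_value, 0.05)
  # identical sets on both sides give no signal
  null_calls <- data.frame(patient_id = rep(c("P1", "P2", "P3"), each = 2),
                           transcript_id = "x", tumor_specific = TRUE)
  # single patient is rejected
  one <- b$matrix
  keep <- one$sample_meta$patient_id == "P01"
  one$values <- one$values[, keep, drop = FALSE]
  one$sample_meta <- one$sample_meta[keep, ]
  expect_error(specificity_ratio_test(calls, one, biotypes, cfg$cutoffs),
               "two patients")
})
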
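test_that("candidate shortlist applies ceiling, expression and prevalence
           rules", {
  # the published instance: 10% of 117 patients requires 12 or more
  expect_equal(ceiling(0.10 * 117), 12)
  mat <- random_expression_matrix(20, 12, seed = 55)
  ids <- rownames(mat$values)
  # build a controlled sharing table: 10% of 12 patients -> ceil(1.2) = 2
  sharing <- data.frame(transcript_id = ids,
                        n_patients_specific = rep(c(1L, 2L, 5L),
                                                  length.out = 20),
                        stringsAsFactors = FALSE)
  sharing$fraction_patients <- sharing$n_patients_specific / 12
  tu <- ncorfTSA:::tumor_samples(mat)
  no <- ncorfTSA:::normal_samples(mat)
  mat$values[, no] <- 0          # no normal prevalence
  mat$values[, tu] <- 0.5        # low tumor expression by default
  high <- ids[c(2, 3, 5)]
  mat$values[high, tu[1]] <- 10  # only these pass the 5-FPKM rule
  got <- select_candidates(sharing, mat)
  oracle <- ids[sharing$n_patients_specific >= 2 & ids %in% high]
  expect_setequal(got$transcript_id, oracle)
  # normal prevalence at or above 1% of normals excludes
  mat$values[high[1], no] <- 2
  got2 <- select_candidates(sharing, mat)
  expect_false(high[1] %in% got2$transcript_id)
  # output is invariant to sharing-table row order
  got3 <- select_candidates(sharing[sample(nrow(sharing)), ], mat)
  expect_equal(got2, got3)
})

test_that("TE overlap merges copies, respects strand and matches a
           per-base oracle", {
  ts <- toy_transcript_set()
  # two LTR copies covering the same 100 bp of transcript A's first exon
  te <- te_annotation(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 101, 1001), width = c(100, 100, 50)),
    strand = c("+", "+", "+"), te_class = c("LTR", "LTR", "LTR")))
  ovA <- te_overlap(ts, "A", te)
  expect_equal(ovA$overlap_bp[ovA$te_class == "LTR"], 100L)  # not 200
  expect_equal(ovA$overlap_fraction[ovA$te_class == "LTR"], 0.5)
  # transcript B is on "-": the "+" TE does not count
  ovB <- te_overlap(ts, "B", te)
  expect_equal(ovB$overlap_bp[ovB$te_class == "LTR"], 0L)
  tr_unstranded <- ts
  tr_unstranded$transcripts$strand[1] <- "*"
  expect_error(te_overlap(tr_unstranded, "A", te), "stranded")
  # unknown-strand features are dropped on construction
  te2 <- te_annotation(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(101, width = 10), strand = "*",
    te_class = "LTR"))
  expect_equal(length(te2), 0L)
})

test_that("TE overlap equals per-base counting on random interval sets", {
  set.seed(71)
  ts <- toy_transcript_set()
  exon_bases <- c(101:200, 301:400)  # transcript A's exonic coordinates
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    starts <- sample(50:450, n)
    widths <- sample(10:120, n, replace = TRUE)
    te <- te_annotation(GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = widths),
      strand = sample(c("+", "-"), n, replace = TRUE), te_class = "LTR"))
    got <- te_overlap(ts, "A", te)$overlap_bp
    plus <- te[as.character(GenomicRanges::strand(te)) == "+"]
    covered <- unique(unlist(lapply(seq_along(plus), function(i) {
      GenomicRanges::start(plus)[i]:GenomicRanges::end(plus)[i]
    })))
    expect_equal(got, length(intersect(covered, exon_bases)))
  }
})

test_that("Fisher enrichment p equals exhaustive hypergeometric enumeration", {
  set.seed(99)
  for (rep in 1:100) {
    tab <- matrix(sample(0:40, 4, replace = TRUE), 2, 2,
                  dimnames = list(c("tumor_specific", "other_expressed"),
                                  c("overlap", "no_overlap")))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    n_spec <- sum(tab[1, ]); n_other <- sum(tab[2, ])
    spec_ids <- sprintf("s%03d", seq_len(n_spec))
    other_ids <- sprintf("o%03d", seq_len(n_other))
    overlaps <- stats::setNames(
      c(rep(c(TRUE, FALSE), tab[1, ]), rep(c(TRUE, FALSE), tab[2, ])),
      c(spec_ids, other_ids))
    res <- herv_enrichment(c(spec_ids, other_ids), spec_ids, overlaps)
    expect_equal(unname(res$table), unname(tab))
    expect_lt(abs(res$p_value - oracle_fisher_p(tab)), 1e-10)
  }
  # identical overlap fractions give p near 1
  flat <- stats::setNames(rep(c(TRUE, FALSE), 20),
                          sprintf("t%03d", 1:40))
  res <- herv_enrichment(names(flat), names(flat)[1:10], flat)
  expect_gt(res$p_value, 0.5)
  # empty margin degrades gracefully
  expect_warning(
    res0 <- herv_enrichment(names(flat), character(0), flat), "margin")
  expect_equal(res0$p_value, 1)
})

test_that("candidate correlations recover co-activation structure", {
  mat <- random_expression_matrix(10, 8, seed = 81)
  ids <- rownames(mat$values)
  tu <- ncorfTSA:::tumor_samples(mat)
  # two transcripts activated in identical patient subsets
  mat$values[ids[1], tu] <- c(10, 10, 0, 0, 10, 0, 0, 10)
  mat$values[ids[2], tu] <- c(12, 11, 0, 0, 9, 0, 0, 11)
  # two independent noisy transcripts
  set.seed(1); mat$values[ids[3], tu] <- runif(8)
  mat$values[ids[4], tu] <- runif(8)
  biotypes <- stats::setNames(rep(c("coding", "lncRNA"), c(2, 8)), ids)
  cc <- candidate_correlations(ids[1:4], mat, biotypes)
  expect_equal(diag(cc$correlations), rep(1, 4), ignore_attr = TRUE)
  expect_gt(cc$correlations[ids[1], ids[2]], 0.95)
  expect_gt(cc$class_means[["coding"]], cc$class_means[["lncRNA"]])
  # zero-variance transcripts yield missing pairs
  mat$values[ids[3], tu] <- 5
  cc2 <- candidate_correlations(ids[1:4], mat, biotypes)
  expect_true(all(is.na(cc2$correlations[ids[3], c(ids[1], ids[2], ids[4])])))
})
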
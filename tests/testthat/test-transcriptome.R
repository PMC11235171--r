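test_that("FPKM conversion follows the definition and is linear", {
  counts <- matrix(c(0L, 100L), 2, 1,
                   dimnames = list(c("t0", "t1"), "s1"))
  f <- ncorfTSA:::fpkm_values(counts, lengths = c(t0 = 500, t1 = 1000),
                              library_sizes = c(s1 = 1e7))
  expect_equal(f["t0", "s1"], 0)
  expect_equal(f["t1", "s1"], 10)  # 100 * 1e9 / (1000 * 1e7)
  # doubling the library size halves every value
  f2 <- ncorfTSA:::fpkm_values(counts, c(t0 = 500, t1 = 1000), c(s1 = 2e7))
  expect_equal(f2, f / 2)
  # additivity in counts at fixed length/library
  c2 <- counts + 40L
  expect_equal(ncorfTSA:::fpkm_values(c2, c(t0 = 500, t1 = 1000), c(s1 = 1e7)),
               f + ncorfTSA:::fpkm_values(matrix(40L, 2, 1,
                                                 dimnames = dimnames(counts)),
                                          c(t0 = 500, t1 = 1000), c(s1 = 1e7)))
  expect_error(ncorfTSA:::fpkm_values(counts, c(t0 = 0, t1 = 1000),
                                      c(s1 = 1e7)), "lengths")
  expect_error(ncorfTSA:::fpkm_values(counts, c(t0 = 500, t1 = 1000),
                                      c(s1 = 0)), "library_sizes")
})

test_that("expression filter is strict and matches a brute-force oracle", {
  mat <- random_expression_matrix(50, 4, seed = 3)
  cut <- cohort_cutoffs(expr_cutoff = 1)
  for (s in colnames(mat$values)) {
    got <- filter_expressed(mat, s, cut)
    oracle <- rownames(mat$values)[mat$values[, s] > 1]
    expect_setequal(got, oracle)
  }
  # boundary: exactly at the cutoff is excluded
  mat$values["T0001", 1] <- 1
  expect_false("T0001" %in% filter_expressed(mat, colnames(mat$values)[1],
                                             cut))
  expect_error(filter_expressed(mat, "nope", cut), "unknown sample")
})

test_that("novel length bounds are inclusive at 300 and 91666", {
  lens <- c(299L, 300L, 5000L, 91666L, 91667L)
  tr <- data.frame(transcript_id = paste0("N", seq_along(lens)),
                   biotype = "novel", chrom = "chr1", strand = "+",
                   spliced_length = lens, stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, by = 2e5, length.out = 5), width = lens),
    strand = "+", transcript_id = tr$transcript_id)
  ts <- transcript_set(tr, exons)
  kept <- filter_novel_length(ts)$transcripts
  expect_setequal(kept$transcript_id, c("N2", "N3", "N4"))
  # annotated transcripts are not length-filtered
  tr$biotype <- "lncRNA"
  ts2 <- transcript_set(tr, exons)
  expect_equal(nrow(filter_novel_length(ts2)$transcripts), 5L)
})

test_that("strand imputation picks the largest overlap and discards orphans", {
  tr <- data.frame(transcript_id = c("n1", "n2", "n3"), biotype = "novel",
                   chrom = "chr1", strand = "*",
                   spliced_length = c(100L, 100L, 100L),
                   stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 5000, 9000), width = 100),
    strand = "*", transcript_id = tr$transcript_id)
  ts <- transcript_set(tr, exons)
  ref <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1000, 4990, 5050, 20000), width = c(100, 40, 100, 50)),
    strand = c("+", "+", "-", "+"),
    ref_id = c("r1", "r2", "r3", "r4"))
  res <- impute_strand(ts, ref)
  tr2 <- res$transcripts$transcripts
  expect_equal(tr2$strand[tr2$transcript_id == "n1"], "+")
  # n2: r2 overlaps 30 bp (+), r3 overlaps 50 bp (-) -> largest wins
  expect_equal(tr2$strand[tr2$transcript_id == "n2"], "-")
  expect_equal(res$discarded, "n3")
})

test_that("equal-overlap strand conflicts break ties by reference id", {
  tr <- data.frame(transcript_id = "n1", biotype = "novel", chrom = "chr1",
                   strand = "*", spliced_length = 100L,
                   stringsAsFactors = FALSE)
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, width = 100),
                                  strand = "*", transcript_id = "n1")
  ts <- transcript_set(tr, exons)
  ref <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1000, 1000), width = 100),
    strand = c("-", "+"), ref_id = c("rB", "rA"))
  r1 <- impute_strand(ts, ref)
  r2 <- impute_strand(ts, ref)
  # deterministic: lexicographically first reference id (rA, "+") wins
  expect_equal(r1$transcripts$transcripts$strand, "+")
  expect_identical(r1$transcripts$transcripts, r2$transcripts$transcripts)
})

test_that("novel merging is single-linkage on same-strand exonic overlap", {
  mk <- function(ids, starts, widths, strands) {
    tr <- data.frame(transcript_id = ids, biotype = "novel", chrom = "chr1",
                     strand = strands, spliced_length = widths,
                     stringsAsFactors = FALSE)
    exons <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = widths), strand = strands,
      transcript_id = ids)
    transcript_set(tr, exons)
  }
  # identical transcripts from two patients collapse to one representative
  ts <- mk(c("p1.n1", "p2.n1"), c(100, 100), c(200L, 200L), c("+", "+"))
  m <- merge_novel_across_patients(ts)
  expect_equal(nrow(m$representatives$transcripts), 1L)
  expect_equal(unique(m$membership$representative_id), "p1.n1")  # tie by id
  # chain A-B-C with A disjoint from C still forms one cluster
  ts <- mk(c("A", "B", "C"), c(100, 250, 400), c(200L, 200L, 200L),
           c("+", "+", "+"))
  m <- merge_novel_across_patients(ts)
  expect_equal(nrow(m$representatives$transcripts), 1L)
  expect_equal(sort(m$membership$transcript_id), c("A", "B", "C"))
  # same coordinates on opposite strands stay apart
  ts <- mk(c("A", "B"), c(100, 100), c(200L, 200L), c("+", "-"))
  m <- merge_novel_across_patients(ts)
  expect_equal(nrow(m$representatives$transcripts), 2L)
  # unstranded input is rejected
  ts <- mk("A", 100, 200L, "*")
  expect_error(merge_novel_across_patients(ts), "stranded")
})

test_that("merging matches brute-force connected components on random sets", {
  set.seed(5)
  for (rep in 1:10) {
    n <- 15
    starts <- sample(1:2000, n)
    widths <- sample(50:400, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    ids <- sprintf("t%02d", 1:n)
    tr <- data.frame(transcript_id = ids, biotype = "novel", chrom = "chr1",
                     strand = strands, spliced_length = widths,
                     stringsAsFactors = FALSE)
    exons <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = widths), strand = strands,
      transcript_id = ids)
    ts <- transcript_set(tr, exons)
    m <- merge_novel_across_patients(ts)
    # oracle: transitive closure of the pairwise overlap relation
    adj <- outer(1:n, 1:n, function(i, j) {
      starts[i] < starts[j] + widths[j] & starts[j] < starts[i] + widths[i] &
        strands[i] == strands[j]
    })
    reach <- adj
    for (k in 1:n) reach <- reach | (reach %*% (reach * 1) > 0)
    comp <- apply(reach, 1, function(r) min(which(r)))
    expect_equal(length(unique(m$membership$representative_id)),
                 length(unique(comp)))
    # membership is a partition covering every input once
    expect_setequal(m$membership$transcript_id, ids)
    # each representative belongs to its own cluster
    expect_true(all(m$membership$representative_id %in% ids))
  }
})
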
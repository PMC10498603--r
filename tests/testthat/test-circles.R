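test_that("junction calling follows the inverted-segment rule", {
  # read prefix downstream of read suffix => circular junction
  one <- data.frame(read_id = "r1", chrom = "chr1",
                    seg1_start = 1990, seg1_end = 2090,
                    seg2_start = 1000, seg2_end = 1100,
                    strand = "+", sample_id = "S1")
  out <- call_junctions(one)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 1000L)
  expect_equal(out$end, 2090L)
  expect_equal(out$split_reads, 1L)

  # collinear segments (prefix upstream of suffix) are not junctions
  collinear <- transform(one, seg1_start = 1000, seg1_end = 1100,
                         seg2_start = 1990, seg2_end = 2090)
  expect_equal(nrow(call_junctions(collinear)), 0)
})

test_that("the minimum non-overlap threshold gates junction calls", {
  # segments of 100 bp overlapping all but 5 bp: each contributes 5 bp
  # of unique span, below the 10 bp minimum
  near <- data.frame(read_id = "r1", chrom = "chr1",
                     seg1_start = 1005, seg1_end = 1105,
                     seg2_start = 1000, seg2_end = 1100,
                     strand = "+", sample_id = "S1")
  expect_equal(nrow(call_junctions(near, min_non_overlap = 10)), 0)
  expect_equal(nrow(call_junctions(near, min_non_overlap = 5)), 1)
  # brute-force check of the overlap arithmetic across offsets
  for (off in c(5, 9, 10, 11, 50)) {
    r <- transform(near, seg1_start = 1000 + off, seg1_end = 1100 + off)
    got <- nrow(call_junctions(r, min_non_overlap = 10))
    expect_equal(got, as.integer(off >= 10), info = paste("offset", off))
  }
})

test_that("inter-chromosomal reads are skipped and counted", {
  reads <- data.frame(read_id = c("r1", "r2"), chrom = "chr1",
                      chrom2 = c("chr1", "chr2"),
                      seg1_start = 1990, seg1_end = 2090,
                      seg2_start = 1000, seg2_end = 1100,
                      strand = "+", sample_id = "S1")
  out <- call_junctions(reads)
  expect_equal(nrow(out), 1)
  expect_equal(attr(out, "skipped_interchrom"), 1L)
})

test_that("identical junctions aggregate their supporting reads per sample", {
  reads <- do.call(rbind, replicate(3, data.frame(
    read_id = "r", chrom = "chr1", seg1_start = 1990, seg1_end = 2090,
    seg2_start = 1000, seg2_end = 1100, strand = "+", sample_id = "S1"),
    simplify = FALSE))
  reads$read_id <- paste0("r", 1:3)
  out <- call_junctions(reads)
  expect_equal(nrow(out), 1)
  expect_equal(out$split_reads, 3L)
})

test_that("merging applies single linkage with the highest-support representative", {
  x <- rbind(toy_circles("chr1", 100, 500, 2), toy_circles("chr1", 105, 495, 3))
  m <- merge_circles(x, merge_params(d_min = 10))
  expect_equal(nrow(m), 1)
  expect_equal(m$split_reads, 5L)
  expect_equal(m$start, 105L)  # representative: highest split-read support
  expect_equal(m$end, 495L)

  # end distance 20 >= d_min: no link
  y <- rbind(toy_circles("chr1", 100, 500, 2), toy_circles("chr1", 100, 520, 2))
  expect_equal(nrow(merge_circles(y, merge_params(d_min = 10))), 2)
})

test_that("merge conserves split reads, is idempotent and permutation-invariant", {
  set.seed(31)
  n <- 1000
  x <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                  start = as.integer(sample(1:2000, n, TRUE)),
                  sample_id = sample(c("S1", "S2"), n, TRUE),
                  stringsAsFactors = FALSE)
  x$end <- x$start + as.integer(sample(50:500, n, TRUE))
  x$split_reads <- as.integer(sample(1:5, n, TRUE))
  p <- merge_params(d_min = 10)
  m1 <- merge_circles(x, p)
  expect_equal(sum(m1$split_reads), sum(x$split_reads))
  expect_identical(merge_circles(m1, p), m1)
  shuffled <- x[sample(nrow(x)), ]
  expect_identical(merge_circles(shuffled, p), m1)
})

test_that("merge representative ties break by smallest start then end", {
  x <- rbind(toy_circles("chr1", 105, 500, 2), toy_circles("chr1", 100, 495, 2))
  m <- merge_circles(x, merge_params(d_min = 10))
  expect_equal(m$start, 100L)
  expect_equal(m$end, 495L)
})

test_that("filtering applies the support, length and chromosome gates", {
  x <- rbind(toy_circles("chr1", 0, 1000, 1),          # low support
             toy_circles("chr1", 0, 150000, 5),        # > 100 kbp
             toy_circles("chrM", 0, 16000, 50),        # mitochondrial
             toy_circles("chr1", 0, 1000, 2),
             toy_circles("chr2", 500, 2000, 3),
             toy_circles("chr3", 0, 99999, 2))
  f <- filter_circles(x, merge_params())
  expect_equal(nrow(f), 3)
  log <- attr(f, "filter_log")
  expect_equal(unname(log["low_support"]), 1L)
  expect_equal(unname(log["too_long"]), 1L)
  expect_equal(unname(log["excluded_chrom"]), 1L)
  # filtering is idempotent
  f2 <- filter_circles(f, merge_params())
  expect_equal(f2[names(f2)], f[names(f)])
  expect_equal(nrow(filter_circles(f[0, ], merge_params())), 0)
})

test_that("call + merge recovers exactly one circle per planted circle", {
  co <- small_cohort(seed = 13)
  planted <- co$circles[co$circles$sample_id == "A1", , drop = FALSE]
  planted <- merge_circles(planted, merge_params(d_min = 10))  # planted may collide
  set.seed(99)
  reads <- simulate_split_reads(planted, reads_per_circle = 3, jitter = 2)
  called <- call_junctions(reads)
  merged <- merge_circles(called, merge_params(d_min = 10))
  expect_equal(nrow(merged), nrow(planted))
  # each recovered junction is within jitter of a planted circle
  ord_p <- order(planted$chrom, planted$start)
  ord_m <- order(merged$chrom, merged$start)
  expect_true(all(abs(merged$start[ord_m] - planted$start[ord_p]) <= 2))
  expect_true(all(abs(merged$end[ord_m] - planted$end[ord_p]) <= 2))
})
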
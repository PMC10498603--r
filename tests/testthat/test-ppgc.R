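test_that("annotation uses half-open overlap semantics", {
  genes <- rbind(toy_genes(1)[0, ],
                 data.frame(gene_id = "G1", gene_name = "G1", chrom = "chr1",
                            start = 599, end = 900, strand = "+", length = 301,
                            coding = TRUE),
                 data.frame(gene_id = "G2", gene_name = "G2", chrom = "chr1",
                            start = 600, end = 900, strand = "+", length = 300,
                            coding = TRUE))
  circ <- toy_circles("chr1", 100, 600)
  asn <- annotate_circles(circ, genes)
  expect_equal(asn$gene_id, "G1")      # [100,600) meets [599,900) in 1 bp
  expect_equal(asn$overlap_bp, 1L)     # [100,600) misses [600,900)
  expect_false(asn$full_gene)
})

test_that("annotation matches a quadratic brute-force overlap scan", {
  set.seed(17)
  genes <- data.frame(gene_id = paste0("G", 1:50), gene_name = paste0("G", 1:50),
                      chrom = sample(c("chr1", "chr2"), 50, TRUE),
                      start = sample(0:50000, 50), strand = "+", coding = TRUE)
  genes$end <- genes$start + sample(100:5000, 50, TRUE)
  genes$length <- genes$end - genes$start
  circ <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                     start = as.integer(sample(0:50000, 200, TRUE)),
                     sample_id = "S1", stringsAsFactors = FALSE)
  circ$end <- circ$start + as.integer(sample(50:8000, 200, TRUE))
  circ$split_reads <- as.integer(sample(1:6, 200, TRUE))

  asn <- annotate_circles(circ, genes)
  # oracle: all-pairs scan with explicit half-open interval arithmetic
  brute <- list()
  for (ci in seq_len(nrow(circ))) for (gi in seq_len(nrow(genes))) {
    if (circ$chrom[ci] != genes$chrom[gi]) next
    ov <- min(circ$end[ci], genes$end[gi]) - max(circ$start[ci], genes$start[gi])
    if (ov >= 1) brute[[length(brute) + 1]] <-
        data.frame(gene_id = genes$gene_id[gi], circle_idx = ci, overlap_bp = ov,
                   full_gene = circ$start[ci] <= genes$start[gi] &&
                     circ$end[ci] >= genes$end[gi])
  }
  brute <- do.call(rbind, brute)
  key <- function(d) d[order(d$circle_idx, d$gene_id),
                       c("gene_id", "circle_idx", "overlap_bp", "full_gene")]
  got <- key(asn); want <- key(brute)
  rownames(got) <- rownames(want) <- NULL
  got$overlap_bp <- as.integer(got$overlap_bp)
  want$overlap_bp <- as.integer(want$overlap_bp)
  expect_identical(got, want)
})

test_that("PpGC formulas reproduce the hand computation", {
  genes <- data.frame(gene_id = c("A", "B"), gene_name = c("A", "B"),
                      chrom = "chr1", start = c(0, 10000),
                      end = c(1000, 12000), strand = "+",
                      length = c(1000, 2000), coding = TRUE)
  circ <- rbind(toy_circles("chr1", 100, 600, 2),
                toy_circles("chr1", 200, 700, 3),
                toy_circles("chr1", 10500, 11000, 4))
  asn <- annotate_circles(circ, genes)
  p <- compute_ppgc(asn, genes, samples = "S1")
  expect_equal(p$l_max, 2000)
  expect_equal(p$raw["A", "S1"], 5)
  expect_equal(p$scaled["A", "S1"], 10)       # 5 * 2000/1000
  expect_equal(p$final["A", "S1"], log2(11), tolerance = 1e-12)
  expect_equal(p$raw["B", "S1"], 4)
  expect_equal(p$scaled["B", "S1"], 4)
  expect_equal(p$final["B", "S1"], log2(5), tolerance = 1e-12)
})

test_that("genes without circles keep final PpGC zero; empty input warns", {
  genes <- toy_genes(3)
  circ <- toy_circles("chr1", 100, 600, 2)   # overlaps G1 only
  asn <- annotate_circles(circ, genes)
  p <- compute_ppgc(asn, genes, samples = c("S1", "S2"))
  expect_equal(p$final["G2", "S1"], 0)
  expect_equal(unname(p$final[, "S2"]), c(0, 0, 0))
  expect_warning(compute_ppgc(asn[0, ], genes, "S1"), "zeros")
})

test_that("final PpGC is invariant to a global rescaling of gene lengths", {
  co <- small_cohort(seed = 21)
  f <- filter_circles(merge_circles(co$circles, merge_params()), merge_params())
  asn <- annotate_circles(f, co$genes)
  p1 <- compute_ppgc(asn, co$genes, co$samples$sample_id)
  genes2 <- co$genes
  genes2$length <- genes2$length * 2L   # L_Max/L_i unchanged
  p2 <- compute_ppgc(asn, genes2, co$samples$sample_id)
  expect_equal(p1$final, p2$final, tolerance = 1e-12)
})

test_that("PpGC sums match a brute-force oracle and adding circles is monotone", {
  set.seed(23)
  genes <- toy_genes(10, len = 2000, gap = 3000)
  circ <- data.frame(chrom = "chr1",
                     start = as.integer(sample(0:45000, 150, TRUE)),
                     sample_id = sample(c("S1", "S2"), 150, TRUE),
                     stringsAsFactors = FALSE)
  circ$end <- circ$start + as.integer(sample(100:4000, 150, TRUE))
  circ$split_reads <- as.integer(sample(1:5, 150, TRUE))
  asn <- annotate_circles(circ, genes)
  p <- compute_ppgc(asn, genes, c("S1", "S2"))
  for (g in genes$gene_id) for (s in c("S1", "S2")) {
    manual <- 0
    for (ci in seq_len(nrow(circ))) {
      if (circ$sample_id[ci] != s) next
      ov <- min(circ$end[ci], genes$end[genes$gene_id == g]) -
        max(circ$start[ci], genes$start[genes$gene_id == g])
      if (ov >= 1) manual <- manual + circ$split_reads[ci]
    }
    expect_equal(unname(p$raw[g, s]), manual)
  }
  # monotonicity: one more circle on G1 never lowers its final value
  extra <- toy_circles("chr1", 100, 900, 3, "S1")
  p2 <- compute_ppgc(annotate_circles(rbind(circ, extra), genes), genes,
                     c("S1", "S2"))
  expect_gte(p2$final["G1", "S1"], p$final["G1", "S1"])
})

test_that("full-gene detection and fractions follow the containment rule", {
  genes <- data.frame(gene_id = "G", gene_name = "G", chrom = "chr1",
                      start = 2000, end = 8000, strand = "+", length = 6000,
                      coding = TRUE)
  full <- annotate_circles(toy_circles("chr1", 0, 10000), genes)
  expect_true(full$full_gene)
  part <- annotate_circles(toy_circles("chr1", 2500, 8000), genes)
  expect_false(part$full_gene)

  # toy cohort: full genes {A} and {A,B} over 10 annotated loci
  asn <- data.frame(gene_id = c(paste0("g", 1:10), "g1", "g1", "g2"),
                    sample_id = c(rep("S1", 10), "S1", "S2", "S2"),
                    circle_idx = 1, overlap_bp = 1,
                    full_gene = c(rep(FALSE, 10), TRUE, TRUE, TRUE),
                    split_reads = 1)
  genes10 <- toy_genes(10)
  genes10$gene_id <- paste0("g", 1:10)
  fs <- full_gene_summary(asn, c("S1", "S2"), genes10,
                          groups = c(S1 = "g", S2 = "g"))
  expect_equal(unname(fs$fractions), c(0.1, 0.2))
  expect_equal(fs$group_summary$mean_fraction, 0.15)
  expect_equal(fs$group_summary$sem_fraction, 0.05)
  expect_true(fs$presence["g1", "S1"] && fs$presence["g2", "S2"])
  expect_false(fs$presence["g2", "S1"])
})
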
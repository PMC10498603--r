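make_matrix <- function(values, samples) {
  matrix(values, nrow = 1, dimnames = list("g1", samples))
}

two_group_matrix <- function(ctrl, case) {
  samples <- c(paste0("C", seq_along(ctrl)), paste0("A", seq_along(case)))
  m <- matrix(c(ctrl, case), nrow = 1, dimnames = list("g1", samples))
  groups <- setNames(rep(c("control", "case"), c(length(ctrl), length(case))),
                     samples)
  list(m = m, groups = groups)
}

test_that("the pooled t-statistic matches the textbook formula", {
  ctrl <- c(0, 0, 0, 0); case <- c(3.0, 3.2, 3.4, 3.4)
  d <- two_group_matrix(ctrl, case)
  res <- difcir(d$m, d$groups)
  # independent hand computation of the classic two-sample pooled t
  n1 <- 4; n2 <- 4
  sp2 <- ((n1 - 1) * var(ctrl) + (n2 - 1) * var(case)) / (n1 + n2 - 2)
  t_hand <- (mean(case) - mean(ctrl)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_hand <- 2 * pt(-abs(t_hand), n1 + n2 - 2)
  expect_equal(res$delta, 3.25)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$call, "up")
  # cross-check against the reference implementation
  tt <- t.test(case, ctrl, var.equal = TRUE)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(res$t_statistic, unname(tt$statistic), tolerance = 1e-12)
})

test_that("identical constant groups give p = 1 and no call", {
  d <- two_group_matrix(c(2, 2, 2, 2), c(2, 2, 2, 2))
  res <- difcir(d$m, d$groups)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)
  expect_equal(res$call, "none")
})

test_that("the fold-change gate is strict and the significance gate inclusive", {
  # delta exactly theta = 1 with tiny p: no call ('more than' the threshold)
  d <- two_group_matrix(c(0, 0, 0, 2e-9), c(1, 1, 1, 1 + 2e-9))
  res <- difcir(d$m, d$groups)
  expect_equal(res$delta, 1)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$call, "none")
  # delta just above theta: called
  d2 <- two_group_matrix(c(0, 0, 0, 2e-9), c(1.001, 1.001, 1.001, 1.001 + 2e-9))
  expect_equal(difcir(d2$m, d2$groups)$call, "up")
})

test_that("swapping group labels negates deltas and exchanges calls", {
  co <- small_cohort(seed = 8)
  run <- suppressWarnings(run_pipeline(co))
  groups <- setNames(co$samples$group, co$samples$sample_id)
  fwd <- suppressWarnings(difcir(run$ppgc, groups))
  rev <- suppressWarnings(difcir(run$ppgc, groups,
                                 case = "control", control = "case"))
  expect_equal(rev$delta, -fwd$delta)
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(rev$call == "up", fwd$call == "down")
  expect_equal(rev$call == "down", fwd$call == "up")
})

test_that("groups with fewer than two samples are rejected", {
  m <- matrix(1:4, nrow = 1, dimnames = list("g", paste0("S", 1:4)))
  groups <- setNames(c("control", "case", "case", "case"), paste0("S", 1:4))
  expect_error(difcir(m, groups), ">= 2 samples")
})

test_that("type-I error is calibrated at alpha = 0.01 on null cohorts", {
  # 50 replicate null simulations x 2000 genes, both groups from one
  # distribution; the rejection rate must sit within binomial 99% bounds
  set.seed(1234)
  n_sim <- 50; n_genes <- 2000
  hits <- 0; total <- 0
  samples <- c(paste0("C", 1:10), paste0("A", 1:9))
  groups <- setNames(rep(c("control", "case"), c(10, 9)), samples)
  for (i in seq_len(n_sim)) {
    m <- matrix(rnorm(n_genes * 19), n_genes,
                dimnames = list(paste0("g", seq_len(n_genes)), samples))
    res <- difcir(m, groups, theta = 0)
    hits <- hits + sum(res$p_value <= 0.01)
    total <- total + n_genes
  }
  rate <- hits / total
  bound <- 2.576 * sqrt(0.01 * 0.99 / total)
  expect_lt(abs(rate - 0.01), bound)
})

test_that("strongly planted hotspot genes are always recovered", {
  for (s in c(101, 202, 303)) {
    co <- small_cohort(seed = s)
    run <- suppressWarnings(run_pipeline(co))
    up <- run$difcir$gene_id[run$difcir$call == "up"]
    expect_true(all(co$truth$hotspot_genes$gene_id %in% up),
                info = paste("seed", s))
  }
})

test_that("hypergeometric chromosome enrichment matches exhaustive enumeration", {
  # N = 20 genes, K = 5 up-DPpGCs; one chromosome holds 4 genes, all hits
  genes <- data.frame(gene_id = paste0("g", 1:20),
                      chrom = rep(c("chr1", "chr2"), c(4, 16)))
  dppgc <- c("g1", "g2", "g3", "g4", "g5")
  res <- chromosome_enrichment(dppgc, genes)
  p_chr1 <- res$p_value[res$chrom == "chr1"]
  expect_equal(p_chr1, 5 / 4845, tolerance = 1e-12)
  # oracle: enumerate all C(20,4) draws of chr1's genes
  draws <- combn(20, 4)
  k_obs <- colSums(draws <= 5)  # genes 1..5 are the up-DPpGCs
  expect_equal(p_chr1, mean(k_obs >= 4), tolerance = 1e-12)
  expect_equal(res$p_value[res$chrom == "chr2"],
               sum(dhyper(1:5, 5, 15, 16)), tolerance = 1e-12)
  # a chromosome with zero hits scores P(X >= 0) = 1
  genes3 <- rbind(genes, data.frame(gene_id = "g21", chrom = "chr3"))
  res3 <- chromosome_enrichment(dppgc, genes3)
  expect_equal(res3$p_value[res3$chrom == "chr3"], 1)
  # degenerate population: one chromosome holding all genes
  one <- chromosome_enrichment(dppgc, transform(genes, chrom = "chr1"))
  expect_equal(one$p_value, 1)
  expect_error(chromosome_enrichment("missing", genes), "absent")
})

test_that("gene-length regression reports OLS slope and R squared", {
  genes <- data.frame(gene_id = paste0("g", 1:20),
                      length = seq(1e4, 2e6, length.out = 20))
  # exact line: R^2 = 1
  res_line <- data.frame(gene_id = genes$gene_id, call = "up",
                         neg_log10_p = 2 + 1e-6 * genes$length)
  fit <- suppressWarnings(gene_length_regression(res_line, genes))  # perfect fit
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(fit$slope, 1e-6, tolerance = 1e-9)
  # constant response: R^2 = 0 by convention
  res_const <- transform(res_line, neg_log10_p = 3)
  expect_equal(gene_length_regression(res_const, genes)$r_squared, 0)
  # noisy points: R^2 equals the closed form 1 - SSR/SST
  set.seed(5)
  y <- 2 + 1e-6 * genes$length + rnorm(20, 0, 0.5)
  res_noise <- transform(res_line, neg_log10_p = y)
  fit_n <- gene_length_regression(res_noise, genes)
  pred <- fit_n$intercept + fit_n$slope * genes$length
  r2_closed <- 1 - sum((y - pred)^2) / sum((y - mean(y))^2)
  expect_equal(fit_n$r_squared, r2_closed, tolerance = 1e-9)
  expect_error(gene_length_regression(res_line[1:2, ], genes), ">= 3")
})
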
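#' Differential per-gene eccDNA production (DifCir)
#'
#' For each gene, group means of the final (scaled, log2-equalized) PpGC
#' values are compared. The log2 fold change is
#' `delta = mean(case) - mean(control)`; significance comes from a two-sided
#' two-sample t-test (pooled-variance Student by default, Welch optional).
#' A gene is called `up` when `delta > theta` and `p <= alpha`, `down`
#' symmetrically with `delta < -theta`; the fold-change gate is strict
#' ("more than" the threshold) while the significance gate is inclusive.
#' Genes constant and equal in both groups get p = 1; genes constant but
#' unequal get the minimum representable positive p with a warning, so that
#' the mean difference decides the call. A Benjamini-Hochberg adjusted column
#' is always emitted for transparency although the default call thresholds
#' raw p-values.
#'
#' @param x A `ppgc_matrix` or a numeric genes x samples matrix of final
#'   PpGC values.
#' @param groups Named character vector mapping sample_id to group label.
#' @param case,control Group labels to compare (case minus control).
#' @param theta Log2 mean-difference threshold (strict `>`), default 1.
#' @param alpha Significance threshold on raw p (inclusive `<=`), default 0.01.
#' @param var_equal Pooled-variance Student t when TRUE (default), Welch
#'   otherwise.
#' @return A data.frame with one row per gene: `gene_id`, `mean_control`,
#'   `mean_case`, `delta`, `t_statistic`, `p_value`, `neg_log10_p`,
#'   `p_adjust_bh`, `call`.
#' @export
difcir <- function(x, groups, case = "case", control = "control",
                   theta = 1, alpha = 0.01, var_equal = TRUE) {
  if (theta < 0) stopf("theta must be >= 0")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0, 1)")
  m <- ppgc_final(x)
  ids_case <- names(groups)[groups == case]
  ids_ctrl <- names(groups)[groups == control]
  if (length(ids_case) < 2 || length(ids_ctrl) < 2)
    stopf("each group needs >= 2 samples (case: %d, control: %d)",
          length(ids_case), length(ids_ctrl))
  missing <- setdiff(c(ids_case, ids_ctrl), colnames(m))
  if (length(missing)) stopf("samples not in matrix: %s", paste(missing, collapse = ", "))

  xc <- m[, ids_case, drop = FALSE]
  xk <- m[, ids_ctrl, drop = FALSE]
  n1 <- ncol(xk); n2 <- ncol(xc)
  m1 <- rowMeans(xk); m2 <- rowMeans(xc)
  v1 <- apply(xk, 1, stats::var); v2 <- apply(xc, 1, stats::var)
  delta <- m2 - m1

  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- delta / se
  p <- 2 * stats::pt(-abs(tstat), df)

  degenerate <- !is.finite(se) | se == 0
  flat_equal <- degenerate & delta == 0
  flat_unequal <- degenerate & delta != 0
  tstat[flat_equal] <- 0; p[flat_equal] <- 1
  if (any(flat_unequal)) {
    warnf("%d gene(s) with zero within-group variance but unequal means; p set to minimum positive",
          sum(flat_unequal))
    tstat[flat_unequal] <- sign(delta[flat_unequal]) * Inf
    p[flat_unequal] <- .Machine$double.xmin
  }

  call <- rep("none", nrow(m))
  call[delta > theta & p <= alpha] <- "up"
  call[delta < -theta & p <= alpha] <- "down"

  data.frame(gene_id = rownames(m),
             mean_control = m1, mean_case = m2, delta = delta,
             t_statistic = tstat, p_value = p,
             neg_log10_p = -log10(p),
             p_adjust_bh = stats::p.adjust(p, "BH"),
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Chromosome enrichment of up-DPpGC genes
#'
#' Upper-tail hypergeometric test per chromosome: with N tested genes of
#' which K are up-DPpGCs, a chromosome holding n tested genes and k
#' up-DPpGCs scores `p = P(X >= k)` for X hypergeometric(N, K, n).
#'
#' @param dppgc_genes Character vector of up-DPpGC gene ids.
#' @param all_tested_genes Data.frame of the tested universe with columns
#'   `gene_id` and `chrom`.
#' @return A data.frame per chromosome: `chrom`, `n_tested`, `n_dppgc`,
#'   `p_value`, `p_adjust_bh`.
#' @export
chromosome_enrichment <- function(dppgc_genes, all_tested_genes) {
  missing <- setdiff(dppgc_genes, all_tested_genes$gene_id)
  if (length(missing))
    stopf("DPpGC gene(s) absent from the tested universe: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  N <- nrow(all_tested_genes)
  K <- length(dppgc_genes)
  chroms <- split(all_tested_genes$gene_id, all_tested_genes$chrom)
  rows <- lapply(names(chroms), function(cn) {
    n <- length(chroms[[cn]])
    k <- sum(dppgc_genes %in% chroms[[cn]])
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(chrom = cn, n_tested = n, n_dppgc = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjust_bh <- stats::p.adjust(out$p_value, "BH")
  out
}

#' Regression of DPpGC significance on gene length
#'
#' Ordinary least squares of `-log10(p)` on gene length, restricted to the
#' up-DPpGC genes, probing whether eccDNA shedding propensity merely tracks
#' gene size.
#'
#' @param results A [difcir()] result table.
#' @param genes Gene models with `gene_id` and `length`.
#' @return A list: `slope`, `intercept`, `r_squared`, `n`.
#' @export
gene_length_regression <- function(results, genes) {
  up <- results[results$call == "up", , drop = FALSE]
  if (nrow(up) < 3) stopf("need >= 3 significant up-DPpGCs, got %d", nrow(up))
  len <- genes$length[match(up$gene_id, genes$gene_id)]
  if (anyNA(len)) stopf("up-DPpGC gene(s) missing from gene models")
  y <- up$neg_log10_p
  if (stats::var(y) == 0) {
    # constant response: slope 0 by convention, R^2 defined as 0
    return(list(slope = 0, intercept = y[1], r_squared = 0, n = length(y)))
  }
  fit <- stats::lm(y ~ len)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       n = length(y))
}
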
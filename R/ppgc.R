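#' Annotate circles with overlapping genes
#'
#' Every (gene, circle) pair with at least 1 bp of overlap under half-open
#' coordinates yields one assignment; a circle spanning k genes yields k
#' assignments. Overlap is strand-blind. `full_gene` is set when the circle
#' interval fully contains the gene interval.
#'
#' @param circles Filtered circle records.
#' @param genes Gene models from [read_genes()].
#' @return A data.frame with one row per assignment: `gene_id`, `sample_id`,
#'   `circle_idx` (row in `circles`), `overlap_bp`, `full_gene`,
#'   `split_reads`.
#' @export
annotate_circles <- function(circles, genes) {
  if (nrow(circles) == 0 || nrow(genes) == 0) {
    return(data.frame(gene_id = character(), sample_id = character(),
                      circle_idx = integer(), overlap_bp = integer(),
                      full_gene = logical(), split_reads = integer(),
                      stringsAsFactors = FALSE))
  }
  # Half-open [start, end) -> 1-based closed IRanges: start+1 .. end
  gr_c <- GenomicRanges::GRanges(circles$chrom,
                                 IRanges::IRanges(circles$start + 1L, circles$end))
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- GenomicRanges::findOverlaps(gr_c, gr_g, minoverlap = 1L,
                                      ignore.strand = TRUE)
  ci <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(IRanges::ranges(gr_c)[ci],
                                           IRanges::ranges(gr_g)[gi]))
  data.frame(gene_id = genes$gene_id[gi],
             sample_id = circles$sample_id[ci],
             circle_idx = ci,
             overlap_bp = ov,
             full_gene = circles$start[ci] <= genes$start[gi] &
               circles$end[ci] >= genes$end[gi],
             split_reads = circles$split_reads[ci],
             stringsAsFactors = FALSE)
}

#' Compute the per-gene eccDNA production (PpGC) matrix
#'
#' For gene i and sample s the unscaled value is the sum of split reads over
#' all circles carrying gene i or a fragment of it. Scaling multiplies by
#' `L_Max / L_i`, where `L_Max` is the length of the longest gene found in
#' the dataset and `L_i` the length of gene i; equalization applies
#' `log2(x + 1)`. Genes without any circle anywhere are retained with final
#' value 0.
#'
#' @param assignments Output of [annotate_circles()].
#' @param genes Gene models.
#' @param samples Character vector of all sample identifiers (so samples
#'   without circles keep zero columns).
#' @param l_max_source `"detected"` takes `L_Max` over genes with at least
#'   one assignment in the run; `"annotation"` over all gene models.
#' @return An object of class `ppgc_matrix`: list with matrices `raw`,
#'   `scaled`, `final` (genes x samples), `genes`, `l_max`, `samples`.
#' @export
compute_ppgc <- function(assignments, genes, samples,
                         l_max_source = c("detected", "annotation")) {
  l_max_source <- match.arg(l_max_source)
  raw <- matrix(0, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  if (nrow(assignments) == 0) {
    warnf("no gene-circle assignments; PpGC matrix is all zeros")
    l_max <- max(genes$length)
  } else {
    sums <- tapply(assignments$split_reads,
                   list(factor(assignments$gene_id, levels = genes$gene_id),
                        factor(assignments$sample_id, levels = samples)),
                   sum, default = 0)
    raw[rownames(sums), colnames(sums)] <- sums
    detected <- genes$gene_id %in% assignments$gene_id
    l_max <- if (l_max_source == "detected") max(genes$length[detected]) else max(genes$length)
  }
  scaled <- raw * (l_max / genes$length)
  final <- log2(scaled + 1)
  structure(list(raw = raw, scaled = scaled, final = final,
                 genes = genes, l_max = l_max, samples = samples),
            class = "ppgc_matrix")
}

#' @export
print.ppgc_matrix <- function(x, ...) {
  cat(sprintf("PpGC matrix: %d genes x %d samples (L_Max = %d bp)\n",
              nrow(x$final), ncol(x$final), x$l_max))
  invisible(x)
}

# Coerce a ppgc_matrix or a plain numeric matrix to the final PpGC matrix.
ppgc_final <- function(x) {
  if (inherits(x, "ppgc_matrix")) x$final
  else if (is.matrix(x)) x
  else stopf("expected a ppgc_matrix or a numeric matrix")
}

#' Summarize full-gene circles
#'
#' A gene locus counts as "full" in a sample when at least one circle of that
#' sample fully contains the gene. Per-sample fractions use as denominator
#' the number of distinct gene loci with at least one circle assignment
#' anywhere in the dataset.
#'
#' @param assignments Output of [annotate_circles()].
#' @param samples All sample identifiers.
#' @param genes Gene models (for the coding/non-coding split).
#' @param groups Optional named vector mapping sample_id to group label; when
#'   given, per-group mean and SEM of the fractions are reported.
#' @return A list with `full_genes` (per-sample list), `presence` (Boolean
#'   gene x sample matrix over full genes), `fractions`, `n_annotated_loci`,
#'   `coding_fractions`, and optional `group_summary`.
#' @export
full_gene_summary <- function(assignments, samples, genes, groups = NULL) {
  annotated <- unique(assignments$gene_id)
  full_asn <- assignments[assignments$full_gene, , drop = FALSE]
  full_genes <- lapply(stats::setNames(samples, samples), function(s)
    sort(unique(full_asn$gene_id[full_asn$sample_id == s])))
  all_full <- sort(unique(unlist(full_genes)))
  presence <- matrix(FALSE, nrow = length(all_full), ncol = length(samples),
                     dimnames = list(all_full, samples))
  for (s in samples) presence[full_genes[[s]], s] <- TRUE
  n_loci <- length(annotated)
  fractions <- vapply(full_genes, function(g)
    if (n_loci == 0) 0 else length(g) / n_loci, numeric(1))
  coding <- genes$gene_id[genes$coding]
  coding_fractions <- vapply(full_genes, function(g) {
    if (length(g) == 0) return(NA_real_)
    mean(g %in% coding)
  }, numeric(1))
  out <- list(full_genes = full_genes, presence = presence,
              fractions = fractions, n_annotated_loci = n_loci,
              coding_fractions = coding_fractions)
  if (!is.null(groups)) {
    out$group_summary <- do.call(rbind, lapply(split(names(groups), groups), function(ids) {
      f <- fractions[ids]
      data.frame(n = length(f), mean_fraction = mean(f),
                 sem_fraction = sem(f))
    }))
  }
  out
}
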
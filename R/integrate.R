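#' Match up-DPpGC genes with differential proteins (tandems)
#'
#' A tandem is a gene that is an up-DPpGC and whose protein is a DEP in at
#' least one subcellular fraction. Direction is taken from the most
#' significant DEP fraction; a tandem is concordant when the eccDNA change
#' and the protein change share their sign. Per-fraction tandem percentages
#' use the number of up-DPpGCs as denominator.
#'
#' @param difcir_results A [difcir()] result table.
#' @param dep_results A [call_deps()] result table.
#' @param mapping Optional two-column data.frame (`gene_id`, `protein_id`);
#'   identity mapping by default. Two genes mapping to one protein is an
#'   error.
#' @return A list: `tandems` (data.frame with gene, delta, fractions,
#'   direction, concordant), `n_up_dppgc`, `per_fraction` (counts and
#'   percentages), `percent_tandem`.
#' @export
match_tandems <- function(difcir_results, dep_results, mapping = NULL) {
  up <- difcir_results[difcir_results$call == "up", , drop = FALSE]
  if (is.null(mapping)) {
    mapping <- data.frame(gene_id = up$gene_id, protein_id = up$gene_id,
                          stringsAsFactors = FALSE)
  }
  if (anyDuplicated(mapping$protein_id))
    stopf("mapping collision: protein '%s' mapped from several genes",
          mapping$protein_id[duplicated(mapping$protein_id)][1])
  deps <- dep_results[dep_results$call != "none", , drop = FALSE]
  prot <- mapping$protein_id[match(up$gene_id, mapping$gene_id)]
  rows <- lapply(seq_len(nrow(up)), function(i) {
    hits <- deps[!is.na(prot[i]) & deps$protein_id == prot[i], , drop = FALSE]
    if (nrow(hits) == 0) return(NULL)
    best <- hits[order(hits$q_value)[1], ]
    data.frame(gene_id = up$gene_id[i], delta = up$delta[i],
               fractions = paste(sort(hits$fraction), collapse = ","),
               dep_direction = best$call,
               dep_log2_ratio = best$avg_log2_ratio,
               concordant = sign(up$delta[i]) == sign(best$avg_log2_ratio),
               stringsAsFactors = FALSE)
  })
  tandems <- do.call(rbind, rows)
  if (is.null(tandems)) tandems <- data.frame(gene_id = character(),
                                              delta = numeric(),
                                              fractions = character(),
                                              dep_direction = character(),
                                              dep_log2_ratio = numeric(),
                                              concordant = logical())
  n_up <- nrow(up)
  fracs <- sort(unique(dep_results$fraction))
  per_fraction <- do.call(rbind, lapply(fracs, function(fr) {
    k <- sum(vapply(strsplit(tandems$fractions, ","), function(f) fr %in% f,
                    logical(1)))
    data.frame(fraction = fr, n_tandems = k,
               percent = if (n_up > 0) 100 * k / n_up else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(tandems = tandems, n_up_dppgc = n_up, per_fraction = per_fraction,
       percent_tandem = if (n_up > 0) 100 * nrow(tandems) / n_up else NA_real_)
}

#' Overlap of a gene set with risk-gene lists
#'
#' Symbols are case-normalized before matching. Reports the per-list overlap
#' counts, the union overlap (no double counting), and percentages against
#' the size of the gene set, rounded for reporting to one decimal.
#'
#' @param gene_set Character vector of gene symbols (e.g. up-DPpGCs or
#'   tandem genes).
#' @param risk_lists Named list of character vectors of risk-gene symbols.
#' @return A list: `n_genes`, `per_list` (data.frame `list`, `n_overlap`,
#'   `percent`), `union_count`, `union_percent`, `union_genes`.
#' @export
risk_overlap <- function(gene_set, risk_lists) {
  genes <- unique(normalize_symbols(gene_set))
  if (length(genes) == 0) stopf("empty gene set")
  lists <- lapply(risk_lists, function(l) unique(normalize_symbols(l)))
  per_list <- do.call(rbind, lapply(names(lists), function(nm) {
    k <- length(intersect(genes, lists[[nm]]))
    data.frame(list = nm, n_overlap = k,
               percent = round(100 * k / length(genes), 1),
               stringsAsFactors = FALSE)
  }))
  union_genes <- intersect(genes, unique(unlist(lists)))
  list(n_genes = length(genes), per_list = per_list,
       union_count = length(union_genes),
       union_percent = round(100 * length(union_genes) / length(genes), 1),
       union_genes = sort(union_genes))
}

#' Compare PpGC levels over a reference gene set (e.g. RDC genes)
#'
#' Pools the final PpGC values of the reference genes over all samples of
#' each group, reports the group means, the case/control fold change of the
#' means, and a two-sided comparison p-value (exact Wilcoxon by default,
#' pooled t optionally). Intended for fragile-gene panels such as recurrent
#' DNA double-strand-break cluster (RDC) genes.
#'
#' @param x A `ppgc_matrix` or numeric final PpGC matrix.
#' @param ref_genes Character vector of reference gene symbols
#'   (case-insensitive match against matrix row names).
#' @param groups Named character vector mapping sample_id to group.
#' @param case,control Group labels.
#' @param test `"wilcoxon"` (exact rank-sum) or `"t"` (pooled two-sample t).
#' @return A list: `genes_used`, `genes_missing`, `mean_control`,
#'   `mean_case`, `fold_change`, `p_value`.
#' @export
rdc_compare <- function(x, ref_genes, groups, case = "case",
                        control = "control", test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  m <- ppgc_final(x)
  norm_rows <- normalize_symbols(rownames(m))
  norm_ref <- unique(normalize_symbols(ref_genes))
  idx <- which(norm_rows %in% norm_ref)
  missing <- setdiff(norm_ref, norm_rows)
  if (length(idx) == 0)
    stopf("no reference genes found in the matrix; missing: %s",
          paste(utils::head(missing, 10), collapse = ", "))
  vc <- as.numeric(m[idx, names(groups)[groups == control], drop = FALSE])
  va <- as.numeric(m[idx, names(groups)[groups == case], drop = FALSE])
  p <- if (test == "wilcoxon") {
    exact_wilcoxon(va, vc)$p_value
  } else {
    stats::t.test(va, vc, var.equal = TRUE)$p.value
  }
  list(genes_used = rownames(m)[idx], genes_missing = missing,
       mean_control = mean(vc), mean_case = mean(va),
       fold_change = mean(va) / mean(vc), p_value = p)
}
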
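#' Run the full eccDNA differential-analysis pipeline
#'
#' Orchestrates the stages end-to-end on a synthetic cohort (or a cohort
#' built from files with the reader functions): split-read simulation,
#' junction calling, merging, filtering, gene annotation, PpGC computation,
#' DifCir differential calling, democratic CPpGC voting, size profiling with
#' the unique-count group comparison, ECTR estimation, DEP calling, and the
#' DPpGC-DEP integration. All stage outputs plus a manifest (parameter
#' values, output file checksums, package version) are written to `out_dir`;
#' reruns under an identical configuration are bit-identical.
#'
#' @param cohort An `eccdna_cohort`; when `NULL` one is simulated from
#'   `config`.
#' @param out_dir Output directory; `NULL` skips writing files.
#' @param config A [simulation_config()] used when `cohort` is `NULL`.
#' @param params A [merge_params()] for merging/filtering.
#' @param theta,alpha DifCir thresholds (log2 FC and significance).
#' @param min_votes Democratic vote minimum.
#' @param k ECTR repeat-count threshold.
#' @param q_threshold,log2_ratio_threshold DEP thresholds.
#' @param window Size-profile smoothing window (bp, odd).
#' @param risk_lists Optional named list of risk-gene vectors for the
#'   integration stage.
#' @return A list of class `circdif_run` with every stage result and the
#'   manifest.
#' @export
run_pipeline <- function(cohort = NULL, out_dir = NULL,
                         config = simulation_config(),
                         params = merge_params(),
                         theta = 1, alpha = 0.01, min_votes = 3, k = 4,
                         q_threshold = 0.05, log2_ratio_threshold = 0.38,
                         window = 31, risk_lists = NULL) {
  if (is.null(cohort)) cohort <- simulate_cohort(config)
  groups <- stats::setNames(cohort$samples$group, cohort$samples$sample_id)
  samples <- cohort$samples$sample_id

  reads <- with_seed(cohort$config$seed + 1L,
                     simulate_split_reads(cohort, reads_per_circle = NULL))
  called <- call_junctions(reads, min_non_overlap = 10)
  merged <- merge_circles(called, params)
  filtered <- filter_circles(merged, params)

  assignments <- annotate_circles(filtered, cohort$genes)
  ppgc <- compute_ppgc(assignments, cohort$genes, samples)
  dif <- difcir(ppgc, groups, theta = theta, alpha = alpha)
  enrich <- chromosome_enrichment(dif$gene_id[dif$call == "up"],
                                  cohort$genes[, c("gene_id", "chrom")])
  demo <- lapply(c(control = "control", case = "case"), function(g) {
    ids <- samples[groups[samples] == g]
    tryCatch(find_cppgc(ppgc, ids, min_votes = min_votes, group = g),
             error = function(e) structure(list(group = g, error = conditionMessage(e)),
                                           class = "democratic_result"))
  })
  full_genes <- full_gene_summary(assignments, samples, cohort$genes, groups)

  profiles <- lapply(stats::setNames(samples, samples), function(s)
    size_profile(filtered[filtered$sample_id == s, , drop = FALSE],
                 window = window))
  counts <- vapply(samples, function(s) sum(filtered$sample_id == s), numeric(1))
  count_cmp <- unique_count_comparison(counts[groups[samples] == "control"],
                                       counts[groups[samples] == "case"])

  ectr <- do.call(rbind, lapply(samples, function(s)
    ectr_sweep(cohort$sequences[[s]], sample_id = s)))
  ectr_k <- ectr[ectr$k == k, , drop = FALSE]
  ectr_cmp <- ectr_group_compare(
    ectr_k$ectr_kbp[match(samples[groups[samples] == "control"], ectr_k$sample_id)],
    ectr_k$ectr_kbp[match(samples[groups[samples] == "case"], ectr_k$sample_id)])

  deps <- NULL
  integration <- NULL
  if (!is.null(cohort$proteins$abundance)) {
    deps <- call_deps(cohort$proteins$abundance, cohort$proteins$pairing,
                      q_threshold = q_threshold,
                      log2_ratio_threshold = log2_ratio_threshold)
    integration <- match_tandems(dif, deps)
    if (!is.null(risk_lists) && nrow(integration$tandems) > 0)
      integration$risk <- risk_overlap(integration$tandems$gene_id, risk_lists)
  }

  run <- list(cohort = cohort, reads = reads, called = called,
              merged = merged, filtered = filtered,
              assignments = assignments, ppgc = ppgc, difcir = dif,
              chromosome_enrichment = enrich, democratic = demo,
              full_genes = full_genes, size_profiles = profiles,
              unique_counts = counts, count_comparison = count_cmp,
              ectr = ectr, ectr_comparison = ectr_cmp,
              deps = deps, integration = integration)
  run$manifest <- list(
    package_version = as.character(utils::packageVersion("circdif")),
    seed = cohort$config$seed,
    parameters = list(d_min = params$d_min,
                      min_split_reads = params$min_split_reads,
                      max_length = params$max_length, theta = theta,
                      alpha = alpha, min_votes = min_votes, k = k,
                      q_threshold = q_threshold,
                      log2_ratio_threshold = log2_ratio_threshold,
                      window = window))
  if (!is.null(out_dir)) run$manifest$files <- write_run(run, out_dir)
  class(run) <- "circdif_run"
  run
}

#' @export
print.circdif_run <- function(x, ...) {
  cat(sprintf(paste0("circdif run: %d circles after filtering, %d up-DPpGC(s), ",
                     "count ratio %.2f (p = %.3g)\n"),
              nrow(x$filtered), sum(x$difcir$call == "up"),
              x$count_comparison$ratio, x$count_comparison$p_value))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  wt <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wt(run$filtered, "circles_filtered.tsv")
  write_matrix(run$ppgc$final, file.path(out_dir, "ppgc_final.tsv"),
               feature_col = "gene_id")
  paths <- c(paths, file.path(out_dir, "ppgc_final.tsv"))
  wt(run$difcir, "difcir.tsv")
  wt(run$chromosome_enrichment, "chromosome_enrichment.tsv")
  wt(run$ectr, "ectr_sweep.tsv")
  if (!is.null(run$deps)) wt(run$deps, "deps.tsv")
  summary_json <- list(
    count_comparison = run$count_comparison,
    ectr_comparison = run$ectr_comparison,
    democratic = lapply(run$democratic, function(d)
      if (!is.null(d$error)) list(error = d$error)
      else list(threshold = d$threshold, mode_value = d$mode_value,
                n_cppgc = length(d$cppgc), cppgc = d$cppgc)),
    full_gene_fractions = as.list(run$full_genes$fractions),
    tandems = if (!is.null(run$integration)) run$integration$tandems$gene_id)
  jp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary_json, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, jp)
  manifest_path <- file.path(out_dir, "manifest.json")
  files <- data.frame(file = basename(paths),
                      md5 = unname(tools::md5sum(paths)),
                      stringsAsFactors = FALSE)
  jsonlite::write_json(list(parameters = run$manifest$parameters,
                            seed = run$manifest$seed,
                            package_version = run$manifest$package_version,
                            files = files),
                       manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files
}
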
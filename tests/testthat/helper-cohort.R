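# Shared fixtures: small synthetic cohorts keep the suite fast while
# preserving the cohort structure (two groups, hotspots, mito, telomeres).

small_config <- function(seed = 42, ...) {
  simulation_config(seed = seed,
                    baseline_circles_per_sample = 60,
                    n_genes = 50,
                    n_proteins = 200,
                    n_dep = 10,
                    background_sequences_per_sample = 10,
                    ...)
}

small_cohort <- function(seed = 42, ...) {
  simulate_cohort(small_config(seed = seed, ...))
}

# Deterministic toy gene set on one chromosome.
toy_genes <- function(n = 5, len = 1000, gap = 5000, chrom = "chr1") {
  start <- seq(0, by = len + gap, length.out = n)
  data.frame(gene_id = paste0("G", seq_len(n)),
             gene_name = paste0("G", seq_len(n)),
             chrom = chrom, start = start, end = start + len,
             strand = "+", length = len, coding = TRUE,
             stringsAsFactors = FALSE)
}

toy_circles <- function(chrom, start, end, split_reads = 2, sample_id = "S1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             split_reads = as.integer(split_reads), sample_id = sample_id,
             stringsAsFactors = FALSE)
}
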
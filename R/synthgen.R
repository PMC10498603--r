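#' Configuration for the synthetic eccDNA cohort generator
#'
#' The defaults emulate the statistical structure of a two-group spinal-cord
#' circulome study: 10 control and 9 case samples, circles scattered over the
#' autosomes with a roughly six-fold higher circle load in the case group,
#' circle lengths concentrated at integer multiples of ~200 bp (the
#' nucleosome-repeat-like periodicity) plus a long tail below 100 kbp, a
#' small mitochondrial contamination fraction, planted hotspot genes that
#' shed extra circles only in case samples, telomeric-repeat circles with a
#' known total TTAGGG content per sample, and a paired protein-abundance
#' panel (5 matched replicate pairs) with planted differential proteins.
#'
#' @param seed Integer RNG seed; a fixed seed gives byte-identical cohorts.
#' @param n_control,n_case Sample counts per group.
#' @param chromosomes Data.frame with columns `name` and `length` (bp). The
#'   default carries five 50 Mbp autosome-like chromosomes plus a 16.3 kbp
#'   mitochondrial chromosome.
#' @param n_genes Number of gene models.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal gene-length
#'   parameters (default median 30 kbp with a heavy right tail reaching
#'   megabase, neural-like genes).
#' @param baseline_circles_per_sample Poisson mean circle count for control
#'   samples.
#' @param case_abundance_multiplier Multiplier on the Poisson mean for case
#'   samples (default 6, emulating the observed case enrichment).
#' @param hotspot_genes Data.frame (`gene_id`, `extra_circles`,
#'   `split_read_boost`) of planted hotspots; `NULL` plants
#'   `n_hotspots` hotspots on randomly chosen genes.
#' @param n_hotspots,hotspot_extra_circles,hotspot_split_reads Defaults used
#'   when `hotspot_genes` is `NULL`: extra circles per case sample and their
#'   split-read support.
#' @param periodicity_bp,periodicity_sd Circle-length mixture: components
#'   centered at `k * periodicity_bp` for `k = 1..n_periods` with this SD.
#' @param n_periods Number of mixture components.
#' @param fraction_tail Fraction of circles drawn from the long tail
#'   (log-uniform up to just below `tail_cap`).
#' @param tail_cap Upper bound (exclusive) of tail circle lengths.
#' @param fraction_mito Fraction of circles placed on the mitochondrial
#'   chromosome.
#' @param split_read_mean Mean extra split reads per circle beyond the
#'   mandatory one (`split_reads = 1 + Poisson(split_read_mean - 1)`).
#' @param telomeric_circles Data.frame (`sample_id`, `n_circles`,
#'   `repeats_per_circle`) of planted telomeric circles; `NULL` plants 24
#'   circles x 244 repeats per control sample (35.1 kbp) and 21 x 242 per
#'   case sample (30.5 kbp).
#' @param background_sequences_per_sample Number of random non-telomeric
#'   circle sequences emitted per sample.
#' @param n_proteins,n_dep,dep_log2_shift,protein_noise_sd,n_protein_pairs
#'   Protein panel: panel size, number of planted differential proteins,
#'   their absolute log2 shift, per-measurement log2 noise SD, and number of
#'   matched replicate pairs.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_control = 10, n_case = 9,
                              chromosomes = default_chromosomes(),
                              n_genes = 120,
                              gene_length_meanlog = log(3e4),
                              gene_length_sdlog = 1.2,
                              baseline_circles_per_sample = 480,
                              case_abundance_multiplier = 6,
                              hotspot_genes = NULL,
                              n_hotspots = 5,
                              hotspot_extra_circles = 5,
                              hotspot_split_reads = 4,
                              periodicity_bp = 200,
                              periodicity_sd = 20,
                              n_periods = 5,
                              fraction_tail = 0.1,
                              tail_cap = 1e5,
                              fraction_mito = 0.05,
                              split_read_mean = 3,
                              telomeric_circles = NULL,
                              background_sequences_per_sample = 30,
                              n_proteins = 1000,
                              n_dep = 50,
                              dep_log2_shift = 1.0,
                              protein_noise_sd = 0.2,
                              n_protein_pairs = 5) {
  cfg <- as.list(environment())
  if (!is.data.frame(cfg$chromosomes) || nrow(cfg$chromosomes) == 0)
    stopf("configuration error: at least one chromosome required")
  if (!is_count(n_genes, 1)) stopf("configuration error: n_genes must be >= 1")
  for (f in c("n_control", "n_case", "n_periods", "n_proteins", "n_dep",
              "n_protein_pairs", "background_sequences_per_sample"))
    if (!is_count(cfg[[f]])) stopf("configuration error: %s must be a non-negative count", f)
  for (f in c("case_abundance_multiplier", "periodicity_bp", "periodicity_sd",
              "tail_cap", "split_read_mean"))
    if (!(is.numeric(cfg[[f]]) && cfg[[f]] > 0))
      stopf("configuration error: %s must be > 0", f)
  if (fraction_mito < 0 || fraction_mito >= 1 || fraction_tail < 0 || fraction_tail >= 1)
    stopf("configuration error: fractions must lie in [0, 1)")
  structure(cfg, class = "simulation_config")
}

#' Default synthetic chromosome set
#' @return Data.frame of five 50 Mbp autosome-like chromosomes plus chrM.
#' @export
default_chromosomes <- function() {
  data.frame(name = c(paste0("chr", 1:5), "chrM"),
             length = c(rep(5e7, 5), 16299L),
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic eccDNA cohort
#'
#' Generates a fully self-contained cohort under a [simulation_config()]:
#' sample table, gene models, per-sample circle records (periodic length
#' mixture plus long tail, mitochondrial contamination, hotspot circles in
#' case samples only), circle consensus sequences (telomeric plus random
#' background), a paired protein abundance matrix with planted differential
#' proteins, and a ground-truth ledger of everything planted.
#'
#' @param config A [simulation_config()].
#' @return A list of class `eccdna_cohort` with elements `samples`, `genes`,
#'   `circles`, `sequences` (per-sample named character vectors),
#'   `proteins` (list: `abundance`, `pairing`), `truth`, `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    samples <- data.frame(
      sample_id = c(paste0("C", seq_len(config$n_control)),
                    paste0("A", seq_len(config$n_case))),
      group = rep(c("control", "case"), c(config$n_control, config$n_case)),
      stringsAsFactors = FALSE)

    genes <- simulate_genes(config)
    hotspots <- config$hotspot_genes
    if (is.null(hotspots) && config$n_hotspots > 0) {
      ids <- sample(genes$gene_id, min(config$n_hotspots, nrow(genes)))
      hotspots <- data.frame(gene_id = ids,
                             extra_circles = config$hotspot_extra_circles,
                             split_read_boost = config$hotspot_split_reads,
                             stringsAsFactors = FALSE)
    }

    circles <- simulate_circles(config, samples, genes, hotspots)
    telo <- telomeric_plan(config, samples)
    sequences <- simulate_sequences(config, samples, telo)
    proteins <- simulate_proteins(config, genes)
    truth <- list(
      hotspot_genes = hotspots,
      dep_proteins = proteins$truth,
      telomeric_kbp = stats::setNames(telo$n_circles * telo$repeats_per_circle * 6 / 1000,
                                      telo$sample_id))
    structure(list(samples = samples, genes = genes, circles = circles,
                   sequences = sequences,
                   proteins = proteins[c("abundance", "pairing")],
                   truth = truth, config = config),
              class = "eccdna_cohort")
  })
}

#' @export
print.eccdna_cohort <- function(x, ...) {
  cat(sprintf("Synthetic eccDNA cohort: %d samples (%d control / %d case), %d genes, %d circles\n",
              nrow(x$samples), sum(x$samples$group == "control"),
              sum(x$samples$group == "case"), nrow(x$genes), nrow(x$circles)))
  invisible(x)
}

simulate_genes <- function(config) {
  autosomes <- config$chromosomes[!config$chromosomes$name %in%
                                    c("chrM", "MT", "chrMT"), , drop = FALSE]
  n <- config$n_genes
  lens <- pmax(500, round(stats::rlnorm(n, config$gene_length_meanlog,
                                        config$gene_length_sdlog)))
  ci <- sample(nrow(autosomes), n, replace = TRUE,
               prob = autosomes$length)
  lens <- pmin(lens, floor(autosomes$length[ci] / 2))
  start <- floor(stats::runif(n, 0, autosomes$length[ci] - lens))
  data.frame(gene_id = sprintf("Gene%04d", seq_len(n)),
             gene_name = sprintf("Gene%04d", seq_len(n)),
             chrom = autosomes$name[ci],
             start = as.integer(start), end = as.integer(start + lens),
             strand = sample(c("+", "-"), n, replace = TRUE),
             length = as.integer(lens),
             coding = stats::runif(n) < 0.85,
             stringsAsFactors = FALSE)
}

# Draw circle lengths: periodic mixture (components at k * periodicity_bp,
# k = 1..n_periods, truncated to > 0) plus a log-uniform long tail < tail_cap.
sample_circle_lengths <- function(n, config) {
  tail <- stats::runif(n) < config$fraction_tail
  len <- integer(n)
  if (any(!tail)) {
    k <- sample(config$n_periods, sum(!tail), replace = TRUE)
    x <- round(stats::rnorm(sum(!tail), k * config$periodicity_bp,
                            config$periodicity_sd))
    while (any(x < 1)) {
      i <- x < 1
      x[i] <- round(stats::rnorm(sum(i), k[i] * config$periodicity_bp,
                                 config$periodicity_sd))
    }
    len[!tail] <- x
  }
  if (any(tail)) {
    lo <- log10(config$n_periods * config$periodicity_bp + 500)
    hi <- log10(config$tail_cap - 1)
    len[tail] <- round(10^stats::runif(sum(tail), lo, hi))
  }
  len
}

simulate_circles <- function(config, samples, genes, hotspots) {
  chroms <- config$chromosomes
  mito_names <- intersect(chroms$name, c("chrM", "MT", "chrMT"))
  autosomes <- chroms[!chroms$name %in% mito_names, , drop = FALSE]
  out <- vector("list", nrow(samples))
  for (si in seq_len(nrow(samples))) {
    s <- samples$sample_id[si]
    mean_n <- config$baseline_circles_per_sample *
      if (samples$group[si] == "case") config$case_abundance_multiplier else 1
    n <- stats::rpois(1, mean_n)
    if (n > 0) {
      mito <- length(mito_names) > 0 & stats::runif(n) < config$fraction_mito
      len <- sample_circle_lengths(n, config)
      chrom <- character(n)
      chrom_len <- numeric(n)
      if (any(!mito)) {
        ci <- sample(nrow(autosomes), sum(!mito), replace = TRUE,
                     prob = autosomes$length)
        chrom[!mito] <- autosomes$name[ci]
        chrom_len[!mito] <- autosomes$length[ci]
      }
      if (any(mito)) {
        chrom[mito] <- mito_names[1]
        chrom_len[mito] <- chroms$length[match(mito_names[1], chroms$name)]
      }
      len <- pmin(len, floor(chrom_len * 0.9))
      start <- floor(stats::runif(n, 0, chrom_len - len))
      base <- data.frame(chrom = chrom, start = as.integer(start),
                         end = as.integer(start + len),
                         split_reads = 1L + stats::rpois(n, max(0, config$split_read_mean - 1)),
                         sample_id = s, stringsAsFactors = FALSE)
    } else {
      base <- empty_circles()
    }
    extra <- NULL
    if (samples$group[si] == "case" && !is.null(hotspots) && nrow(hotspots) > 0) {
      extra <- do.call(rbind, lapply(seq_len(nrow(hotspots)), function(hi) {
        g <- genes[genes$gene_id == hotspots$gene_id[hi], ]
        ne <- hotspots$extra_circles[hi]
        if (ne == 0) return(NULL)
        len <- sample_circle_lengths(ne, config)
        chrom_len <- chroms$length[match(g$chrom, chroms$name)]
        # anchor inside the gene so every extra circle overlaps it
        start_max <- pmin(g$end - 1, chrom_len - len)
        start_min <- pmin(g$start, start_max)
        start <- start_min + floor(stats::runif(ne) * (start_max - start_min + 1))
        start <- pmax(start, 0)
        # split_read_boost is a guaranteed floor; Poisson extra on top gives
        # the between-sample variance real cohorts show
        data.frame(chrom = g$chrom, start = as.integer(start),
                   end = as.integer(pmin(start + len, chrom_len)),
                   split_reads = as.integer(hotspots$split_read_boost[hi] +
                                              stats::rpois(ne, 1)),
                   sample_id = s, stringsAsFactors = FALSE)
      }))
    }
    out[[si]] <- rbind(base, extra)
  }
  circles <- do.call(rbind, out)
  rownames(circles) <- NULL
  validate_circles(circles, "simulated circles")
}

# Per-sample telomeric circle plan. Defaults target group means of 35.1
# (control) and 30.5 kbp (case) with Poisson sample-to-sample variability
# in the circle count, mirroring the high inter-sample spread of real ECTR
# estimates. A user-supplied plan is taken verbatim.
telomeric_plan <- function(config, samples) {
  if (!is.null(config$telomeric_circles)) return(config$telomeric_circles)
  mean_n <- ifelse(samples$group == "control", 24, 21)
  data.frame(sample_id = samples$sample_id,
             n_circles = stats::rpois(nrow(samples), mean_n),
             repeats_per_circle = ifelse(samples$group == "control", 244L, 242L),
             stringsAsFactors = FALSE)
}

simulate_sequences <- function(config, samples, telo) {
  seqs <- lapply(seq_len(nrow(samples)), function(si) {
    s <- samples$sample_id[si]
    tp <- telo[telo$sample_id == s, , drop = FALSE]
    telo_seqs <- character(0)
    if (nrow(tp) == 1 && tp$n_circles > 0) {
      telo_seqs <- stats::setNames(
        rep(strrep("TTAGGG", tp$repeats_per_circle), tp$n_circles),
        sprintf("%s_telo%03d", s, seq_len(tp$n_circles)))
    }
    nb <- config$background_sequences_per_sample
    bg <- character(0)
    if (nb > 0) {
      lens <- sample(300:1000, nb, replace = TRUE)
      bg <- stats::setNames(
        vapply(lens, function(l)
          paste(sample(c("A", "C", "G", "T"), l, replace = TRUE), collapse = ""),
          character(1)),
        sprintf("%s_bg%03d", s, seq_len(nb)))
    }
    c(telo_seqs, bg)
  })
  stats::setNames(seqs, samples$sample_id)
}

simulate_proteins <- function(config, genes) {
  np <- config$n_proteins
  npairs <- config$n_protein_pairs
  if (np == 0 || npairs == 0) {
    return(list(abundance = NULL, pairing = NULL, truth = NULL))
  }
  # name the panel after genes where possible so gene-protein tandems can
  # arise under the default identity mapping
  n_shared <- min(np, nrow(genes))
  ids <- c(genes$gene_id[seq_len(n_shared)],
           sprintf("Prot%04d", seq_len(np - n_shared) + n_shared))
  ctrl_ids <- paste0("PC", seq_len(npairs))
  case_ids <- paste0("PA", seq_len(npairs))
  base <- stats::rnorm(np, 20, 2)    # log2 abundance baseline
  log2_ctrl <- matrix(base + stats::rnorm(np * npairs, 0, config$protein_noise_sd),
                      nrow = np, dimnames = list(ids, ctrl_ids))
  log2_case <- matrix(base + stats::rnorm(np * npairs, 0, config$protein_noise_sd),
                      nrow = np, dimnames = list(ids, case_ids))
  truth <- NULL
  if (config$n_dep > 0) {
    dep_idx <- sample(np, min(config$n_dep, np))
    direction <- rep(c(1, -1), length.out = length(dep_idx))
    log2_case[dep_idx, ] <- log2_case[dep_idx, ] +
      direction * config$dep_log2_shift
    truth <- data.frame(protein_id = ids[dep_idx],
                        direction = ifelse(direction > 0, "up", "down"),
                        log2_shift = direction * config$dep_log2_shift,
                        stringsAsFactors = FALSE)
  }
  list(abundance = 2^cbind(log2_ctrl, log2_case),
       pairing = data.frame(case = case_ids, control = ctrl_ids,
                            stringsAsFactors = FALSE),
       truth = truth)
}

#' Simulate split-read alignment records for circles
#'
#' Emits, for every circle, `reads_per_circle` split-read records whose two
#' segments map to the circle's end and start in inverted order (the read
#' runs across the junction). Junction coordinates of reads of one circle
#' are jittered independently by up to `jitter` bp, so a downstream merge
#' with `d_min = 10` bp coalesces them back into one circle.
#'
#' @param x An `eccdna_cohort` or a circle record data.frame.
#' @param reads_per_circle Reads per circle; `NULL` uses each circle's own
#'   `split_reads` count (so the caller reproduces the planted support).
#' @param segment_length Target segment length in bp (shrunk for short
#'   circles so the two segments stay disjoint).
#' @param jitter Maximum absolute junction jitter in bp.
#' @return Data.frame of split-read records (8-column layout, see
#'   [read_split_reads()]); circles too short to host two segments are
#'   skipped and counted in the `skipped_short` attribute.
#' @export
simulate_split_reads <- function(x, reads_per_circle = NULL,
                                 segment_length = 50, jitter = 2) {
  circles <- if (inherits(x, "eccdna_cohort")) x$circles else x
  if (nrow(circles) == 0) stopf("no circle records to simulate reads from")
  if (!is.null(reads_per_circle) && (!is_count(reads_per_circle, 1)))
    stopf("reads_per_circle must be >= 1")
  nreads <- if (is.null(reads_per_circle)) circles$split_reads
            else rep(as.integer(reads_per_circle), nrow(circles))
  len <- circles$end - circles$start
  seg <- pmin(segment_length, floor(len / 2) - 3)
  ok <- seg >= 10
  skipped <- sum(!ok)
  idx <- rep(which(ok), nreads[ok])
  segL <- rep(seg[ok], nreads[ok])
  n <- length(idx)
  jit <- function(n) if (jitter > 0) sample(seq(-jitter, jitter), n, replace = TRUE) else integer(n)
  js <- circles$start[idx] + jit(n)
  je <- circles$end[idx] + jit(n)
  js <- pmax(js, 0)
  reads <- data.frame(
    read_id = sprintf("%s_c%d_r%d", circles$sample_id[idx], idx,
                      unlist(lapply(nreads[ok], seq_len))),
    chrom = circles$chrom[idx],
    seg1_start = as.integer(je - segL), seg1_end = as.integer(je),
    seg2_start = as.integer(js), seg2_end = as.integer(js + segL),
    strand = "+",
    sample_id = circles$sample_id[idx],
    stringsAsFactors = FALSE)
  attr(reads, "skipped_short") <- skipped
  reads
}

#' Write a synthetic cohort to disk
#'
#' Emits per-sample circle BED tables, genes as BED6, circle sequences as
#' FASTA, the protein abundance matrix and pairing as TSV, the sample table
#' as TSV, and the ground-truth ledger as JSON. All files are plain text and
#' byte-identical for a fixed configuration.
#'
#' @param cohort An `eccdna_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "circles"), showWarnings = FALSE)
  dir.create(file.path(dir, "sequences"), showWarnings = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_genes(cohort$genes, file.path(dir, "genes.bed"))
  for (s in cohort$samples$sample_id) {
    write_circles(cohort$circles[cohort$circles$sample_id == s, , drop = FALSE],
                  file.path(dir, "circles", paste0(s, ".bed")))
    if (length(cohort$sequences[[s]]))
      write_circle_sequences(cohort$sequences[[s]],
                             file.path(dir, "sequences", paste0(s, ".fasta")))
  }
  if (!is.null(cohort$proteins$abundance)) {
    write_matrix(cohort$proteins$abundance, file.path(dir, "proteins.tsv"),
                 feature_col = "protein_id")
    utils::write.table(cohort$proteins$pairing, file.path(dir, "protein_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
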
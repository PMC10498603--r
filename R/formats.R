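#' Read circle records from a BED-like table
#'
#' Circles are stored as tab-separated BED-derived tables with at least four
#' columns: chromosome, 0-based start, exclusive end, and the split-read count
#' supporting the junction. Coordinates follow the BED half-open convention
#' used throughout the package.
#'
#' @param path Path to a tab-separated file without header.
#' @param sample_id Sample identifier attached to every record.
#' @return A data.frame with columns `chrom`, `start`, `end`, `split_reads`,
#'   `sample_id`, in file order.
#' @export
read_circles <- function(path, sample_id) {
  if (!file.exists(path)) stopf("circle file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(empty_circles())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 4)) {
    stopf("malformed circle line %d in %s: fewer than 4 columns",
          which(n_fields < 4)[1], path)
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  sr_chr <- vapply(fields, `[[`, "", 4)
  sr <- suppressWarnings(as.numeric(sr_chr))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) | end != floor(end))
  if (length(bad)) stopf("malformed circle line %d in %s: non-integer coordinates", bad[1], path)
  bad <- which(is.na(sr) | sr != floor(sr))
  if (length(bad)) stopf("malformed circle line %d in %s: non-integer split_reads '%s'",
                         bad[1], path, sr_chr[bad[1]])
  validate_circles(data.frame(chrom = chrom, start = as.integer(start),
                              end = as.integer(end), split_reads = as.integer(sr),
                              sample_id = sample_id, stringsAsFactors = FALSE),
                   context = path)
}

empty_circles <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             split_reads = integer(), sample_id = character(),
             stringsAsFactors = FALSE)
}

# Enforce the CircleRecord invariants: 0 <= start < end, split_reads >= 1.
validate_circles <- function(circles, context = "circles") {
  required <- c("chrom", "start", "end", "split_reads", "sample_id")
  missing <- setdiff(required, names(circles))
  if (length(missing)) stopf("%s: missing columns %s", context, paste(missing, collapse = ", "))
  bad <- which(circles$start < 0 | circles$start >= circles$end)
  if (length(bad)) stopf("%s: line %d violates 0 <= start < end (%d, %d)",
                         context, bad[1], circles$start[bad[1]], circles$end[bad[1]])
  bad <- which(circles$split_reads < 1)
  if (length(bad)) stopf("%s: line %d has split_reads < 1", context, bad[1])
  circles
}

#' Write circle records to a BED-like table
#'
#' @param circles Data.frame as returned by [read_circles()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_circles <- function(circles, path) {
  utils::write.table(circles[, c("chrom", "start", "end", "split_reads", "sample_id")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED6 or a GTF subset
#'
#' BED input is taken as 0-based half-open; GTF `gene` features (1-based
#' inclusive) are converted to the internal half-open convention on read.
#' The BED name column doubles as `gene_id` and `gene_name`; GTF attributes
#' `gene_id`, `gene_name` and `gene_type`/`gene_biotype` are honoured when
#' present. Protein-coding status defaults to `TRUE` when the annotation does
#' not state a biotype.
#'
#' @param path Path to a BED6 or GTF file.
#' @param format One of "auto", "bed", "gtf". "auto" decides by extension.
#' @return A data.frame with columns `gene_id`, `gene_name`, `chrom`, `start`,
#'   `end`, `strand`, `length`, `coding`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("gene file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.gtf$|\\.gff$", path, ignore.case = TRUE)) "gtf" else "bed"
  }
  genes <- if (format == "bed") read_genes_bed(path) else read_genes_gtf(path)
  validate_genes(genes, context = path)
}

read_genes_bed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 4) stopf("BED gene file needs >= 4 columns: %s", path)
  strand <- if (ncol(tab) >= 6) tab[[6]] else "."
  data.frame(gene_id = tab[[4]], gene_name = tab[[4]], chrom = tab[[1]],
             start = as.integer(tab[[2]]), end = as.integer(tab[[3]]),
             strand = strand, length = as.integer(tab[[3]]) - as.integer(tab[[2]]),
             coding = TRUE, stringsAsFactors = FALSE)
}

read_genes_gtf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  keep <- vapply(fields, function(f) length(f) >= 9 && f[3] == "gene", logical(1))
  fields <- fields[keep]
  if (!length(fields)) stopf("no 'gene' features in GTF: %s", path)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0(key, " \"([^\"]+)\""), attrs))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  }
  rows <- lapply(fields, function(f) {
    gid <- attr_get(f[9], "gene_id")
    gname <- attr_get(f[9], "gene_name")
    biotype <- attr_get(f[9], "gene_type")
    if (is.na(biotype)) biotype <- attr_get(f[9], "gene_biotype")
    data.frame(gene_id = gid, gene_name = if (is.na(gname)) gid else gname,
               chrom = f[1],
               start = as.integer(f[4]) - 1L,  # GTF 1-based inclusive -> half-open
               end = as.integer(f[5]),
               strand = f[7], stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, rows)
  genes$length <- genes$end - genes$start
  genes$coding <- TRUE
  genes
}

validate_genes <- function(genes, context = "genes") {
  if (anyNA(genes$gene_id)) stopf("%s: gene without gene_id", context)
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stopf("%s: duplicate gene_id '%s'", context, dup[1])
  bad <- which(genes$end - genes$start <= 0)
  if (length(bad)) stopf("%s: zero-length gene '%s'", context, genes$gene_id[bad[1]])
  genes$length <- genes$end - genes$start
  genes
}

#' Write gene models as BED6
#'
#' @param genes Gene model data.frame from [read_genes()].
#' @param path Output path.
#' @export
write_genes <- function(genes, path) {
  bed <- data.frame(genes$chrom, genes$start, genes$end, genes$gene_id,
                    0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix from TSV
#'
#' Expects a header row of sample identifiers and a first column of feature
#' (gene or protein) identifiers. All values must be finite; malformed or
#' ragged input is rejected rather than coerced.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with feature row names and sample column names.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) stopf("ragged rows in matrix file %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = NA)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stopf("non-numeric values in matrix file %s", path)
  if (any(!is.finite(m))) stopf("non-finite value in matrix file %s", path)
  if (anyNA(rownames(m)) || any(rownames(m) == "")) stopf("missing feature id in %s", path)
  m
}

#' Write an abundance matrix as TSV
#'
#' Values are written with 10 significant digits so that a write/read round
#' trip is the identity up to that precision.
#'
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @param feature_col Name for the leading feature-id column.
#' @export
write_matrix <- function(m, path, feature_col = "feature_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  formatted <- apply(m, 2, function(col) sprintf("%.10g", col))
  if (is.null(dim(formatted))) formatted <- matrix(formatted, nrow = nrow(m))
  out <- cbind(rownames(m), formatted)
  colnames(out) <- c(feature_col, colnames(m))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read split-read alignment records
#'
#' The 8-column TSV layout is: read_id, chrom, seg1_start, seg1_end,
#' seg2_start, seg2_end, strand, sample_id. Segment 1 is the read prefix,
#' segment 2 the read suffix; an inverted genomic order of the two segments
#' evidences a circular junction.
#'
#' @param path Path to the TSV (with header).
#' @return A data.frame of split-read alignments.
#' @export
read_split_reads <- function(path) {
  if (!file.exists(path)) stopf("split-read file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  required <- c("read_id", "chrom", "seg1_start", "seg1_end",
                "seg2_start", "seg2_end", "strand", "sample_id")
  missing <- setdiff(required, names(tab))
  if (length(missing)) stopf("%s: missing columns %s", path, paste(missing, collapse = ", "))
  tab
}

#' Write split-read alignment records
#' @param reads Data.frame from [simulate_split_reads()] or [read_split_reads()].
#' @param path Output path.
#' @export
write_split_reads <- function(reads, path) {
  utils::write.table(reads, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a risk-gene list (one symbol per line)
#'
#' Symbols are case-folded and trimmed; duplicates after normalization are
#' removed so each list is a set.
#'
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- normalize_symbols(readLines(path))
  unique(x[nzchar(x)])
}

#' Read circle consensus sequences from FASTA
#' @param path Path to a FASTA file.
#' @return A named character vector of upper-case sequences.
#' @export
read_circle_sequences <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(seqs)), names(seqs))
}

#' Write circle consensus sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_circle_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
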
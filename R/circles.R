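#' Merge and filter parameters for circle post-processing
#'
#' Defaults follow the analysis protocol: junction clusters closer than
#' `d_min = 10` bp at both breakpoints are coalesced, circles supported by
#' fewer than two split reads are discarded, circle size is capped at 100 kbp,
#' and mitochondrial circles are excluded.
#'
#' @param d_min Maximum breakpoint distance (bp, strict `<`) for coalescing.
#' @param min_split_reads Minimum split-read support to retain a circle.
#' @param max_length Maximum circle length in bp.
#' @param excluded_chroms Chromosome names removed by [filter_circles()]
#'   (mitochondrial aliases by default).
#' @return A list of class `merge_params`.
#' @export
merge_params <- function(d_min = 10, min_split_reads = 2, max_length = 1e5,
                         excluded_chroms = c("chrM", "MT", "chrMT")) {
  if (!is_count(d_min)) stopf("d_min must be a non-negative integer")
  if (!is_count(min_split_reads, min = 1)) stopf("min_split_reads must be >= 1")
  if (!(is.numeric(max_length) && max_length > 0)) stopf("max_length must be > 0")
  structure(list(d_min = d_min, min_split_reads = min_split_reads,
                 max_length = max_length, excluded_chroms = excluded_chroms),
            class = "merge_params")
}

#' Call circle junctions from split-read alignments
#'
#' A split read whose prefix segment maps genomically downstream of its
#' suffix segment evidences a circular template: the read runs across the
#' circle junction. Such a read yields the candidate circle
#' `(chrom, min(segment starts), max(segment ends))`. Both segments must
#' contribute at least `min_non_overlap` bp of genomic span not shared with
#' the other segment. Reads with collinear segments are not junctions; reads
#' whose segments map to different chromosomes (column `chrom2`, if present)
#' are skipped and counted. Identical junctions within a sample are
#' aggregated, each supporting read adding 1 to `split_reads`.
#'
#' @param alignments Data.frame of split-read records (see
#'   [read_split_reads()] for the column layout).
#' @param min_non_overlap Minimum non-shared genomic span per segment, bp.
#' @return Circle records (one row per distinct junction per sample) with a
#'   `skipped_interchrom` attribute counting discarded inter-chromosomal reads.
#' @export
call_junctions <- function(alignments, min_non_overlap = 10) {
  required <- c("chrom", "seg1_start", "seg1_end", "seg2_start", "seg2_end", "sample_id")
  missing <- setdiff(required, names(alignments))
  if (length(missing)) stopf("alignments: missing columns %s", paste(missing, collapse = ", "))
  a <- alignments
  len1 <- a$seg1_end - a$seg1_start
  len2 <- a$seg2_end - a$seg2_start
  if (any(len1 < 1 | len2 < 1)) stopf("alignment with segment length < 1")

  skipped <- 0L
  if ("chrom2" %in% names(a)) {
    inter <- !is.na(a$chrom2) & a$chrom2 != a$chrom
    skipped <- sum(inter)
    a <- a[!inter, , drop = FALSE]
    len1 <- len1[!inter]; len2 <- len2[!inter]
  }

  # Inverted order: read prefix downstream of read suffix => circular junction.
  inverted <- a$seg1_start > a$seg2_start & a$seg1_end > a$seg2_end
  ov <- pmax(0, pmin(a$seg1_end, a$seg2_end) - pmax(a$seg1_start, a$seg2_start))
  enough <- (len1 - ov) >= min_non_overlap & (len2 - ov) >= min_non_overlap
  keep <- inverted & enough
  a <- a[keep, , drop = FALSE]

  if (nrow(a) == 0) {
    out <- empty_circles()
  } else {
    start <- pmin(a$seg1_start, a$seg2_start)
    end <- pmax(a$seg1_end, a$seg2_end)
    key <- paste(a$sample_id, a$chrom, start, end, sep = "\r")
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, "\r", fixed = TRUE)
    out <- data.frame(chrom = vapply(parts, `[[`, "", 2),
                      start = as.integer(vapply(parts, `[[`, "", 3)),
                      end = as.integer(vapply(parts, `[[`, "", 4)),
                      split_reads = as.integer(agg$Freq),
                      sample_id = vapply(parts, `[[`, "", 1),
                      stringsAsFactors = FALSE)
    out <- out[order(out$sample_id, out$chrom, out$start, out$end), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "skipped_interchrom") <- skipped
  out
}

#' Coalesce near-duplicate circles
#'
#' Two circles of the same sample are linked when they lie on the same
#' chromosome and both breakpoints differ by less than `d_min` bp
#' (`|start1 - start2| < d_min` and `|end1 - end2| < d_min`, strict).
#' Clusters are the connected components under single linkage; each cluster
#' collapses to one circle whose split-read count is the sum over members and
#' whose coordinates are those of the member with the highest split-read
#' support (ties broken by smallest start, then smallest end). Total
#' split-read mass is conserved.
#'
#' @param circles Circle records (may span several samples; merging is
#'   per sample).
#' @param params A [merge_params()] object.
#' @return Merged circle records, sorted by sample, chromosome, start.
#' @export
merge_circles <- function(circles, params = merge_params()) {
  if (nrow(circles) == 0) return(circles)
  validate_circles(circles, "merge_circles input")
  pieces <- split(circles, paste(circles$sample_id, circles$chrom, sep = "\r"))
  merged <- lapply(pieces, merge_one_group, d_min = params$d_min)
  out <- do.call(rbind, merged)
  out <- out[order(out$sample_id, out$chrom, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Single-linkage merge of one sample x chromosome group via union-find.
merge_one_group <- function(g, d_min) {
  n <- nrow(g)
  if (n == 1 || d_min == 0) return(g)
  ord <- order(g$start)
  g <- g[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n - 1)) {
    j <- i + 1
    while (j <= n && g$start[j] - g$start[i] < d_min) {
      if (abs(g$end[j] - g$end[i]) < d_min) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
      j <- j + 1
    }
  }
  comp <- vapply(seq_len(n), function(i) as.integer(find(i)), integer(1))
  rows <- lapply(split(seq_len(n), comp), function(idx) {
    sub <- g[idx, , drop = FALSE]
    # representative: highest support, then smallest start, then smallest end
    rep_i <- order(-sub$split_reads, sub$start, sub$end)[1]
    rep <- sub[rep_i, , drop = FALSE]
    rep$split_reads <- sum(sub$split_reads)
    rep
  })
  do.call(rbind, rows)
}

#' Filter merged circles
#'
#' Retains circles with split-read support of at least `min_split_reads`,
#' length at most `max_length`, and a chromosome outside the excluded set
#' (mitochondrial circles by default). The number of circles failing each
#' criterion is attached as the `filter_log` attribute.
#'
#' @param circles Merged circle records.
#' @param params A [merge_params()] object.
#' @return The retained circles with a `filter_log` attribute.
#' @export
filter_circles <- function(circles, params = merge_params()) {
  if (nrow(circles) == 0) {
    attr(circles, "filter_log") <- c(low_support = 0L, too_long = 0L,
                                     excluded_chrom = 0L, removed = 0L)
    return(circles)
  }
  low <- circles$split_reads < params$min_split_reads
  long <- (circles$end - circles$start) > params$max_length
  excl <- circles$chrom %in% params$excluded_chroms
  keep <- !(low | long | excl)
  out <- circles[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_log") <- c(low_support = sum(low), too_long = sum(long),
                               excluded_chrom = sum(excl), removed = sum(!keep))
  out
}
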
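#' Exact Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon rank-sum test with mid-ranks for ties. For combined
#' sample sizes up to `exact_max_n` the p-value is computed from the full
#' null distribution of the rank-sum statistic (all `choose(n1+n2, n1)`
#' splits, enumerated by dynamic programming over the doubled mid-ranks);
#' beyond that, the normal approximation with tie correction and continuity
#' correction is used. The two-sided p doubles the smaller one-sided tail
#' and is capped at 1.
#'
#' @param x,y Numeric samples for the two groups.
#' @param exact_max_n Largest `n1 + n2` for which the exact null
#'   distribution is enumerated (default 25).
#' @return A list: `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
exact_wilcoxon <- function(x, y, exact_max_n = 25) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  if (N <= exact_max_n) {
    r2 <- as.integer(round(2 * r))     # doubled mid-ranks are integers
    w2 <- as.integer(round(2 * w))
    counts <- ranksum_null_counts(r2, n1)
    total <- choose(N, n1)
    sums <- seq_along(counts) - 1L     # achievable doubled sums
    p_le <- sum(counts[sums <= w2]) / total
    p_ge <- sum(counts[sums >= w2]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    u <- w - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with tie correction"
  }
  list(statistic = w, p_value = p, method = method)
}

# Number of ways to choose n1 of the doubled ranks with each possible sum.
# counts[s + 1] = #subsets of size n1 with doubled-rank sum s.
ranksum_null_counts <- function(r2, n1) {
  S <- sum(sort(r2, decreasing = TRUE)[seq_len(n1)])
  f <- matrix(0, nrow = n1 + 1, ncol = S + 1)
  f[1, 1] <- 1
  for (v in r2) {
    for (k in n1:1) {
      shifted <- c(rep(0, v), f[k, seq_len(S + 1 - v)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  f[n1 + 1, ]
}

#' Compare unique circle counts between groups
#'
#' Reports group means with SEM, the case/control fold ratio, and the exact
#' two-sided Wilcoxon rank-sum p-value for per-sample unique circle counts.
#'
#' @param counts_control,counts_case Per-sample unique circle counts.
#' @return A list: `mean_control`, `sem_control`, `mean_case`, `sem_case`,
#'   `ratio` (case/control), `p_value`, `method`.
#' @export
unique_count_comparison <- function(counts_control, counts_case) {
  stopifnot(length(counts_control) >= 1, length(counts_case) >= 1)
  wt <- exact_wilcoxon(counts_case, counts_control)
  list(mean_control = mean(counts_control), sem_control = sem(counts_control),
       mean_case = mean(counts_case), sem_case = sem(counts_case),
       ratio = mean(counts_case) / mean(counts_control),
       p_value = wt$p_value, method = wt$method)
}

#' Circle length profile: histogram, smoothing, periodicity
#'
#' Builds a 1 bp histogram of circle lengths up to `max_len`, smooths it with
#' a centered moving average (reflect padding), and detects local maxima on
#' the smoothed curve (strictly greater than both neighbours, with height at
#' least `prominence_frac` of the global smoothed maximum). The median
#' spacing between consecutive maxima captures the length periodicity of the
#' circle population (about 200 bp in nucleosome-associated circle cohorts).
#'
#' @param circles Circle records of one sample, or a numeric vector of
#'   circle lengths in bp.
#' @param window Moving-average window in bp; must be odd.
#' @param max_len Histogram upper bound in bp.
#' @param prominence_frac Minimum peak height as a fraction of the global
#'   smoothed maximum.
#' @param below_threshold Threshold for the reported fraction of circles
#'   below a given size (default 1e4 bp).
#' @return An object of class `size_profile`: `histogram`, `smoothed`,
#'   `peaks` (bp positions), `median_spacing` (NA when < 2 peaks),
#'   `fraction_below`, `n_circles`, and `per_chromosome` summaries when the
#'   input carries chromosome names.
#' @export
size_profile <- function(circles, window = 31, max_len = 1e4,
                         prominence_frac = 0.05, below_threshold = 1e4) {
  if (window %% 2 == 0) stopf("window must be odd (centered moving average)")
  if (is.data.frame(circles)) {
    lengths <- circles$end - circles$start
    chrom <- circles$chrom
  } else {
    lengths <- as.numeric(circles)
    chrom <- NULL
  }
  per_chrom <- NULL
  if (!is.null(chrom) && length(lengths)) {
    per_chrom <- do.call(rbind, lapply(split(lengths, chrom), function(l)
      data.frame(n = length(l), mean_length = mean(l), median_length = stats::median(l))))
    per_chrom$chrom <- rownames(per_chrom)
    rownames(per_chrom) <- NULL
  }
  if (length(lengths) == 0) {
    return(structure(list(histogram = integer(max_len), smoothed = numeric(max_len),
                          peaks = numeric(0), median_spacing = NA_real_,
                          fraction_below = NA_real_, n_circles = 0L,
                          per_chromosome = per_chrom, window = window),
                     class = "size_profile"))
  }
  h <- tabulate(lengths[lengths >= 1 & lengths <= max_len], nbins = max_len)
  s <- reflect_smooth(h, window)
  peaks <- find_peaks(s, prominence_frac, min_separation = window)
  spacing <- if (length(peaks) >= 2) stats::median(diff(peaks)) else NA_real_
  structure(list(histogram = h, smoothed = s, peaks = peaks,
                 median_spacing = spacing,
                 fraction_below = mean(lengths < below_threshold),
                 n_circles = length(lengths), per_chromosome = per_chrom,
                 window = window),
            class = "size_profile")
}

# Centered moving average with reflect padding at both ends.
reflect_smooth <- function(h, window) {
  pad <- (window - 1) / 2
  n <- length(h)
  if (n <= pad) return(as.numeric(h))
  padded <- c(rev(h[seq_len(pad)]), h, rev(h[(n - pad + 1):n]))
  s <- stats::filter(padded, rep(1 / window, window), sides = 2)
  as.numeric(s[(pad + 1):(pad + n)])
}

# Local maxima with a topographic-prominence floor. Candidates are
# positions not below either neighbour (plateaus allowed); candidates
# closer than min_separation collapse to their highest point (plateau ties
# resolve to the middle), so bin-level jitter on one summit yields one
# peak. A peak's prominence is its height above the key col: on each side,
# walk until terrain higher than the peak (or the boundary) and take the
# minimum; the key col is the higher of the two side minima. Shoulder
# bumps riding a larger peak's slope have near-zero prominence and are
# dropped by the prominence_frac * max(s) floor.
find_peaks <- function(s, prominence_frac, min_separation = 31) {
  n <- length(s)
  if (n < 3) return(numeric(0))
  i <- 2:(n - 1)
  cand <- i[s[i] >= s[i - 1] & s[i] >= s[i + 1]]
  if (!length(cand)) return(numeric(0))
  cluster <- cumsum(c(1, diff(cand) >= min_separation))
  peaks <- vapply(split(cand, cluster), function(idx) {
    top <- idx[s[idx] == max(s[idx])]
    top[ceiling(length(top) / 2)]
  }, numeric(1))
  prom <- vapply(peaks, function(p) peak_prominence(s, p), numeric(1))
  unname(peaks[prom >= prominence_frac * max(s)])
}

peak_prominence <- function(s, p) {
  h <- s[p]
  side_col <- function(idx) {
    if (!length(idx)) return(NA_real_)       # boundary: side ignored
    higher <- which(s[idx] > h)
    if (!length(higher)) return(NA_real_)
    min(s[idx[seq_len(higher[1])]])
  }
  left <- side_col(rev(seq_len(p - 1)))
  right <- side_col(seq(p + 1, length(s)))
  key_col <- suppressWarnings(max(left, right, na.rm = TRUE))
  if (!is.finite(key_col)) return(h)         # global maximum
  h - key_col
}

#' @export
print.size_profile <- function(x, ...) {
  cat(sprintf("Size profile: %d circles, %d peak(s), median spacing %s bp\n",
              x$n_circles, length(x$peaks),
              if (is.na(x$median_spacing)) "NA" else format(x$median_spacing)))
  invisible(x)
}
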
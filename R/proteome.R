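#' Paired t-test on matched case/control values
#'
#' One-sample t-test on the per-pair differences, two-sided. All-zero
#' differences give t = 0 and p = 1; constant nonzero differences give the
#' minimum representable positive p with a warning (the sign of the mean
#' difference still carries the direction).
#'
#' @param case,control Equal-length paired numeric vectors (n >= 2).
#' @return A list: `t_statistic`, `p_value`, `df`, `mean_difference`.
#' @export
paired_t <- function(case, control) {
  if (length(case) != length(control)) stopf("unpaired lengths: %d vs %d",
                                             length(case), length(control))
  n <- length(case)
  if (n < 2) stopf("paired t-test needs >= 2 pairs")
  d <- case - control
  s <- stats::sd(d)
  if (s == 0) {
    if (all(d == 0)) return(list(t_statistic = 0, p_value = 1, df = n - 1,
                                 mean_difference = 0))
    warnf("constant nonzero paired differences; p set to minimum positive")
    return(list(t_statistic = sign(mean(d)) * Inf,
                p_value = .Machine$double.xmin, df = n - 1,
                mean_difference = mean(d)))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t_statistic = t, p_value = 2 * stats::pt(-abs(t), n - 1), df = n - 1,
       mean_difference = mean(d))
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 on a lambda grid by
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)` and extrapolates to
#' lambda -> 1 with a cubic smoothing spline (the "smoother" method of the
#' original q-value procedure), clamped to (0, 1]. For small collections
#' (m < 100) a fixed-lambda estimate at 0.5 is used for stability.
#' The q-value of the i-th ordered p-value is
#' `min over j >= i of pi0 * m * p(j) / j`, capped at 1; q-values are
#' monotone non-decreasing in p, and with pi0 = 1 they equal
#' Benjamini-Hochberg adjusted p-values exactly.
#'
#' @param p Vector of p-values in [0, 1].
#' @param lambda Lambda grid for pi0 estimation.
#' @param pi0_method `"smoother"` (default) or `"fixed"` (single lambda).
#' @param fixed_lambda Lambda used by the fixed method.
#' @param pi0 Optional override of the pi0 estimate (e.g. 1 for a pure BH
#'   correction).
#' @return Numeric vector of q-values with attribute `pi0`.
#' @export
storey_q <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                     pi0_method = c("smoother", "fixed"), fixed_lambda = 0.5,
                     pi0 = NULL) {
  if (any(p < 0 | p > 1 | is.na(p))) stopf("p-values must lie in [0, 1]")
  pi0_method <- match.arg(pi0_method)
  m <- length(p)
  if (is.null(pi0)) {
    if (m < 100 || pi0_method == "fixed") {
      pi0 <- mean(p > fixed_lambda) / (1 - fixed_lambda)
    } else {
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
    pi0 <- min(max(pi0, .Machine$double.eps), 1)
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially expressed proteins (DEPs)
#'
#' Per protein and subcellular fraction: the average log2 case/control ratio
#' over replicate pairs, a paired t-test on the per-pair log2 differences,
#' Storey q-values across the fraction's proteins, and the DEP call
#' `up`/`down`/`none`. A protein is a DEP when `q < q_threshold` and
#' `|average log2 ratio| > log2_ratio_threshold` (both gates required).
#' Proteins with missing values in more than half of the pairs are excluded
#' and counted. Fractions are analyzed independently.
#'
#' @param matrices A non-negative abundance matrix (proteins x samples), or
#'   a named list of such matrices, one per fraction (e.g. CP, ME, sNE, cNE,
#'   Cysk).
#' @param pairing Data.frame with columns `case` and `control` giving the
#'   matched replicate sample ids.
#' @param q_threshold Storey q cutoff (default 0.05).
#' @param log2_ratio_threshold Absolute average log2 ratio cutoff (strict
#'   `>`, default 0.38).
#' @param log2_transform Log2-transform abundances before differencing
#'   (default TRUE; set FALSE when the matrix is already in log2 units).
#' @param ... Passed to [storey_q()].
#' @return A data.frame with one row per protein per fraction: `protein_id`,
#'   `fraction`, `avg_log2_ratio`, `t_statistic`, `p_value`, `q_value`,
#'   `call`; the number of excluded proteins per fraction is attached as the
#'   `excluded` attribute.
#' @export
call_deps <- function(matrices, pairing, q_threshold = 0.05,
                      log2_ratio_threshold = 0.38, log2_transform = TRUE, ...) {
  if (q_threshold <= 0 || q_threshold >= 1) stopf("q_threshold must be in (0, 1)")
  if (log2_ratio_threshold < 0) stopf("log2_ratio_threshold must be >= 0")
  if (!all(c("case", "control") %in% names(pairing)))
    stopf("pairing needs 'case' and 'control' columns")
  if (is.matrix(matrices)) matrices <- list(all = matrices)
  excluded <- integer(0)
  res <- lapply(names(matrices), function(fr) {
    m <- matrices[[fr]]
    missing <- setdiff(c(pairing$case, pairing$control), colnames(m))
    if (length(missing)) stopf("fraction %s: samples not in matrix: %s",
                               fr, paste(missing, collapse = ", "))
    vals <- if (log2_transform) log2(m) else m
    dmat <- vals[, pairing$case, drop = FALSE] - vals[, pairing$control, drop = FALSE]
    n_ok <- rowSums(is.finite(dmat))
    drop <- n_ok < ncol(dmat) / 2 | n_ok < 2
    excluded[fr] <<- sum(drop)
    dmat <- dmat[!drop, , drop = FALSE]
    stats <- t(apply(dmat, 1, function(d) {
      d <- d[is.finite(d)]
      pt <- suppressWarnings(paired_t(d, numeric(length(d))))
      c(mean(d), pt$t_statistic, pt$p_value)
    }))
    q <- storey_q(stats[, 3], ...)
    call <- rep("none", nrow(stats))
    dep <- q < q_threshold & abs(stats[, 1]) > log2_ratio_threshold
    call[dep & stats[, 1] > 0] <- "up"
    call[dep & stats[, 1] < 0] <- "down"
    data.frame(protein_id = rownames(dmat), fraction = fr,
               avg_log2_ratio = stats[, 1], t_statistic = stats[, 2],
               p_value = stats[, 3], q_value = as.numeric(q), call = call,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "excluded") <- excluded
  out
}
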
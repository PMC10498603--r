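#' Vote threshold from a distribution mode (ceiling rule)
#'
#' The democratic method derives each group's vote threshold as the ceiling
#' of the mode of the group's empirical PpGC distribution; a mode that is an
#' exact integer is its own threshold.
#'
#' @param mode_value The mode (grid argmax) of the PpGC distribution.
#' @return Integer vote threshold `ceiling(mode_value)`.
#' @export
vote_threshold <- function(mode_value) {
  stopifnot(is.numeric(mode_value), is.finite(mode_value))
  as.integer(ceiling(mode_value))
}

#' Mode of the positive PpGC distribution and its ceiling threshold
#'
#' The empirical distribution of all positive final PpGC values of one group
#' is estimated by a Gaussian kernel density with Silverman's bandwidth on a
#' 1024-point grid over [0, max]; the mode is the grid argmax. Zeros are
#' excluded: the zero spike of undetected genes would otherwise always
#' dominate the mode.
#'
#' @param values Numeric vector of final PpGC values of one group (all
#'   gene-sample values).
#' @param grid_n Number of density grid points.
#' @return A list with `mode_value` and integer `threshold`.
#' @export
mode_threshold <- function(values, grid_n = 1024) {
  pos <- values[values > 0]
  if (length(pos) < 10)
    stopf("fewer than 10 positive PpGC values (%d); supply a manual threshold",
          length(pos))
  d <- stats::density(pos, bw = "nrd0", n = grid_n, from = 0, to = max(pos))
  mode_value <- d$x[which.max(d$y)]
  list(mode_value = mode_value, threshold = vote_threshold(mode_value))
}

#' Find commonly produced per-gene circles (CPpGCs) by democratic voting
#'
#' A sample votes for gene i when its final PpGC value reaches the group's
#' vote threshold (`>=`). Genes collecting at least `min_votes` votes within
#' the group are the group's CPpGCs.
#'
#' @param x A `ppgc_matrix` or numeric final PpGC matrix.
#' @param group_samples Sample identifiers of the group.
#' @param min_votes Minimum number of votes (default 3).
#' @param threshold Optional manual integer threshold; when NULL it is
#'   derived with [mode_threshold()] from the group's positive values.
#' @param group Label used in the result.
#' @return A list of class `democratic_result`: `group`, `mode_value`,
#'   `threshold`, `votes` (named integer per gene), `cppgc` (gene ids).
#' @export
find_cppgc <- function(x, group_samples, min_votes = 3, threshold = NULL,
                       group = "group") {
  if (!is_count(min_votes, min = 1)) stopf("min_votes must be >= 1")
  m <- ppgc_final(x)
  missing <- setdiff(group_samples, colnames(m))
  if (length(missing)) stopf("samples not in matrix: %s", paste(missing, collapse = ", "))
  sub <- m[, group_samples, drop = FALSE]
  mode_value <- NA_real_
  if (is.null(threshold)) {
    mt <- mode_threshold(as.numeric(sub))
    mode_value <- mt$mode_value
    threshold <- mt$threshold
  }
  votes <- rowSums(sub >= threshold)
  storage.mode(votes) <- "integer"
  structure(list(group = group, mode_value = mode_value,
                 threshold = threshold, votes = votes,
                 cppgc = names(votes)[votes >= min_votes]),
            class = "democratic_result")
}

#' @export
print.democratic_result <- function(x, ...) {
  cat(sprintf("Democratic voting [%s]: threshold %d (mode %.4f), %d CPpGC gene(s)\n",
              x$group, x$threshold,
              if (is.na(x$mode_value)) NA else x$mode_value,
              length(x$cppgc)))
  invisible(x)
}
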
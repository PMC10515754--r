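#' Permutation null ensemble for a decoding timecourse
#'
#' Builds the label-permutation null for a fitted decoding timecourse: the
#' trained models (and hence their held-out predictions) are left
#' untouched, and the test-set embedding rows are shuffled. One shuffling
#' index is drawn per permutation and applied identically in every
#' cross-validation fold (which therefore requires equal test-set sizes);
#' correlations are computed against the shuffled labels and fold-averaged.
#' The default is 1,000 permutations.
#'
#' @param tc a [decode_timecourse()] result with `keep_predictions = TRUE`.
#' @param n_permutations number of label permutations.
#' @param seed integer seed for the shuffling indices.
#' @return object of class `null_ensemble`: `null_r` (permutations x
#'   dimensions x timepoints, fold-averaged), `n_permutations`, `seed`.
#' @export
permutation_null <- function(tc, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(tc, "decoding_timecourse"))
  if (is.null(tc$predictions) || is.null(tc$predictions[[1]]))
    stop("timecourse was fit with keep_predictions = FALSE")
  sizes <- vapply(tc$truth, nrow, integer(1))
  if (length(unique(sizes)) != 1)
    stop("inconsistent shuffle index: fold test sets differ in size")
  n <- sizes[1]
  n_dim <- nrow(tc$r_mean)
  n_t <- ncol(tc$r_mean)
  n_f <- length(tc$predictions)

  # standardize once; a zero-variance column contributes r = 0
  .std <- function(m) {
    s <- scale(m)
    s[, attr(s, "scaled:scale") == 0] <- 0
    s[is.na(s)] <- 0
    s
  }
  Ps <- lapply(tc$predictions, function(P) .std(matrix(P, n, n_dim * n_t)))
  Ys <- lapply(tc$truth, .std)
  rep_cols <- rep(seq_len(n_dim), times = n_t)

  set.seed(seed)
  null_r <- array(NA_real_, c(n_permutations, n_dim, n_t))
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(n)
    acc <- matrix(0, n_dim, n_t)
    for (fi in seq_len(n_f)) {
      Z <- Ys[[fi]][idx, , drop = FALSE]
      acc <- acc + matrix(colSums(Ps[[fi]] * Z[, rep_cols, drop = FALSE]) /
                            (n - 1), n_dim, n_t)
    }
    null_r[b, , ] <- acc / n_f
  }
  structure(list(null_r = null_r, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), times_ms = tc$times_ms,
                 dimensions = rownames(tc$r_mean)),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble: %d permutations x %d dimensions x %d timepoints\n",
              dim(x$null_r)[1], dim(x$null_r)[2], dim(x$null_r)[3]))
  invisible(x)
}

#' Max-statistic corrected significance threshold
#'
#' Computes the 99th percentile of the permutation null separately for
#' every (dimension, timepoint) cell, then returns the maximum of these
#' percentiles across all cells as a single threshold -- family-wise error
#' control over the whole dimensions x timepoints family.
#'
#' @param null a [permutation_null()] ensemble.
#' @param percentile per-cell percentile, default 99.
#' @return scalar threshold, with the per-cell percentile matrix attached
#'   as attribute `"percentiles"`.
#' @export
corrected_threshold <- function(null, percentile = 99) {
  stopifnot(inherits(null, "null_ensemble"))
  if (null$n_permutations < 100)
    warning("99th percentile unstable with fewer than 100 permutations")
  per_cell <- apply(null$null_r, c(2, 3), quantile,
                    probs = percentile / 100, names = FALSE)
  structure(max(per_cell), percentiles = per_cell)
}

#' Significance mask for a decoding timecourse
#'
#' Marks every (dimension, timepoint) cell whose observed fold-averaged
#' correlation strictly exceeds the corrected threshold, and records each
#' dimension's onset latency (first supra-threshold timepoint).
#'
#' @param observed a `decoding_timecourse`.
#' @param threshold scalar, typically [corrected_threshold()].
#' @return object of class `significance_mask`: logical `mask` (dimensions
#'   x timepoints), `threshold`, `onset_ms` (NA where never significant),
#'   and `n_sig` per dimension.
#' @export
significance_mask <- function(observed, threshold) {
  stopifnot(inherits(observed, "decoding_timecourse"),
            is.numeric(threshold), length(threshold) == 1)
  mask <- observed$r_mean > as.numeric(threshold)
  onset <- apply(mask, 1, function(m)
    if (any(m)) observed$times_ms[which(m)[1]] else NA_real_)
  structure(list(mask = mask, threshold = as.numeric(threshold),
                 times_ms = observed$times_ms, onset_ms = onset,
                 n_sig = rowSums(mask)),
            class = "significance_mask")
}

#' @export
print.significance_mask <- function(x, ...) {
  cat(sprintf("significance_mask: threshold %.4f; %d/%d dimensions significant somewhere\n",
              x$threshold, sum(x$n_sig > 0), length(x$n_sig)))
  invisible(x)
}

#' Compare within- and across-participant decoding at selected timepoints
#'
#' At each selected timepoint, tests the within-minus-across difference in
#' fold-averaged decoding correlation with a paired t-test (pairing over
#' dimensions by default, switchable to participants), Bonferroni-corrected
#' over the number of tested timepoints.
#'
#' @param within_tc,across_tc `decoding_timecourse` objects on the same
#'   dimensions and time grid.
#' @param timepoints_ms timepoints to test, default
#'   `c(100, 200, 300, 400, 500, 600)`.
#' @param alpha significance level applied to the corrected p-values,
#'   default 0.01.
#' @param pair_over `"dimensions"` (default) or `"participants"`.
#' @return data.frame with one row per tested timepoint: `time_ms`,
#'   `mean_diff`, `t`, `p_raw`, `p_bonferroni`, `significant`.
#' @export
compare_models <- function(within_tc, across_tc,
                           timepoints_ms = c(100, 200, 300, 400, 500, 600),
                           alpha = 0.01,
                           pair_over = c("dimensions", "participants")) {
  pair_over <- match.arg(pair_over)
  stopifnot(inherits(within_tc, "decoding_timecourse"),
            inherits(across_tc, "decoding_timecourse"))
  if (!isTRUE(all.equal(within_tc$times_ms, across_tc$times_ms)) ||
      nrow(within_tc$r_mean) != nrow(across_tc$r_mean))
    stop("timecourses must share dimensions and time grid")
  times <- within_tc$times_ms

  .per_participant <- function(tc) {
    pid <- vapply(tc$folds, `[[`, character(1), "test_participant")
    ids <- unique(pid)
    t(vapply(ids, function(p)
      colMeans(apply(tc$r[, , pid == p, drop = FALSE], c(1, 2), mean)),
      numeric(ncol(tc$r_mean))))
  }
  if (pair_over == "participants") {
    w_mat <- .per_participant(within_tc)
    a_mat <- .per_participant(across_tc)
    if (nrow(w_mat) != nrow(a_mat))
      stop("participant sets differ between the two timecourses")
  }

  rows <- lapply(timepoints_ms, function(tp) {
    ti <- which.min(abs(times - tp))
    if (abs(times[ti] - tp) > 1e-9)
      warning(sprintf("timepoint %g ms not on grid; using nearest sample %g ms",
                      tp, times[ti]))
    diffs <- if (pair_over == "dimensions")
      within_tc$r_mean[, ti] - across_tc$r_mean[, ti]
    else w_mat[, ti] - a_mat[, ti]
    if (sd(diffs) == 0) {
      tt <- list(statistic = if (mean(diffs) == 0) 0 else Inf,
                 p.value = if (mean(diffs) == 0) 1 else 0)
    } else {
      tt <- t.test(diffs)
    }
    data.frame(time_ms = times[ti], mean_diff = mean(diffs),
               t = unname(tt$statistic), p_raw = tt$p.value)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p_raw * length(timepoints_ms))
  out$significant <- out$p_bonferroni < alpha
  out
}
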
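#' Boxcar-smooth a timecourse
#'
#' Moving-average smoothing with a centred boxcar window; at the series
#' edges the window shrinks to the available samples. The window width in
#' ms is converted to samples on the series' grid and rounded to the
#' nearest odd sample count. `window_ms = 0` is the identity.
#'
#' @param tc numeric vector, or matrix with one series per row.
#' @param window_ms window width in ms (>= 0).
#' @param times_ms the series' time axis (used for the sample step).
#' @return smoothed series, same shape as the input.
#' @export
smooth_timecourse <- function(tc, window_ms, times_ms) {
  stopifnot(window_ms >= 0)
  if (is.matrix(tc)) {
    out <- t(apply(tc, 1, smooth_timecourse, window_ms = window_ms,
                   times_ms = times_ms))
    dimnames(out) <- dimnames(tc)
    return(out)
  }
  if (window_ms == 0) return(tc)
  step <- diff(times_ms[1:2])
  n_w <- max(1L, round(window_ms / step))
  half <- floor(n_w / 2)
  if (2 * half + 1 > length(tc))
    stop("smoothing window exceeds the series length")
  if (half == 0) return(tc)
  vapply(seq_along(tc), function(i) {
    lo <- max(1L, i - half)
    hi <- min(length(tc), i + half)
    mean(tc[lo:hi])
  }, numeric(1))
}

#' Z-normalize dimension timecourses and average across participants
#'
#' Each (dimension, participant) series is z-scored over time (mean 0, SD
#' 1) so that only the shape, not the signal-to-noise ratio, enters the
#' subsequent warping analysis; the normalized series are then averaged
#' across participants. Zero-variance series are dropped with a warning
#' (their dimensions are listed in the `"dropped"` attribute).
#'
#' @param tcs array dimensions x timepoints x participants, or a list of
#'   dimensions x timepoints matrices (one per participant).
#' @return dimensions x timepoints matrix of participant-averaged,
#'   z-normalized series.
#' @export
znormalize_timecourses <- function(tcs) {
  if (is.list(tcs))
    tcs <- array(unlist(tcs), dim = c(dim(tcs[[1]]), length(tcs)),
                 dimnames = c(dimnames(tcs[[1]]), list(NULL)))
  if (length(dim(tcs)) == 2) tcs <- array(tcs, c(dim(tcs), 1),
                                          dimnames = c(dimnames(tcs), list(NULL)))
  n_dim <- dim(tcs)[1]
  dropped <- logical(n_dim)
  z <- tcs
  for (p in seq_len(dim(tcs)[3])) {
    for (d in seq_len(n_dim)) {
      x <- tcs[d, , p]
      s <- sd(x)
      if (s == 0) { dropped[d] <- TRUE; z[d, , p] <- NA } else
        z[d, , p] <- (x - mean(x)) / s
    }
  }
  if (any(dropped))
    warning("dropping zero-variance series for dimension(s): ",
            paste(which(dropped), collapse = ", "))
  out <- apply(z, c(1, 2), mean)
  dimnames(out) <- dimnames(tcs)[1:2]
  out <- out[!dropped, , drop = FALSE]
  attr(out, "dropped") <- which(dropped)
  out
}

#' Exclude the lowest-SNR dimension timecourses
#'
#' Orders dimensions by their total count of significant timepoints
#' (summed across participants) and removes the lowest `frac` fraction --
#' `floor(frac * n)` dimensions; ties broken by smaller count first, then
#' stable input order. With 66 dimensions and the default 5% this excludes
#' exactly 3.
#'
#' @param significance_counts integer vector, per-dimension significant
#'   timepoint counts (named or not).
#' @param frac fraction to exclude, in \[0, 1).
#' @return list with `retained` and `excluded` index vectors (and names,
#'   if the input was named).
#' @export
exclude_low_snr <- function(significance_counts, frac = 0.05) {
  if (frac >= 1) stop("frac must be < 1")
  if (frac < 0) stop("frac must be >= 0")
  n <- length(significance_counts)
  n_excl <- floor(frac * n)
  ord <- order(significance_counts, seq_len(n)) # stable: count, then input order
  excluded <- sort(ord[seq_len(n_excl)])
  retained <- sort(setdiff(seq_len(n), excluded))
  list(retained = retained, excluded = excluded,
       retained_names = names(significance_counts)[retained],
       excluded_names = names(significance_counts)[excluded])
}

#' Dynamic-time-warping alignment of two series
#'
#' Shape-based dissimilarity between two univariate series: a local cost
#' matrix of pairwise Euclidean (absolute) distances between timepoints is
#' searched for the lowest-cost path from the first to the last timepoint
#' pair, under the warping rules that the series ends align, the path
#' never goes back in time, and it is continuous (steps from
#' \{(1,0),(0,1),(1,1)\}). The total cost is the sum of local distances
#' along that path; identical series give cost 0 along the diagonal.
#'
#' @param a,b finite numeric series (lengths >= 1; may differ).
#' @return object of class `dtw_alignment`: `total_cost`, `path` (two-
#'   column matrix of 1-based index pairs), `local_cost`.
#' @export
dtw_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty series")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  cost <- abs(outer(as.numeric(a), as.numeric(b), "-"))
  res <- .dtw_core(cost)
  structure(list(total_cost = res$total_cost, path = res$path,
                 local_cost = cost),
            class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat(sprintf("dtw_alignment: %d x %d series, total cost %.4f, path length %d\n",
              nrow(x$local_cost), ncol(x$local_cost), x$total_cost,
              nrow(x$path)))
  invisible(x)
}

#' Pairwise DTW dissimilarity matrix
#'
#' Applies [dtw_distance()] to every pair of series (rows), returning the
#' symmetric matrix of total alignment costs with a zero diagonal.
#'
#' @param tcs matrix with one (smoothed, z-normalized, participant-
#'   averaged) series per row.
#' @return symmetric dissimilarity matrix with the input rownames.
#' @export
dtw_matrix <- function(tcs) {
  tcs <- as.matrix(tcs)
  stopifnot(all(is.finite(tcs)))
  out <- .dtw_pairwise(tcs)
  dimnames(out) <- list(rownames(tcs), rownames(tcs))
  out
}

#' Hierarchical clustering of timecourse shapes
#'
#' Agglomerative clustering (average linkage by default) on a precomputed
#' DTW dissimilarity matrix, with flat clusters obtained by cutting the
#' tree at half the maximum observed pairwise distance. Each cluster's
#' prototype is the mean of its member series.
#'
#' @param d dissimilarity matrix from [dtw_matrix()] (symmetric, zero
#'   diagonal, >= 2 rows).
#' @param tcs the series matrix the distances were computed from (rows
#'   match `d`); used for the prototypes.
#' @param linkage linkage method passed to [stats::hclust()].
#' @param cut_factor cut height as a fraction of `max(d)`, default 0.5.
#' @return object of class `timecourse_clusters`: `labels` (integer per
#'   series), `k`, `prototypes` (k x timepoints), `tree` (hclust),
#'   `cut_height`, `d`.
#' @export
cluster_timecourses <- function(d, tcs, linkage = "average",
                                cut_factor = 0.5) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 retained dimensions to cluster")
  stopifnot(isSymmetric(unname(d)), all(diag(d) == 0), nrow(tcs) == nrow(d))
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  h <- cut_factor * max(d)
  labels <- stats::cutree(tree, h = h)
  k <- max(labels)
  prototypes <- t(vapply(seq_len(k), function(cl)
    colMeans(tcs[labels == cl, , drop = FALSE]), numeric(ncol(tcs))))
  structure(list(labels = labels, k = k, prototypes = prototypes,
                 tree = tree, cut_height = h, d = d),
            class = "timecourse_clusters")
}

#' @export
print.timecourse_clusters <- function(x, ...) {
  cat(sprintf("timecourse_clusters: %d clusters over %d series (cut at %.3f)\n",
              x$k, length(x$labels), x$cut_height))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @export
plot.timecourse_clusters <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(x$tree, main = "DTW dendrogram", xlab = "", sub = "")
  graphics::abline(h = x$cut_height, lty = 2, col = 2)
  graphics::matplot(t(x$prototypes), type = "l", lty = 1, lwd = 2,
                    xlab = "timepoint", ylab = "z",
                    main = "cluster prototypes", ...)
  invisible(x)
}

#' Full shape-analysis pipeline for dimension timecourses
#'
#' Fixed processing order: boxcar smoothing, per-participant z-scoring,
#' participant averaging, low-SNR exclusion, pairwise DTW, hierarchical
#' clustering at half the maximum distance.
#'
#' @param tcs array dimensions x timepoints x participants (or a list of
#'   matrices, one per participant).
#' @param times_ms shared time axis of the series.
#' @param significance_counts per-dimension significant timepoint counts
#'   (summed across participants) driving the exclusion; `NULL` disables
#'   exclusion.
#' @param window_ms smoothing window (default 50 ms).
#' @param exclude_frac fraction of dimensions to exclude (default 0.05).
#' @param linkage,cut_factor passed to [cluster_timecourses()].
#' @return a [cluster_timecourses()] solution, with the retained series as
#'   element `series` and the exclusion bookkeeping as element `exclusion`.
#' @export
shape_analysis <- function(tcs, times_ms, significance_counts = NULL,
                           window_ms = 50, exclude_frac = 0.05,
                           linkage = "average", cut_factor = 0.5) {
  if (is.list(tcs))
    tcs <- array(unlist(tcs), dim = c(dim(tcs[[1]]), length(tcs)),
                 dimnames = c(dimnames(tcs[[1]]), list(NULL)))
  if (length(dim(tcs)) == 2) tcs <- array(tcs, c(dim(tcs), 1),
                                          dimnames = c(dimnames(tcs), list(NULL)))
  sm <- tcs
  for (p in seq_len(dim(tcs)[3]))
    sm[, , p] <- smooth_timecourse(tcs[, , p], window_ms, times_ms)
  avg <- znormalize_timecourses(sm)
  excl <- if (!is.null(significance_counts))
    exclude_low_snr(significance_counts, exclude_frac)
  else list(retained = seq_len(nrow(avg)), excluded = integer(0))
  series <- avg[excl$retained, , drop = FALSE]
  sol <- cluster_timecourses(dtw_matrix(series), series,
                             linkage = linkage, cut_factor = cut_factor)
  sol$series <- series
  sol$exclusion <- excl
  sol
}
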
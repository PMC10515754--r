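t_ms <- seq(0, 100, by = 10)

test_that("boxcar smoothing has the documented identity and edge behaviour", {
  x <- rnorm(11)
  expect_identical(smooth_timecourse(x, 0, t_ms), x)
  expect_equal(smooth_timecourse(rep(3, 11), 50, t_ms), rep(3, 11))
  imp <- c(0, 0, 0, 0, 0, 1, 0, 0, 0, 0, 0)
  sm <- smooth_timecourse(imp, 30, t_ms)   # 3-sample window
  expect_equal(sm[5:7], rep(1 / 3, 3))
  expect_equal(sum(sm), 1)
  expect_error(smooth_timecourse(x[1:3], 200, t_ms), "exceeds")
})

test_that("z-normalization gives mean 0 / sd 1 and is affine-invariant", {
  x <- matrix(rnorm(22), 2, 11)
  z <- znormalize_timecourses(array(x, c(2, 11, 1)))
  expect_lt(max(abs(rowMeans(z))), 1e-12)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-12)
  z2 <- znormalize_timecourses(array(3.7 * x + 2, c(2, 11, 1)))
  expect_equal(z, z2, tolerance = 1e-12)
  # identical shapes at different amplitudes average to the common shape
  two <- array(c(x, 5 * x), c(2, 11, 2))
  expect_equal(znormalize_timecourses(two), z, tolerance = 1e-12)
  flat <- array(rbind(rep(1, 11), rnorm(11)), c(2, 11, 1))
  expect_warning(znormalize_timecourses(flat), "zero-variance")
})

test_that("the lowest-5% exclusion rule drops floor(frac * n) dimensions", {
  counts66 <- seq_len(66)
  expect_length(exclude_low_snr(counts66, 0.05)$excluded, 3L)
  expect_equal(exclude_low_snr(counts66, 0.05)$excluded, 1:3)
  expect_length(exclude_low_snr(counts66, 0)$excluded, 0L)
  expect_equal(exclude_low_snr(0:19, 0.05)$excluded, 1L)
  # ties broken by input order: both zeros tie, the first is dropped
  expect_equal(exclude_low_snr(c(5, 0, 0, 7), 0.25)$excluded, 2L)
  expect_error(exclude_low_snr(counts66, 1), "frac")
})

test_that("identical series align along the diagonal at zero cost", {
  a <- c(0, 1, 3, 2, 0)
  res <- dtw_distance(a, a)
  expect_equal(res$total_cost, 0)
  expect_equal(res$path, cbind(1:5, 1:5))
})

test_that("DTW satisfies the path rules and is symmetric", {
  set.seed(80)
  for (i in 1:10) {
    a <- rnorm(sample(3:8, 1))
    b <- rnorm(sample(3:8, 1))
    res <- dtw_distance(a, b)
    p <- res$path
    expect_equal(p[1, ], c(1, 1))
    expect_equal(p[nrow(p), ], c(length(a), length(b)))
    steps <- diff(p)
    expect_true(all(steps >= 0 & steps <= 1))
    expect_true(all(rowSums(steps) >= 1))
    expect_equal(res$total_cost, sum(res$local_cost[p]))
    expect_equal(res$total_cost, dtw_distance(b, a)$total_cost)
    expect_gte(res$total_cost, 0)
  }
  expect_error(dtw_distance(numeric(0), 1:3), "empty")
})

test_that("dynamic programming equals the exhaustive path-enumeration oracle", {
  a <- c(0, 0, 1, 0)
  b <- c(0, 1, 0, 0)
  expect_equal(dtw_distance(a, b)$total_cost, dtw_brute_force(a, b))
  set.seed(81)
  for (i in 1:20) {
    a <- round(rnorm(sample(2:6, 1)), 2)
    b <- round(rnorm(sample(2:6, 1)), 2)
    expect_identical(dtw_distance(a, b)$total_cost, dtw_brute_force(a, b))
  }
})

test_that("warping can only reduce the diagonal alignment cost", {
  set.seed(82)
  for (i in 1:10) {
    a <- rnorm(12)
    b <- rnorm(12)
    expect_lte(dtw_distance(a, b)$total_cost, sum(abs(a - b)))
  }
})

test_that("the dissimilarity matrix is consistent with pairwise alignments", {
  set.seed(83)
  tcs <- rbind(s1 = rnorm(15), s2 = NA, s3 = rnorm(15))
  tcs[2, ] <- tcs[1, ]
  d <- dtw_matrix(tcs)
  expect_true(all(diag(d) == 0))
  expect_equal(d, t(d))
  expect_equal(d[1, 2], 0)
  expect_gt(d[1, 3], 0)
  expect_equal(d[1, 3], d[2, 3])
  for (i in 1:2) for (j in 3:3)
    expect_equal(d[i, j], dtw_distance(tcs[i, ], tcs[j, ])$total_cost)
})

test_that("planted shape families are recovered as two clusters", {
  fam <- planted_shape_families()
  sol <- cluster_timecourses(dtw_matrix(fam$tcs), fam$tcs)
  expect_equal(sol$k, 2L)
  expect_true(same_partition(sol$labels, fam$family))
  expect_equal(dim(sol$prototypes), c(2L, length(fam$times_ms)))
  # prototypes are the member means
  expect_equal(sol$prototypes[sol$labels[1], ],
               unname(colMeans(fam$tcs[fam$family == fam$family[1], ])))
})

test_that("degenerate clustering inputs behave as documented", {
  tcs <- matrix(rep(c(0, 1, 0, 0), 3), 3, 4, byrow = TRUE)
  sol <- cluster_timecourses(dtw_matrix(tcs), tcs)
  expect_equal(sol$k, 1L)
  expect_error(cluster_timecourses(matrix(0, 1, 1), tcs[1, , drop = FALSE]),
               "at least 2")
  # cutting just below the top merge splits the tree
  fam <- planted_shape_families()
  d <- dtw_matrix(fam$tcs)
  tree <- stats::hclust(stats::as.dist(d), method = "average")
  just_below <- (max(tree$height) - 1e-9) / max(d)
  sol2 <- cluster_timecourses(d, fam$tcs, cut_factor = just_below)
  expect_gte(sol2$k, 2L)
})

test_that("cluster labels do not depend on input ordering", {
  fam <- planted_shape_families()
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  sol1 <- cluster_timecourses(dtw_matrix(fam$tcs), fam$tcs)
  sol2 <- cluster_timecourses(dtw_matrix(fam$tcs[perm, ]), fam$tcs[perm, ])
  expect_true(same_partition(sol1$labels[perm], sol2$labels))
})

test_that("shape_analysis runs the documented processing order", {
  fam <- planted_shape_families()
  arr <- array(fam$tcs, c(nrow(fam$tcs), ncol(fam$tcs), 1),
               dimnames = list(rownames(fam$tcs), NULL, NULL))
  counts <- c(0, rep(10, 7))   # first series has fewest significant points
  sol <- shape_analysis(arr, fam$times_ms, significance_counts = counts,
                        window_ms = 30, exclude_frac = 0.13)
  manual_sm <- smooth_timecourse(fam$tcs, 30, fam$times_ms)
  manual_z <- znormalize_timecourses(array(manual_sm, c(8, 61, 1)))
  keep <- exclude_low_snr(counts, 0.13)$retained
  manual <- cluster_timecourses(dtw_matrix(manual_z[keep, ]),
                                manual_z[keep, ])
  expect_equal(unname(sol$labels), unname(manual$labels))
  expect_equal(sol$exclusion$excluded, 1L)
  expect_equal(nrow(sol$series), 7L)
})
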
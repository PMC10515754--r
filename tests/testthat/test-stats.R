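test_that("the unshuffled labels reproduce the observed correlations exactly", {
  tc <- small_within_tc()
  n_dim <- nrow(tc$r_mean)
  for (fi in c(1, 3)) {
    rec <- vapply(seq_len(ncol(tc$r_mean)), function(t)
      vapply(seq_len(n_dim), function(d)
        cor(tc$predictions[[fi]][, d, t], tc$truth[[fi]][, d]), numeric(1)),
      numeric(n_dim))
    expect_equal(rec, unname(tc$r[, , fi]), tolerance = 1e-12)
  }
})

test_that("the permutation null is deterministic given its seed", {
  tc <- small_within_tc()
  n1 <- permutation_null(tc, 50, seed = 5)
  n2 <- permutation_null(tc, 50, seed = 5)
  expect_identical(n1$null_r, n2$null_r)
  expect_warning(corrected_threshold(n1), "unstable")
})

test_that("unequal fold test sizes are rejected", {
  tc <- small_within_tc()
  broken <- tc
  broken$truth[[1]] <- broken$truth[[1]][-1, ]
  expect_error(permutation_null(broken, 10), "inconsistent shuffle index")
})

test_that("the corrected threshold is the max of per-cell percentiles", {
  mk_null <- function(arr) structure(
    list(null_r = arr, n_permutations = dim(arr)[1], seed = 1L),
    class = "null_ensemble")
  z <- mk_null(array(0, c(200, 3, 4)))
  expect_equal(as.numeric(corrected_threshold(z)), 0)
  set.seed(70)
  arr <- array(rnorm(200 * 3 * 4, sd = 0.1), c(200, 3, 4))
  thr <- corrected_threshold(mk_null(arr))
  per_cell <- attr(thr, "percentiles")
  expect_true(all(as.numeric(thr) >= per_cell))        # max dominance
  arr2 <- arr
  arr2[, 2, 2] <- arr[, 2, 2] + 10                     # shift one cell by +c
  thr2 <- corrected_threshold(mk_null(arr2))
  expect_equal(as.numeric(thr2),
               as.numeric(quantile(arr[, 2, 2], 0.99)) + 10)
})

test_that("per-cell null percentiles match an independent resimulation oracle", {
  ns <- noise_study()
  nl <- fixture("noise_null", function() permutation_null(ns$tc, 1000, seed = 6))
  # oracle: fold-averaged correlation of k independent noise predictions
  # against the same label set, resimulated from scratch
  k <- length(ns$tc$predictions)
  n <- nrow(ns$tc$truth[[1]])
  y <- ns$tc$truth[[1]][, 1]
  set.seed(7)
  oracle <- replicate(4000, mean(replicate(k, cor(rnorm(n), y))))
  q_oracle <- quantile(oracle, 0.99, names = FALSE)
  q_null <- mean(apply(nl$null_r, c(2, 3), quantile, 0.99, names = FALSE))
  expect_equal(q_null, q_oracle, tolerance = 0.15)
})

test_that("per-fold observed statistics are rank-uniform in their own null", {
  ns <- noise_study()
  # single-fold statistic: exchangeability holds exactly there
  one <- ns$tc
  one$predictions <- one$predictions[1]
  one$truth <- one$truth[1]
  nl <- permutation_null(one, 400, seed = 8)
  pvals <- vapply(seq_len(dim(nl$null_r)[3]), function(t)
    mean(nl$null_r[, 2, t] >= one$r[2, t, 1]), numeric(1))
  expect_gt(mean(pvals), 0.35)
  expect_lt(mean(pvals), 0.65)
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("significance masks use strict exceedance and record onsets", {
  tc <- small_within_tc()
  empty <- significance_mask(tc, Inf)
  expect_false(any(empty$mask))
  expect_true(all(is.na(empty$onset_ms)))
  # exact equality is not significant
  thr <- max(tc$r_mean)
  expect_false(any(significance_mask(tc, thr)$mask))
  m <- significance_mask(tc, 0.15)
  first <- which(tc$r_mean[1, ] > 0.15)[1]
  expect_equal(unname(m$onset_ms[1]), tc$times_ms[first])
  # planted early dimensions come up before their 125 ms peak
  expect_lt(m$onset_ms[[1]], 125)
})

test_that("model comparison flags no difference for identical inputs", {
  tc <- small_within_tc()
  cmp <- compare_models(tc, tc, timepoints_ms = c(100, 300))
  expect_equal(cmp$mean_diff, c(0, 0))
  expect_false(any(cmp$significant))
  expect_equal(cmp$p_bonferroni, c(1, 1))
})

test_that("Bonferroni correction multiplies raw p-values by the family size", {
  tc <- small_within_tc()
  s <- small_study()
  fp <- make_session_folds(s$datasets$P2$trial_table)
  tc2 <- fixture("small_within_tc_p2", function()
    decode_timecourse(s$datasets["P2"], s$images, fp,
                      keep_predictions = FALSE))
  cmp <- compare_models(tc, tc2, timepoints_ms = c(100, 300))
  expect_equal(cmp$p_bonferroni, pmin(1, cmp$p_raw * 2))
  expect_warning(compare_models(tc, tc2, timepoints_ms = 103), "nearest")
})
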
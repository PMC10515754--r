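test_that("generated embeddings have the requested shape and sparsity", {
  emb <- generate_embedding(1854, 66, sparsity = 0.5, seed = 1)
  expect_equal(dim(emb), c(1854L, 66L))
  expect_equal(emb$level, "concept")
  expect_true(all(emb$weights >= 0))
  expect_equal(mean(emb$weights == 0), 0.5, tolerance = 0.02)
  expect_true(all(apply(emb$weights, 2, var) > 0))
  dense <- generate_embedding(10, 3, sparsity = 0, seed = 0)
  expect_true(all(dense$weights > 0))
})

test_that("embedding generation is deterministic and rejects degenerate sparsity", {
  a <- generate_embedding(50, 5, sparsity = 0.3, seed = 7)
  b <- generate_embedding(50, 5, sparsity = 0.3, seed = 7)
  expect_identical(a, b)
  expect_error(generate_embedding(50, 5, sparsity = 1, seed = 1),
               "degenerate")
})

test_that("image expansion bookkeeping and zero-noise behaviour", {
  emb <- generate_embedding(20, 4, seed = 3)
  out <- expand_to_images(emb, exemplars_per_concept = 12,
                          exemplar_noise_sd = 0, seed = 4)
  expect_equal(nrow(out$images$weights), 240L)
  expect_equal(out$images$level, "image")
  # every exemplar inherits its concept's weights exactly
  for (s in c(1, 7)) {
    ids <- sprintf("%s_s%02d", rownames(emb$weights), s)
    expect_equal(unname(out$images$weights[ids, ]), unname(emb$weights))
  }
  expect_error(expand_to_images(emb, feature_dim = 2),
               "rank-deficient")
})

test_that("noiseless features are an invertible linear map of image weights", {
  emb <- generate_embedding(30, 4, seed = 5)
  out <- expand_to_images(emb, exemplars_per_concept = 2,
                          exemplar_noise_sd = 0.1, feature_dim = 8,
                          feature_noise_sd = 0, seed = 6)
  rec <- lm.fit(out$features$features, out$images$weights)
  expect_lt(max(abs(rec$residuals)), 1e-8)
})

test_that("the noiseless forward model is proportional to weight x kernel", {
  cfg <- generator_config(n_participants = 1, n_sessions = 2, n_concepts = 5,
                          n_sensors = 1, n_dims = 1, noise_sd = 0,
                          shared_fraction_per_dim = 1,
                          epoch_window = c(-100, 600), seed = 10)
  emb <- generate_embedding(5, 1, sparsity = 0, seed = 11)
  img <- expand_to_images(emb, exemplars_per_concept = 2,
                          exemplar_noise_sd = 0, seed = 12)
  ds <- simulate_epochs(cfg, img$images, seed = 13)$P1
  g <- make_profile(cfg$profile_assignments[[1]], ds$times_ms,
                    cfg$stim_duration_ms)
  y <- img$images$weights[ds$trial_table$image_id, 1]
  # baseline z-scoring only recentres here (zero baseline variance), so
  # each trial's trace is weight x kernel x (unit sensor projection +-1)
  ratio <- ds$data[, 1, which.max(g)] / (y * max(g))
  expect_equal(unname(abs(ratio)), rep(1, 10), tolerance = 1e-10)
  # the whole post-stimulus trace of one trial is proportional to y * g(t)
  post <- which(ds$times_ms >= 0 & g > 1e-6)
  ratios <- ds$data[2, 1, post] / (y[2] * g[post])
  expect_lt(diff(range(ratios)), 1e-9)
})

test_that("fully shared mixing makes noiseless participants identical up to trial order", {
  cfg <- generator_config(n_participants = 2, n_sessions = 2, n_concepts = 20,
                          n_sensors = 8, n_dims = 3, noise_sd = 0,
                          shared_fraction_per_dim = 1,
                          epoch_window = c(-100, 600), seed = 20)
  emb <- generate_embedding(20, 3, seed = 21)
  img <- expand_to_images(emb, exemplars_per_concept = 2,
                          exemplar_noise_sd = 0, seed = 22)
  ds <- simulate_epochs(cfg, img$images, seed = 23)
  o1 <- order(ds$P1$trial_table$image_id)
  o2 <- order(ds$P2$trial_table$image_id)
  expect_equal(ds$P1$data[o1, , ], ds$P2$data[o2, , ], tolerance = 1e-12)
})

test_that("simulation is bit-identical given config and seed", {
  cfg <- generator_config(n_participants = 1, n_sessions = 2, n_concepts = 10,
                          n_sensors = 4, n_dims = 2,
                          epoch_window = c(-100, 400), seed = 30)
  emb <- generate_embedding(10, 2, seed = 31)
  img <- expand_to_images(emb, exemplars_per_concept = 2, seed = 32)
  a <- simulate_epochs(cfg, img$images, seed = 33)
  b <- simulate_epochs(cfg, img$images, seed = 33)
  expect_identical(a, b)
})

test_that("baseline window is exactly z-scored per trial and sensor", {
  s <- small_study()
  ds <- s$datasets$P1
  bidx <- which(ds$times_ms < 0)
  b <- ds$data[1:20, , bidx]
  m <- apply(b, c(1, 2), mean)
  v <- apply(b, c(1, 2), var)
  expect_lt(max(abs(m)), 1e-9)
  expect_lt(max(abs(v - 1)), 1e-9)
})

test_that("missing embedding rows are reported by id", {
  cfg <- generator_config(n_participants = 1, n_sessions = 2, n_concepts = 10,
                          n_sensors = 4, n_dims = 2,
                          epoch_window = c(-100, 400), seed = 40)
  emb <- generate_embedding(10, 2, seed = 41)
  img <- expand_to_images(emb, exemplars_per_concept = 1, seed = 42)
  expect_error(simulate_epochs(cfg, img$images, seed = 43),
               "missing image ids.*_s02")
})

test_that("study-scale bookkeeping follows from the configuration alone", {
  tc <- trial_counts(full_scale_config())
  expect_identical(tc$trials_per_participant, 22248L)
  expect_identical(tc$cv_train_trials, 20394L)
  expect_identical(tc$cv_test_trials, 1854L)
})
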
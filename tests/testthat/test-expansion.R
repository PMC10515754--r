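mk_expansion_problem <- function(n = 200, d = 4, f = 12, noise = 0,
                                 seed = 90) {
  set.seed(seed)
  W <- abs(matrix(rnorm(n * d), n, d))
  rownames(W) <- sprintf("c%03d", seq_len(n))
  colnames(W) <- sprintf("dim%02d", seq_len(d))
  A <- matrix(rnorm(f * d), f, d)
  Fm <- W %*% t(A) + matrix(rnorm(n * f, sd = noise), n, f)
  rownames(Fm) <- rownames(W)
  list(W = embedding_table(W, "concept"), F = feature_table(Fm))
}

test_that("noiseless linear features give held-out correlation > 0.99", {
  p <- mk_expansion_problem()
  tr <- 1:150
  model <- fit_expansion(feature_table(p$F$features[tr, ]),
                         embedding_table(p$W$weights[tr, ], "concept"))
  pred <- predict(model, p$F$features[-tr, ])
  r <- diag(cor(pred$weights, p$W$weights[-tr, ]))
  expect_true(all(r > 0.99))
})

test_that("permuted targets fit at chance", {
  p <- mk_expansion_problem(noise = 0.1, seed = 91)
  set.seed(92)
  Wp <- p$W$weights[sample(200), ]
  rownames(Wp) <- rownames(p$W$weights)
  tr <- 1:150
  model <- fit_expansion(feature_table(p$F$features[tr, ]),
                         embedding_table(Wp[tr, ], "concept"))
  r <- diag(cor(predict(model, p$F$features[-tr, ])$weights, Wp[-tr, ]))
  expect_lt(mean(abs(r)), 0.1)
})

test_that("infinite shrinkage predicts a constant", {
  p <- mk_expansion_problem(seed = 93)
  model <- fit_expansion(p$F, p$W, alpha_grid = 1e12)
  pred <- predict(model, p$F)
  expect_lt(max(apply(pred$weights, 2, sd)),
            1e-6 * max(apply(p$W$weights, 2, sd)))
})

test_that("prediction is deterministic and validates its inputs", {
  p <- mk_expansion_problem(n = 50, seed = 94)
  model <- fit_expansion(p$F, p$W)
  a <- predict(model, p$F)
  b <- predict_image_weights(model, p$F)
  expect_identical(a, b)
  expect_equal(nrow(a$weights), 50L)
  expect_error(predict(model, p$F$features[, 1:5]), "mismatch")
  expect_error(fit_expansion(feature_table(p$F$features[1, , drop = FALSE]),
                             embedding_table(p$W$weights[1, , drop = FALSE],
                                             "concept")),
               "at least 2")
})

test_that("a constant dimension is flagged and zeroed", {
  p <- mk_expansion_problem(n = 40, seed = 95)
  W <- p$W$weights
  W[, 2] <- 1
  expect_warning(model <- fit_expansion(p$F, embedding_table(W, "concept")),
                 "constant dimension")
  expect_true(all(model$beta[, 2] == 0))
  pred <- predict(model, p$F)
  expect_equal(unname(pred$weights[, 2]), rep(1, 40))
})

test_that("image-level predictions beat copied concept weights under exemplar noise", {
  set.seed(96)
  emb <- generate_embedding(150, 5, seed = 97)
  out <- expand_to_images(emb, exemplars_per_concept = 4,
                          exemplar_noise_sd = 0.3, feature_dim = 16,
                          feature_noise_sd = 0.05, seed = 98)
  # reference image: exemplar 1 of each concept
  ref_ids <- sprintf("%s_s01", rownames(emb$weights))
  model <- fit_expansion(feature_table(out$features$features[ref_ids, ]),
                         emb)
  pred <- predict(model, out$features)
  concept_of <- sub("_s[0-9]+$", "", rownames(out$images$weights))
  copied <- emb$weights[concept_of, ]
  truth <- out$images$weights
  r_img <- diag(cor(pred$weights, truth))
  r_copy <- diag(cor(copied, truth))
  expect_true(all(r_img > r_copy))
})
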
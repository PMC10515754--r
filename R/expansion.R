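#' Fit the concept-to-image embedding expansion model
#'
#' Mirrors the augmentation step that turns a concept-level similarity
#' embedding into image-level weights: one ridge regression per dimension
#' predicts the concept's dimension weight from the feature vector of the
#' concept's reference image, with the penalty chosen per dimension by
#' internal 5-fold cross-validation over `alpha_grid`. The fitted model is
#' then applied to the features of all images ([predict()]).
#'
#' @param features a [feature_table()] with one row per concept (the
#'   concept's reference image), aligned with `concept_weights` rows.
#' @param concept_weights a concept-level [embedding_table()].
#' @param alpha_grid ridge penalty grid, default [default_alpha_grid()]
#'   (the same grid used by the decoding models).
#' @param k internal CV folds, default 5.
#' @return object of class `expansion_model`: `beta` (features x
#'   dimensions), `intercept`, `alpha` per dimension, and `fit_r`
#'   (in-sample prediction correlation per dimension). A constant
#'   dimension draws a warning and a zero coefficient vector.
#' @export
fit_expansion <- function(features, concept_weights,
                          alpha_grid = default_alpha_grid(), k = 5L) {
  stopifnot(inherits(features, "feature_table"),
            inherits(concept_weights, "embedding_table"))
  X <- features$features
  W <- concept_weights$weights
  if (nrow(X) != nrow(W))
    stop("one feature row per concept required (", nrow(X), " vs ",
         nrow(W), ")")
  if (nrow(X) < 2) stop("need at least 2 concepts to fit the expansion")
  const <- apply(W, 2, sd) == 0
  if (any(const))
    warning("constant dimension(s): ",
            paste(colnames(W)[const], collapse = ", "),
            "; coefficient vectors set to 0")
  fit <- suppressWarnings(
    fit_timepoint_decoder(X, W, alpha_grid, cv = "kfold",
                          k = min(k, nrow(X))))
  fit$beta[, const] <- 0
  fitted <- predict(fit, X)
  structure(list(beta = fit$beta, intercept = fit$intercept,
                 alpha = fit$alpha, scaler = fit$scaler,
                 fit_r = .safe_cor(fitted, W),
                 dimensions = colnames(W)),
            class = "expansion_model")
}

#' @export
print.expansion_model <- function(x, ...) {
  cat(sprintf("expansion_model: %d features -> %d dimensions\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  in-sample r: median %.3f (range %.3f..%.3f)\n",
              stats::median(x$fit_r), min(x$fit_r), max(x$fit_r)))
  invisible(x)
}

#' @export
coef.expansion_model <- function(object, ...) object$beta

#' Predict image-level dimension weights
#'
#' Applies a fitted [fit_expansion()] model to the feature vectors of any
#' image set. Predictions are unconstrained (negative predicted weights
#' are allowed and must be accepted downstream).
#'
#' @param object an `expansion_model`.
#' @param features a [feature_table()] (or plain matrix) whose columns
#'   match the model's feature space.
#' @param ... unused.
#' @return an image-level [embedding_table()] with one row per image.
#' @export
predict.expansion_model <- function(object, features, ...) {
  X <- if (inherits(features, "feature_table")) features$features
  else as.matrix(features)
  if (ncol(X) != nrow(object$beta))
    stop("feature dimensionality mismatch: ", ncol(X), " vs ",
         nrow(object$beta))
  Xs <- .apply_scaler(X, object$scaler)
  W <- sweep(Xs %*% object$beta, 2, object$intercept, "+")
  colnames(W) <- object$dimensions
  embedding_table(W, "image")
}

#' @rdname predict.expansion_model
#' @export
predict_image_weights <- function(object, features) {
  predict(object, features)
}
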
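#' Default regularization grid
#'
#' 100 linearly spaced ridge penalties between 1e-6 and 30,000, the grid
#' used for every timepoint-wise fit in the package.
#'
#' @return strictly increasing numeric vector of length 100.
#' @export
default_alpha_grid <- function() seq(1e-6, 30000, length.out = 100)

# Standardization parameters estimated on training data only.
.fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- sqrt(colSums(sweep(X, 2, ctr)^2) / (nrow(X) - 1))
  zero <- scl == 0
  scl[zero] <- 1
  list(center = ctr, scale = scl, zero_var = zero)
}

.apply_scaler <- function(X, sc) {
  Xs <- sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")
  if (any(sc$zero_var)) Xs[, sc$zero_var] <- 0
  Xs
}

#' Fit a multi-target ridge decoder at one timepoint
#'
#' Ridge regression mapping a trials x sensors pattern to trials x
#' dimensions targets, with the penalty selected per target by internal
#' cross-validation over `alpha_grid`. Predictors are z-scored with
#' parameters estimated on the training data only; targets are centred
#' (intercept per target). The solver is an eigendecomposition of the
#' predictor Gram matrix, which yields the whole regularization path and
#' exact leave-one-out errors at negligible extra cost.
#'
#' @param X numeric matrix, trials x predictors (sensor pattern at one
#'   timepoint, or embedding weights for encoding fits).
#' @param Y numeric matrix (or vector), trials x targets.
#' @param alpha_grid candidate penalties, positive and nonempty.
#' @param cv `"loo"` (exact leave-one-out, the default) or `"kfold"`.
#' @param k folds for `cv = "kfold"`.
#' @param per_target if `TRUE` (default) each target gets its own penalty;
#'   otherwise one penalty minimizing the summed CV error is shared.
#' @return object of class `timepoint_decoder` with elements `beta`
#'   (predictors x targets, on the standardized scale), `intercept`,
#'   `alpha` (chosen penalty per target), `scaler`, and `cv_error`.
#'   Zero-variance predictors get coefficient 0 with a warning.
#' @export
fit_timepoint_decoder <- function(X, Y, alpha_grid = default_alpha_grid(),
                                  cv = c("loo", "kfold"), k = 5L,
                                  per_target = TRUE) {
  cv <- match.arg(cv)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y), nrow(X) >= 3,
            length(alpha_grid) >= 1, all(alpha_grid > 0))
  sc <- .fit_scaler(X)
  if (any(sc$zero_var))
    warning(sum(sc$zero_var), " zero-variance predictor(s); coefficients set to 0")
  Xs <- .apply_scaler(X, sc)
  ybar <- colMeans(Y)
  Yc <- sweep(Y, 2, ybar)

  eg <- eigen(crossprod(Xs), symmetric = TRUE)
  d2 <- pmax(eg$values, 0)
  V <- eg$vectors
  Gm <- Xs %*% V                 # n x p, column j has squared norm d2[j]
  GtY <- crossprod(Gm, Yc)       # p x q

  n <- nrow(Xs)
  q <- ncol(Yc)
  n_a <- length(alpha_grid)
  cv_err <- matrix(NA_real_, n_a, q)

  if (cv == "loo") {
    G2 <- Gm^2
    for (a in seq_len(n_a)) {
      w <- 1 / (d2 + alpha_grid[a])
      fit <- Gm %*% (w * GtY)                  # n x q ridge fits
      h <- pmin(G2 %*% w, 1 - 1e-12)           # leverage h_ii = sum_j G_ij^2 w_j
      E <- (Yc - fit) / c(1 - h)
      cv_err[a, ] <- colMeans(E^2)
    }
  } else {
    fold <- rep_len(seq_len(k), n) # deterministic interleaved folds
    sse <- matrix(0, n_a, q)
    for (f in seq_len(k)) {
      tr <- fold != f
      sct <- .fit_scaler(X[tr, , drop = FALSE])
      Xt <- .apply_scaler(X[tr, , drop = FALSE], sct)
      Xv <- .apply_scaler(X[!tr, , drop = FALSE], sct)
      yb <- colMeans(Y[tr, , drop = FALSE])
      Yt <- sweep(Y[tr, , drop = FALSE], 2, yb)
      Yv <- sweep(Y[!tr, , drop = FALSE], 2, yb)
      e <- eigen(crossprod(Xt), symmetric = TRUE)
      Gt <- Xt %*% e$vectors
      GtYf <- crossprod(Gt, Yt)
      XvV <- Xv %*% e$vectors
      dd <- pmax(e$values, 0)
      for (a in seq_len(n_a)) {
        pred <- XvV %*% ((1 / (dd + alpha_grid[a])) * GtYf)
        sse[a, ] <- sse[a, ] + colSums((Yv - pred)^2)
      }
    }
    cv_err <- sse / n
  }

  if (per_target) {
    best <- apply(cv_err, 2, which.min)
  } else {
    best <- rep(which.min(rowSums(cv_err)), q)
  }
  beta <- matrix(0, ncol(Xs), q)
  for (a in unique(best)) {
    cols <- best == a
    w <- 1 / (d2 + alpha_grid[a])
    beta[, cols] <- V %*% (w * GtY[, cols, drop = FALSE])
  }
  dimnames(beta) <- list(colnames(X), colnames(Y))

  structure(list(beta = beta, intercept = ybar,
                 alpha = alpha_grid[best], scaler = sc,
                 cv = cv, cv_error = cv_err[cbind(best, seq_len(q))]),
            class = "timepoint_decoder")
}

#' @export
coef.timepoint_decoder <- function(object, ...) object$beta

#' Predict from a fitted timepoint decoder
#'
#' @param object a [fit_timepoint_decoder()] fit.
#' @param newdata trials x predictors matrix on the original scale.
#' @param ... unused.
#' @return trials x targets matrix of predictions.
#' @export
predict.timepoint_decoder <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$beta))
    stop("newdata has ", ncol(newdata), " predictors; model expects ",
         nrow(object$beta))
  Xs <- .apply_scaler(newdata, object$scaler)
  sweep(Xs %*% object$beta, 2, object$intercept, "+")
}

#' @export
print.timepoint_decoder <- function(x, ...) {
  cat(sprintf("timepoint_decoder: %d predictors -> %d target(s)\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  alpha (per target, %s-CV): %s\n", x$cv,
              paste(signif(unique(x$alpha), 3), collapse = ", ")))
  invisible(x)
}

# Pearson correlation per column pair, 0 (flagged) where either side is
# constant: a constant prediction carries no information.
.safe_cor <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  r <- numeric(ncol(A))
  for (j in seq_len(ncol(A))) {
    if (sd(A[, j]) == 0 || sd(B[, j]) == 0) r[j] <- 0
    else r[j] <- cor(A[, j], B[, j])
  }
  r
}
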
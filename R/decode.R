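#' Timepoint-wise decoding of embedding dimensions from sensor patterns
#'
#' The package's central estimator. At every timepoint and for every
#' cross-validation fold, a multi-target ridge decoder
#' ([fit_timepoint_decoder()]) maps the trials x sensors pattern to the
#' trials x dimensions embedding weights; held-out predictions are scored
#' by Pearson-correlating predicted against true weights per dimension
#' across the fold's test trials. The fold-averaged correlation timecourse
#' per dimension is the result.
#'
#' @param datasets an [epoched_dataset()] or a named list of them (one per
#'   participant; required for across-participant fold plans). Names must
#'   match the fold plan's participant tags.
#' @param embedding an [embedding_table()] whose rows cover every
#'   `image_id` appearing in the trial tables.
#' @param folds a [make_session_folds()] or [make_across_folds()] plan.
#' @param alpha_grid ridge penalty grid, default [default_alpha_grid()].
#' @param cv internal CV used to tune the penalty (see
#'   [fit_timepoint_decoder()]).
#' @param keep_predictions keep per-fold held-out predictions (needed by
#'   [permutation_null()]); default `TRUE`.
#' @param verbose print a progress line per fold.
#' @return object of class `decoding_timecourse`: `r` (dimensions x
#'   timepoints x folds), `r_mean` (fold-averaged, dimensions x
#'   timepoints), `times_ms`, `scheme`, `folds` (tags per fold), `alpha`
#'   (chosen penalties, targets x timepoints x folds), and, if kept,
#'   `predictions`/`truth` per fold.
#' @export
decode_timecourse <- function(datasets, embedding, folds,
                              alpha_grid = default_alpha_grid(),
                              cv = c("loo", "kfold"),
                              keep_predictions = TRUE, verbose = FALSE) {
  cv <- match.arg(cv)
  stopifnot(inherits(folds, "fold_plan"), inherits(embedding, "embedding_table"))
  if (inherits(datasets, "epoched_dataset")) {
    pid <- unique(datasets$trial_table$participant_id)
    datasets <- setNames(list(datasets), pid)
  }
  stopifnot(is.list(datasets), !is.null(names(datasets)))
  lapply(datasets, function(d) stopifnot(inherits(d, "epoched_dataset")))

  times <- datasets[[1]]$times_ms
  W <- embedding$weights
  dims <- colnames(W)
  n_dim <- ncol(W)
  n_t <- length(times)
  n_f <- length(folds$folds)

  .trial_weights <- function(ds, idx) {
    ids <- ds$trial_table$image_id[idx]
    missing <- setdiff(unique(ids), rownames(W))
    if (length(missing))
      stop("embedding is missing image ids: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5)
             sprintf(" (and %d more)", length(missing) - 5))
    W[ids, , drop = FALSE]
  }

  r <- array(NA_real_, c(n_dim, n_t, n_f), dimnames = list(dims, NULL, NULL))
  alpha <- array(NA_real_, c(n_dim, n_t, n_f))
  predictions <- if (keep_predictions) vector("list", n_f)
  truth <- if (keep_predictions) vector("list", n_f)

  for (fi in seq_len(n_f)) {
    f <- folds$folds[[fi]]
    ds_tr <- datasets[[f$train_participant]]
    ds_te <- datasets[[f$test_participant]]
    if (is.null(ds_tr) || is.null(ds_te))
      stop("fold plan references a participant not present in `datasets`")
    Ytr <- .trial_weights(ds_tr, f$train)
    Yte <- .trial_weights(ds_te, f$test)
    pred_f <- if (keep_predictions)
      array(NA_real_, c(length(f$test), n_dim, n_t))
    for (t in seq_len(n_t)) {
      fit <- suppressWarnings(fit_timepoint_decoder(
        ds_tr$data[f$train, , t], Ytr, alpha_grid, cv = cv))
      pred <- predict(fit, ds_te$data[f$test, , t])
      r[, t, fi] <- .safe_cor(pred, Yte)
      alpha[, t, fi] <- fit$alpha
      if (keep_predictions) pred_f[, , t] <- pred
    }
    if (keep_predictions) {
      predictions[[fi]] <- pred_f
      truth[[fi]] <- Yte
    }
    if (verbose)
      message(sprintf("fold %d/%d (%s -> %s) done", fi, n_f,
                      f$train_participant, f$test_participant))
  }

  structure(list(
    r = r,
    r_mean = apply(r, c(1, 2), mean),
    times_ms = times, scheme = folds$scheme,
    folds = lapply(folds$folds, function(f)
      f[c("train_participant", "test_participant", "test_session")]),
    alpha = alpha,
    predictions = predictions, truth = truth
  ), class = "decoding_timecourse")
}

#' Dimension-averaged decoding timecourse
#'
#' @param tc a `decoding_timecourse`.
#' @return numeric vector over timepoints: the mean of the per-dimension
#'   fold-averaged correlations.
#' @export
grand_average <- function(tc) {
  stopifnot(inherits(tc, "decoding_timecourse"))
  colMeans(tc$r_mean)
}

#' @export
print.decoding_timecourse <- function(x, ...) {
  cat(sprintf("decoding_timecourse (%s): %d dimensions x %d timepoints, %d folds\n",
              x$scheme, nrow(x$r_mean), ncol(x$r_mean), dim(x$r)[3]))
  ga <- grand_average(x)
  cat(sprintf("  peak dimension-averaged r = %.3f at %g ms\n",
              max(ga), x$times_ms[which.max(ga)]))
  invisible(x)
}

#' @export
summary.decoding_timecourse <- function(object, ...) {
  peak_i <- apply(object$r_mean, 1, which.max)
  out <- data.frame(
    dimension = rownames(object$r_mean),
    peak_r = object$r_mean[cbind(seq_len(nrow(object$r_mean)), peak_i)],
    peak_ms = object$times_ms[peak_i],
    mean_r = rowMeans(object$r_mean),
    row.names = NULL)
  class(out) <- c("summary.decoding_timecourse", "data.frame")
  out
}

#' Plot decoding timecourses
#'
#' One line per dimension (fold-averaged correlation over time) plus the
#' dimension average in black.
#'
#' @param x a `decoding_timecourse`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.decoding_timecourse <- function(x, ...) {
  graphics::matplot(x$times_ms, t(x$r_mean), type = "l", lty = 1,
                    col = grDevices::hcl.colors(nrow(x$r_mean), "Dark 3"),
                    xlab = "time (ms)", ylab = "correlation (r)",
                    main = sprintf("decoding (%s)", x$scheme), ...)
  graphics::lines(x$times_ms, grand_average(x), lwd = 2)
  graphics::abline(v = 0, h = 0, lty = 3)
  invisible(x)
}
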
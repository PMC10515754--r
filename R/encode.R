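#' Timepoint-wise encoding of sensor responses from the embedding
#'
#' The sensor-relevance companion of [decode_timecourse()]: at every
#' timepoint and fold, a ridge model predicts each sensor's univariate
#' response from the full multidimensional embedding, and the held-out
#' predictions are Pearson-correlated with the observed responses per
#' sensor. Sensors whose encoding correlation is high at a timepoint are
#' the ones carrying dimension information there.
#'
#' @param dataset an [epoched_dataset()] (one participant).
#' @param embedding an [embedding_table()] covering the dataset's image
#'   ids.
#' @param folds a session-wise [make_session_folds()] plan for this
#'   participant.
#' @param alpha_grid ridge penalty grid, shared with the decoding analysis.
#' @param cv internal CV for the penalty (see [fit_timepoint_decoder()]).
#' @return object of class `encoding_timecourse`: `r` (sensors x
#'   timepoints x folds), `r_mean` (fold-averaged), `times_ms`,
#'   `participant`. A sensor that is constant within a fold's test split
#'   gets r = 0 there and is listed in the `flagged` element.
#' @export
encode_sensor_timecourse <- function(dataset, embedding, folds,
                                     alpha_grid = default_alpha_grid(),
                                     cv = c("loo", "kfold")) {
  cv <- match.arg(cv)
  stopifnot(inherits(dataset, "epoched_dataset"),
            inherits(embedding, "embedding_table"),
            inherits(folds, "fold_plan"))
  if (folds$scheme != "within_session")
    stop("encoding uses the session-wise (within-participant) fold plan")
  W <- embedding$weights
  ids <- dataset$trial_table$image_id
  missing <- setdiff(unique(ids), rownames(W))
  if (length(missing))
    stop("embedding is missing image ids: ",
         paste(head(missing, 5), collapse = ", "))
  X <- W[ids, , drop = FALSE]          # trials x dims predictor
  n_sens <- dim(dataset$data)[2]
  n_t <- length(dataset$times_ms)
  n_f <- length(folds$folds)
  r <- array(NA_real_, c(n_sens, n_t, n_f))
  flagged <- matrix(FALSE, n_sens, n_f)

  for (fi in seq_len(n_f)) {
    f <- folds$folds[[fi]]
    Xtr <- X[f$train, , drop = FALSE]
    Xte <- X[f$test, , drop = FALSE]
    for (t in seq_len(n_t)) {
      Ytr <- dataset$data[f$train, , t]
      Yte <- dataset$data[f$test, , t]
      fit <- suppressWarnings(fit_timepoint_decoder(Xtr, Ytr, alpha_grid,
                                                    cv = cv))
      pred <- predict(fit, Xte)
      const <- apply(Yte, 2, sd) == 0
      flagged[, fi] <- flagged[, fi] | const
      r[, t, fi] <- .safe_cor(pred, Yte)
    }
  }
  structure(list(r = r, r_mean = apply(r, c(1, 2), mean),
                 times_ms = dataset$times_ms,
                 participant = unique(dataset$trial_table$participant_id),
                 flagged = which(rowSums(flagged) > 0)),
            class = "encoding_timecourse")
}

#' @export
print.encoding_timecourse <- function(x, ...) {
  cat(sprintf("encoding_timecourse: %d sensors x %d timepoints (%s)\n",
              nrow(x$r_mean), ncol(x$r_mean), x$participant))
  best <- which.max(apply(x$r_mean, 2, max))
  cat(sprintf("  best sensor r = %.3f at %g ms\n",
              max(x$r_mean), x$times_ms[best]))
  invisible(x)
}

#' @export
plot.encoding_timecourse <- function(x, ...) {
  graphics::matplot(x$times_ms, t(x$r_mean), type = "l", lty = 1,
                    col = grDevices::grey(0.6), xlab = "time (ms)",
                    ylab = "correlation (r)", main = "sensor encoding", ...)
  graphics::lines(x$times_ms, colMeans(x$r_mean), lwd = 2)
  graphics::abline(v = 0, h = 0, lty = 3)
  invisible(x)
}
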
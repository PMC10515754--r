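#' Epoched dataset constructor
#'
#' Container for trial-locked multichannel data: a trials x sensors x
#' timepoints array, a per-trial metadata table, and the epoch time axis.
#'
#' @param data numeric array, trials x sensors x timepoints, baseline
#'   z-scored.
#' @param trial_table data.frame with columns `participant_id`,
#'   `session_id`, `concept_id`, `image_id`; one row per trial, in tensor
#'   order.
#' @param times_ms strictly increasing timepoint positions in ms relative
#'   to stimulus onset.
#' @return object of class `epoched_dataset`.
#' @export
epoched_dataset <- function(data, trial_table, times_ms) {
  data <- unname(data)
  if (length(dim(data)) != 3) stop("data must be a 3-d array")
  if (nrow(trial_table) != dim(data)[1])
    stop("trial count mismatch: trial_table has ", nrow(trial_table),
         " rows but data has ", dim(data)[1], " trials")
  need <- c("participant_id", "session_id", "concept_id", "image_id")
  if (!all(need %in% names(trial_table)))
    stop("trial_table must have columns ", paste(need, collapse = ", "))
  if (length(times_ms) != dim(data)[3])
    stop("times_ms length does not match the timepoint axis")
  if (is.unsorted(times_ms, strictly = TRUE))
    stop("times_ms must be strictly increasing")
  n_per <- table(trial_table$session_id)
  if (length(unique(n_per)) > 1)
    stop("every session must contain the same number of trials")
  structure(list(data = data, trial_table = as.data.frame(trial_table),
                 times_ms = as.numeric(times_ms)),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(paste0("epoched_dataset: %d trials x %d sensors x %d",
                     " timepoints (%g..%g ms)\n"),
              d[1], d[2], d[3], min(x$times_ms), max(x$times_ms)))
  cat(sprintf("  participant %s, %d session(s)\n",
              paste(unique(x$trial_table$participant_id), collapse = ","),
              length(unique(x$trial_table$session_id))))
  invisible(x)
}

#' @export
dim.epoched_dataset <- function(x) dim(x$data)

#' Baseline-correct an epoch array by z-scoring
#'
#' For every trial and sensor, the mean and SD of the pre-stimulus baseline
#' window (timepoints with `times_ms < 0`) are used to z-score the whole
#' epoch. Zero-variance baselines (possible only in noiseless simulations)
#' are mean-centred without scaling.
#'
#' @param data trials x sensors x timepoints array.
#' @param times_ms time axis; the baseline is `times_ms < 0`.
#' @return array of the same shape; over the baseline window each
#'   trial/sensor trace has mean 0 and SD 1.
#' @export
baseline_zscore <- function(data, times_ms) {
  bidx <- which(times_ms < 0)
  if (length(bidx) < 2)
    stop("baseline window needs at least 2 pre-stimulus timepoints")
  d <- dim(data)
  nb <- length(bidx)
  b <- matrix(data[, , bidx], nrow = d[1] * d[2])
  m <- rowMeans(b)
  s <- sqrt(rowSums((b - m)^2) / (nb - 1))
  s[s == 0] <- 1
  array((c(data) - m) / s, dim = d) # m, s recycle over the timepoint axis
}

#' Simulate epoched multichannel recordings with planted temporal profiles
#'
#' Forward model: the trial with image weights `y` evokes, at time `t` and
#' sensor `s`, the signal `sum_d y_d * g_d(t) * m_d[s]` plus i.i.d.
#' Gaussian noise, where `g_d` is dimension `d`'s temporal kernel
#' ([make_profile()]) and `m_d` its sensor projection. Each projection
#' blends a mixing vector shared by all participants with a
#' participant-specific one, `m_d = f_d * M_shared_d + (1 - f_d) *
#' M_subj_d` (`f_d` = `shared_fraction_per_dim`, both `M` unit-norm), so
#' high `f_d` makes a dimension's sensor pattern generalize across
#' participants. Each participant sees one image per concept per session,
#' in randomized order; epochs are baseline z-scored per trial and sensor.
#'
#' @param config a [generator_config()].
#' @param image_embedding image-level [embedding_table()] covering every
#'   `<concept>_s<session>` id implied by the config (see
#'   [expand_to_images()]).
#' @param seed integer seed; defaults to `config$seed`. Identical config
#'   and seed give bit-identical output.
#' @return named list of [epoched_dataset()] objects, one per participant
#'   (`"P1"`, `"P2"`, ...).
#' @export
simulate_epochs <- function(config, image_embedding, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"),
            inherits(image_embedding, "embedding_table"))
  times <- config_times(config)
  n_tr <- config$n_sessions * config$n_concepts
  concepts <- sprintf("concept%04d", seq_len(config$n_concepts))

  need_ids <- as.vector(outer(concepts, seq_len(config$n_sessions),
                              function(cc, s) sprintf("%s_s%02d", cc, s)))
  missing <- setdiff(need_ids, rownames(image_embedding$weights))
  if (length(missing))
    stop("embedding is missing image ids: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  if (ncol(image_embedding$weights) != config$n_dims)
    stop("embedding dimensionality does not match config n_dims")

  G <- vapply(config$profile_assignments, make_profile, numeric(length(times)),
              times_ms = times, stim_duration_ms = config$stim_duration_ms)

  set.seed(seed)
  unit_cols <- function(n, k) {
    m <- matrix(rnorm(n * k), n, k)
    sweep(m, 2, sqrt(colSums(m^2)), "/")
  }
  M_shared <- unit_cols(config$n_sensors, config$n_dims)

  out <- vector("list", config$n_participants)
  names(out) <- sprintf("P%d", seq_len(config$n_participants))
  for (p in seq_len(config$n_participants)) {
    M_subj <- unit_cols(config$n_sensors, config$n_dims)
    f <- config$shared_fraction_per_dim
    Mp <- sweep(M_shared, 2, f, "*") + sweep(M_subj, 2, 1 - f, "*")

    ord <- unlist(lapply(seq_len(config$n_sessions),
                         function(s) sample.int(config$n_concepts)))
    sess <- rep(seq_len(config$n_sessions), each = config$n_concepts)
    cid <- concepts[ord]
    iid <- sprintf("%s_s%02d", cid, sess)
    Y <- image_embedding$weights[iid, , drop = FALSE]

    X <- array(rnorm(n_tr * config$n_sensors * length(times),
                     sd = config$noise_sd),
               dim = c(n_tr, config$n_sensors, length(times)))
    for (t in seq_along(times)) {
      g <- G[t, ]
      if (any(g != 0))
        X[, , t] <- X[, , t] + tcrossprod(sweep(Y, 2, g, "*"), Mp)
    }
    X <- baseline_zscore(X, times)

    out[[p]] <- epoched_dataset(
      X,
      data.frame(participant_id = names(out)[p], session_id = sess,
                 concept_id = cid, image_id = iid,
                 stringsAsFactors = FALSE),
      times
    )
  }
  out
}
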
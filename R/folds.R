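#' Session-wise cross-validation folds (within participant)
#'
#' One fold per recording session: the decoder trains on all other sessions
#' of the same participant and tests on the held-out session, so every
#' session serves as test data exactly once. With the study-scale design of
#' 12 sessions x 1,854 trials this gives 20,394 training and 1,854 test
#' trials per fold.
#'
#' @param trial_table data.frame with `participant_id` and `session_id`
#'   columns (one participant).
#' @param participant id recorded in the folds; defaults to the table's
#'   single participant id.
#' @return object of class `fold_plan`, scheme `"within_session"`: a list
#'   of folds, each with `train`/`test` row indices and
#'   `train_participant`/`test_participant` tags.
#' @export
make_session_folds <- function(trial_table,
                               participant = unique(trial_table$participant_id)) {
  stopifnot(is.data.frame(trial_table), "session_id" %in% names(trial_table))
  if (length(participant) != 1)
    stop("trial_table must contain exactly one participant")
  sessions <- sort(unique(trial_table$session_id))
  if (length(sessions) < 2)
    stop("session-wise cross-validation needs at least 2 sessions")
  idx <- seq_len(nrow(trial_table))
  folds <- lapply(sessions, function(s) {
    test <- idx[trial_table$session_id == s]
    if (length(test) == 0) stop("session ", s, " has zero trials")
    list(train = idx[trial_table$session_id != s], test = test,
         train_participant = participant, test_participant = participant,
         test_session = s)
  })
  structure(list(scheme = "within_session", folds = folds),
            class = "fold_plan")
}

#' Participant-wise cross-validation folds (across participants)
#'
#' Generalization scheme: for every ordered pair of participants (A, B) and
#' every session index, the decoder trains on A's data excluding that
#' session and tests on B's held-out session -- session-wise splits so that
#' train and test sizes match the within-participant analysis exactly. All
#' ordered pairwise comparisons are enumerated.
#'
#' @param trial_tables named list of per-participant trial tables sharing
#'   the same session structure.
#' @return `fold_plan` with scheme `"across_participant"`; fold indices
#'   refer to rows of the train/test participant's own table.
#' @export
make_across_folds <- function(trial_tables) {
  stopifnot(is.list(trial_tables), length(trial_tables) >= 2)
  if (is.null(names(trial_tables)))
    names(trial_tables) <- sprintf("P%d", seq_along(trial_tables))
  sess <- lapply(trial_tables, function(tt) sort(unique(tt$session_id)))
  sizes <- lapply(trial_tables, function(tt) as.vector(table(tt$session_id)))
  if (length(unique(vapply(sess, length, integer(1)))) > 1 ||
      !all(vapply(sizes, identical, logical(1), sizes[[1]])))
    stop("participants must share the session/trial structure")
  sessions <- sess[[1]]
  if (length(sessions) < 2)
    stop("session-wise cross-validation needs at least 2 sessions")
  ids <- names(trial_tables)
  folds <- list()
  for (a in ids) for (b in ids) {
    if (a == b) next
    for (s in sessions) {
      tta <- trial_tables[[a]]; ttb <- trial_tables[[b]]
      folds[[length(folds) + 1L]] <- list(
        train = which(tta$session_id != s),
        test = which(ttb$session_id == s),
        train_participant = a, test_participant = b, test_session = s)
    }
  }
  structure(list(scheme = "across_participant", folds = folds),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  ntr <- vapply(x$folds, function(f) length(f$train), integer(1))
  nte <- vapply(x$folds, function(f) length(f$test), integer(1))
  cat(sprintf("fold_plan (%s): %d folds, train %s, test %s trials\n",
              x$scheme, length(x$folds),
              paste(unique(range(ntr)), collapse = "-"),
              paste(unique(range(nte)), collapse = "-")))
  invisible(x)
}

#' @export
length.fold_plan <- function(x) length(x$folds)
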
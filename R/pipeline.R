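#' Run the full analysis pipeline on synthetic data
#'
#' End-to-end orchestration of every stage: simulate epoched data from a
#' generator configuration (embedding, image expansion, forward model),
#' decode within participants (session-wise folds), decode across
#' participants, encode sensor responses for the first participant, build
#' the permutation null and max-statistic significance mask, compare the
#' within and across models at selected timepoints, and cluster the
#' dimension timecourse shapes. All stage outputs are written to
#' `out_dir` as TSV/JSON with the run-manifest hash in their comment
#' headers; any stage error aborts with the stage name.
#'
#' @param config a [generator_config()]; `config$n_sessions` must be >= 2.
#' @param out_dir output directory (created; must be empty or absent).
#' @param seed root seed; every stage seed derives from it.
#' @param n_permutations permutations for the null ensemble (default 200
#'   at desk scale; the study-scale convention is 1,000).
#' @param compare_timepoints_ms timepoints for [compare_models()].
#' @param verbose print stage progress.
#' @return (invisibly) a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = config$seed,
                         n_permutations = 200L,
                         compare_timepoints_ms = c(100, 200, 300, 400, 500, 600),
                         verbose = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  stages <- c("embedding", "expansion", "simulate", "permute")
  seeds <- derive_seeds(seed, stages)
  say <- function(...) if (verbose) message(sprintf(...))
  step <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timing <- c()
  tick <- function(name) {
    timing[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
  }

  say("simulating %d participant(s)...", config$n_participants)
  emb <- step("embedding", generate_embedding(config$n_concepts,
                                              config$n_dims,
                                              seed = seeds[["embedding"]]))
  exp_out <- step("expansion", expand_to_images(
    emb, exemplars_per_concept = config$n_sessions,
    seed = seeds[["expansion"]]))
  datasets <- step("simulate", simulate_epochs(config, exp_out$images,
                                               seed = seeds[["simulate"]]))
  tick("simulate")

  say("planning folds...")
  within_plans <- step("folds", lapply(datasets, function(d)
    make_session_folds(d$trial_table)))
  across_plan <- if (config$n_participants >= 2)
    step("folds", make_across_folds(lapply(datasets, `[[`, "trial_table")))
  manifest <- run_manifest(config, seed, seeds,
                           fold_digest = .digest(within_plans))

  say("decoding (within)...")
  within_tc <- step("decode_within", {
    per <- lapply(names(datasets), function(p)
      decode_timecourse(datasets[p], exp_out$images, within_plans[[p]]))
    merge_timecourses(per)
  })
  tick("decode_within")

  across_tc <- NULL
  if (!is.null(across_plan)) {
    say("decoding (across)...")
    across_tc <- step("decode_across",
                      decode_timecourse(datasets, exp_out$images, across_plan))
    tick("decode_across")
  }

  say("encoding sensors (participant 1)...")
  enc <- step("encode", encode_sensor_timecourse(
    datasets[[1]], exp_out$images, within_plans[[1]]))
  tick("encode")

  say("permutation null (%d permutations)...", n_permutations)
  null <- step("permute", permutation_null(within_tc, n_permutations,
                                           seed = seeds[["permute"]]))
  thr <- step("threshold", corrected_threshold(null))
  mask <- step("mask", significance_mask(within_tc, thr))
  tick("stats")

  cmp <- NULL
  if (!is.null(across_tc)) {
    cmp <- step("compare", compare_models(within_tc, across_tc,
                                          compare_timepoints_ms))
  }

  say("shape analysis...")
  shapes <- step("shape", {
    per_p <- per_participant_timecourses(within_tc)
    shape_analysis(per_p, within_tc$times_ms,
                   significance_counts = mask$n_sig * dim(per_p)[3])
  })
  tick("shape")

  say("writing outputs...")
  h <- paste("manifest:", manifest$hash)
  write_timecourse(within_tc, file.path(out_dir, "decoding_within.tsv"), h)
  if (!is.null(across_tc))
    write_timecourse(across_tc, file.path(out_dir, "decoding_across.tsv"), h)
  write_timecourse(enc, file.path(out_dir, "encoding.tsv"), h)
  write_embedding(exp_out$images, file.path(out_dir, "image_embedding.tsv"), h)
  if (!is.null(cmp)) {
    con <- file(file.path(out_dir, "model_comparison.tsv"), "w")
    writeLines(paste0("# ", h), con)
    write.table(cmp, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  con <- file(file.path(out_dir, "clusters.tsv"), "w")
  writeLines(paste0("# ", h), con)
  write.table(data.frame(dimension = names(shapes$labels),
                         cluster = shapes$labels),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  manifest$timing_s <- as.list(timing)
  jsonlite::write_json(manifest[setdiff(names(manifest), "")],
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("done.")
  invisible(list(config = config, datasets = datasets,
                 embedding = exp_out$images, within = within_tc,
                 across = across_tc, encoding = enc, null = null,
                 threshold = as.numeric(thr), mask = mask,
                 comparison = cmp, shapes = shapes, manifest = manifest))
}

#' Merge per-participant decoding timecourses
#'
#' Concatenates decoding timecourses fit on the same dimensions and time
#' grid (typically one per participant) into a single object whose folds
#' are the union of the inputs' folds, re-averaging `r_mean` over all of
#' them.
#'
#' @param tcs list of `decoding_timecourse` objects.
#' @return a `decoding_timecourse`.
#' @export
merge_timecourses <- function(tcs) {
  stopifnot(length(tcs) >= 1)
  if (length(tcs) == 1) return(tcs[[1]])
  r <- do.call(abind3, lapply(tcs, `[[`, "r"))
  alpha <- do.call(abind3, lapply(tcs, `[[`, "alpha"))
  structure(list(
    r = r, r_mean = apply(r, c(1, 2), mean),
    times_ms = tcs[[1]]$times_ms, scheme = tcs[[1]]$scheme,
    folds = do.call(c, lapply(tcs, `[[`, "folds")),
    alpha = alpha,
    predictions = do.call(c, lapply(tcs, `[[`, "predictions")),
    truth = do.call(c, lapply(tcs, `[[`, "truth"))
  ), class = "decoding_timecourse")
}

# bind 3-d arrays along the third margin
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1]])
  out <- array(unlist(xs), c(d[1], d[2], sum(vapply(xs, function(x)
    dim(x)[3], numeric(1)))))
  dimnames(out)[1:2] <- dimnames(xs[[1]])[1:2]
  out
}

#' Per-participant fold-averaged decoding timecourses
#'
#' @param tc a `decoding_timecourse` (possibly merged across participants).
#' @return array dimensions x timepoints x participants of fold-averaged
#'   correlations, split by the fold's test participant.
#' @export
per_participant_timecourses <- function(tc) {
  pid <- vapply(tc$folds, `[[`, character(1), "test_participant")
  ids <- unique(pid)
  out <- array(NA_real_, c(dim(tc$r_mean), length(ids)),
               dimnames = c(dimnames(tc$r_mean), list(ids)))
  for (i in seq_along(ids))
    out[, , i] <- apply(tc$r[, , pid == ids[i], drop = FALSE], c(1, 2), mean)
  out
}
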
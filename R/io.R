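#' Write / read an epoched dataset
#'
#' The package's on-disk container for epoched data is a directory of
#' plain-text files with a documented schema: `data.tsv` (one row per
#' (trial, sensor), columns `trial`, `sensor`, then one column per
#' timepoint), `times_ms.tsv`, `trials.tsv` (the trial table) and
#' `meta.yaml` (shape and provenance). All invariant checks run on load.
#'
#' @param ds an [epoched_dataset()].
#' @param path directory to write into (created if needed).
#' @return `read_epoched()` returns a validated [epoched_dataset()].
#' @export
write_epoched <- function(ds, path) {
  stopifnot(inherits(ds, "epoched_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  d <- dim(ds$data)
  flat <- matrix(aperm(ds$data, c(2, 1, 3)), d[1] * d[2], d[3])
  dt <- data.table::data.table(
    trial = rep(seq_len(d[1]), each = d[2]),
    sensor = rep(seq_len(d[2]), times = d[1]))
  dt <- cbind(dt, data.table::as.data.table(flat))
  data.table::setnames(dt, c("trial", "sensor",
                             sprintf("t%d", seq_len(d[3]))))
  data.table::fwrite(dt, file.path(path, "data.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(times_ms = ds$times_ms),
                     file.path(path, "times_ms.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(ds$trial_table),
                     file.path(path, "trials.tsv"), sep = "\t")
  yaml::write_yaml(list(n_trials = d[1], n_sensors = d[2], n_times = d[3],
                        written_by = paste("dimtrace",
                                           as.character(packageVersion("dimtrace")))),
                   file.path(path, "meta.yaml"))
  invisible(path)
}

#' @rdname write_epoched
#' @export
read_epoched <- function(path) {
  need <- c("data.tsv", "times_ms.tsv", "trials.tsv", "meta.yaml")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop("epoched container is missing node ", f)
  meta <- yaml::read_yaml(file.path(path, "meta.yaml"))
  times <- data.table::fread(file.path(path, "times_ms.tsv"))$times_ms
  trials <- as.data.frame(data.table::fread(file.path(path, "trials.tsv")))
  dt <- data.table::fread(file.path(path, "data.tsv"))
  d <- c(meta$n_trials, meta$n_sensors, meta$n_times)
  if (nrow(dt) != d[1] * d[2] || ncol(dt) != d[3] + 2)
    stop("data.tsv shape does not match meta.yaml")
  if (length(times) != d[3]) stop("times_ms length mismatch")
  if (nrow(trials) != d[1])
    stop("trial count mismatch: trials.tsv has ", nrow(trials),
         " rows for ", d[1], " trials")
  flat <- as.matrix(dt[, -(1:2)])
  data <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
  epoched_dataset(data, trials, times)
}

#' Write a decoding or encoding timecourse as long-format TSV
#'
#' Columns `dimension` (or `sensor`), `time_ms`, `fold`, `r`, plus the
#' fold-averaged rows tagged `fold = "mean"`. An optional comment header
#' (e.g. the run-manifest hash) is written as `#`-prefixed first lines.
#'
#' @param tc a `decoding_timecourse` or `encoding_timecourse`.
#' @param path output file.
#' @param comment optional comment string(s).
#' @export
write_timecourse <- function(tc, path, comment = NULL) {
  unit <- if (inherits(tc, "encoding_timecourse")) "sensor" else "dimension"
  r <- tc$r
  labs <- if (!is.null(rownames(tc$r_mean))) rownames(tc$r_mean)
  else sprintf("%s%02d", unit, seq_len(nrow(tc$r_mean)))
  n_f <- dim(r)[3]
  long <- do.call(rbind, lapply(seq_len(n_f), function(fi)
    data.frame(unit = rep(labs, times = length(tc$times_ms)),
               time_ms = rep(tc$times_ms, each = length(labs)),
               fold = as.character(fi), r = c(r[, , fi]))))
  long <- rbind(long,
                data.frame(unit = rep(labs, times = length(tc$times_ms)),
                           time_ms = rep(tc$times_ms, each = length(labs)),
                           fold = "mean", r = c(tc$r_mean)))
  names(long)[1] <- unit
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(long, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Stable digest of an R object (serialized to a temp file, md5-hashed).
.digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Build a run manifest
#'
#' Captures everything needed to reproduce a pipeline run: the
#' configuration snapshot, root and derived stage seeds, package version,
#' and a digest of the fold plan. The manifest hash is written into the
#' comment header of every output table of the run.
#'
#' @param config a [generator_config()].
#' @param seed root seed of the run.
#' @param stage_seeds named integer vector of derived per-stage seeds.
#' @param fold_digest digest string for the fold plan(s).
#' @return list of class `run_manifest` with a `hash` element.
#' @export
run_manifest <- function(config, seed, stage_seeds, fold_digest = NULL) {
  m <- list(package = "dimtrace",
            version = as.character(packageVersion("dimtrace")),
            config = unclass(config)[setdiff(names(config),
                                             "profile_assignments")],
            profiles = lapply(config$profile_assignments, unclass),
            root_seed = seed,
            stage_seeds = as.list(stage_seeds),
            fold_digest = fold_digest)
  m$hash <- .digest(m)
  class(m) <- "run_manifest"
  m
}

#' Derive per-stage seeds from one root seed
#'
#' All pipeline randomness flows from a single root seed; stage seeds are
#' drawn deterministically from it (each below 2^31).
#'
#' @param seed integer root seed.
#' @param stages character vector of stage names.
#' @return named integer vector.
#' @export
derive_seeds <- function(seed, stages) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max, length(stages)), stages)
}
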
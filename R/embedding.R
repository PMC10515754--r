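#' Embedding table constructor
#'
#' A stimuli x dimensions matrix of continuous weights, at either the
#' concept level (one row per object concept) or the image level (one row
#' per presented image). Rows are keyed by stimulus id (rownames).
#'
#' @param weights numeric matrix, stimuli x dimensions, finite, with
#'   rownames (stimulus ids) and colnames (dimension names).
#' @param level `"concept"` or `"image"`.
#' @return object of class `embedding_table`.
#' @export
embedding_table <- function(weights, level = c("concept", "image")) {
  level <- match.arg(level)
  weights <- as.matrix(weights)
  if (is.null(rownames(weights))) stop("weights must have stimulus ids as rownames")
  if (anyDuplicated(rownames(weights))) stop("duplicate stimulus ids")
  if (is.null(colnames(weights)))
    colnames(weights) <- sprintf("dim%02d", seq_len(ncol(weights)))
  if (!all(is.finite(weights))) stop("embedding weights must be finite")
  structure(list(weights = weights, level = level), class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("embedding_table (%s level): %d stimuli x %d dimensions\n",
              x$level, nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' @export
dim.embedding_table <- function(x) dim(x$weights)

#' Generate a sparse nonnegative concept-level embedding
#'
#' Draws concept weights as |Normal(0,1)| values with an independent
#' Bernoulli sparsity mask, emulating the sparse, nonnegative character of
#' behavior-derived similarity embeddings. Every dimension is guaranteed
#' nonzero variance.
#'
#' @param n_concepts number of object concepts.
#' @param n_dims number of embedding dimensions.
#' @param sparsity expected fraction of exactly-zero entries, in \[0, 1).
#' @param seed integer seed; output is deterministic given the seed.
#' @return a concept-level [embedding_table()].
#' @examples
#' emb <- generate_embedding(1854, 66, sparsity = 0.5, seed = 1)
#' dim(emb)  # 1854 x 66
#' @export
generate_embedding <- function(n_concepts, n_dims, sparsity = 0.5, seed = 1L) {
  if (sparsity >= 1) stop("degenerate embedding: sparsity must be < 1")
  if (sparsity < 0) stop("sparsity must be >= 0")
  stopifnot(n_concepts >= 1, n_dims >= 1)
  set.seed(seed)
  w <- abs(matrix(rnorm(n_concepts * n_dims), n_concepts, n_dims))
  if (sparsity > 0)
    w <- w * (matrix(runif(n_concepts * n_dims), n_concepts, n_dims) >= sparsity)
  # guard: a dimension must carry signal variance to be decodable at all
  for (d in which(apply(w, 2, var) == 0)) {
    i <- seq_len(min(2, n_concepts))
    w[i, d] <- abs(rnorm(length(i)))
  }
  rownames(w) <- sprintf("concept%04d", seq_len(n_concepts))
  colnames(w) <- sprintf("dim%02d", seq_len(n_dims))
  embedding_table(w, "concept")
}

#' Feature table constructor
#'
#' Continuous image feature vectors (images x F), the synthetic stand-in
#' for activations of a pretrained image encoder.
#'
#' @param features numeric matrix with image ids as rownames.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(features) {
  features <- as.matrix(features)
  if (is.null(rownames(features))) stop("features must have image ids as rownames")
  if (!all(is.finite(features))) stop("features must be finite")
  structure(list(features = features), class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d images x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Expand a concept embedding to image exemplars with feature vectors
#'
#' Creates `exemplars_per_concept` image exemplars per concept (one per
#' session in the simulated design). Image weights are the concept weights
#' plus Gaussian exemplar perturbation, clipped at zero; image features are
#' a fixed random linear map of the image weights plus feature noise.
#'
#' @param concept_embedding a concept-level [embedding_table()].
#' @param exemplars_per_concept number of image exemplars per concept
#'   (>= 1); exemplar `s` is the image assigned to session `s`.
#' @param exemplar_noise_sd SD of the exemplar perturbation (>= 0).
#' @param feature_dim length of the feature vectors; must be >= the number
#'   of embedding dimensions so the map has full column rank.
#' @param feature_noise_sd SD of additive feature noise.
#' @param seed integer seed.
#' @return list with `images` (image-level [embedding_table()], ids of the
#'   form `<concept>_s<session>`) and `features` (a [feature_table()] over
#'   the same ids).
#' @export
expand_to_images <- function(concept_embedding, exemplars_per_concept = 12L,
                             exemplar_noise_sd = 0.1, feature_dim = 128L,
                             feature_noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(concept_embedding, "embedding_table"),
            concept_embedding$level == "concept",
            exemplars_per_concept >= 1, exemplar_noise_sd >= 0)
  W <- concept_embedding$weights
  if (feature_dim < ncol(W))
    stop("rank-deficient feature map: feature_dim must be >= n_dims")
  set.seed(seed)
  n_img <- nrow(W) * exemplars_per_concept
  Wimg <- W[rep(seq_len(nrow(W)), times = exemplars_per_concept), , drop = FALSE]
  if (exemplar_noise_sd > 0)
    Wimg <- pmax(Wimg + matrix(rnorm(length(Wimg), sd = exemplar_noise_sd),
                               nrow(Wimg), ncol(Wimg)), 0)
  ids <- sprintf("%s_s%02d", rep(rownames(W), times = exemplars_per_concept),
                 rep(seq_len(exemplars_per_concept), each = nrow(W)))
  rownames(Wimg) <- ids
  A <- matrix(rnorm(feature_dim * ncol(W)), feature_dim, ncol(W)) /
    sqrt(ncol(W))
  Fmat <- Wimg %*% t(A)
  if (feature_noise_sd > 0)
    Fmat <- Fmat + matrix(rnorm(length(Fmat), sd = feature_noise_sd),
                          nrow(Fmat), ncol(Fmat))
  rownames(Fmat) <- ids
  colnames(Fmat) <- sprintf("f%03d", seq_len(feature_dim))
  list(images = embedding_table(Wimg, "image"), features = feature_table(Fmat))
}

#' Write / read an embedding table as TSV
#'
#' Plain TSV with a header row: first column `stimulus_id`, remaining
#' columns the dimension names. Comment lines starting with `#` (e.g. a
#' manifest hash) are skipped on read.
#'
#' @param x an [embedding_table()].
#' @param path file path.
#' @param level level tag to assign on read.
#' @param comment optional comment line(s) written before the header.
#' @return `read_embedding` returns an [embedding_table()].
#' @export
write_embedding <- function(x, path, comment = NULL) {
  stopifnot(inherits(x, "embedding_table"))
  df <- data.frame(stimulus_id = rownames(x$weights), x$weights,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path, level = c("concept", "image")) {
  level <- match.arg(level)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- tryCatch(
    read.delim(path, comment.char = "#", check.names = FALSE,
               stringsAsFactors = FALSE),
    error = function(e) stop("empty or malformed embedding file: ", path))
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or malformed embedding file")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate stimulus id in ", path)
  w <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(w)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric cell(s) in column '%s'", names(df[-1])[bad]))
  }
  rownames(w) <- ids
  embedding_table(w, level)
}
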
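# Shared fixtures, lazily built once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, make) {
  if (!exists(name, envir = .fixtures)) assign(name, make(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Small simulated study: 2 participants, 3 sessions x 80 concepts,
# 16 sensors, 4 dimensions (2 early / 2 late), 100 Hz, -100..600 ms.
small_study <- function() fixture("small_study", function() {
  cfg <- generator_config(
    n_participants = 2, n_sessions = 3, n_concepts = 80, n_sensors = 16,
    n_dims = 4, epoch_window = c(-100, 600), seed = 301)
  emb <- generate_embedding(cfg$n_concepts, cfg$n_dims, seed = 302)
  img <- expand_to_images(emb, exemplars_per_concept = cfg$n_sessions,
                          seed = 303)
  ds <- simulate_epochs(cfg, img$images, seed = 304)
  list(cfg = cfg, concepts = emb, images = img$images,
       features = img$features, datasets = ds)
})

small_within_tc <- function() fixture("small_within_tc", function() {
  s <- small_study()
  decode_timecourse(s$datasets["P1"], s$images,
                    make_session_folds(s$datasets$P1$trial_table))
})

# Pure-noise study (no planted signal) for null-calibration checks.
noise_study <- function() fixture("noise_study", function() {
  cfg <- generator_config(
    n_participants = 1, n_sessions = 2, n_concepts = 60, n_sensors = 8,
    n_dims = 4, epoch_window = c(-100, 310), amplitude = 0, seed = 401)
  emb <- generate_embedding(cfg$n_concepts, cfg$n_dims, seed = 402)
  img <- expand_to_images(emb, exemplars_per_concept = cfg$n_sessions,
                          seed = 403)
  ds <- simulate_epochs(cfg, img$images, seed = 404)
  tc <- decode_timecourse(ds, img$images,
                          make_session_folds(ds$P1$trial_table))
  list(cfg = cfg, images = img$images, datasets = ds, tc = tc)
})

# Exhaustive DTW oracle: enumerate every admissible warping path
# (boundary-aligned, monotone, steps {(1,0),(0,1),(1,1)}) and return the
# minimal summed local cost. Only feasible for short series.
dtw_brute_force <- function(a, b) {
  cost <- abs(outer(a, b, "-"))
  n <- length(a); m <- length(b)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible())
    }
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}

# Two planted shape families on a common grid: early Gaussian bumps vs
# late sigmoidal ramps, with small additive noise, z-scored per series.
planted_shape_families <- function(n_per = 4, noise_sd = 0.05, seed = 99) {
  set.seed(seed)
  t_ms <- seq(0, 600, by = 10)
  early <- t(replicate(n_per,
    exp(-(t_ms - 125)^2 / (2 * 30^2)) + rnorm(length(t_ms), sd = noise_sd)))
  late <- t(replicate(n_per,
    1 / (1 + exp(-(t_ms - 300) / 50)) + rnorm(length(t_ms), sd = noise_sd)))
  tcs <- rbind(early, late)
  tcs <- t(apply(tcs, 1, function(x) (x - mean(x)) / sd(x)))
  rownames(tcs) <- c(sprintf("early%d", seq_len(n_per)),
                     sprintf("late%d", seq_len(n_per)))
  list(tcs = tcs, family = rep(c(1, 2), each = n_per), times_ms = t_ms)
}

# Agreement of two flat clusterings up to label renaming.
same_partition <- function(a, b) {
  length(unique(a)) == length(unique(b)) &&
    all(table(a, b) %in% c(0, table(a)))
}
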
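#' Phantom benchmark configurations
#'
#' The end-to-end phantom benchmark trains the toy hourglass (stem width 8,
#' block width 8, depth 4) on toy8 phantoms. Depth 4 gives the deepest
#' features a receptive field covering the whole 48^3 grid, which the
#' blob-to-channel assignment needs; augmentation is milder than the
#' clinical defaults (crops retain at least 70% per axis, rotations within
#' 10 degrees, translations within 5%, 1-voxel elastic displacements) and
#' the learning rate is raised to 0.01, both matched to the schematic
#' phantom task rather than clinical data. See the methods vignette for the
#' rationale.
#'
#' @param seed initialization / shuffling seed.
#' @param max_epochs,patience training budget of the benchmark run.
#' @return A [network_config()] / [train_config()].
#' @export
benchmark_network_config <- function(seed = 1L) {
  network_config(out_channels = 8L, stem_features = 8L,
                 block_features = c(8L, 8L, 8L), gn_groups = 8L,
                 depth = 4L, seed = seed)
}

#' @rdname benchmark_network_config
#' @export
benchmark_train_config <- function(seed = 1L, max_epochs = 40L,
                                   patience = 12L) {
  train_config(learning_rate = 0.01, crop_max_fraction = 0.3,
               rotation_range = c(-10, 10),
               translation_range = c(-0.05, 0.05), elastic_max_disp = 1,
               max_epochs = max_epochs, patience = patience, seed = seed)
}

#' Run the end-to-end phantom benchmark
#'
#' Generates disjoint train/validation/held-out phantom cases from one
#' [phantom_spec()], trains the toy hourglass, predicts the held-out
#' cases, and summarizes the landmark error.
#'
#' @param spec a [phantom_spec()] (the study conditions).
#' @param n_train,n_val,n_test case counts; held-out cases use indices
#'   after the train/validation block so changing `n_train` never changes
#'   the evaluation cases.
#' @param net_cfg,train_cfg configurations, defaulting to the benchmark
#'   ones.
#' @param case_offset first case index (default 1).
#' @return `list(checkpoint, mean_mm, sdr2_pct, sdr3p2_pct, misses, n,
#'   distances)`.
#' @export
run_phantom_benchmark <- function(spec = phantom_spec(template = "toy8",
                                                      seed = 11L),
                                  n_train = 40L, n_val = 10L, n_test = 10L,
                                  net_cfg = benchmark_network_config(),
                                  train_cfg = benchmark_train_config(),
                                  case_offset = 1L) {
  max_train <- 40L # fixed pool so held-out indices are size-independent
  stopifnot(n_train <= max_train)
  idx0 <- case_offset - 1L
  train <- lapply(idx0 + seq_len(n_train), function(i)
    generate_case(spec, i))
  val <- lapply(idx0 + max_train + seq_len(n_val), function(i)
    generate_case(spec, i))
  test <- lapply(idx0 + max_train + n_val + seq_len(n_test), function(i)
    generate_case(spec, i))
  ck <- train_network(train, val, net_cfg, train_cfg)
  dists <- c()
  misses <- 0L
  for (s in test) {
    pr <- predict_landmarks(ck, s$volume)
    for (id in present_ids(s$landmarks)) {
      q <- lm_coord(pr, id)
      if (is.null(q)) misses <- misses + 1L
      else dists <- c(dists,
                      landmark_distance(lm_coord(s$landmarks, id), q))
    }
  }
  list(checkpoint = ck, mean_mm = mean(dists), sdr2_pct = sdr(dists, 2),
       sdr3p2_pct = sdr(dists, 3.2), misses = misses,
       n = length(dists), distances = dists)
}

#' Training-set-size study on the phantom benchmark
#'
#' Trains the benchmark network on nested training subsets (sizes
#' default 10, 20, 40 phantoms) for a fixed epoch budget, repeating over
#' several network/shuffling seeds, and reports the per-size median of the
#' held-out mean landmark error. Used to verify that held-out error
#' improves monotonically with more training data.
#'
#' @param spec a [phantom_spec()].
#' @param sizes training-set sizes (nested subsets of one pool).
#' @param seeds network/shuffle seeds to repeat over.
#' @param epochs fixed epoch budget per run.
#' @param n_val,n_test validation / held-out case counts.
#' @return Data frame with one row per (size, seed) plus the per-size
#'   medians as the `"medians"` attribute.
#' @export
training_size_study <- function(spec = phantom_spec(template = "toy8",
                                                    seed = 11L),
                                sizes = c(10L, 20L, 40L), seeds = 1:3,
                                epochs = 12L, n_val = 10L, n_test = 10L) {
  rows <- list()
  for (sz in sizes) {
    for (sd in seeds) {
      r <- run_phantom_benchmark(
        spec, n_train = sz, n_val = n_val, n_test = n_test,
        net_cfg = benchmark_network_config(seed = sd),
        train_cfg = benchmark_train_config(seed = sd, max_epochs = epochs,
                                           patience = epochs))
      rows[[length(rows) + 1L]] <-
        data.frame(size = sz, seed = sd, mean_mm = r$mean_mm,
                   sdr3p2_pct = r$sdr3p2_pct, misses = r$misses)
    }
  }
  out <- do.call(rbind, rows)
  med <- vapply(split(out$mean_mm, out$size), stats::median, 0)
  attr(out, "medians") <- med[order(as.numeric(names(med)))]
  out
}
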
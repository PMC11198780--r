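# Shared fixture builders for the test suite (everything is generated in
# code; no binary fixtures).

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
}

# full46 landmark set from the built-in template (no jitter)
full46_landmarks <- function() {
  landmark_set(phantom_template("full46"), schema = "clinical46")
}

# toy network/training configs used across training tests
toy_net_config <- function(out_channels = 8L, seed = 1L, depth = 2L)
  network_config(out_channels = out_channels, stem_features = 8L,
                 block_features = c(8L, 8L, 8L), gn_groups = 8L,
                 depth = depth, seed = seed)

no_aug_config <- function(...) {
  base <- list(crop_max_fraction = 0, rotation_range = c(0, 0),
               translation_range = c(0, 0), elastic_max_disp = 0,
               contrast_range = c(1, 1), brightness_range = c(0, 0))
  do.call(train_config, utils::modifyList(base, list(...)))
}

# mm distance between the same landmark in two sets (NA if absent)
lm_dist <- function(a, b, id) {
  pa <- a$coords[id, ]; pb <- b$coords[id, ]
  if (any(is.na(pa)) || any(is.na(pb))) return(NA_real_)
  sqrt(sum((pa - pb)^2))
}
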
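#' Training configuration
#'
#' Optimization and augmentation settings. Defaults follow the reference
#' recipe: AdamW with learning rate 0.001 and weight decay 0.01, binary
#' cross-entropy on Gaussian heatmap targets (sigma 1.5 voxels) generated on
#' the network's output grid, input volumes resampled to 1.6 mm isotropic
#' spacing, and augmentation by random crops (up to 75% removed per axis),
#' local elastic deformation, rotations in (-15, 15) degrees, translations
#' in (-10%, 10%) of the extent, and random contrast/brightness changes.
#' Training stops when the validation mean landmark distance has not
#' improved for `patience` epochs (or at `max_epochs`).
#'
#' @param learning_rate AdamW step size (gamma).
#' @param weight_decay AdamW decoupled weight decay (lambda).
#' @param sigma_voxels Gaussian target width, in voxels of the output grid.
#' @param target_spacing isotropic resampling spacing in mm.
#' @param crop_max_fraction per-axis maximum fraction removable by the
#'   random crop (retained window length uniform in
#'   `[1 - crop_max_fraction, 1]` of the axis, position uniform).
#' @param rotation_range rotation range in degrees, per axis.
#' @param translation_range translation range as a fraction of the axis
#'   extent.
#' @param elastic_spacing coarse displacement-grid spacing in voxels.
#' @param elastic_max_disp maximum per-axis elastic displacement in voxels
#'   (0 disables).
#' @param contrast_range,brightness_range multiplicative contrast about the
#'   mean and additive brightness as a fraction of the intensity range.
#' @param patience epochs without validation improvement before stopping.
#' @param max_epochs hard epoch cap.
#' @param rel_threshold,min_peak decoder settings (see [decode_heatmaps()]).
#' @param seed master seed for shuffling and augmentation draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.01,
                         sigma_voxels = 1.5, target_spacing = 1.6,
                         crop_max_fraction = 0.75,
                         rotation_range = c(-15, 15),
                         translation_range = c(-0.10, 0.10),
                         elastic_spacing = 8, elastic_max_disp = 2,
                         contrast_range = c(0.8, 1.2),
                         brightness_range = c(-0.1, 0.1),
                         patience = 20L, max_epochs = 100L,
                         rel_threshold = 0.5, min_peak = 0.1, seed = 1L) {
  stopifnot(learning_rate > 0, crop_max_fraction >= 0,
            crop_max_fraction < 1, patience >= 1, max_epochs >= 0,
            sigma_voxels > 0, target_spacing > 0, elastic_max_disp >= 0)
  structure(list(learning_rate = learning_rate,
                 weight_decay = weight_decay, sigma_voxels = sigma_voxels,
                 target_spacing = target_spacing,
                 crop_max_fraction = crop_max_fraction,
                 rotation_range = rotation_range,
                 translation_range = translation_range,
                 elastic_spacing = elastic_spacing,
                 elastic_max_disp = elastic_max_disp,
                 contrast_range = contrast_range,
                 brightness_range = brightness_range,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 rel_threshold = rel_threshold, min_peak = min_peak,
                 seed = as.integer(seed)),
            class = "train_config")
}

# --- augmentation --------------------------------------------------------

rot_matrix <- function(deg) {
  a <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  rz %*% ry %*% rx
}

voxel_grid_coords <- function(d) {
  cbind(rep.int(seq_len(d[1]) - 1, times = d[2] * d[3]),
        rep.int(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3]),
        rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
}

# Dense elastic displacement field (voxels), trilinearly interpolated from a
# coarse grid of zero-mean uniform draws.
elastic_field <- function(d, spacing, max_disp) {
  nc <- pmax(ceiling((d - 1) / spacing) + 1, 2)
  field <- matrix(0, prod(d), 3)
  fine <- voxel_grid_coords(d) / spacing
  for (ax in 1:3) {
    coarse <- array(runif(prod(nc), -max_disp, max_disp), nc)
    field[, ax] <- .cpp_sample_trilinear(coarse, nc, fine, 0)
  }
  field
}

#' Augment a volume/landmark pair
#'
#' Applies, in order: a random crop (array windowing; the world frame is
#' unchanged and landmarks falling outside the retained window become
#' absent), a rigid rotation about the volume center plus translation, a
#' local elastic deformation, and intensity contrast/brightness changes.
#' All spatial transforms move the image content and the landmark
#' coordinates identically; with every range set to zero the operation is
#' the exact identity. Draws come from the current RNG state; seed before
#' calling for reproducibility.
#'
#' @param vol a [volume()].
#' @param landmarks the matching [landmark_set()].
#' @param cfg a [train_config()].
#' @return `list(volume =, landmarks =)`.
#' @export
augment_sample <- function(vol, landmarks, cfg) {
  d <- dim(vol$data)
  # 1. random crop -------------------------------------------------------
  if (cfg$crop_max_fraction > 0) {
    keep <- runif(3, 1 - cfg$crop_max_fraction, 1)
    len <- pmax(pmin(round(keep * d), d), 4L)
    start <- floor(runif(3) * (d - len + 1)) # 0-based
    newdata <- vol$data[start[1] + seq_len(len[1]),
                        start[2] + seq_len(len[2]),
                        start[3] + seq_len(len[3]), drop = FALSE]
    vol <- volume(newdata, spacing = vol$spacing,
                  origin = voxel_to_world(vol, start),
                  direction = vol$direction)
    d <- len
    landmarks <- drop_outside(landmarks, vol)
  }
  # 2+3. rigid + elastic, one resampling pass ----------------------------
  rot <- runif(3, cfg$rotation_range[1], cfg$rotation_range[2])
  trans <- runif(3, cfg$translation_range[1], cfg$translation_range[2]) *
    (d * vol$spacing)
  do_rigid <- any(rot != 0) || any(trans != 0)
  do_elastic <- cfg$elastic_max_disp > 0
  if (do_rigid || do_elastic) {
    R <- rot_matrix(rot)
    center <- voxel_to_world(vol, (d - 1) / 2)
    disp <- if (do_elastic)
      elastic_field(d, cfg$elastic_spacing, cfg$elastic_max_disp)
    else matrix(0, prod(d), 3)
    # image: output voxel i samples input at W2V(Tinv(V2W(i))) + disp(i)
    w <- voxel_to_world(vol, voxel_grid_coords(d))
    winv <- t(t(w) - center - trans) %*% R # == Rinv (w - c - t), then + c
    winv <- t(t(winv) + center)
    src <- world_to_voxel(vol, winv) + disp
    vals <- .cpp_sample_trilinear(vol$data, d, src, min(vol$data))
    newvol <- volume(array(vals, d), vol$spacing, vol$origin, vol$direction)
    # landmarks: p -> T(p), then elastic transport c' = c - disp(c)
    m <- landmarks$coords
    pres <- stats::complete.cases(m)
    if (any(pres)) {
      p <- t(R %*% (t(m[pres, , drop = FALSE]) - center) + center + trans)
      if (do_elastic) {
        cvox <- world_to_voxel(vol, p)
        dsp <- vapply(1:3, function(ax)
          sample_at(array(disp[, ax], d), cvox, fill = 0), numeric(nrow(p)))
        p <- voxel_to_world(vol, cvox - dsp)
      }
      m[pres, ] <- p
    }
    landmarks$coords <- m
    vol <- newvol
    landmarks <- drop_outside(landmarks, vol)
  }
  # 4. intensity ---------------------------------------------------------
  a <- runif(1, cfg$contrast_range[1], cfg$contrast_range[2])
  b <- runif(1, cfg$brightness_range[1], cfg$brightness_range[2])
  if (a != 1 || b != 0) {
    mu <- mean(vol$data)
    rng <- diff(range(vol$data))
    vol$data <- mu + a * (vol$data - mu) + b * rng
  }
  list(volume = vol, landmarks = landmarks)
}

# Landmarks transported outside the grid's physical support become absent.
drop_outside <- function(landmarks, vol) {
  m <- landmarks$coords
  pres <- which(stats::complete.cases(m))
  if (length(pres)) {
    v <- world_to_voxel(vol, m[pres, , drop = FALSE])
    d <- dim(vol$data)
    out <- v[, 1] < -0.5 | v[, 1] > d[1] - 0.5 |
      v[, 2] < -0.5 | v[, 2] > d[2] - 0.5 |
      v[, 3] < -0.5 | v[, 3] > d[3] - 0.5
    m[pres[out], ] <- NA_real_
  }
  landmarks$coords <- m
  landmarks
}

# --- loss ----------------------------------------------------------------

#' Masked binary cross-entropy between heatmap stacks
#'
#' Voxelwise BCE averaged over the voxels of channels whose *target*
#' presence mask is true; channels of absent landmarks contribute nothing,
#' so adding an absent channel never changes the loss. Predictions are
#' clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred,target [heatmap_stack()]s with identical geometry and
#'   channel ids.
#' @return Scalar loss.
#' @export
bce_loss <- function(pred, target) {
  stopifnot(inherits(pred, "heatmap_stack"), inherits(target, "heatmap_stack"))
  if (!identical(pred$ids, target$ids) ||
      !all(dim(pred$maps) == dim(target$maps)))
    stop("prediction and target stacks must share geometry and channels",
         call. = FALSE)
  bce_core(pred$maps, target$maps, target$present_mask)$loss
}

bce_core <- function(pred, target, present, with_grad = FALSE) {
  if (!any(present))
    stop("no supervised landmarks: every target channel is masked",
         call. = FALSE)
  eps <- 1e-7
  idx <- which(present)
  p <- pred[, , , idx, drop = FALSE]
  t <- target[, , , idx, drop = FALSE]
  p <- pmin(pmax(p, eps), 1 - eps)
  n <- length(p)
  loss <- -sum(t * log(p) + (1 - t) * log1p(-p)) / n
  out <- list(loss = loss)
  if (with_grad) {
    # gradient w.r.t. the pre-sigmoid logits: (p - t) / n on supervised
    # channels (exact through the sigmoid), zero elsewhere
    g <- array(0, dim(pred))
    g[, , , idx] <- (p - t) / n
    out$glogits <- g
  }
  out
}

# --- AdamW ---------------------------------------------------------------

adamw_init <- function(params) {
  walk <- function(x) {
    if (is.numeric(x)) list(m = x * 0, v = x * 0)
    else if (is.list(x)) lapply(x, walk)
    else NULL
  }
  lapply(params, walk)
}

# One decoupled-weight-decay Adam step over the nested parameter tree.
# Scalars k/cin/cout inside conv nodes are skipped (no matching grad).
adamw_step <- function(params, grads, state, t, lr, wd,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  step <- function(p, g, s) {
    if (is.numeric(p)) {
      if (is.null(g)) return(list(p = p, s = s))
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      p <- p - lr * (mhat / (sqrt(vhat) + eps) + wd * p)
      list(p = p, s = s)
    } else if (is.list(p)) {
      for (nm in names(p)) {
        r <- step(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p
        s[[nm]] <- r$s
      }
      list(p = p, s = s)
    } else {
      list(p = p, s = s)
    }
  }
  out <- step(params, grads, state)
  list(params = out$p, state = out$s)
}

# --- training ------------------------------------------------------------

#' Train the hourglass network
#'
#' Reference training loop, deterministic given the seeds: per epoch each
#' training sample is resampled to the target spacing, augmented, encoded
#' into Gaussian heatmap targets on the network's output grid, and used for
#' one AdamW step on the masked BCE loss (batch size 1, full volumes).
#' After every epoch the validation mean Euclidean landmark distance is
#' computed via [predict_landmarks()]; the parameters with the lowest
#' validation distance are kept, and training stops after `patience` epochs
#' without improvement or at `max_epochs`.
#'
#' @param train_set,val_set lists of `list(volume =, landmarks =)` samples;
#'   `val_set` must be non-empty.
#' @param net_cfg a [network_config()].
#' @param train_cfg a [train_config()].
#' @param verbose print one line per epoch.
#' @return A `ceph_checkpoint`: fields `params`, `net_config`,
#'   `train_config`, `best_val_mm`, `epoch`, `history` (one row per epoch:
#'   loss, validation mm, miss count).
#' @export
train_network <- function(train_set, val_set, net_cfg, train_cfg,
                          verbose = FALSE) {
  stopifnot(length(val_set) >= 1)
  for (s in c(train_set, val_set))
    if (!inherits(s$volume, "ceph_volume") ||
        !inherits(s$landmarks, "landmark_set"))
      stop("every sample needs a volume and a landmark set", call. = FALSE)
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(train_cfg$seed)

  ids <- rownames(train_set[[1]]$landmarks$coords)
  if (length(ids) != net_cfg$out_channels)
    stop("network has ", net_cfg$out_channels, " output channels but the ",
         "landmark schema has ", length(ids), " entries", call. = FALSE)
  net <- build_network(net_cfg)
  state <- adamw_init(net$params)
  tstep <- 0L

  pre <- function(s) {
    v <- if (all(abs(s$volume$spacing - train_cfg$target_spacing) < 1e-12))
      s$volume else resample_isotropic(s$volume, train_cfg$target_spacing)
    list(volume = v, landmarks = s$landmarks)
  }
  train_set <- lapply(train_set, pre)
  val_set <- lapply(val_set, pre)

  validate <- function() {
    ck <- list(params = net$params, net_config = net_cfg,
               train_config = train_cfg, landmark_ids = ids)
    class(ck) <- "ceph_checkpoint"
    dists <- c()
    miss <- 0L
    for (s in val_set) {
      pr <- predict_landmarks(ck, s$volume)
      for (id in present_ids(s$landmarks)) {
        q <- lm_coord(pr, id)
        if (is.null(q)) miss <- miss + 1L
        else dists <- c(dists, sqrt(sum((lm_coord(s$landmarks, id) - q)^2)))
      }
    }
    list(mm = if (length(dists)) mean(dists) else NA_real_, miss = miss)
  }

  v0 <- validate()
  if (!is.finite(v0$mm) && v0$miss == 0L)
    stop("training error: validation set contains no present landmarks",
         call. = FALSE)
  best <- list(params = net$params, mm = v0$mm, epoch = 0L, miss = v0$miss)
  history <- data.frame(epoch = 0L, loss = NA_real_, val_mm = v0$mm,
                        misses = v0$miss)
  since_best <- 0L

  epoch <- 0L
  while (epoch < train_cfg$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(length(train_set))
    losses <- numeric(0)
    for (i in ord) {
      s <- train_set[[i]]
      aug <- augment_sample(s$volume, s$landmarks, train_cfg)
      d <- dim(aug$volume$data)
      if (any(d < 2L^net_cfg$depth * net_cfg$stem_stride)) next
      geom <- output_geometry(net, aug$volume)
      tgt <- suppressWarnings(
        encode_heatmaps(aug$landmarks, geom, train_cfg$sigma_voxels))
      if (!any(tgt$present_mask)) next
      fw <- net_forward(net, aug$volume$data, keep = TRUE)
      bc <- bce_core(fw$out, tgt$maps, tgt$present_mask, with_grad = TRUE)
      grads <- net_backprop(net, fw$cache, bc$glogits)
      tstep <- tstep + 1L
      upd <- adamw_step(net$params, grads, state, tstep,
                        train_cfg$learning_rate, train_cfg$weight_decay)
      net$params <- upd$params
      state <- upd$state
      losses <- c(losses, bc$loss)
    }
    v <- validate()
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = mean(losses),
                                val_mm = v$mm, misses = v$miss))
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  val %.3f mm  misses %d",
                      epoch, mean(losses), v$mm, v$miss))
    improved <- is.finite(v$mm) && (!is.finite(best$mm) || v$mm < best$mm)
    if (improved) {
      best <- list(params = net$params, mm = v$mm, epoch = epoch,
                   miss = v$miss)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= train_cfg$patience) break
    }
  }
  if (!is.finite(best$mm))
    stop("training error: validation never produced a finite distance",
         call. = FALSE)

  structure(list(params = best$params, net_config = net_cfg,
                 train_config = train_cfg, landmark_ids = ids,
                 best_val_mm = best$mm, epoch = best$epoch,
                 val_misses = best$miss, history = history),
            class = "ceph_checkpoint")
}

#' @export
print.ceph_checkpoint <- function(x, ...) {
  cat(sprintf("<ceph_checkpoint> best validation %.3f mm at epoch %d\n",
              x$best_val_mm, x$epoch))
  invisible(x)
}

#' Save / load a checkpoint
#'
#' Single-file checkpoint holding the parameter tree, both configurations,
#' and the training history; loadable without any external configuration.
#'
#' @param ckpt a `ceph_checkpoint`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "ceph_checkpoint"))
  saveRDS(c(unclass(ckpt), list(format_version = 1L)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  structure(x[setdiff(names(x), "format_version")],
            class = "ceph_checkpoint")
}

#' Predict landmarks for a volume
#'
#' Full inference pipeline: resample to the checkpoint's target spacing,
#' run the network, decode each channel by thresholded center of mass on
#' the output grid, and return world-mm coordinates (the resampler and the
#' output grid share the input volume's world frame, so coordinates are
#' directly comparable with annotations of the original volume). Channels
#' peaking below `min_peak` are reported absent.
#'
#' @param ckpt a `ceph_checkpoint` (from [train_network()] or
#'   [load_checkpoint()]).
#' @param vol a [volume()].
#' @param schema schema for the returned set; defaults to channel ids.
#' @return A [landmark_set()] with decoder confidences.
#' @export
predict_landmarks <- function(ckpt, vol, schema = NULL) {
  stopifnot(inherits(ckpt, "ceph_checkpoint"))
  tc <- ckpt$train_config
  net <- structure(list(config = ckpt$net_config, params = ckpt$params),
                   class = "ceph_network")
  v <- if (all(abs(vol$spacing - tc$target_spacing) < 1e-12)) vol
  else resample_isotropic(vol, tc$target_spacing)
  check_input_size(net, dim(v$data))
  out <- net_forward(net, v$data, keep = FALSE)$out
  geom <- output_geometry(net, v)
  ids <- ckpt$landmark_ids
  if (is.null(ids)) ids <- default_channel_ids(dim(out)[4])
  stack <- heatmap_stack(pmin(pmax(out, 0), 1), geom, ids)
  decode_heatmaps(stack, tc$rel_threshold, tc$min_peak,
                  schema = if (is.null(schema)) ids else schema)
}

default_channel_ids <- function(n) {
  if (n == 46L) landmark_schema("clinical46")$id
  else if (n == 8L) TOY8_IDS
  else sprintf("ch%02d", seq_len(n))
}
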
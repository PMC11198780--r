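#' Grid geometry of a heatmap stack
#'
#' The shared voxel grid (size, spacing, origin, direction) a heatmap stack
#' lives on. For network outputs this is the half-resolution grid derived
#' from the input volume (spacing doubled, origin at the first output voxel
#' center, i.e. the input origin).
#'
#' @param dims integer length-3 grid size.
#' @param spacing,origin,direction world geometry as in [volume()].
#' @return An object of class `grid_geometry`.
#' @export
grid_geometry <- function(dims, spacing = c(1.6, 1.6, 1.6),
                          origin = c(0, 0, 0), direction = diag(3)) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L))
  spacing <- as.numeric(spacing)
  stopifnot(length(spacing) == 3L, all(spacing > 0))
  structure(list(dims = dims, spacing = spacing,
                 origin = as.numeric(origin),
                 direction = matrix(as.numeric(direction), 3, 3)),
            class = "grid_geometry")
}

#' @rdname grid_geometry
#' @param vol a [volume()] whose grid should be described.
#' @export
geometry_of <- function(vol) {
  grid_geometry(dim(vol$data), vol$spacing, vol$origin, vol$direction)
}

# voxel_to_world / world_to_voxel only touch spacing/origin/direction, so
# grid_geometry objects can be passed wherever a volume's geometry is needed.

#' Per-landmark Gaussian heatmap stacks
#'
#' Container for one activation grid per schema landmark, values in [0, 1],
#' with the shared grid geometry and a per-channel presence mask. Channels
#' of absent landmarks are identically zero with mask `FALSE`.
#'
#' @param maps 4D array (x, y, z, channel), values in [0, 1].
#' @param geometry a [grid_geometry()].
#' @param ids character vector of landmark ids, one per channel.
#' @param present_mask logical per channel.
#' @export
heatmap_stack <- function(maps, geometry, ids,
                          present_mask = rep(TRUE, length(ids))) {
  stopifnot(length(dim(maps)) == 4L, dim(maps)[4] == length(ids),
            all(dim(maps)[1:3] == geometry$dims))
  if (min(maps) < 0 || max(maps) > 1)
    stop("heatmap activations must lie in [0, 1]", call. = FALSE)
  structure(list(maps = maps, geometry = geometry, ids = ids,
                 present_mask = as.logical(present_mask)),
            class = "heatmap_stack")
}

#' @export
print.heatmap_stack <- function(x, ...) {
  cat(sprintf("<heatmap_stack> %d channels on %s grid, %d present\n",
              length(x$ids), paste(x$geometry$dims, collapse = "x"),
              sum(x$present_mask)))
  invisible(x)
}

#' Encode landmarks as truncated Gaussian-sphere heatmaps
#'
#' Each present landmark with continuous voxel position `c` produces a
#' channel with value `exp(-||v - c||^2 / (2 sigma^2))` at voxel `v`
#' (distance in voxel units), truncated to exactly zero beyond `3 sigma`.
#' The peak equals 1 only when the landmark falls exactly on a voxel
#' center; no renormalization is applied at fractional positions. Landmarks
#' absent from the set, or lying more than `3 sigma` outside the grid, give
#' an all-zero channel with presence mask `FALSE` (the latter with a
#' warning).
#'
#' @param landmarks a [landmark_set()].
#' @param geometry a [grid_geometry()] for the target grid.
#' @param sigma_voxels Gaussian width in voxels of `geometry` (default 1.5,
#'   i.e. 2.4 mm on the 1.6 mm training grid).
#' @return A [heatmap_stack()] with one channel per schema landmark.
#' @examples
#' g <- grid_geometry(c(24, 24, 24))
#' lms <- landmark_set(list(N = c(16, 19.2, 22.4)), "toy8")
#' hs <- encode_heatmaps(lms, g)
#' max(hs$maps[, , , match("N", hs$ids)]) # 1 at the voxel center
#' @export
encode_heatmaps <- function(landmarks, geometry, sigma_voxels = 1.5) {
  stopifnot(sigma_voxels > 0)
  ids <- rownames(landmarks$coords)
  d <- geometry$dims
  maps <- array(0, c(d, length(ids)))
  mask <- logical(length(ids))
  r <- 3 * sigma_voxels
  for (i in seq_along(ids)) {
    p <- lm_coord(landmarks, ids[i])
    if (is.null(p)) next
    cc <- world_to_voxel(geometry, p)
    if (any(cc < -r) || any(cc > d - 1 + r)) {
      warning("landmark ", ids[i], " lies more than 3 sigma outside the ",
              "grid; channel left empty", call. = FALSE)
      next
    }
    lo <- pmax(floor(cc - r), 0)
    hi <- pmin(ceiling(cc + r), d - 1)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    d2 <- outer(outer((xs - cc[1])^2, (ys - cc[2])^2, "+"),
                (zs - cc[3])^2, "+")
    blk <- exp(-d2 / (2 * sigma_voxels^2))
    blk[d2 > r^2] <- 0
    maps[xs + 1, ys + 1, zs + 1, i] <- blk
    mask[i] <- TRUE
  }
  heatmap_stack(maps, geometry, ids, mask)
}

#' Decode heatmaps to landmark coordinates by center of mass
#'
#' Per channel: if the peak activation is below `min_peak` the landmark is
#' reported absent; otherwise voxels below `rel_threshold` times the channel
#' maximum are zeroed (suppressing diffuse low-level activation that would
#' bias the estimate toward the grid center) and the intensity-weighted
#' center of mass in continuous voxel space is mapped to world coordinates
#' through the stack geometry. Confidence is the channel maximum.
#'
#' @param stack a [heatmap_stack()].
#' @param rel_threshold fraction of the channel max kept before the center
#'   of mass (default 0.5).
#' @param min_peak minimum peak activation for a detection (default 0.1).
#' @param schema schema passed to the resulting [landmark_set()]; defaults
#'   to the stack's channel ids.
#' @return A [landmark_set()] with a `confidence` attribute per landmark.
#' @export
decode_heatmaps <- function(stack, rel_threshold = 0.5, min_peak = 0.1,
                            schema = NULL) {
  ids <- stack$ids
  d <- stack$geometry$dims
  coords <- matrix(NA_real_, length(ids), 3,
                   dimnames = list(ids, c("x", "y", "z")))
  conf <- setNames(rep(NA_real_, length(ids)), ids)
  nvox <- prod(d)
  gx <- rep.int(seq_len(d[1]) - 1, times = d[2] * d[3])
  gy <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  gz <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  for (i in seq_along(ids)) {
    ch <- stack$maps[, , , i]
    mx <- max(ch)
    if (!is.finite(mx) || mx < min_peak) next
    w <- as.numeric(ch)
    w[w < rel_threshold * mx] <- 0
    s <- sum(w)
    com <- c(sum(w * gx), sum(w * gy), sum(w * gz)) / s
    coords[i, ] <- voxel_to_world(stack$geometry, com)
    conf[i] <- mx
  }
  landmark_set(coords, schema = if (is.null(schema)) ids else schema,
               confidence = conf)
}

#' Dump / reload a heatmap stack as a multi-channel NIfTI
#'
#' Debug serialization: channels become the 4th NIfTI dimension, the grid
#' geometry goes into the sform, and the channel ids plus presence mask
#' into a JSON sidecar (`<path>.channels.json`). Double precision on both
#' sides, so round trips are bit-exact.
#'
#' @param stack a [heatmap_stack()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_heatmaps <- function(stack, path) {
  img <- RNifti::asNifti(stack$maps)
  RNifti::pixdim(img) <- c(stack$geometry$spacing, 1)
  xf <- rbind(cbind(stack$geometry$direction %*%
                      diag(stack$geometry$spacing),
                    stack$geometry$origin), c(0, 0, 0, 1))
  img <- RNifti::`sform<-`(img, structure(xf, code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(ids = stack$ids,
                            present_mask = stack$present_mask),
                       paste0(path, ".channels.json"))
  invisible(path)
}

#' @rdname write_heatmaps
#' @export
read_heatmaps <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stop("expected a 4D multi-channel heatmap image: ", path,
         call. = FALSE)
  xf <- RNifti::xform(img)
  lin <- xf[1:3, 1:3]
  spacing <- sqrt(colSums(lin^2))
  side <- jsonlite::read_json(paste0(path, ".channels.json"),
                              simplifyVector = TRUE)
  g <- grid_geometry(d[1:3], spacing, xf[1:3, 4],
                     sweep(lin, 2, spacing, "/"))
  heatmap_stack(array(as.numeric(img), d), g, side$ids,
                as.logical(side$present_mask))
}

#' Encode-decode round-trip error
#'
#' Encodes landmarks on a grid, decodes them back, and reports the per-
#' landmark Euclidean error in mm. Used to characterize the quantization
#' floor of the heatmap representation (about half a voxel for interior
#' landmarks).
#'
#' @inheritParams encode_heatmaps
#' @inheritParams decode_heatmaps
#' @return Named numeric vector of mm errors (NA where the landmark was
#'   absent or dropped).
#' @export
roundtrip_error <- function(landmarks, geometry, sigma_voxels = 1.5,
                            rel_threshold = 0.5, min_peak = 0.1) {
  enc <- encode_heatmaps(landmarks, geometry, sigma_voxels)
  dec <- decode_heatmaps(enc, rel_threshold, min_peak)
  ids <- rownames(landmarks$coords)
  err <- setNames(rep(NA_real_, length(ids)), ids)
  for (id in present_ids(landmarks)) {
    q <- lm_coord(dec, id)
    if (!is.null(q)) err[id] <- sqrt(sum((lm_coord(landmarks, id) - q)^2))
  }
  err
}
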
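#' 3D intensity volume with world geometry
#'
#' A `ceph_volume` couples a 3D intensity array with the metadata needed to
#' place every voxel in world (scanner) coordinates: voxel spacing in mm, the
#' world position of the center of voxel `(0, 0, 0)`, and a 3x3 direction
#' matrix mapping voxel axes to world axes. Continuous voxel indices are
#' 0-based with voxel centers at integer indices, so
#' `world = origin + direction %*% (spacing * index)`.
#'
#' @param data numeric 3D array of intensities (all finite).
#' @param spacing numeric length-3, mm per voxel along each axis; all > 0.
#' @param origin numeric length-3, world mm position of the center of the
#'   first voxel.
#' @param direction 3x3 orthonormal matrix (checked to 1e-6).
#' @return An object of class `ceph_volume`.
#' @examples
#' vol <- volume(array(0, c(8, 8, 8)), spacing = c(1.6, 1.6, 1.6))
#' dim(vol$data)
#' @export
volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ",
         length(dim(data)), " dimension(s)", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(is.finite(data)))
    stop("volume intensities must all be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values", call. = FALSE)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("direction matrix must be orthonormal (within 1e-6)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "ceph_volume")
}

#' @export
print.ceph_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ceph_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(x$spacing, digits = 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, intensity range [%.4g, %.4g]\n",
              paste(format(x$origin, digits = 4), collapse = ", "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Convert between continuous voxel indices and world coordinates
#'
#' `voxel_to_world()` maps continuous 0-based voxel indices to world mm via
#' the volume's affine geometry; `world_to_voxel()` is its exact inverse.
#' Out-of-grid indices are legal and mapped as-is.
#'
#' @param vol a [volume()].
#' @param index,point numeric length-3 vector or an n x 3 matrix.
#' @return A vector or matrix of the same shape in the other coordinate
#'   system.
#' @examples
#' vol <- volume(array(0, c(4, 4, 4)), spacing = c(1.6, 1.6, 1.6),
#'               origin = c(10, 0, 0))
#' world_to_voxel(vol, c(13.2, 0, 0)) # (2, 0, 0)
#' @export
voxel_to_world <- function(vol, index) {
  idx <- rbind_points(index)
  w <- t(vol$direction %*% (t(idx) * vol$spacing) + vol$origin)
  shape_like(w, index)
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, point) {
  pts <- rbind_points(point)
  i <- t((t(vol$direction) %*% (t(pts) - vol$origin)) / vol$spacing)
  shape_like(i, point)
}

rbind_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x
  } else {
    matrix(as.numeric(x), ncol = 3L)
  }
}

shape_like <- function(res, template) {
  if (is.matrix(template)) res else drop(res)
}

#' Resample a volume to isotropic voxel spacing
#'
#' Trilinearly resamples onto an isotropic grid, preserving the world frame:
#' the new grid keeps the input origin and direction, with per-axis size
#' `round(size * spacing / target)` (minimum 1) so the physical field of view
#' drifts by at most half an output voxel per axis. Samples falling outside
#' the input grid take the input's minimum intensity (air).
#'
#' @param vol a [volume()].
#' @param target isotropic spacing in mm (default 1.6, the training grid).
#' @return A [volume()] with spacing `c(target, target, target)`.
#' @examples
#' vol <- volume(array(rnorm(160), c(8, 5, 4)), spacing = c(0.4, 0.4, 0.6))
#' dim(resample_isotropic(vol, 1.6)$data)
#' @export
resample_isotropic <- function(vol, target = 1.6) {
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0)
    stop("target spacing must be a single positive number", call. = FALSE)
  din <- dim(vol$data)
  dout <- pmax(as.integer(round(din * vol$spacing / target)), 1L)
  # Output voxel o lies at world origin + direction %*% (target * o); in input
  # index space that is simply o * target / spacing (same origin/direction).
  scale <- target / vol$spacing
  g <- as.matrix(expand.grid(x = (seq_len(dout[1]) - 1) * scale[1],
                             y = (seq_len(dout[2]) - 1) * scale[2],
                             z = (seq_len(dout[3]) - 1) * scale[3]))
  vals <- .cpp_sample_trilinear(vol$data, din, g, min(vol$data))
  volume(array(vals, dout), spacing = rep(target, 3), origin = vol$origin,
         direction = vol$direction)
}

# Trilinear sample of a plain 3D array at continuous 0-based voxel coords.
sample_at <- function(data, coords, fill = min(data)) {
  .cpp_sample_trilinear(data, dim(data), rbind_points(coords), fill)
}
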
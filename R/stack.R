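#' 3D image stack for one time point
#'
#' Container for a single bright-field z-stack: a 3D grayscale volume with
#' physical voxel sizes. Intensities are expected in `[0, 1]`; use
#' [normalize_stack()] to min-max scale raw data. The array is indexed
#' `[x, y, z]` where `x` is the image column, `y` the image row and `z`
#' ascends with acquisition depth. Physical positions follow the
#' pixel-center convention: the center of voxel index `i` (1-based) lies at
#' `(i - 0.5) * voxel_size`.
#'
#' @param data numeric 3D array, dimensions `(nx, ny, nz)`, `nz >= 3`.
#' @param voxel_size_um numeric length-3, `(dx, dy, dz)` in micrometers,
#'   all strictly positive.
#' @param frame_index integer time index of this stack (0-based by
#'   convention of the file naming, but any integer is accepted).
#' @param t_min acquisition time in minutes.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0.5, c(4, 4, 5)), c(0.87, 0.87, 5))
#' dim(s)
#' @export
image_stack <- function(data, voxel_size_um, frame_index = 0L, t_min = 0) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("'data' must be a 3D array (nx, ny, nz)")
  if (dim(data)[3L] < 3L)
    stop("an image stack needs at least 3 z-planes")
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3L || anyNA(voxel_size_um) ||
      any(!is.finite(voxel_size_um)) || any(voxel_size_um <= 0))
    stop("'voxel_size_um' must be three strictly positive numbers (dx, dy, dz)")
  structure(
    list(data = data, voxel_size_um = voxel_size_um,
         frame_index = as.integer(frame_index), t_min = as.numeric(t_min)),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %d x %d x %d voxels, voxel %.3g x %.3g x %.3g um, frame %d (t = %g min)\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3], x$frame_index, x$t_min))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Physical z-coordinates of the stack's plane centers
#'
#' @param stack an [image_stack()].
#' @return numeric vector of length `nz`, in micrometers.
#' @export
z_centers_um <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  (seq_len(dim(stack$data)[3L]) - 0.5) * stack$voxel_size_um[3L]
}

#' Min-max normalize a stack to [0, 1]
#'
#' Per-stack min-max scaling so that 8/12/16-bit inputs behave identically
#' downstream. Pearson correlation is affine-invariant, so classification is
#' unaffected; the fixed scale matters for template fitting diagnostics and
#' rendering comparisons. A constant stack is returned unchanged.
#'
#' @param stack an [image_stack()].
#' @return the normalized `image_stack`.
#' @export
normalize_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  r <- range(stack$data)
  if (r[2] > r[1]) stack$data <- (stack$data - r[1]) / (r[2] - r[1])
  stack
}

# deterministic 32-bit sub-seed for (scene seed, frame, salt)
.substream_seed <- function(seed, frame, salt = 0L) {
  s <- (as.numeric(seed) %% 2147483647) * 7919 +
    (as.numeric(frame) + 1) * 104729 + as.numeric(salt) * 1299709
  as.integer(s %% 2147483647)
}
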
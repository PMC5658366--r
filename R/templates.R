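#' 1D z-intensity profile
#'
#' The intensity-versus-depth vector at one lateral pixel position. These
#' profiles are the 1D matched filters of the whole method: a cell sitting
#' near some depth imprints an antisymmetric defocus signature (bright lobe
#' above focus, dark lobe below) on the columns it covers, and profiles are
#' compared by Pearson correlation.
#'
#' @param values numeric vector of intensities along z (finite, length >= 3).
#' @param dz_um z sampling step in micrometers (> 0).
#' @param origin_z_um physical z of the first sample (defaults to `dz/2`,
#'   the center of the first plane).
#' @return An object of class `zprofile`.
#' @export
zprofile <- function(values, dz_um, origin_z_um = dz_um / 2) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("a z-profile needs at least 3 samples")
  if (anyNA(values) || any(!is.finite(values))) stop("z-profile values must be finite")
  if (!is.finite(dz_um) || dz_um <= 0) stop("'dz_um' must be positive")
  structure(list(values = values, dz_um = as.numeric(dz_um),
                 origin_z_um = as.numeric(origin_z_um)),
            class = "zprofile")
}

#' @export
length.zprofile <- function(x) length(x$values)

#' @export
print.zprofile <- function(x, ...) {
  cat(sprintf("<zprofile> %d samples, dz = %g um, z in [%g, %g] um\n",
              length(x$values), x$dz_um, x$origin_z_um,
              x$origin_z_um + (length(x$values) - 1) * x$dz_um))
  invisible(x)
}

#' Z sample positions of a profile
#' @param profile a [zprofile()].
#' @return numeric vector of physical z positions (um).
#' @export
profile_z_um <- function(profile) {
  stopifnot(inherits(profile, "zprofile"))
  profile$origin_z_um + (seq_along(profile$values) - 1) * profile$dz_um
}

#' @export
plot.zprofile <- function(x, ..., xlab = "z (um)", ylab = "intensity", type = "l") {
  graphics::plot(profile_z_um(x), x$values, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Extract the z-intensity profile at a lateral pixel
#'
#' A pure read of the intensity column at `(x, y)`, all z-planes, with the
#' z step and origin copied from the stack.
#'
#' @param stack an [image_stack()].
#' @param x,y 1-based pixel indices (x = column, y = row).
#' @return a [zprofile()].
#' @export
extract_profile <- function(stack, x, y) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  if (x < 1L || x > d[1L] || y < 1L || y > d[2L])
    stop(sprintf("pixel (%d, %d) outside lateral bounds %d x %d", x, y, d[1L], d[2L]))
  zprofile(stack$data[x, y, ], dz_um = stack$voxel_size_um[3L],
           origin_z_um = stack$voxel_size_um[3L] / 2)
}

.profile_values <- function(p) if (inherits(p, "zprofile")) p$values else as.numeric(p)

#' Pearson correlation of two z-profiles
#'
#' Standard product-moment coefficient, the similarity measure used both for
#' cell/background classification and as the region-growing stopping
#' criterion. Symmetric, invariant under positive affine transforms of either
#' argument, and clamped to `[-1, 1]` against floating-point overshoot.
#'
#' @param a,b [zprofile()]s or numeric vectors of equal length (>= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  av <- .profile_values(a); bv <- .profile_values(b)
  if (length(av) != length(bv)) stop("profiles must have equal length")
  if (length(av) < 3L) stop("correlation of profiles shorter than 3 samples is meaningless")
  if (stats::var(av) == 0 || stats::var(bv) == 0)
    stop("undefined correlation: zero-variance profile")
  r <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  min(1, max(-1, r))
}

# Correlation of every column of a stack against a reference profile,
# vectorized over pixels. Zero-variance columns give NA.
.column_corr <- function(stack, ref_values) {
  d <- dim(stack$data)
  np <- d[1L] * d[2L]
  X <- matrix(stack$data, np, d[3L])
  Xc <- X - rowMeans(X)
  rs <- sqrt(rowSums(Xc * Xc))
  t0 <- ref_values - mean(ref_values)
  tn <- sqrt(sum(t0 * t0))
  if (tn == 0) stop("reference profile has zero variance")
  r <- as.vector(Xc %*% (t0 / tn)) / rs
  r[rs == 0] <- NA_real_
  matrix(pmin(1, pmax(-1, r)), d[1L], d[2L])
}

#' Cell and background template pair
#'
#' The two manually selected reference z-profiles that drive detection: one
#' taken at a cell, one at a homogeneous cell-free patch of background.
#' Because the bright-field defocus signature depends sensitively on the
#' microscope setup and cell type, templates are selected per experiment;
#' here the selection is programmatic (coordinates recorded in the run
#' configuration and log).
#'
#' `ref_z_um` anchors the sub-voxel z-fit: it is the physical z the template
#' cell is taken to sit at, so an estimated z is `ref_z_um + fitted offset`.
#' If unknown it defaults to the midpoint of the template's z-range, which
#' keeps relative z (and hence tracking) correct up to a constant.
#'
#' @param cell,background [zprofile()]s of equal length, each with nonzero
#'   variance.
#' @param source_xy optional 2x2 matrix of the source pixel coordinates
#'   (rows: cell, background).
#' @param source_frame frame index the templates were extracted from.
#' @param ref_z_um reference z (um) of the cell template; see Details.
#' @return An object of class `template_pair`.
#' @export
template_pair <- function(cell, background, source_xy = NULL,
                          source_frame = NA_integer_, ref_z_um = NULL) {
  stopifnot(inherits(cell, "zprofile"), inherits(background, "zprofile"))
  if (length(cell$values) != length(background$values))
    stop("cell and background templates must have equal length")
  if (stats::var(cell$values) == 0) stop("cell template has zero variance")
  if (stats::var(background$values) == 0) stop("background template has zero variance")
  if (cell$dz_um != background$dz_um) stop("templates must share dz")
  if (is.null(ref_z_um)) {
    zg <- profile_z_um(cell)
    ref_z_um <- (zg[1L] + zg[length(zg)]) / 2
  }
  structure(list(cell = cell, background = background, source_xy = source_xy,
                 source_frame = as.integer(source_frame),
                 ref_z_um = as.numeric(ref_z_um)),
            class = "template_pair")
}

#' @export
print.template_pair <- function(x, ...) {
  cat(sprintf("<template_pair> %d z-samples, dz = %g um, ref z = %g um, source frame %s\n",
              length(x$cell$values), x$cell$dz_um, x$ref_z_um,
              ifelse(is.na(x$source_frame), "?", x$source_frame)))
  invisible(x)
}

#' Extract a template pair from a stack
#'
#' The template profile is averaged over the `(2 * patch_radius_px + 1)^2`
#' pixel neighborhood of the selected coordinate (clipped at image borders).
#' A single column carries one camera-noise realization; left in the
#' template, that realization biases the sub-voxel translation fit (linear
#' resampling smooths the template's noise at non-integer offsets, creating
#' spurious mismatch minima away from the true position). Averaging a small
#' patch of the selected cell or background region suppresses it while
#' leaving the defocus signature intact. Set `patch_radius_px = 0` for the
#' raw single column.
#'
#' @param stack an [image_stack()] (normalize first; see [normalize_stack()]).
#' @param cell_xy,background_xy integer length-2 `(x, y)` pixel coordinates
#'   of the cell and background template columns.
#' @param ref_z_um optional reference z of the template cell (um); see
#'   [template_pair()].
#' @param patch_radius_px Chebyshev radius of the averaging patch
#'   (default 2, a 5x5 mean; keep the patch inside the selected cell).
#' @return a [template_pair()].
#' @export
templates_from_stack <- function(stack, cell_xy, background_xy, ref_z_um = NULL,
                                 patch_radius_px = 2L) {
  cell <- .patch_profile(stack, cell_xy[1L], cell_xy[2L], patch_radius_px)
  bg <- .patch_profile(stack, background_xy[1L], background_xy[2L], patch_radius_px)
  template_pair(cell, bg,
                source_xy = rbind(cell = as.integer(cell_xy),
                                  background = as.integer(background_xy)),
                source_frame = stack$frame_index, ref_z_um = ref_z_um)
}

# Mean z-profile over the in-bounds (2r+1)^2 neighborhood of (x, y).
.patch_profile <- function(stack, x, y, r) {
  d <- dim(stack$data)
  if (x < 1L || x > d[1L] || y < 1L || y > d[2L])
    stop(sprintf("pixel (%d, %d) outside lateral bounds %d x %d", x, y, d[1L], d[2L]))
  if (r == 0L) return(extract_profile(stack, x, y))
  xs <- max(1L, x - r):min(d[1L], x + r)
  ys <- max(1L, y - r):min(d[2L], y + r)
  v <- apply(stack$data[xs, ys, , drop = FALSE], 3L, mean)
  zprofile(v, dz_um = stack$voxel_size_um[3L],
           origin_z_um = stack$voxel_size_um[3L] / 2)
}

#' Rank candidate template pixels by profile amplitude
#'
#' Helper for choosing the cell template column: ranks pixels by the
#' peak-to-peak amplitude of their z-profile (cells produce the strongest
#' axial modulation). The final choice remains the user's and is recorded in
#' the run configuration.
#'
#' @param stack an [image_stack()].
#' @param n number of suggestions to return.
#' @param stride evaluate every `stride`-th pixel in x and y.
#' @return data.frame with columns `x`, `y`, `peak_to_peak`, best first.
#' @export
autosuggest_template <- function(stack, n = 5L, stride = 2L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  xs <- seq(1L, d[1L], by = stride)
  ys <- seq(1L, d[2L], by = stride)
  sub <- stack$data[xs, ys, , drop = FALSE]
  X <- matrix(sub, length(xs) * length(ys), d[3L])
  ptp <- apply(X, 1L, function(v) diff(range(v)))
  ord <- order(ptp, decreasing = TRUE)[seq_len(min(n, length(ptp)))]
  data.frame(x = xs[(ord - 1L) %% length(xs) + 1L],
             y = ys[(ord - 1L) %/% length(xs) + 1L],
             peak_to_peak = ptp[ord])
}

#' Write / read a z-profile as a two-column CSV
#'
#' Storage format for templates: columns `z_um`, `intensity`.
#'
#' @param profile a [zprofile()].
#' @param path file path.
#' @return `write_template` returns `path` invisibly; `read_template`
#'   returns a [zprofile()].
#' @export
write_template <- function(profile, path) {
  stopifnot(inherits(profile, "zprofile"))
  utils::write.csv(data.frame(z_um = profile_z_um(profile),
                              intensity = profile$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("z_um", "intensity") %in% names(d)))
    stop("template CSV needs columns 'z_um' and 'intensity'")
  dz <- diff(d$z_um)
  if (length(dz) < 2L || max(abs(dz - dz[1L])) > 1e-6 * abs(dz[1L]))
    stop("template z grid must be uniform")
  zprofile(d$intensity, dz_um = dz[1L], origin_z_um = d$z_um[1L])
}
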
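#' Sub-voxel axial localization by template fitting
#'
#' The axial sampling of a z-stack (typically 5 um) is coarse compared to
#' the lateral pixel size (0.87 um). A cell's z-position is nevertheless
#' recoverable with sub-voxel precision because the whole defocus signature
#' shifts continuously with the cell: the cell template is translated along
#' z (and allowed a limited linear stretch to absorb minor profile
#' variations from sampling artifacts and noise), resampled onto the
#' profile's z-grid by linear interpolation, amplitude-matched by a
#' least-squares affine gain/offset, and compared to the measured profile by
#' mean absolute difference (the area between the two curves). The
#' translation minimizing this mismatch, found by exhaustive grid search,
#' gives the profile's z.
#'
#' @name zfit
#' @keywords internal
NULL

# Precompute the resampled-template design for a fixed profile z-grid.
# Mapping: template coordinate zeta relates to profile coordinate z via
#   z = ref + offset + stretch * (zeta - ref),
# so the template's reference point lands at ref + offset and an estimated
# z is ref + offset.
.zfit_design <- function(template, z_grid_um, offset_step_um, stretches,
                         ref_z_um, min_overlap) {
  tv <- template$values
  tz <- profile_z_um(template)
  if (stats::var(tv) == 0) stop("invalid template: zero variance")
  nz <- length(z_grid_um)
  offs <- seq(min(z_grid_um) - ref_z_um, max(z_grid_um) - ref_z_um,
              by = offset_step_um)
  grid <- cbind(offset = rep(offs, times = length(stretches)),
                stretch = rep(stretches, each = length(offs)))
  m <- nrow(grid)
  Z <- matrix(z_grid_um, m, nz, byrow = TRUE)
  ZETA <- ref_z_um + (Z - ref_z_um - grid[, "offset"]) / grid[, "stretch"]
  TMv <- stats::approx(tz, tv, xout = as.vector(ZETA), rule = 1L)$y
  TM <- matrix(TMv, m, nz)
  V <- !is.na(TM)
  n <- rowSums(V)
  TM0 <- TM
  TM0[!V] <- 0
  St <- rowSums(TM0)
  Stt <- rowSums(TM0 * TM0)
  valid <- n >= min_overlap & (n * Stt - St * St) > 1e-12
  if (!any(valid))
    stop("fit failure: no template translation leaves enough overlap with the profile")
  list(grid = grid, TM0 = TM0, V = V * 1, n = n, St = St, Stt = Stt,
       valid = valid, ref_z_um = ref_z_um, nz = nz, m = m)
}

# Evaluate the grid for one profile vector; returns the argmin row.
.zfit_eval <- function(des, p) {
  Sp <- as.vector(des$V %*% p)
  Spt <- as.vector(des$TM0 %*% p)
  Spp <- as.vector(des$V %*% (p * p))
  denom <- des$n * des$Stt - des$St^2
  a <- (des$n * Spt - des$St * Sp) / denom
  a[!is.finite(a)] <- 0
  b <- (Sp - a * des$St) / des$n
  Pm <- matrix(p, des$m, des$nz, byrow = TRUE)
  R <- abs(Pm - des$TM0 * a - b) * des$V
  mism <- rowSums(R) / des$n
  mism[!des$valid] <- Inf
  i <- which.min(mism)
  list(offset_um = unname(des$grid[i, "offset"]),
       stretch = unname(des$grid[i, "stretch"]),
       mismatch = mism[i],
       z_um = des$ref_z_um + unname(des$grid[i, "offset"]),
       n_overlap = des$n[i])
}

#' Fit the cell template to a z-profile
#'
#' Exhaustive grid search over axial translation and limited linear stretch,
#' minimizing the mean absolute difference between the profile and the
#' translated/stretched, affine-gain-matched template (see [zfit]). The grid
#' search is deterministic and immune to local minima; ties resolve to the
#' smallest offset, then smallest stretch.
#'
#' @param profile a [zprofile()] (the measured column).
#' @param template a [zprofile()] (the cell template); must share `dz` with
#'   `profile` and have nonzero variance.
#' @param offset_step_um grid resolution of the translation search (um);
#'   default `dz / 20` (0.25 um at dz = 5 um); must be at most `dz / 10`.
#' @param stretch_limits numeric `(lo, hi)` bounds of the linear stretch
#'   factor (default `c(0.9, 1.1)`).
#' @param stretch_step spacing of the stretch grid (default 0.05, giving
#'   `{0.9, 0.95, 1, 1.05, 1.1}` at the default limits).
#' @param ref_z_um reference z of the template (um); defaults to the
#'   midpoint of the template's z-range. The fitted `z_um` equals
#'   `ref_z_um + offset_um`.
#' @param min_overlap minimum number of profile samples the translated
#'   template must still cover (default `max(4, ceiling(nz / 2))`).
#' @return list of class `zfit` with `offset_um`, `stretch`, `mismatch`
#'   (mean absolute residual at the optimum), `z_um`, `n_overlap`.
#' @export
fit_profile <- function(profile, template, offset_step_um = NULL,
                        stretch_limits = c(0.9, 1.1), stretch_step = 0.05,
                        ref_z_um = NULL, min_overlap = NULL) {
  stopifnot(inherits(profile, "zprofile"), inherits(template, "zprofile"))
  if (abs(profile$dz_um - template$dz_um) > 1e-9)
    stop("profile and template must share dz")
  dz <- profile$dz_um
  if (is.null(offset_step_um)) offset_step_um <- dz / 20
  if (offset_step_um > dz / 10 + 1e-12)
    stop("offset grid resolution must be at most dz / 10")
  if (stretch_limits[1L] <= 0 || stretch_limits[2L] < stretch_limits[1L])
    stop("invalid stretch limits")
  stretches <- seq(stretch_limits[1L], stretch_limits[2L], by = stretch_step)
  if (is.null(ref_z_um)) {
    tz <- profile_z_um(template)
    ref_z_um <- (tz[1L] + tz[length(tz)]) / 2
  }
  nz <- length(profile$values)
  if (is.null(min_overlap)) min_overlap <- max(4L, ceiling(nz / 2))
  des <- .zfit_design(template, profile_z_um(profile), offset_step_um,
                      stretches, ref_z_um, min_overlap)
  structure(.zfit_eval(des, profile$values), class = "zfit")
}

#' @export
print.zfit <- function(x, ...) {
  cat(sprintf("<zfit> z = %.3f um (offset %.3f, stretch %.2f), mismatch %.4g over %d samples\n",
              x$z_um, x$offset_um, x$stretch, x$mismatch, x$n_overlap))
  invisible(x)
}

#' Sub-voxel z-position of a detected cell
#'
#' Fits the cell template (see [fit_profile()]) to the z-profile of each of
#' the central `central_fraction` of the candidate's pixels (those nearest
#' the lateral centroid, in micrometers). Border pixels are excluded because
#' their z-signal is weak and orientation-distorted. The cell's z is the
#' median of the per-pixel fitted z values; the 95% confidence interval is
#' the empirical 2.5th-97.5th percentile range of those values.
#'
#' @param candidate a `cell_candidate` from [label_candidates()].
#' @param stack the [image_stack()] the candidate was detected in.
#' @param template the cell template, a [zprofile()].
#' @param central_fraction fraction of candidate pixels (nearest the
#'   centroid) used (default 0.5). Candidates smaller than 4 pixels fall
#'   back to all pixels (with a message).
#' @param background optional background template ([zprofile()], same grid).
#'   When given, it is subtracted from both the cell template and each pixel
#'   profile before fitting. This removes the static axial illumination
#'   structure, which otherwise biases the fitted translation toward the
#'   template's own position (the illumination does not shift with the
#'   cell, so leaving it in rewards a zero offset).
#' @param ref_z_um,offset_step_um,stretch_limits,stretch_step,min_overlap
#'   passed to the fit; see [fit_profile()].
#' @return list of class `z_estimate` with `z_um`, `ci95_um` (length-2),
#'   `n_voxels_used`, and `z_values` (the per-pixel fits, for diagnostics).
#' @export
cell_z <- function(candidate, stack, template, central_fraction = 0.5,
                   background = NULL, ref_z_um = NULL, offset_step_um = NULL,
                   stretch_limits = c(0.9, 1.1), stretch_step = 0.05,
                   min_overlap = NULL) {
  stopifnot(inherits(candidate, "cell_candidate"), inherits(stack, "image_stack"),
            inherits(template, "zprofile"))
  if (central_fraction <= 0 || central_fraction > 1)
    stop("'central_fraction' must be in (0, 1]")
  px <- candidate$pixels
  n <- nrow(px)
  if (n == 0L) stop("empty candidate")
  dx <- stack$voxel_size_um[1L]; dy <- stack$voxel_size_um[2L]
  dz <- stack$voxel_size_um[3L]
  if (n < 4L) {
    message("candidate smaller than 4 pixels: using all pixels for the z-fit")
    sel <- seq_len(n)
  } else {
    d2 <- ((px[, 1L] - 0.5) * dx - candidate$centroid_xy_um[1L])^2 +
      ((px[, 2L] - 0.5) * dy - candidate$centroid_xy_um[2L])^2
    k <- max(1L, ceiling(central_fraction * n))
    sel <- order(d2)[seq_len(k)]
  }
  if (is.null(offset_step_um)) offset_step_um <- dz / 20
  if (is.null(ref_z_um)) {
    tz <- profile_z_um(template)
    ref_z_um <- (tz[1L] + tz[length(tz)]) / 2
  }
  nz <- dim(stack$data)[3L]
  if (is.null(min_overlap)) min_overlap <- max(4L, ceiling(nz / 2))
  stretches <- seq(stretch_limits[1L], stretch_limits[2L], by = stretch_step)
  zg <- z_centers_um(stack)
  bg <- if (!is.null(background)) {
    stopifnot(inherits(background, "zprofile"))
    if (length(background$values) != nz)
      stop("background template length does not match the stack")
    background$values
  } else rep(0, nz)
  fit_template <- zprofile(template$values - bg, template$dz_um,
                           template$origin_z_um)
  des <- .zfit_design(fit_template, zg, offset_step_um, stretches, ref_z_um,
                      min_overlap)
  zv <- vapply(sel, function(i) {
    .zfit_eval(des, stack$data[px[i, 1L], px[i, 2L], ] - bg)$z_um
  }, 0)
  ci <- unname(stats::quantile(zv, c(0.025, 0.975), type = 7L))
  structure(list(z_um = stats::median(zv), ci95_um = ci,
                 n_voxels_used = length(sel), z_values = zv),
            class = "z_estimate")
}

#' @export
print.z_estimate <- function(x, ...) {
  cat(sprintf("<z_estimate> z = %.3f um, 95%% CI [%.3f, %.3f], %d voxel(s)\n",
              x$z_um, x$ci95_um[1L], x$ci95_um[2L], x$n_voxels_used))
  invisible(x)
}
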